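#' Build the cuboidal node lattice
#'
#' The depth axis x (index i) runs from the skin surface (i = 0) into the
#' head; the lateral axes y (j) and z (k) are centred on the cloth patch, so
#' j and k run over -ny/2 .. ny/2. Node spacing is uniform along all axes.
#'
#' @param L,H,W Depth, height, width of the domain (m); each must be an
#'   integer multiple of `h`.
#' @param h Node spacing (m), > 0.
#' @return An object of class `grid3d` with fields `h`, `nx`, `ny`, `nz`,
#'   `L`, `H`, `W` and the index vectors `i`, `j`, `k`.
#' @examples
#' g <- build_grid(L = 8e-3, H = 8e-3, W = 8e-3, h = 2e-3)
#' g$nx # 4 subintervals -> 27 interior unknowns, 64 cells
#' @export
build_grid <- function(L, H, W, h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("build_grid: h must be a single positive number", call. = FALSE)
  }
  n_of <- function(len, axis) {
    n <- len / h
    if (abs(n - round(n)) > 1e-9 * max(1, n)) {
      stop("build_grid: length along ", axis, " (", len,
           " m) is not an integer multiple of h = ", h, " m", call. = FALSE)
    }
    as.integer(round(n))
  }
  nx <- n_of(L, "x"); ny <- n_of(H, "y"); nz <- n_of(W, "z")
  if (nx < 2L) stop("build_grid: need at least 2 subintervals along x", call. = FALSE)
  if (ny < 2L || ny %% 2L != 0L) stop("build_grid: ny must be even and >= 2", call. = FALSE)
  if (nz < 2L || nz %% 2L != 0L) stop("build_grid: nz must be even and >= 2", call. = FALSE)
  structure(list(
    h = h, nx = nx, ny = ny, nz = nz, L = L, H = H, W = W,
    i = 0:nx, j = seq.int(-ny %/% 2L, ny %/% 2L), k = seq.int(-nz %/% 2L, nz %/% 2L)
  ), class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d nodes (h = %g mm), %d cells, %d interior unknowns\n",
              x$nx + 1L, x$ny + 1L, x$nz + 1L, x$h * 1e3,
              x$nx * x$ny * x$nz, (x$nx - 1L) * (x$ny - 1L) * (x$nz - 1L)))
  invisible(x)
}

#' All nodes of a grid as a table
#'
#' @param grid A [build_grid()] lattice.
#' @return `data.frame` with columns `i`, `j`, `k` (indices) and `x`, `y`,
#'   `z` (coordinates in m); row order matches the internal array layout
#'   (i fastest).
#' @export
grid_nodes <- function(grid) {
  g <- expand.grid(i = grid$i, j = grid$j, k = grid$k, KEEP.OUT.ATTRS = FALSE)
  g$x <- g$i * grid$h
  g$y <- g$j * grid$h
  g$z <- g$k * grid$h
  g
}

# 1-based array subscripts for signed node indices
node_sub <- function(grid, i, j, k) {
  cbind(i + 1L, j + grid$ny %/% 2L + 1L, k + grid$nz %/% 2L + 1L)
}

#' Layered structure of the forehead stack
#'
#' Layers are ordered by increasing depth and assigned by half-open depth
#' intervals (tie goes to the deeper layer; the final layer is closed at the
#' deep end). The scalp is optionally split at `scalp_split` into an outer
#' part with no metabolic heat and an inner part with the database value.
#'
#' @param thicknesses Named numeric vector of layer thicknesses (m) in
#'   depth order, e.g. `c(scalp = 4.5e-3, skull = 3.5e-3, csf = 2e-3)`.
#' @param scalp_split Depth (m) splitting outer from inner scalp; defaults
#'   to the scalp mid-thickness when a layer named `scalp` exists, `NULL`
#'   otherwise.
#' @param scalp_Qm_outer Metabolic rate of the outer scalp (W m-3).
#' @return An object of class `layer_field`.
#' @export
layer_field <- function(thicknesses = c(scalp = 4.5e-3, skull = 3.5e-3, csf = 2e-3),
                        scalp_split = NULL, scalp_Qm_outer = 0) {
  if (is.null(names(thicknesses)) || any(!nzchar(names(thicknesses)))) {
    stop("layer_field: thicknesses must be a named vector", call. = FALSE)
  }
  if (any(!is.finite(thicknesses)) || any(thicknesses <= 0)) {
    stop("layer_field: all thicknesses must be positive", call. = FALSE)
  }
  if (is.null(scalp_split) && "scalp" %in% names(thicknesses)) {
    scalp_split <- unname(thicknesses[["scalp"]]) / 2
  }
  structure(list(
    thicknesses = thicknesses,
    bounds = cumsum(unname(thicknesses)),
    names = names(thicknesses),
    total = sum(thicknesses),
    scalp_split = scalp_split,
    scalp_Qm_outer = scalp_Qm_outer
  ), class = "layer_field")
}

#' Layer id at a given depth
#'
#' @param x Depth below the surface (m); must lie in `[0, total thickness]`.
#' @param layers A [layer_field()].
#' @return Layer name (character scalar).
#' @examples
#' ly <- layer_field()
#' assign_layer(0, ly)       # "scalp"
#' assign_layer(4.5e-3, ly)  # boundary belongs to the deeper layer: "skull"
#' @export
assign_layer <- function(x, layers) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("assign_layer: x must be a single finite number", call. = FALSE)
  }
  tol <- 1e-12 * max(1, layers$total)
  if (x < -tol || x > layers$total + tol) {
    stop("assign_layer: depth ", x, " m outside the layer stack [0, ",
         layers$total, "]", call. = FALSE)
  }
  idx <- findInterval(x, layers$bounds, left.open = FALSE) + 1L
  if (idx > length(layers$names)) idx <- length(layers$names) # deep end closed
  layers$names[idx]
}
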