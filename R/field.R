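#' Nodal temperature field
#'
#' Thin container for temperatures (degrees C) on every node of a grid,
#' together with solve metadata.
#'
#' @param values Numeric array of dim `(nx+1, ny+1, nz+1)`.
#' @param cfg The [scenario_config()] the field belongs to.
#' @param meta List of solver metadata (residual norm, method, ...).
#' @param time Time point (s) for transient snapshots, `NA` for steady.
#' @return An object of class `temperature_field`.
#' @export
temperature_field <- function(values, cfg, meta = list(), time = NA_real_) {
  g <- cfg$grid
  stopifnot(identical(dim(values), as.integer(c(g$nx + 1L, g$ny + 1L, g$nz + 1L))))
  if (!all(is.finite(values))) {
    stop("temperature_field: non-finite temperatures", call. = FALSE)
  }
  structure(list(T = values, cfg = cfg, meta = meta, time = time),
            class = "temperature_field")
}

#' Read one node of a temperature field
#'
#' @param field A [temperature_field()].
#' @param i,j,k Node indices (i from 0 at the surface; j, k signed, centred).
#' @return Temperature in degrees C.
#' @export
field_at <- function(field, i, j, k) {
  g <- field$cfg$grid
  if (any(i < 0 | i > g$nx) || any(abs(j) > g$ny %/% 2L) || any(abs(k) > g$nz %/% 2L)) {
    stop("field_at: node (", i, ",", j, ",", k, ") outside the grid", call. = FALSE)
  }
  field$T[node_sub(g, as.integer(i), as.integer(j), as.integer(k))]
}

#' @export
as.data.frame.temperature_field <- function(x, ...) {
  g <- x$cfg$grid
  nodes <- grid_nodes(g)
  data.frame(
    i = nodes$i, j = nodes$j, k = nodes$k,
    x_mm = nodes$x * 1e3, y_mm = nodes$y * 1e3, z_mm = nodes$z * 1e3,
    layer = vapply(nodes$x, assign_layer, character(1), layers = x$cfg$layers),
    T_C = as.vector(x$T)
  )
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("temperature_field (%s%s): range %.2f .. %.2f C over %d nodes\n",
              x$cfg$name,
              if (is.na(x$time)) "" else sprintf(", t = %g s", x$time),
              min(x$T), max(x$T), length(x$T)))
  invisible(x)
}
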