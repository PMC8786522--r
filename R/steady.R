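# Steady-state seven-point-stencil system for the Pennes bioheat equation:
#   sum(6 neighbours) - (6 + h^2 w / k) T = -(h^2 / k)(w TA + Qm + Qe),
# with w = mb*cb and per-node layer constants. Dirichlet neighbours fold
# into the right-hand side; zero-flux lateral faces are eliminated by a
# zero-gradient copy of the adjacent interior node (so the unknowns are the
# interior nodes plus, in Robin mode, the surface plane); the Robin surface
# uses a central ghost node, k (T1 - Tghost)/(2h) = he (T0 - Tw).

# Resolve a node reference to an unknown column or a known constant.
# uidx: array of unknown column indices (NA where not an unknown).
resolve_node <- function(i, j, k, cfg, uidx) {
  g <- cfg$grid
  jm <- g$ny %/% 2L; km <- g$nz %/% 2L
  sh <- cfg$shared; b <- cfg$boundaries
  repeat {
    if (i == g$nx) {
      if (b$deep == "dirichlet") return(list(type = "c", val = sh$TA))
      i <- g$nx - 1L
      next
    }
    if (i == 0L && b$surface == "dirichlet") return(list(type = "c", val = sh$Tw))
    if (i >= 1L && abs(j) == jm) { j <- sign(j) * (jm - 1L); next }
    if (i >= 1L && abs(k) == km) { k <- sign(k) * (km - 1L); next }
    col <- uidx[node_sub(g, i, j, k)]
    if (is.na(col)) stop("internal: unresolved node (", i, ",", j, ",", k, ")")
    return(list(type = "u", col = col))
  }
}

#' Assemble the steady linear system M T = N
#'
#' Builds the sparse seven-point-stencil system for the interior unknowns
#' (plus the surface plane in Robin mode). Strict diagonal dominance holds
#' whenever the perfusion term mb*cb is positive.
#'
#' @param cfg A steady [scenario_config()].
#' @return An object of class `linear_system`: sparse matrix `M`, right-hand
#'   side `N`, and the unknown index table `unknowns` (columns `i, j, k`).
#' @export
assemble_steady <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  g <- cfg$grid
  jm <- g$ny %/% 2L; km <- g$nz %/% 2L
  sh <- cfg$shared; b <- cfg$boundaries
  h <- g$h; w <- sh$mb * sh$cb
  props <- node_props(cfg)
  if (any(props$k <= 0)) stop("assemble_steady: zero or negative conductivity", call. = FALSE)

  ji <- seq.int(-(jm - 1L), jm - 1L); ki <- seq.int(-(km - 1L), km - 1L)
  unknowns <- rbind(
    if (b$surface == "robin") expand.grid(i = 0L, j = g$j, k = g$k, KEEP.OUT.ATTRS = FALSE),
    expand.grid(i = seq_len(g$nx - 1L), j = ji, k = ki, KEEP.OUT.ATTRS = FALSE)
  )
  nu <- nrow(unknowns)
  uidx <- array(NA_integer_, dim = c(g$nx + 1L, g$ny + 1L, g$nz + 1L))
  uidx[node_sub(g, unknowns$i, unknowns$j, unknowns$k)] <- seq_len(nu)

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  N <- numeric(nu)
  add <- function(row, col, val) {
    ti[[length(ti) + 1L]] <<- row; tj[[length(tj) + 1L]] <<- col
    tv[[length(tv) + 1L]] <<- val
  }

  for (row in seq_len(nu)) {
    i <- unknowns$i[row]; j <- unknowns$j[row]; k <- unknowns$k[row]
    ku <- props$k[i + 1L]; Qm <- props$Qm[i + 1L]
    if (i == 0L && b$robin_order == 1L) {
      # one-sided Robin closure: (k/h + he) T0 - (k/h) T1 = he Tw
      add(row, row, ku / h + sh$he)
      nb <- resolve_node(1L, j, k, cfg, uidx)
      if (nb$type == "u") add(row, nb$col, -ku / h) else
        N[row] <- N[row] + (ku / h) * nb$val
      N[row] <- N[row] + sh$he * sh$Tw
      next
    }
    eta <- h^2 * w / ku
    diag <- -(6 + eta)
    rhs <- -(h^2 / ku) * (w * sh$TA + Qm + sh$Qe)
    nbrs <- list()
    if (i == 0L) { # Robin surface, central ghost eliminated
      nbrs[[1L]] <- list(c(1L, j, k), 2)
      diag <- diag - 2 * h * sh$he / ku
      rhs <- rhs - (2 * h * sh$he / ku) * sh$Tw
      lat <- list(c(0L, j - 1L, k), c(0L, j + 1L, k), c(0L, j, k - 1L), c(0L, j, k + 1L))
      for (n in lat) {
        # mirror ghost when the lateral neighbour falls outside the plane
        if (abs(n[2L]) > jm) n[2L] <- j - sign(n[2L] - j)
        if (abs(n[3L]) > km) n[3L] <- k - sign(n[3L] - k)
        nbrs[[length(nbrs) + 1L]] <- list(n, 1)
      }
    } else {
      for (n in list(c(i - 1L, j, k), c(i + 1L, j, k), c(i, j - 1L, k),
                     c(i, j + 1L, k), c(i, j, k - 1L), c(i, j, k + 1L))) {
        nbrs[[length(nbrs) + 1L]] <- list(n, 1)
      }
    }
    add(row, row, diag)
    for (nb in nbrs) {
      n <- nb[[1L]]; coef <- nb[[2L]]
      r <- resolve_node(n[1L], n[2L], n[3L], cfg, uidx)
      if (r$type == "u") add(row, r$col, coef) else rhs <- rhs - coef * r$val
    }
    N[row] <- rhs
  }

  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nu, nu))
  structure(list(M = M, N = N, unknowns = unknowns, cfg = cfg),
            class = "linear_system")
}

#' Solve the steady-state temperature field
#'
#' Direct sparse factorization of the system from [assemble_steady()], then
#' population of the full node lattice: Dirichlet planes take their clamped
#' values and lateral zero-flux faces copy the adjacent interior values.
#'
#' @param cfg A steady [scenario_config()].
#' @return A [temperature_field()]; `$meta` holds the relative residual
#'   norm, the solver label, and the unknown count.
#' @export
solve_steady <- function(cfg) {
  sys <- assemble_steady(cfg)
  sol <- tryCatch(as.numeric(Matrix::solve(sys$M, sys$N)),
                  error = function(e) stop("solve_steady: singular system (",
                                           conditionMessage(e), ")", call. = FALSE))
  res <- max(abs(sys$M %*% sol - sys$N))
  if (res > 1e-10 * max(1, max(abs(sys$N)))) {
    stop("solve_steady: residual ", res, " exceeds tolerance", call. = FALSE)
  }
  g <- cfg$grid
  arr <- array(NA_real_, dim = c(g$nx + 1L, g$ny + 1L, g$nz + 1L))
  arr[node_sub(g, sys$unknowns$i, sys$unknowns$j, sys$unknowns$k)] <- sol
  if (cfg$boundaries$surface == "dirichlet") arr[1L, , ] <- cfg$shared$Tw
  if (cfg$boundaries$deep == "dirichlet") arr[g$nx + 1L, , ] <- cfg$shared$TA
  # zero-flux lateral faces: copy the adjacent interior values
  irows <- seq.int(2L, g$nx) # i = 1 .. nx-1
  arr[irows, 1L, ] <- arr[irows, 2L, ]
  arr[irows, g$ny + 1L, ] <- arr[irows, g$ny, ]
  arr[irows, , 1L] <- arr[irows, , 2L]
  arr[irows, , g$nz + 1L] <- arr[irows, , g$nz]
  if (cfg$boundaries$deep == "neumann_zero") arr[g$nx + 1L, , ] <- arr[g$nx, , ]
  temperature_field(arr, cfg,
                    meta = list(residual = res, method = "sparse-LU",
                                n_unknowns = nrow(sys$unknowns)))
}

#' Maximum stencil residual of a field
#'
#' Evaluates every equation of the assembled steady system at the stored
#' nodal values and returns the largest absolute residual, in temperature
#' units (first-order Robin closure rows are rescaled by their diagonal so
#' all rows share the scale of the stencil equation).
#'
#' @param field A [temperature_field()].
#' @param cfg The matching steady [scenario_config()]; defaults to the
#'   field's own config.
#' @return Max absolute residual (degrees C).
#' @export
steady_residual <- function(field, cfg = field$cfg) {
  g <- cfg$grid
  if (!identical(dim(field$T), as.integer(c(g$nx + 1L, g$ny + 1L, g$nz + 1L)))) {
    stop("steady_residual: field and config grids do not match", call. = FALSE)
  }
  sys <- assemble_steady(cfg)
  tvals <- field$T[node_sub(g, sys$unknowns$i, sys$unknowns$j, sys$unknowns$k)]
  r <- as.numeric(sys$M %*% tvals - sys$N)
  if (cfg$boundaries$surface == "robin" && cfg$boundaries$robin_order == 1L) {
    surf <- sys$unknowns$i == 0L
    r[surf] <- r[surf] / (node_props(cfg)$k[1L] / g$h + cfg$shared$he)
  }
  max(abs(r))
}
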