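# Independent oracles: the 1D steady fin equation k T'' - w (T - TA) + Q = 0
# on a homogeneous slab has a closed cosh/sinh form; the 3D solver on a
# laterally insulated slab must degenerate to it.

#' One-dimensional homogeneous slab problem
#'
#' @param props [tissue_properties()] of the single material.
#' @param shared [shared_constants()].
#' @param L Slab depth (m), > 0.
#' @param surface `"robin"` (k T'(0) = he (T(0) - Tw)) or `"dirichlet"`
#'   (T(0) = Tw); the deep end is always Dirichlet at `TA`.
#' @return An object of class `slab_problem`.
#' @export
slab_problem <- function(props, shared, L, surface = c("robin", "dirichlet")) {
  surface <- match.arg(surface)
  stopifnot(inherits(props, "tissue_properties"), inherits(shared, "shared_constants"),
            L > 0)
  structure(list(props = props, shared = shared, L = L, surface = surface),
            class = "slab_problem")
}

#' Closed-form steady slab temperature
#'
#' For perfusion w = mb*cb > 0 the solution is
#' `T(x) = TA + Q/w + A cosh(m x) + B sinh(m x)` with `m = sqrt(w/k)` and
#' `Q = Qm + Qe`; A and B follow from a 2x2 solve of the end conditions
#' (Robin or Dirichlet at x = 0, Dirichlet `TA` at x = L). For w = 0 the
#' profile is the quadratic from direct integration.
#'
#' @param p A [slab_problem()].
#' @param x Depth(s) in `[0, L]` (m); vectorised.
#' @return Temperature(s) in degrees C.
#' @export
analytic_slab <- function(p, x) {
  if (any(x < -1e-12) || any(x > p$L + 1e-12)) {
    stop("analytic_slab: x outside [0, L]", call. = FALSE)
  }
  k <- p$props$k; Q <- p$props$Qm + p$shared$Qe
  w <- p$shared$mb * p$shared$cb
  TA <- p$shared$TA; Tw <- p$shared$Tw; he <- p$shared$he; L <- p$L
  if (w > 0) {
    m <- sqrt(w / k)
    # v = T - (TA + Q/w); v(L) = -Q/w; surface couples v(0), v'(0)
    vL <- -Q / w
    if (p$surface == "robin") {
      # he*A - k*m*B = -he*(TA + Q/w - Tw);  A cosh(mL) + B sinh(mL) = vL
      Mm <- rbind(c(he, -k * m), c(cosh(m * L), sinh(m * L)))
      rhs <- c(-he * (TA + Q / w - Tw), vL)
    } else {
      Mm <- rbind(c(1, 0), c(cosh(m * L), sinh(m * L)))
      rhs <- c(Tw - TA - Q / w, vL)
    }
    ab <- solve(Mm, rhs)
    TA + Q / w + ab[1] * cosh(m * x) + ab[2] * sinh(m * x)
  } else {
    # k T'' + Q = 0 -> T = -Q x^2 / (2k) + c1 x + c2
    if (p$surface == "robin") {
      # k c1 = he (c2 - Tw); T(L) = TA
      c2 <- (TA + Q * L^2 / (2 * k) + he * Tw * L / k) / (1 + he * L / k)
      c1 <- he * (c2 - Tw) / k
    } else {
      c2 <- Tw
      c1 <- (TA - Tw + Q * L^2 / (2 * k)) / L
    }
    -Q * x^2 / (2 * k) + c1 * x + c2
  }
}

#' Dense 1D finite-difference slab solve
#'
#' Brute-force cross-check of [analytic_slab()]: the same fin equation
#' discretised on `n` subintervals and solved densely, independent of the
#' 3D machinery.
#'
#' @param p A [slab_problem()].
#' @param n Number of subintervals (default 10000).
#' @return `data.frame` with columns `x` and `T_C`.
#' @export
fd_slab_1d <- function(p, n = 10000L) {
  k <- p$props$k; Q <- p$props$Qm + p$shared$Qe
  w <- p$shared$mb * p$shared$cb
  TA <- p$shared$TA; Tw <- p$shared$Tw; he <- p$shared$he
  h <- p$L / n
  x <- seq(0, p$L, length.out = n + 1L)
  # unknowns T_0 .. T_{n-1}; T_n = TA
  nu <- n
  M <- matrix(0, nu, nu); N <- numeric(nu)
  for (r in seq_len(nu)) {
    i <- r - 1L
    if (i == 0L) {
      if (p$surface == "dirichlet") { M[r, r] <- 1; N[r] <- Tw; next }
      # Robin with central ghost: T(-1) = T(1) - (2h he/k)(T0 - Tw)
      M[r, r] <- -(2 + h^2 * w / k + 2 * h * he / k)
      M[r, r + 1L] <- 2
      N[r] <- -h^2 / k * (w * TA + Q) - (2 * h * he / k) * Tw
      next
    }
    M[r, r] <- -(2 + h^2 * w / k)
    M[r, r - 1L] <- 1
    if (r + 1L <= nu) M[r, r + 1L] <- 1 else N[r] <- -TA
    N[r] <- N[r] - h^2 / k * (w * TA + Q)
  }
  sol <- solve(M, N)
  data.frame(x = x, T_C = c(sol, TA))
}

#' Observed spatial convergence order against the slab oracle
#'
#' Solves the 3D steady system on laterally thin slab grids at each spacing
#' in `h_list`, measures the max absolute error against [analytic_slab()]
#' along the depth axis, and reports log2 ratios of successive errors
#' (expected about 2 for the central/ghost-node discretisation, about 1
#' with the one-sided Robin closure).
#'
#' @param p A [slab_problem()].
#' @param h_list Decreasing spacings (m), each dividing `L`; at least 3.
#' @param robin_order Passed to the slab scenario (2 or 1).
#' @return List with `h`, `errors`, `orders`, `estimate`, and `exact`
#'   (`TRUE` when all errors sit at direct-solver round-off, below 1e-10,
#'   and no order is meaningful).
#' @export
convergence_order <- function(p, h_list, robin_order = 2L) {
  if (length(h_list) < 3L) {
    stop("convergence_order: need at least 3 spacings", call. = FALSE)
  }
  if (any(diff(h_list) >= 0)) {
    stop("convergence_order: h_list must be strictly decreasing", call. = FALSE)
  }
  for (h in h_list) {
    if (abs(p$L / h - round(p$L / h)) > 1e-9) {
      stop("convergence_order: spacing ", h, " does not divide L = ", p$L,
           call. = FALSE)
    }
  }
  errors <- vapply(h_list, function(h) {
    cfg <- slab_scenario(p$props, p$shared, L = p$L, h = h,
                         surface = p$surface, robin_order = robin_order)
    fld <- solve_steady(cfg)
    xs <- cfg$grid$i * h
    num <- vapply(cfg$grid$i, function(i) field_at(fld, i, 0L, 0L), numeric(1))
    max(abs(num - analytic_slab(p, xs)))
  }, numeric(1))
  if (all(errors < 1e-10)) {
    return(list(h = h_list, errors = errors, orders = NULL, estimate = NA_real_,
                exact = TRUE))
  }
  orders <- log(errors[-length(errors)] / errors[-1]) /
    log(h_list[-length(h_list)] / h_list[-1])
  list(h = h_list, errors = errors, orders = orders,
       estimate = mean(orders), exact = FALSE)
}
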