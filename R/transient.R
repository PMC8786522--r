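# Explicit forward-time centred-space marching of the bioheat equation:
#   T{n+1} = T{n} + (dt / rho c) [ k (sum of 6 neighbours - 6 T)/h^2
#                                  + mb cb (TA - T) + Qm + Qe ],
# with ghost-node boundary handling matching the steady solver: central
# mirror ghosts on zero-flux faces, Robin ghost at the skin surface,
# clamped Dirichlet planes. Conditionally stable; dt must not exceed
# rho c h^2 / (6 k + h^2 mb cb) in the most restrictive layer.

#' Explicit stability limit of a configuration
#'
#' Largest time step keeping the explicit update's self-coefficient
#' non-negative: the minimum over depth nodes of
#' `rho c h^2 / (6 k + h^2 mb cb)`.
#'
#' @param cfg A [scenario_config()].
#' @return `dt_max` in seconds.
#' @examples
#' stability_limit(preset_scenario("case1_38C", mode = "transient")) # skull-bound
#' @export
stability_limit <- function(cfg) {
  p <- node_props(cfg)
  w <- cfg$shared$mb * cfg$shared$cb
  h <- cfg$grid$h
  min(p$rc * h^2 / (6 * p$k + h^2 * w))
}

#' Explicit update weights at a given step size
#'
#' Diagnostic for the positivity of the FTCS update viewed as a weighted
#' average: per depth node, the weight on the node itself, on each
#' neighbour, and on the arterial temperature. The surface row includes the
#' Robin exchange term when the surface is Robin-coupled.
#'
#' @param cfg A [scenario_config()].
#' @param dt Time step (s).
#' @return `data.frame` with columns `i`, `self`, `neighbour`, `arterial`.
#' @export
update_weights <- function(cfg, dt) {
  p <- node_props(cfg)
  sh <- cfg$shared
  w <- sh$mb * sh$cb
  h <- cfg$grid$h
  extra <- ifelse(p$i == 0L & cfg$boundaries$surface == "robin", 2 * sh$he / h, 0)
  data.frame(
    i = p$i,
    self = 1 - dt * (6 * p$k / h^2 + w + extra) / p$rc,
    neighbour = dt * p$k / (h^2 * p$rc),
    arterial = dt * w / p$rc
  )
}

# Property arrays broadcast over the lattice (depth-dependent only).
prop_arrays <- function(cfg) {
  g <- cfg$grid
  p <- node_props(cfg)
  d <- c(g$nx + 1L, g$ny + 1L, g$nz + 1L)
  list(k = array(p$k, dim = d), rc = array(p$rc, dim = d),
       Qm = array(p$Qm, dim = d))
}

#' Transient marching state
#'
#' @param field A [temperature_field()] giving the current temperatures.
#' @param t Current time (s).
#' @param step Step counter.
#' @param dt_used Last substep size (s).
#' @return An object of class `transient_state`.
#' @export
transient_state <- function(field, t = 0, step = 0L, dt_used = NA_real_) {
  stopifnot(inherits(field, "temperature_field"), t >= 0)
  structure(list(field = field, t = t, step = step, dt_used = dt_used),
            class = "transient_state")
}

#' One explicit FTCS step
#'
#' Updates every non-Dirichlet node; Dirichlet planes are left unchanged.
#' Refuses a step size above the stability limit.
#'
#' @param state A [transient_state()].
#' @param dt Step size (s); must satisfy `dt <= stability_limit(cfg)`.
#' @param cfg The [scenario_config()]; defaults to the state's config.
#' @return The advanced [transient_state()].
#' @export
ftcs_step <- function(state, dt, cfg = state$field$cfg) {
  limit <- stability_limit(cfg)
  if (dt > limit * (1 + 1e-12)) {
    stop("ftcs_step: dt = ", dt, " s exceeds the explicit stability limit ",
         signif(limit, 6), " s; refusing to step", call. = FALSE)
  }
  g <- cfg$grid; sh <- cfg$shared; b <- cfg$boundaries
  h <- g$h; w <- sh$mb * sh$cb
  Tc <- state$field$T
  pa <- prop_arrays(cfg)
  d <- dim(Tc)

  # padded array with ghost planes
  P <- array(NA_real_, dim = d + 2L)
  P[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- Tc
  # lateral zero-flux: central mirror ghosts
  P[, 1L, ] <- P[, 3L, ]; P[, d[2] + 2L, ] <- P[, d[2], ]
  P[, , 1L] <- P[, , 3L]; P[, , d[3] + 2L] <- P[, , d[3]]
  # skin-surface ghost (i = -1)
  if (b$surface == "robin") {
    k0 <- pa$k[1L, 1L, 1L]
    P[1L, 2:(d[2] + 1L), 2:(d[3] + 1L)] <-
      Tc[2L, , ] - (2 * h * sh$he / k0) * (Tc[1L, , ] - sh$Tw)
  } else {
    P[1L, 2:(d[2] + 1L), 2:(d[3] + 1L)] <- Tc[2L, , ] # mirror; plane re-clamped below
  }
  # deep ghost (i = nx + 1); only used when the deep face is zero-flux
  P[d[1] + 2L, 2:(d[2] + 1L), 2:(d[3] + 1L)] <- Tc[d[1] - 1L, , ]

  ii <- 2:(d[1] + 1L); jj <- 2:(d[2] + 1L); kk <- 2:(d[3] + 1L)
  # per-axis pairing keeps the sum bitwise invariant under j/k mirroring,
  # so symmetric states stay symmetric exactly
  sum6 <- (P[ii - 1L, jj, kk] + P[ii + 1L, jj, kk]) +
    (P[ii, jj - 1L, kk] + P[ii, jj + 1L, kk]) +
    (P[ii, jj, kk - 1L] + P[ii, jj, kk + 1L])
  Tn <- Tc + (dt / pa$rc) *
    (pa$k * (sum6 - 6 * Tc) / h^2 + w * (sh$TA - Tc) + pa$Qm + sh$Qe)
  if (b$surface == "dirichlet") Tn[1L, , ] <- Tc[1L, , ]
  if (b$deep == "dirichlet") Tn[d[1], , ] <- Tc[d[1], , ]

  transient_state(
    temperature_field(Tn, cfg, meta = state$field$meta, time = state$t + dt),
    t = state$t + dt, step = state$step + 1L, dt_used = dt
  )
}

# One backward-Euler step: (rc/dt) T' - L[T'] = (rc/dt) T + sources, with
# the same ghost conventions as ftcs_step. Unconditionally stable.
implicit_step <- function(state, dt, cfg = state$field$cfg) {
  g <- cfg$grid; sh <- cfg$shared; b <- cfg$boundaries
  h <- g$h; w <- sh$mb * sh$cb
  p <- node_props(cfg)
  Tc <- state$field$T
  d <- dim(Tc)

  nodes <- grid_nodes(g)
  clamped_deep <- b$deep == "dirichlet" & nodes$i == g$nx
  clamped_surf <- b$surface == "dirichlet" & nodes$i == 0L
  unknown <- !(clamped_deep | clamped_surf)
  uidx <- array(NA_integer_, dim = d)
  uidx[cbind(nodes$i + 1L, nodes$j + g$ny %/% 2L + 1L, nodes$k + g$nz %/% 2L + 1L)[unknown, , drop = FALSE]] <-
    seq_len(sum(unknown))
  un <- nodes[unknown, c("i", "j", "k")]
  nu <- nrow(un)
  jm <- g$ny %/% 2L; km <- g$nz %/% 2L

  # mirror-ghost resolution (central mirrors on every zero-flux face)
  resolve <- function(i, j, k, at) {
    if (abs(j) > jm) j <- 2L * at[2L] - j
    if (abs(k) > km) k <- 2L * at[3L] - k
    if (i > g$nx) i <- 2L * at[1L] - i # deep mirror (zero-flux deep face)
    if (i == g$nx && b$deep == "dirichlet") return(list(type = "c", val = sh$TA))
    if (i == 0L && b$surface == "dirichlet") return(list(type = "c", val = sh$Tw))
    list(type = "u", col = uidx[node_sub(g, i, j, k)])
  }

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  N <- numeric(nu)
  for (row in seq_len(nu)) {
    i <- un$i[row]; j <- un$j[row]; k <- un$k[row]
    ku <- p$k[i + 1L]; rc <- p$rc[i + 1L]; Qm <- p$Qm[i + 1L]
    diag <- rc / dt + 6 * ku / h^2 + w
    rhs <- rc / dt * Tc[node_sub(g, i, j, k)] + w * sh$TA + Qm + sh$Qe
    nbrs <- list(c(i - 1L, j, k), c(i + 1L, j, k), c(i, j - 1L, k),
                 c(i, j + 1L, k), c(i, j, k - 1L), c(i, j, k + 1L))
    for (n in nbrs) {
      coef <- ku / h^2
      if (n[1L] < 0L) { # surface Robin ghost substitution
        diag <- diag + coef * (2 * h * sh$he / ku)
        rhs <- rhs + coef * (2 * h * sh$he / ku) * sh$Tw
        n <- c(1L, j, k)
      }
      r <- resolve(n[1L], n[2L], n[3L], c(i, j, k))
      if (r$type == "u") {
        ti[[length(ti) + 1L]] <- row; tj[[length(tj) + 1L]] <- r$col
        tv[[length(tv) + 1L]] <- -coef
      } else rhs <- rhs + coef * r$val
    }
    ti[[length(ti) + 1L]] <- row; tj[[length(tj) + 1L]] <- row
    tv[[length(tv) + 1L]] <- diag
    N[row] <- rhs
  }
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nu, nu))
  sol <- as.numeric(Matrix::solve(M, N))
  Tn <- Tc
  Tn[node_sub(g, un$i, un$j, un$k)] <- sol
  transient_state(
    temperature_field(Tn, cfg, meta = state$field$meta, time = state$t + dt),
    t = state$t + dt, step = state$step + 1L, dt_used = dt
  )
}

#' Initial temperature field for a transient run
#'
#' Surface plane at the cloth temperature, deep plane at the arterial
#' temperature, interior per the config's `init` choice (depth-linear
#' between the two by default).
#'
#' @param cfg A transient-capable [scenario_config()].
#' @return A [temperature_field()] at t = 0.
#' @export
initial_field <- function(cfg) {
  g <- cfg$grid; sh <- cfg$shared
  prof <- switch(cfg$init,
    linear = sh$Tw + (sh$TA - sh$Tw) * (g$i / g$nx),
    uniform_arterial = rep(sh$TA, g$nx + 1L),
    uniform_body = rep(37, g$nx + 1L)
  )
  prof[1L] <- sh$Tw
  prof[g$nx + 1L] <- sh$TA
  arr <- array(prof, dim = c(g$nx + 1L, g$ny + 1L, g$nz + 1L))
  temperature_field(arr, cfg, meta = list(method = "initial"), time = 0)
}

#' March a scenario in time
#'
#' Integrates with internal substepping at `safety_factor` times the
#' explicit stability limit (or at `dt` for the backward-Euler method),
#' shortening the final substep of each span so that output times and
#' cloth-reset ticks are hit exactly. Snapshots are captured before the
#' reset is applied, so a reading that coincides with a reset tick shows
#' the rewarmed skin.
#'
#' @param cfg A transient [scenario_config()].
#' @param t_end End time (s); defaults to the schedule's `t_end`.
#' @param output_times Capture times (s), sorted, within `[0, t_end]`;
#'   defaults to multiples of the schedule's `output_interval`.
#' @param method `"ftcs"` (explicit, stability-guarded) or
#'   `"backward_euler"` (unconditionally stable).
#' @param dt Substep size for `"backward_euler"`; default 10 s.
#' @return An object of class `transient_result`: list with `fields` (one
#'   [temperature_field()] per output time) and `times`.
#' @export
run_transient <- function(cfg, t_end = NULL, output_times = NULL,
                          method = c("ftcs", "backward_euler"), dt = 10) {
  method <- match.arg(method)
  if (is.null(cfg$schedule) && (is.null(t_end) || is.null(output_times))) {
    stop("run_transient: no schedule in the config and no explicit t_end/output_times",
         call. = FALSE)
  }
  if (is.null(t_end)) t_end <- cfg$schedule$t_end
  if (is.null(output_times)) {
    output_times <- seq(cfg$schedule$output_interval, t_end,
                        by = cfg$schedule$output_interval)
  }
  if (length(output_times) == 0L) {
    stop("run_transient: empty output schedule", call. = FALSE)
  }
  output_times <- sort(unique(output_times))
  if (any(output_times < 0) || any(output_times > t_end + 1e-9)) {
    stop("run_transient: output times must lie in [0, t_end]", call. = FALSE)
  }
  resets <- if (!is.null(cfg$schedule$reset_interval)) {
    seq(cfg$schedule$reset_interval, t_end, by = cfg$schedule$reset_interval)
  } else numeric(0)

  dt_target <- if (method == "ftcs") cfg$safety_factor * stability_limit(cfg) else dt
  stepper <- if (method == "ftcs") ftcs_step else implicit_step

  state <- transient_state(initial_field(cfg))
  fields <- list()
  if (any(abs(output_times - 0) < 1e-9)) fields[[length(fields) + 1L]] <- state$field
  events <- sort(unique(round(c(output_times, resets, t_end), 9)))
  events <- events[events > 1e-9]
  for (te in events) {
    span <- te - state$t
    if (span > 1e-9) {
      nsub <- max(1L, ceiling(span / dt_target - 1e-9))
      dts <- span / nsub
      for (s in seq_len(nsub)) state <- stepper(state, dts, cfg)
      state$t <- te # guard against roundoff drift
    }
    if (any(abs(output_times - te) < 1e-9)) {
      f <- state$field; f$time <- te
      fields[[length(fields) + 1L]] <- f
    }
    if (any(abs(resets - te) < 1e-9) &&
        cfg$reset_action == "clamp_surface_dirichlet" &&
        cfg$boundaries$surface != "dirichlet") {
      state$field$T[1L, , ] <- cfg$shared$Tw
    }
  }
  structure(list(fields = fields,
                 times = vapply(fields, `[[`, numeric(1), "time"),
                 cfg = cfg, method = method),
            class = "transient_result")
}

#' @export
print.transient_result <- function(x, ...) {
  cat(sprintf("transient_result (%s, %s): %d snapshots at t = %s s\n",
              x$cfg$name, x$method, length(x$fields),
              paste(x$times, collapse = ", ")))
  invisible(x)
}

#' Extract the cooling curve at one node
#'
#' @param result A [run_transient()] result (or plain list of
#'   [temperature_field()]s).
#' @param node Integer vector `c(i, j, k)`.
#' @return `data.frame` with columns `t_s` and `T_C`.
#' @export
cooling_curve <- function(result, node) {
  fields <- if (inherits(result, "transient_result")) result$fields else result
  data.frame(
    t_s = vapply(fields, `[[`, numeric(1), "time"),
    T_C = vapply(fields, function(f) field_at(f, node[1L], node[2L], node[3L]),
                 numeric(1))
  )
}
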