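# Shared builders for test scenarios, plus an independent dense solver used
# as the brute-force oracle for the sparse steady path.

# Homogeneous cubic box, paper-sized lattice by default.
box_config <- function(props = tissue_properties(k = 0.5, rho = 1000, c = 3000, Qm = 0),
                       shared = shared_constants(mb = 0, TA = 38, Tw = 7, he = 100),
                       surface = "robin", deep = "dirichlet",
                       L = 8e-3, h = 2e-3, n_lat = NULL) {
  HW <- if (is.null(n_lat)) L else n_lat * h
  scenario_config(
    grid = build_grid(L = L, H = HW, W = HW, h = h),
    layers = layer_field(thicknesses = c(tissue = L)),
    materials = list(tissue = props),
    shared = shared,
    boundaries = boundary_spec(surface = surface, deep = deep),
    mode = "steady", name = "box"
  )
}

# Random admissible configuration; caller controls the RNG seed.
random_config <- function(surface = sample(c("robin", "dirichlet"), 1),
                          mb = stats::runif(1, 0, 0.01),
                          Qm = stats::runif(1, 0, 2000)) {
  box_config(
    props = tissue_properties(k = stats::runif(1, 0.2, 0.7),
                              rho = stats::runif(1, 800, 1600),
                              c = stats::runif(1, 1500, 4000),
                              Qm = Qm),
    shared = shared_constants(mb = mb, cb = 4010,
                              TA = stats::runif(1, 37, 41),
                              Tw = stats::runif(1, 4, 15),
                              he = stats::runif(1, 10, 500)),
    surface = surface
  )
}

# Independent dense enumeration of the steady equations: plain nested loops
# over interior (+ Robin surface) unknowns, explicit if-chains for every
# boundary fold, base-R solve(). Deliberately avoids the package's sparse
# assembly helpers.
brute_force_steady <- function(cfg) {
  g <- cfg$grid; sh <- cfg$shared; b <- cfg$boundaries
  stopifnot(b$robin_order == 2L)
  jm <- g$ny %/% 2L; km <- g$nz %/% 2L
  h <- g$h; w <- sh$mb * sh$cb
  props <- lapply(g$i, function(i) {
    layer <- assign_layer(i * h, cfg$layers)
    lookup_properties(layer, i * h, cfg$layers, cfg$materials)
  })

  unk <- list()
  if (b$surface == "robin") {
    for (kk in -km:km) for (jj in -jm:jm) unk[[length(unk) + 1L]] <- c(0L, jj, kk)
  }
  for (kk in (-km + 1L):(km - 1L)) for (jj in (-jm + 1L):(jm - 1L))
    for (ii in 1:(g$nx - 1L)) unk[[length(unk) + 1L]] <- c(ii, jj, kk)
  nu <- length(unk)
  id <- function(n) {
    for (r in seq_len(nu)) if (all(unk[[r]] == n)) return(r)
    NA_integer_
  }
  # value of a referenced node: column index (unknown) or known constant
  place <- function(n) {
    ii <- n[1L]; jj <- n[2L]; kk <- n[3L]
    while (TRUE) {
      if (ii == g$nx) {
        if (b$deep == "dirichlet") return(list(val = sh$TA))
        ii <- g$nx - 1L; next
      }
      if (ii == 0L && b$surface == "dirichlet") return(list(val = sh$Tw))
      if (ii >= 1L && abs(jj) == jm) { jj <- sign(jj) * (jm - 1L); next }
      if (ii >= 1L && abs(kk) == km) { kk <- sign(kk) * (km - 1L); next }
      return(list(col = id(c(ii, jj, kk))))
    }
  }

  M <- matrix(0, nu, nu); N <- numeric(nu)
  for (r in seq_len(nu)) {
    n <- unk[[r]]; ii <- n[1L]; jj <- n[2L]; kk <- n[3L]
    p <- props[[ii + 1L]]
    eta <- h^2 * w / p$k
    M[r, r] <- M[r, r] - (6 + eta)
    N[r] <- -(h^2 / p$k) * (w * sh$TA + p$Qm + sh$Qe)
    nbrs <- list()
    if (ii == 0L) {
      nbrs[[1L]] <- list(c(1L, jj, kk), 2)
      M[r, r] <- M[r, r] - 2 * h * sh$he / p$k
      N[r] <- N[r] - (2 * h * sh$he / p$k) * sh$Tw
      for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
        nj <- jj + d[1L]; nk <- kk + d[2L]
        if (abs(nj) > jm) nj <- jj - d[1L]
        if (abs(nk) > km) nk <- kk - d[2L]
        nbrs[[length(nbrs) + 1L]] <- list(c(0L, nj, nk), 1)
      }
    } else {
      for (d in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                     c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        nbrs[[length(nbrs) + 1L]] <- list(c(ii + d[1L], jj + d[2L], kk + d[3L]), 1)
      }
    }
    for (nb in nbrs) {
      pl <- place(nb[[1L]])
      if (!is.null(pl$col)) M[r, pl$col] <- M[r, pl$col] + nb[[2L]]
      else N[r] <- N[r] - nb[[2L]] * pl$val
    }
  }
  sol <- solve(M, N)
  list(unknowns = do.call(rbind, unk), values = sol)
}
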