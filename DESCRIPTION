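Package: bioheat3d
Title: Three-Dimensional Pennes Bioheat Simulation of Tepid-Sponge Cooling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finite-difference simulation of heat transfer through the
    scalp, skull, and cerebrospinal-fluid layers of the forehead while a
    cool wet cloth is held against the skin (tepid sponging for fever).
    Solves the Pennes bioheat equation on a cuboidal node lattice with a
    seven-point stencil: a sparse direct steady-state solver and a
    stability-guarded explicit (forward-time centred-space) transient
    solver with a periodic cloth-reset schedule, plus an unconditionally
    stable backward-Euler stepper. Robin, Dirichlet, and zero-flux
    boundary handling via ghost nodes; a material database for the three
    tissue layers; closed-form one-dimensional fin-equation oracles,
    grid-convergence measurement, discrete maximum-principle audits, and
    comparison tooling against published reference temperature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
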