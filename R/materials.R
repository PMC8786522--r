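#' Thermal properties of a tissue layer
#'
#' Bundle the four per-layer constants of the Pennes bioheat equation:
#' conductivity, density, specific heat capacity, and volumetric metabolic
#' heat generation.
#'
#' @param k Thermal conductivity (W m-1 K-1), > 0.
#' @param rho Density (kg m-3), > 0.
#' @param c Specific heat capacity (J kg-1 K-1), > 0.
#' @param Qm Metabolic heat generation (W m-3), >= 0.
#' @return An object of class `tissue_properties`.
#' @examples
#' tissue_properties(k = 0.342, rho = 1070, c = 3600, Qm = 1800)
#' @export
tissue_properties <- function(k, rho, c, Qm = 0) {
  for (nm in c("k", "rho", "c", "Qm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("tissue_properties: '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (k <= 0) stop("tissue_properties: k must be > 0", call. = FALSE)
  if (rho <= 0) stop("tissue_properties: rho must be > 0", call. = FALSE)
  if (c <= 0) stop("tissue_properties: c must be > 0", call. = FALSE)
  if (Qm < 0) stop("tissue_properties: Qm must be >= 0", call. = FALSE)
  structure(list(k = k, rho = rho, c = c, Qm = Qm), class = "tissue_properties")
}

#' Constants shared across all layers
#'
#' Blood perfusion and boundary-exchange constants: perfusion exchanges heat
#' between tissue and arterial blood at temperature `TA` (the fever
#' temperature in this model); the wet cloth at `Tw` acts at the skin surface
#' through the heat-transfer coefficient `he`.
#'
#' @param mb Blood perfusion rate (kg m-3 s-1), >= 0.
#' @param cb Specific heat of blood (J kg-1 K-1), > 0.
#' @param TA Arterial (fever) temperature (degrees C).
#' @param Qe External volumetric source (W m-3); 0 by default, the cloth
#'   acts through the surface boundary condition.
#' @param he Surface heat-transfer coefficient (W m-2 K-1), >= 0.
#' @param Tw Wet-cloth temperature (degrees C).
#' @return An object of class `shared_constants`.
#' @export
shared_constants <- function(mb = 6.06e-3, cb = 4010, TA = 38, Qe = 0,
                             he = 0.64, Tw = 7) {
  for (nm in c("mb", "cb", "TA", "Qe", "he", "Tw")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("shared_constants: '", nm, "' must be a single finite number", call. = FALSE)
    }
  }
  if (mb < 0) stop("shared_constants: mb must be >= 0", call. = FALSE)
  if (cb <= 0) stop("shared_constants: cb must be > 0", call. = FALSE)
  if (he < 0) stop("shared_constants: he must be >= 0", call. = FALSE)
  structure(list(mb = mb, cb = cb, TA = TA, Qe = Qe, he = he, Tw = Tw),
            class = "shared_constants")
}

#' Published material database for the scalp/skull/CSF stack
#'
#' Constants for the three layers of the forehead model. The scalp entry
#' carries the inner-scalp metabolic rate (1800 W m-3); the outer half of
#' the scalp generates no metabolic heat, which [lookup_properties()]
#' applies through the scalp-split depth of the layer field.
#'
#' @return Named list of [tissue_properties()] for `scalp`, `skull`, `csf`.
#' @export
default_materials <- function() {
  list(
    scalp = tissue_properties(k = 0.342, rho = 1070, c = 3600, Qm = 1.8e3),
    skull = tissue_properties(k = 0.651, rho = 1520, c = 1590, Qm = 0),
    csf   = tissue_properties(k = 0.217, rho = 880,  c = 2360, Qm = 0.3e3)
  )
}

#' Look up the material constants governing a node
#'
#' Returns the per-layer constants at depth `x`. Within the scalp the
#' metabolic term is depth-dependent: zero outside (shallower than) the
#' scalp-split depth, the database value at or beyond it.
#'
#' @param layer Layer id (name into `materials`).
#' @param x Depth below the skin surface (m); used only for the scalp split.
#' @param layers A [layer_field()].
#' @param materials Named list of [tissue_properties()].
#' @return A [tissue_properties()] with `Qm` resolved for this depth.
#' @export
lookup_properties <- function(layer, x, layers, materials) {
  p <- materials[[layer]]
  if (is.null(p)) {
    stop("lookup_properties: no material constants for layer '", layer, "'",
         call. = FALSE)
  }
  if (identical(layer, "scalp") && !is.null(layers$scalp_split) && x < layers$scalp_split) {
    p$Qm <- layers$scalp_Qm_outer
  }
  p
}
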