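# Condition presets. Baseline absolute values (vascular fraction 0.30,
# coverage 0.60, ghost 0.25 at D7) are free generator parameters; the
# relative changes between presets encode the measured condition effects:
# control vascular area falls to 70% by D14 then stabilizes, diabetic
# networks regress to 30% of the D7 control by D28, pericyte coverage drops
# 3-fold under diabetic treatment, the ghost-vessel fraction rises 1.6-fold
# (diabetic D7 -> D28) and is 1.3-fold higher than control at D28, and
# TNF-alpha raises permeability 4.7-fold over the ~1e-7 cm/s baseline.
# diabetic_D14 sits at the log-midpoint of D7 and D28 values because the
# major diabetic changes develop between D14 and D28.

.preset_registry <- new.env(parent = emptyenv())

.default_noise <- function() list(
  gaussian_sd = 400,       # ~2% of the 0-20000 display range
  poisson_scale = 0.01,    # photon gain: relative shot noise ~8% at peak
  background_slope = 0.05) # background ramps to 5% of range across x

.zero_noise <- function() list(gaussian_sd = 0, poisson_scale = 0,
                               background_slope = 0)

.make_preset <- function(name, vascular, coverage, ghost, astro = 40L,
                         apoEC = 0.03, apoPC = 0.03, leak = 1e-7,
                         noise = .default_noise()) {
  new("ScenePreset", name = name, vascularAreaFraction = vascular,
      coverageFraction = coverage, ghostFraction = ghost,
      astrocyteCount = as.integer(astro), apoptoticFractionEC = apoEC,
      apoptoticFractionPC = apoPC, leakPermeability = leak, noise = noise)
}

.init_presets <- function() {
  reg <- function(p) assign(p@name, p, envir = .preset_registry)
  base_v <- 0.30; base_c <- 0.60; base_g <- 0.25
  d28_v <- 0.30 * base_v       # regressed to 30% of initial control value
  d28_c <- base_c / 3          # 3-fold coverage reduction
  d28_g <- 1.6 * base_g        # ghost fraction up 1.6-fold D7 -> D28
  reg(.make_preset("control_D7", base_v, base_c, base_g))
  reg(.make_preset("control_D14", 0.70 * base_v, base_c, base_g))
  reg(.make_preset("control_D28", 0.70 * base_v, base_c, d28_g / 1.3))
  reg(.make_preset("diabetic_D14", sqrt(base_v * d28_v), sqrt(base_c * d28_c),
                   sqrt(base_g * d28_g), apoEC = 0.12, apoPC = 0.12))
  reg(.make_preset("diabetic_D28", d28_v, d28_c, d28_g,
                   apoEC = 0.12, apoPC = 0.12))
  reg(.make_preset("untreated", base_v, base_c, base_g, leak = 1e-7))
  reg(.make_preset("tnf_24h", base_v, base_c, base_g, leak = 4.7e-7))
}

#' Retrieve a registered condition preset
#'
#' Presets parameterize the synthetic scene generator per experimental
#' condition (control/diabetic culture at D7/D14/D28; untreated vs
#' TNF-alpha-treated for permeability). They are immutable: `getPreset()`
#' returns a copy and there is no setter.
#'
#' @param name preset label; see [listPresets()].
#' @return a [ScenePreset-class].
#' @examples
#' getPreset("control_D7")
#' listPresets()
#' @export
getPreset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !exists(name, envir = .preset_registry, inherits = FALSE))
    stop("unknown preset '", name, "'; see listPresets()")
  get(name, envir = .preset_registry, inherits = FALSE)
}

#' @rdname getPreset
#' @export
listPresets <- function() sort(ls(envir = .preset_registry))
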