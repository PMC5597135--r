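#' Physical constants used by the transport model
#'
#' Returns the constants the model evaluates with. The Boltzmann constant is
#' the exact SI value; the electron mass defaults to the rounded value
#' 9.109e-31 kg conventionally used with tabulated carbon-nanotube effective
#' masses, and can be overridden.
#'
#' @param me Electron rest mass in kg. Defaults to 9.109e-31.
#' @return Named list with `kB` (J/K) and `me` (kg).
#' @export
#' @examples
#' transport_constants()$kB
transport_constants <- function(me = 9.109e-31) {
  stopifnot(is.numeric(me), length(me) == 1L, is.finite(me), me > 0)
  list(kB = 1.380649e-23, me = me)
}

#' Carrier presets
#'
#' Built-in presets describe semiconducting single-wall carbon nanotubes by
#' chirality, with effective masses taken from tight-binding band-structure
#' tabulations, at body temperature and a relaxation time typical of soft
#' condensed matter. The registry is a JSON file so users can supply their
#' own carriers.
#'
#' @param name Preset name, e.g. `"cnt_3_1"` or `"cnt_7_3"`.
#' @param registry Path to a JSON registry file. Defaults to the registry
#'   shipped with the package.
#' @return A `carrier_preset` object: list with `label`, `n`, `m`,
#'   `m_eff_ratio` (multiple of the electron mass), `default_tau_s` and
#'   `default_temperature_K`.
#' @export
#' @examples
#' get_preset("cnt_3_1")$m_eff_ratio  # 0.507
get_preset <- function(name, registry = default_preset_registry()) {
  presets <- load_presets(registry)
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  p <- presets[[name]]
  structure(p, class = "carrier_preset")
}

#' @rdname get_preset
#' @export
list_presets <- function(registry = default_preset_registry()) {
  names(load_presets(registry))
}

default_preset_registry <- function() {
  system.file("extdata", "presets.json", package = "nanodrude", mustWork = TRUE)
}

load_presets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(p) {
    stopifnot(is.numeric(p$m_eff_ratio), p$m_eff_ratio > 0)
    for (f in c("m_eff_ratio", "default_tau_s", "default_temperature_K")) {
      p[[f]] <- as.numeric(p[[f]])
    }
    p
  })
  names(out) <- vapply(raw, function(p) p$label, character(1))
  out
}

#' Convert a diffusion coefficient from m²/s to cm²/s
#'
#' The conversion factor is exactly 1e4.
#'
#' @param value Diffusion coefficient(s) in m²/s.
#' @return Value(s) in cm²/s.
#' @export
#' @examples
#' convert_diffusion(9.2675e-4)  # 9.2675 cm²/s
convert_diffusion <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  value * 1e4
}
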