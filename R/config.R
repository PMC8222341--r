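# Pipeline configuration: a nested list, deep-mergeable from JSON.

#' Default pipeline configuration
#'
#' @return nested list of configuration values: `morph` (SH degree cap,
#'   attraction-repulsion constants, smoothing), `texture`, `func` (phase
#'   times, relative-enhancement switch), `classifier` (family and
#'   hyper-parameters).
#' @export
default_config <- function() {
  list(
    morph = list(
      L_max = 70L,
      ar = list(CA1 = 0.003, CA2 = 0.3, CR = 1.0, T = 1e-4,
                max_iters = 5000L, literal_alpha = FALSE),
      smooth = list(iters = 10L, factor = 0.5),
      normalize_errors = FALSE),
    texture = list(levels = 256L),
    func = list(times = c(0, 35, 50, 180), relative = FALSE),
    classifier = list(family = "rf")
  )
}

#' Desk-scale configuration for tests and benchmarks
#'
#' Same pipeline, with the spherical-harmonic degree cap lowered to 25 and
#' the attraction-repulsion iteration cap reduced, so a full study runs in
#' seconds instead of minutes.  Marker counts other than the morphological
#' ones are unchanged.
#'
#' @param L_max degree cap (default 25).
#' @param max_iters attraction-repulsion iteration cap (default 400).
#' @return configuration list.
#' @export
test_scale_config <- function(L_max = 25L, max_iters = 400L) {
  cfg <- default_config()
  cfg$morph$L_max <- as.integer(L_max)
  cfg$morph$ar$max_iters <- as.integer(max_iters)
  cfg
}

#' Load a configuration file
#'
#' Reads a JSON file and deep-merges it over [default_config()].
#'
#' @param path JSON file path, or `NULL` for the defaults.
#' @return configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  deep_merge(cfg, user)
}

deep_merge <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}
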