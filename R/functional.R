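# Enhancement-kinetics markers: the piecewise slope of the mean tumor
# intensity across the four contrast phases.  Wash-in is the rise from
# pre-contrast to the late arterial phase; wash-out the subsequent decline
# into the portal venous and delayed phases (negative slopes).

#' Wash-in / wash-out slope markers (3 values)
#'
#' Mean mask intensity is taken per phase on the raw (unquantized) volumes;
#' slopes are intensity change per second between consecutive phases:
#' `slope_washin` (pre to arterial), `slope_pv` (arterial to portal venous),
#' `slope_del` (portal venous to delayed).  With `relative = TRUE` each
#' phase mean is first converted to relative enhancement
#' `(I - I_pre) / I_pre`.
#'
#' @param study a [tumor_study()].
#' @param times override the study phase times (seconds).
#' @param relative compute slopes of relative enhancement instead of raw
#'   intensity (default `FALSE`).
#' @return named numeric vector `slope_washin`, `slope_pv`, `slope_del`.
#' @export
enhancement_slopes <- function(study, times = NULL, relative = FALSE) {
  if (!any(study$mask)) stop("empty mask")
  t <- if (is.null(times)) study$phase_times else as.double(times)
  if (length(t) != 4L || any(diff(t) <= 0)) stop("bad phase times")
  m <- vapply(study$phases, function(v) mean(v[study$mask]), 0)
  if (relative) {
    if (m[1] == 0) stop("zero pre-contrast mean")
    m <- (m - m[1]) / m[1]
  }
  sl <- diff(m) / diff(t)
  c(slope_washin = unname(sl[1]), slope_pv = unname(sl[2]),
    slope_del = unname(sl[3]))
}

#' Enhancement curve of a study
#'
#' @param study a [tumor_study()].
#' @return data.frame with `phase`, `time` (s) and `mean_intensity`.
#' @export
enhancement_curve <- function(study) {
  data.frame(phase = PHASES, time = study$phase_times,
             mean_intensity = vapply(study$phases,
                                     function(v) mean(v[study$mask]), 0),
             row.names = NULL)
}
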