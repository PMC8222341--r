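# The integrated marker record: 70 morphological + 104 first-order +
# 24 GLCM + 48 GLRLM + 3 functional = 249 named values per tumor, in a
# fixed schema shared by every study.

#' The fixed marker schema
#'
#' @param L_max spherical-harmonic degree cap (default 70; the default
#'   configuration yields the standard 249-marker schema).
#' @return data.frame with columns `name` and `group`
#'   (`morphological`, `first_order`, `glcm`, `glrlm`, `functional`).
#' @export
marker_schema <- function(L_max = 70L) {
  pfx <- c("pre", "art", "pv", "del")
  fo_names <- c("mean", "variance", "sd", "skewness", "kurtosis", "entropy",
                sprintf("cdf_%03d", seq(10, 100, 10)),
                sprintf("pct_%03d", seq(10, 100, 10)))
  glcm_names <- c("contrast", "dissimilarity", "homogeneity", "asm",
                  "energy", "correlation")
  glrlm_names <- c("gln", "hglre", "lre", "lrhgle", "lrlgle", "lglre",
                   "re", "rln", "rp", "sre", "srhgle", "srlgle")
  name <- c(sprintf("SH_err_%03d", seq_len(L_max)),
            as.vector(t(outer(pfx, fo_names, function(a, b) paste0(a, "_fo_", b)))),
            as.vector(t(outer(pfx, glcm_names, function(a, b) paste0(a, "_glcm_", b)))),
            as.vector(t(outer(pfx, glrlm_names, function(a, b) paste0(a, "_glrlm_", b)))),
            c("slope_washin", "slope_pv", "slope_del"))
  group <- c(rep("morphological", L_max),
             rep("first_order", 4 * length(fo_names)),
             rep("glcm", 4 * length(glcm_names)),
             rep("glrlm", 4 * length(glrlm_names)),
             rep("functional", 3))
  data.frame(name = name, group = group, stringsAsFactors = FALSE)
}

#' Extract the full marker vector of a study
#'
#' Runs the morphology, texture and functional modules and concatenates
#' their outputs into one named record following [marker_schema()].  The
#' computation is deterministic: no step draws random numbers.
#'
#' @param study a [tumor_study()].
#' @param cfg configuration list (see [default_config()]).
#' @return object of class `marker_vector`: `study_id`, `values` (named
#'   numeric), `group` (named character), `grade` (may be `NULL`).
#' @export
extract_all_markers <- function(study, cfg = default_config()) {
  with_module <- function(module, expr) {
    tryCatch(expr, error = function(e)
      stop(module, ": ", conditionMessage(e), call. = FALSE))
  }
  morph <- with_module("morphology", morphological_markers(study, cfg))
  tex <- with_module("texture", textural_markers(study))
  fun <- with_module("function_markers",
                     enhancement_slopes(study, times = cfg$func$times,
                                        relative = isTRUE(cfg$func$relative)))
  schema <- marker_schema(cfg$morph$L_max)
  values <- c(morph, tex, fun)[schema$name]
  if (anyNA(values) || any(!is.finite(values)))
    stop("non-finite marker values")
  structure(list(study_id = study$study_id, values = values,
                 group = setNames(schema$group, schema$name),
                 grade = study$grade),
            class = "marker_vector")
}

#' @export
print.marker_vector <- function(x, ...) {
  cat("<marker_vector> ", x$study_id, ": ", length(x$values), " markers (",
      paste(table(x$group)[unique(x$group)], collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' Write marker vectors to a CSV table
#'
#' One row per study: `study_id`, `grade` (empty when unknown), then one
#' column per marker.  Values are written with 17 significant digits so the
#' table round-trips doubles exactly.
#'
#' @param records list of `marker_vector` objects sharing one schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(records, path) {
  if (inherits(records, "marker_vector")) records <- list(records)
  stopifnot(length(records) > 0)
  nm <- names(records[[1]]$values)
  for (r in records)
    if (!identical(names(r$values), nm)) stop("inconsistent marker schema")
  df <- data.frame(
    study_id = vapply(records, `[[`, "", "study_id"),
    grade = vapply(records, function(r) if (is.null(r$grade)) "" else r$grade, ""),
    stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(records, function(r) unname(r$values)))
  vals <- apply(vals, c(1, 2), function(x) formatC(x, digits = 17, format = "g"))
  vals <- as.data.frame(vals, stringsAsFactors = FALSE)
  names(vals) <- nm
  write.csv(cbind(df, vals), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#'
#' @param path CSV path.
#' @return list with `X` (numeric matrix, studies x markers, rownames =
#'   study ids), `study_id`, `grade` (character, `NA` when unknown).
#' @export
read_marker_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("study_id", "grade") %in% names(df)))
  X <- as.matrix(df[, setdiff(names(df), c("study_id", "grade")), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$study_id
  grade <- as.character(df$grade)
  grade[is.na(grade) | grade == ""] <- NA_character_
  list(X = X, study_id = df$study_id, grade = grade)
}

#' Assemble a marker matrix from a list of studies
#'
#' Convenience wrapper: extract markers for every study and stack them.
#'
#' @param studies list of [tumor_study()] objects.
#' @param cfg configuration list.
#' @param progress print a dot per study.
#' @return list with `X` (matrix), `grade` (character vector).
#' @export
extract_cohort_markers <- function(studies, cfg = default_config(),
                                   progress = FALSE) {
  recs <- lapply(studies, function(s) {
    if (progress) cat(".")
    extract_all_markers(s, cfg)
  })
  if (progress) cat("\n")
  X <- do.call(rbind, lapply(recs, function(r) r$values))
  rownames(X) <- vapply(recs, `[[`, "", "study_id")
  grade <- vapply(recs, function(r) if (is.null(r$grade)) NA_character_ else r$grade, "")
  list(X = X, grade = grade)
}
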