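# The unit of analysis: one tumor, four co-registered contrast phases, a
# binary mask, voxel spacing, and the acquisition times of the phases.

#' Construct a tumor study
#'
#' Bundles the four contrast-phase volumes (pre-contrast, late arterial,
#' portal venous, delayed), the binary tumor mask, the voxel spacing and the
#' phase acquisition times into the object every extraction routine consumes.
#' All volumes must share one grid; the mask must have at least one
#' foreground voxel and form a single 26-connected component.
#'
#' @param study_id character identifier.
#' @param phases named list of four 3D arrays, keyed
#'   `pre`, `arterial`, `venous`, `delayed`.
#' @param mask binary 3D array on the same grid.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param phase_times acquisition time of each phase in seconds, strictly
#'   increasing.  Default `c(0, 35, 50, 180)`, the nominal protocol times.
#' @param grade optional ground-truth grade, one of `"LR1"`..`"LR5"`.
#' @return object of class `tumor_study`.
#' @export
tumor_study <- function(study_id, phases, mask, spacing = c(1, 1, 1),
                        phase_times = c(0, 35, 50, 180), grade = NULL) {
  if (!is.list(phases) || !setequal(names(phases), PHASES))
    stop("phases must be a named list keyed ", paste(PHASES, collapse = "/"))
  phases <- phases[PHASES]
  dims <- dim(phases[[1]])
  if (length(dims) != 3L) stop("phase volumes must be 3D")
  for (p in PHASES) {
    if (!identical(dim(phases[[p]]), dims)) stop("grid mismatch")
  }
  if (!identical(dim(mask), dims)) stop("grid mismatch")
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  if (!is_single_component_26(mask)) stop("mask is not a single 26-connected component")
  if (length(phase_times) != 4L || any(diff(phase_times) <= 0))
    stop("bad phase times")
  if (!is.null(grade)) {
    grade <- as.character(grade)
    if (!grade %in% GRADES) stop("unknown grade: ", grade)
  }
  structure(list(study_id = as.character(study_id), phases = phases,
                 mask = mask, spacing = as.double(spacing),
                 phase_times = as.double(phase_times), grade = grade),
            class = "tumor_study")
}

#' @export
print.tumor_study <- function(x, ...) {
  cat("<tumor_study> ", x$study_id,
      if (!is.null(x$grade)) paste0(" [", x$grade, "]"), "\n",
      "  grid ", paste(dim(x$mask), collapse = "x"),
      ", spacing ", paste(format(x$spacing), collapse = "x"), " mm",
      ", ", sum(x$mask), " mask voxels\n",
      "  phase times ", paste(x$phase_times, collapse = ", "), " s\n", sep = "")
  invisible(x)
}

#' Load a study from NIfTI files
#'
#' Reads the four phase volumes and the mask, checks grid congruence, and
#' takes the voxel spacing from the mask header.
#'
#' @param phase_paths character vector of four paths, in order
#'   pre-contrast, late arterial, portal venous, delayed (or named with
#'   those keys).
#' @param mask_path path to the binary mask volume.
#' @param phase_times optional phase times in seconds; default
#'   `c(0, 35, 50, 180)`.
#' @param study_id identifier; defaults to the mask filename stem.
#' @param grade optional grade label.
#' @return a [tumor_study()].
#' @export
load_study <- function(phase_paths, mask_path, phase_times = c(0, 35, 50, 180),
                       study_id = NULL, grade = NULL) {
  if (length(phase_paths) != 4L) stop("need exactly four phase volumes")
  if (!is.null(names(phase_paths)) && all(names(phase_paths) %in% PHASES))
    phase_paths <- phase_paths[PHASES]
  vols <- lapply(phase_paths, read_nifti)
  msk <- read_nifti(mask_path)
  dims <- dim(msk$data)
  for (v in vols) if (!identical(dim(v$data), dims)) stop("grid mismatch")
  if (is.null(study_id))
    study_id <- sub("\\.nii(\\.gz)?$", "", basename(mask_path))
  tumor_study(study_id,
              phases = setNames(lapply(vols, `[[`, "data"), PHASES),
              mask = msk$data != 0, spacing = msk$spacing,
              phase_times = phase_times, grade = grade)
}

# Single 26-connected foreground component?  Frontier dilation from an
# arbitrary seed voxel, intersected with the mask, until a fixed point.
is_single_component_26 <- function(mask) {
  n <- sum(mask)
  if (n == 0L) return(FALSE)
  if (n == 1L) return(TRUE)
  mask <- crop_to_bbox(mask, margin = 0L)
  dims <- dim(mask)
  comp <- array(FALSE, dims)
  comp[which(mask)[1]] <- TRUE
  shifts <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  repeat {
    grown <- comp
    for (s in seq_len(nrow(shifts)))
      grown <- grown | shift_array(comp, shifts[s, 1], shifts[s, 2], shifts[s, 3])
    grown <- grown & mask
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  sum(comp) == n
}

# Crop a logical array to the bounding box of its foreground (plus margin);
# keeps whole-grid scans out of the inner loops of connectivity checks.
crop_to_bbox <- function(mask, margin = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

# Shift a 3D logical/numeric array by (di, dj, dk), padding with `fill`.
shift_array <- function(a, di, dj, dk, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  if (any(abs(c(di, dj, dk)) >= d)) return(out)
  src <- function(n, s) if (s >= 0) seq_len(n - s) else (1 - s):n
  dst <- function(n, s) if (s >= 0) (1 + s):n else seq_len(n + s)
  out[dst(d[1], di), dst(d[2], dj), dst(d[3], dk)] <-
    a[src(d[1], di), src(d[2], dj), src(d[3], dk)]
  out
}
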