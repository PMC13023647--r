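# Reading, writing and validating structure mask sets.
#
# A mask set is the unit of input for every measurement: five co-registered
# binary rasters (heart, ventricular septum, whole thorax, thorax, descending
# aorta) plus a small JSON manifest. Masks are stored one PNG per structure
# because heart/whole_thorax/thorax overlap, which an indexed palette cannot
# represent.

#' Structure names of a four-chamber-view mask set
#' @export
MASK_STRUCTURES <- c("heart", "ventricular_septum", "whole_thorax",
                     "thorax", "descending_aorta")

#' Construct a structure mask set
#'
#' @param masks Named list of binary matrices, one per structure in
#'   [MASK_STRUCTURES]; any value > 0 is foreground and is binarised to 0/1.
#' @param source_id Opaque image identifier.
#' @param pixel_spacing Optional isotropic length per pixel; ratios and angles
#'   are spacing-invariant so this is metadata only.
#' @param presentation Declared fetal presentation:
#'   `"cephalic"`, `"breech"` or `"unknown"`.
#' @param extractable Whether a four-chamber view was obtainable for the
#'   source video (used by patient-level screening).
#' @return Object of class `mask_set`.
#' @export
mask_set <- function(masks, source_id = "unknown", pixel_spacing = NULL,
                     presentation = "unknown", extractable = TRUE) {
  missing <- setdiff(MASK_STRUCTURES, names(masks))
  if (length(missing) > 0) {
    abort_fourcv("load", paste0("missing structure mask(s): ",
                                paste(missing, collapse = ", ")))
  }
  dims <- vapply(masks[MASK_STRUCTURES], dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_fourcv("format", "structure masks have mismatched dimensions")
  }
  presentation <- match.arg(presentation, c("unknown", "cephalic", "breech"))
  masks <- lapply(masks[MASK_STRUCTURES], function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[m > 0] <- 1L
    out
  })
  structure(
    list(width = ncol(masks[[1]]), height = nrow(masks[[1]]),
         masks = masks, pixel_spacing = pixel_spacing,
         source_id = source_id, presentation = presentation,
         extractable = isTRUE(extractable)),
    class = "mask_set"
  )
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %s: %dx%d px, presentation=%s\n",
              x$source_id, x$width, x$height, x$presentation))
  counts <- vapply(x$masks, sum, numeric(1))
  for (s in names(counts)) cat(sprintf("  %-18s %d px\n", s, counts[s]))
  invisible(x)
}

#' Write a mask set to a directory
#'
#' One 8-bit grayscale PNG per structure (0 background, 255 foreground) plus
#' `manifest.json`. `read_mask_set(write_mask_set(x))` reproduces the rasters
#' bit-exactly.
#'
#' @param ms `mask_set`.
#' @param directory_path Output directory (created if needed).
#' @return `directory_path`, invisibly.
#' @export
write_mask_set <- function(ms, directory_path) {
  stopifnot(inherits(ms, "mask_set"))
  ok <- dir.exists(directory_path) || dir.create(directory_path, recursive = TRUE)
  if (!ok) abort_fourcv("io", paste0("cannot create directory ", directory_path))
  files <- stats::setNames(paste0(MASK_STRUCTURES, ".png"), MASK_STRUCTURES)
  for (s in MASK_STRUCTURES) {
    png::writePNG(ms$masks[[s]] * 1.0, file.path(directory_path, files[[s]]))
  }
  manifest <- list(
    structures = as.list(files),
    source_id = ms$source_id,
    presentation = ms$presentation,
    extractable = ms$extractable,
    pixel_spacing = ms$pixel_spacing
  )
  jsonlite::write_json(manifest, file.path(directory_path, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(directory_path)
}

#' Read a mask set from a directory
#'
#' Expects a `manifest.json` naming one PNG per structure. Any nonzero sample
#' is foreground, so 0/1 and 0/255 mask dialects load identically.
#'
#' @param directory_path Directory containing the manifest and mask PNGs.
#' @return Validated `mask_set`.
#' @export
read_mask_set <- function(directory_path) {
  mf_path <- file.path(directory_path, "manifest.json")
  if (!file.exists(mf_path)) {
    abort_fourcv("load", paste0("manifest.json not found in ", directory_path))
  }
  manifest <- jsonlite::read_json(mf_path)
  masks <- list()
  for (s in MASK_STRUCTURES) {
    fname <- manifest$structures[[s]]
    if (is.null(fname)) {
      abort_fourcv("load", paste0("manifest missing structure entry: ", s),
                   structure_name = s)
    }
    fpath <- file.path(directory_path, fname)
    if (!file.exists(fpath)) {
      abort_fourcv("load", paste0("mask file for ", s, " not found: ", fname),
                   structure_name = s)
    }
    img <- png::readPNG(fpath)
    if (length(dim(img)) == 3) img <- img[, , 1]   # collapse any colour PNG
    masks[[s]] <- img
  }
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort_fourcv("format", "mask files have mismatched dimensions")
  }
  mask_set(
    masks,
    source_id = manifest$source_id %||% basename(directory_path),
    pixel_spacing = manifest$pixel_spacing,
    presentation = manifest$presentation %||% "unknown",
    extractable = manifest$extractable %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a mask set's geometric preconditions
#'
#' Checks the invariants every measurement assumes: binary rasters, shared
#' dimensions, non-empty whole thorax, and the containments
#' heart within whole_thorax and ventricular_septum within heart (up to a
#' stray-pixel tolerance, since real segmentations leak at boundaries).
#'
#' Validation reports violations; it never raises.
#'
#' @param ms `mask_set`.
#' @param containment_tol Tolerated stray-pixel fraction (default 0.02).
#' @return Character vector of violation descriptors; empty if valid.
#' @export
validate_mask_set <- function(ms, containment_tol = 0.02) {
  violations <- character(0)
  dims <- vapply(ms$masks, dim, integer(2))
  if (any(dims[1, ] != ms$height) || any(dims[2, ] != ms$width)) {
    violations <- c(violations, "dimensions: masks do not share one canvas")
  }
  for (s in MASK_STRUCTURES) {
    v <- ms$masks[[s]]
    if (!all(v %in% c(0L, 1L))) {
      violations <- c(violations, paste0("binary: ", s, " is not strictly binary"))
    }
  }
  if (sum(ms$masks$whole_thorax) == 0) {
    violations <- c(violations, "whole_thorax empty")
  }
  stray <- function(inner, outer) {
    n <- sum(ms$masks[[inner]])
    if (n == 0) return(0)
    sum(ms$masks[[inner]] > 0 & ms$masks[[outer]] == 0) / n
  }
  if (stray("heart", "whole_thorax") > containment_tol) {
    violations <- c(violations,
                    "containment: heart ⊄ whole_thorax")
  }
  if (stray("ventricular_septum", "heart") > containment_tol) {
    violations <- c(violations,
                    "containment: ventricular_septum ⊄ heart")
  }
  violations
}
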