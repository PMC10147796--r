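#' Blind randomized presentation order for ROI scoring
#'
#' Produces the presentation list used for blind segmentation/scoring: a
#' uniformly random permutation of the ROI records exposing only the blinded
#' ID and file references, together with a sealed key mapping blinded IDs
#' back to animal and group for post-hoc unblinding. The presentation
#' records never carry group or animal identity.
#'
#' @param records Data frame with at least a `blinded_id` column; typically
#'   the `metadata` of a [generate_cohort()] result. `image_path` /
#'   `roi_path` columns, when present, are carried into the presentation.
#' @param seed Integer seed; the same seed reproduces the same order.
#' @return List with `presentation` (shuffled data frame restricted to
#'   `blinded_id`, `image_path`, `roi_path`) and `key` (unshuffled
#'   `blinded_id` to `roi_id`/`animal_id`/`group`/`region` mapping).
#' @export
blind_order <- function(records, seed) {
  stopifnot(is.data.frame(records), "blinded_id" %in% names(records))
  if (anyDuplicated(records$blinded_id)) {
    stop("duplicate blinded_ids in records")
  }
  show_cols <- intersect(c("blinded_id", "image_path", "roi_path"),
                         names(records))
  key_cols <- intersect(c("blinded_id", "roi_id", "animal_id", "group",
                          "region", "side", "section_index"),
                        names(records))
  perm <- if (nrow(records) > 0) {
    withr::with_seed(as.integer(seed), sample(nrow(records)))
  } else integer(0)
  presentation <- records[perm, show_cols, drop = FALSE]
  rownames(presentation) <- NULL
  key <- records[, key_cols, drop = FALSE]
  rownames(key) <- NULL
  list(presentation = presentation, key = key)
}

#' Robust background staining level of an ROI
#'
#' Estimates the unspecific background staining inside an ROI on the
#' inverted-intensity scale (`1 - intensity`, so that more stain = larger
#' value) as the median of the ROI pixels, with the median absolute
#' deviation (MAD, scaled for normal consistency) as robust spread. The
#' median is robust as long as stained cells cover well under half of the
#' ROI, which holds for area fractions typical of pS6 material.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param roi Logical mask (same dimensions) or polygon `list(x, y)`.
#' @return List with `background` (median inverted intensity) and `mad`.
#' @export
estimate_background <- function(image, roi) {
  mask <- resolve_roi(roi, dim(image))
  px <- 1 - image[mask]
  list(background = stats::median(px), mad = stats::mad(px))
}

#' Threshold stained pixels within an ROI
#'
#' A pixel is called stained iff its inverted intensity exceeds
#' `background + k * MAD`, with background and MAD estimated robustly from
#' the ROI itself (see [estimate_background()]) unless given explicitly.
#' The returned mask is restricted to the ROI. `k = 5` (the default) places
#' the threshold well above background fluctuations while remaining far
#' below the stain depression of DAB-Ni labelled cytoplasm.
#'
#' @inheritParams estimate_background
#' @param k Positive threshold multiplier.
#' @param background,spread Optional explicit background level and spread on
#'   the inverted scale, overriding the per-ROI estimate (useful when an ROI
#'   is almost fully stained, or to share one threshold across ROIs).
#' @return Logical matrix: stained pixels inside the ROI.
#' @export
stain_mask <- function(image, roi, k = 5, background = NULL, spread = NULL) {
  stopifnot(k > 0)
  mask <- resolve_roi(roi, dim(image))
  if (is.null(background) || is.null(spread)) {
    est <- estimate_background(image, mask)
    if (is.null(background)) background <- est$background
    if (is.null(spread)) spread <- est$mad
  }
  out <- matrix(FALSE, nrow(image), ncol(image))
  out[mask] <- (1 - image[mask]) > background + k * spread
  out
}

#' Measure the stained-area fraction of one ROI
#'
#' Computes the core activation measure: the area stained divided by the
#' total area segmented, for one ROI. Areas are reported both in pixels and
#' in square micrometres (`px * resolution_um^2`).
#'
#' @inheritParams stain_mask
#' @param resolution_um Micrometres per pixel.
#' @return One-row data.frame of class `stain_measurement`: `stained_px`,
#'   `total_px`, `stained_um2`, `total_um2`, `fraction`, `threshold_used`
#'   (inverted-intensity scale), `k`, `level = "roi"`.
#' @export
measure_roi <- function(image, roi, k = 5, resolution_um = 1.6,
                        background = NULL, spread = NULL) {
  mask <- resolve_roi(roi, dim(image))
  if (is.null(background) || is.null(spread)) {
    est <- estimate_background(image, mask)
    if (is.null(background)) background <- est$background
    if (is.null(spread)) spread <- est$mad
  }
  sm <- stain_mask(image, mask, k = k, background = background,
                   spread = spread)
  stained <- sum(sm); total <- sum(mask)
  px_um2 <- resolution_um^2
  out <- data.frame(
    stained_px = stained, total_px = total,
    stained_um2 = stained * px_um2, total_um2 = total * px_um2,
    fraction = stained / total,
    threshold_used = background + k * spread, k = k,
    level = "roi", stringsAsFactors = FALSE
  )
  class(out) <- c("stain_measurement", "data.frame")
  out
}

#' Pool ROI measurements to one value per animal and region
#'
#' For a brain part segmented in several areas (both sides, several
#' sections), the pooled stained fraction is area-weighted:
#' `sum(stained_area) / sum(total_area)` across the ROIs — the single
#' "area stained / total area segmented" ratio for that brain part — not
#' the mean of per-ROI ratios.
#'
#' @param measurements Data frame of ROI-level measurements for one animal
#'   and one region (columns `stained_px`, `total_px`, `stained_um2`,
#'   `total_um2`; and `animal_id`/`region`, checked for homogeneity when
#'   present).
#' @return One-row data.frame with pooled areas, `fraction`, `n_rois`, and
#'   `level = "animal_region"`.
#' @export
aggregate_animal <- function(measurements) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1)
  for (col in c("animal_id", "region")) {
    if (col %in% names(measurements) &&
        length(unique(measurements[[col]])) > 1) {
      stop("measurements mix more than one ", col)
    }
  }
  out <- data.frame(
    stained_px = sum(measurements$stained_px),
    total_px = sum(measurements$total_px),
    stained_um2 = sum(measurements$stained_um2),
    total_um2 = sum(measurements$total_um2),
    n_rois = nrow(measurements),
    level = "animal_region", stringsAsFactors = FALSE
  )
  out$fraction <- out$stained_px / out$total_px
  for (col in c("animal_id", "group", "region")) {
    if (col %in% names(measurements)) out[[col]] <- measurements[[col]][1]
  }
  class(out) <- c("stain_measurement", "data.frame")
  out
}

#' Measure every ROI of a cohort
#'
#' Applies [measure_roi()] to each ROI of a synthetic (or on-disk) cohort,
#' reading images from disk when they are not held in memory.
#'
#' @param cohort A `ps6_cohort` from [generate_cohort()] or [read_cohort()].
#' @param k Threshold multiplier passed to [measure_roi()].
#' @return Data frame, one row per ROI: cohort metadata columns plus the
#'   [measure_roi()] measurement columns.
#' @export
measure_cohort <- function(cohort, k = 5) {
  stopifnot(inherits(cohort, "ps6_cohort"))
  md <- cohort$metadata
  res_um <- cohort_resolution(cohort)
  rows <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    roi_id <- md$roi_id[i]
    img <- if (!is.null(cohort$images)) cohort$images[[roi_id]] else
      tiff::readTIFF(file.path(cohort$dir, md$image_path[i]))
    m <- measure_roi(img, cohort$rois[[roi_id]], k = k,
                     resolution_um = res_um)
    rows[[i]] <- cbind(
      md[i, c("roi_id", "animal_id", "group", "region", "side",
              "section_index", "blinded_id")],
      m
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cohort_resolution <- function(cohort) {
  bf <- cohort$spec$base_field
  if (!is.null(bf$resolution_um)) bf$resolution_um else 1.6
}

#' Pool a cohort's ROI measurements to animal x region level
#'
#' @param roi_measurements Output of [measure_cohort()].
#' @return Data frame with one row per animal x region: `animal_id`,
#'   `group`, `region`, `n_rois`, pooled areas and `fraction`.
#' @export
aggregate_animals <- function(roi_measurements) {
  stopifnot(is.data.frame(roi_measurements))
  if (nrow(roi_measurements) == 0) {
    return(data.frame(animal_id = character(0), group = character(0),
                      region = character(0), n_rois = integer(0),
                      stained_px = numeric(0), total_px = numeric(0),
                      stained_um2 = numeric(0), total_um2 = numeric(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  pieces <- split(roi_measurements,
                  list(roi_measurements$animal_id, roi_measurements$region),
                  drop = TRUE)
  out <- do.call(rbind, lapply(pieces, aggregate_animal))
  out <- out[order(out$group, out$animal_id, out$region),
             c("animal_id", "group", "region", "n_rois", "stained_px",
               "total_px", "stained_um2", "total_um2", "fraction")]
  rownames(out) <- NULL
  out
}
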