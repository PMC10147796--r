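#' Specification of a synthetic immunostained section field
#'
#' Describes one simulated bright-field view of DAB-Ni pS6 immunostained
#' tissue: a light background with slight smooth unspecific staining, on
#' which activated neurons appear as dark cytoplasmic annuli (the reaction
#' product fills the cell body around an unstained nucleus; dendrites and
#' axons are not stained). Intensities are on a normalized \[0, 1\] scale
#' where 1 is white; stained structures are *darker* than background.
#'
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @param resolution_um Physical resolution, micrometres per pixel
#'   (default 1.6, a slide-scanner resolution typical for this assay).
#' @param background_level Mean background intensity in \[0, 1\].
#' @param background_stain_sd Standard deviation of the smooth, low-frequency
#'   unspecific background staining field (intensity units; 0 disables).
#' @param cell_density Expected number of stained cells per mm^2.
#' @param cell_radius_um Outer radius of the stained cytoplasm, micrometres.
#' @param nucleus_radius_um Radius of the unstained nucleus, micrometres;
#'   must be strictly smaller than `cell_radius_um`.
#' @param stain_level Intensity depression of stained cytoplasm relative to
#'   the local background, in \[0, 1\].
#' @param noise_sd Standard deviation of additive pixel noise (intensity).
#' @param seed Integer seed for reproducible generation, or `NULL` to draw
#'   from the current RNG stream.
#'
#' @return An object of class `stain_field_spec` (a validated list).
#' @seealso [generate_section()], [cohort_spec()]
#' @export
#' @examples
#' spec <- stain_field_spec(image_shape = c(64, 64), seed = 1)
#' sec <- generate_section(spec)
#' sec$truth$fraction
stain_field_spec <- function(image_shape = c(200L, 200L),
                             resolution_um = 1.6,
                             background_level = 0.85,
                             background_stain_sd = 0.02,
                             cell_density = 200,
                             cell_radius_um = 8,
                             nucleus_radius_um = 4,
                             stain_level = 0.35,
                             noise_sd = 0.02,
                             seed = NULL) {
  spec <- list(
    image_shape = as.integer(image_shape),
    resolution_um = resolution_um,
    background_level = background_level,
    background_stain_sd = background_stain_sd,
    cell_density = cell_density,
    cell_radius_um = cell_radius_um,
    nucleus_radius_um = nucleus_radius_um,
    stain_level = stain_level,
    noise_sd = noise_sd,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(spec) <- "stain_field_spec"
  validate_stain_field_spec(spec)
  spec
}

validate_stain_field_spec <- function(spec) {
  stopifnot(inherits(spec, "stain_field_spec"))
  if (length(spec$image_shape) != 2 || any(spec$image_shape <= 0)) {
    stop("image_shape must be two positive integers (height, width)")
  }
  if (spec$resolution_um <= 0) stop("resolution_um must be positive")
  for (f in c("background_level", "stain_level")) {
    v <- spec[[f]]
    if (!is.finite(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  for (f in c("background_stain_sd", "noise_sd", "cell_density")) {
    if (!is.finite(spec[[f]]) || spec[[f]] < 0) stop(f, " must be >= 0")
  }
  if (spec$nucleus_radius_um >= spec$cell_radius_um) {
    stop("nucleus_radius_um must be smaller than cell_radius_um")
  }
  if (spec$cell_radius_um <= 0) stop("cell_radius_um must be positive")
  invisible(spec)
}

# Smooth low-frequency field: coarse iid Gaussian grid, bilinearly
# interpolated to pixel resolution. grid_px controls the correlation length.
smooth_background_field <- function(h, w, sd, grid_px = 32) {
  if (sd <= 0) return(matrix(0, h, w))
  gh <- max(2L, ceiling(h / grid_px) + 1L)
  gw <- max(2L, ceiling(w / grid_px) + 1L)
  grid <- matrix(stats::rnorm(gh * gw, sd = sd), gh, gw)
  # pixel centers mapped onto the grid coordinate system
  gy <- (seq_len(h) - 0.5) / h * (gh - 1) + 1
  gx <- (seq_len(w) - 0.5) / w * (gw - 1) + 1
  y0 <- pmin(floor(gy), gh - 1); x0 <- pmin(floor(gx), gw - 1)
  fy <- gy - y0; fx <- gx - x0
  idx <- function(dy, dx) {
    matrix(grid[outer(y0 + dy, (x0 + dx - 1L) * gh, "+")], h, w)
  }
  idx(0, 0) * outer(1 - fy, 1 - fx) + idx(1, 0) * outer(fy, 1 - fx) +
    idx(0, 1) * outer(1 - fy, fx) + idx(1, 1) * outer(fy, fx)
}

# Union annulus mask for cells at (cy, cx) in 0-based pixel coordinates.
# Pixel (r, c) (1-based matrix indices) has center (r - 0.5, c - 0.5).
annulus_union_mask <- function(h, w, cy, cx, r_in, r_out) {
  mask <- matrix(FALSE, h, w)
  for (i in seq_along(cy)) {
    rows <- max(1L, floor(cy[i] - r_out + 0.5)) : min(h, ceiling(cy[i] + r_out + 0.5))
    cols <- max(1L, floor(cx[i] - r_out + 0.5)) : min(w, ceiling(cx[i] + r_out + 0.5))
    if (length(rows) == 0 || length(cols) == 0) next
    dy2 <- (rows - 0.5 - cy[i])^2
    dx2 <- (cols - 0.5 - cx[i])^2
    d2 <- outer(dy2, dx2, "+")
    ann <- d2 <= r_out^2 & d2 > r_in^2
    mask[rows, cols] <- mask[rows, cols] | ann
  }
  mask
}

#' Generate one synthetic immunostained section with ground truth
#'
#' Simulates a single-channel bright-field image: cells are placed by a
#' homogeneous Poisson process; each contributes a stained cytoplasmic
#' annulus (intensity depressed by `stain_level`) around an unstained
#' nucleus disc; overlapping cells are merged by mask union. A smooth
#' unspecific background staining field and iid pixel noise are added, the
#' image is clipped to \[0, 1\] and quantized to 16-bit levels so in-memory
#' values match TIFF round trips exactly. The returned ground truth marks
#' exactly the stained cytoplasm pixels (background variation and noise
#' never enter the mask).
#'
#' @param spec A [stain_field_spec()].
#' @return A list of class `ps6_section`:
#'   \describe{
#'     \item{image}{numeric matrix (height x width) in \[0, 1\].}
#'     \item{resolution_um}{micrometres per pixel.}
#'     \item{truth}{list with `mask` (logical matrix of stained pixels),
#'       `stained_px`, and `fraction` = stained / total pixels.}
#'     \item{spec}{the generating spec.}
#'   }
#' @export
generate_section <- function(spec) {
  validate_stain_field_spec(spec)
  gen <- function() {
    h <- spec$image_shape[1]; w <- spec$image_shape[2]
    img <- matrix(spec$background_level, h, w) +
      smooth_background_field(h, w, spec$background_stain_sd)
    area_mm2 <- h * w * spec$resolution_um^2 / 1e6
    n_cells <- stats::rpois(1, spec$cell_density * area_mm2)
    if (n_cells > 0) {
      cy <- stats::runif(n_cells, 0, h)
      cx <- stats::runif(n_cells, 0, w)
      mask <- annulus_union_mask(
        h, w, cy, cx,
        spec$nucleus_radius_um / spec$resolution_um,
        spec$cell_radius_um / spec$resolution_um
      )
    } else {
      mask <- matrix(FALSE, h, w)
    }
    img[mask] <- img[mask] - spec$stain_level
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    }
    img <- pmin(pmax(img, 0), 1)
    img <- round(img * 65535) / 65535  # 16-bit quantization
    structure(
      list(
        image = img,
        resolution_um = spec$resolution_um,
        truth = list(
          mask = mask,
          stained_px = sum(mask),
          fraction = sum(mask) / length(mask)
        ),
        spec = spec
      ),
      class = "ps6_section"
    )
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, gen()) else gen()
}

#' Specification of a synthetic multi-group cohort
#'
#' Describes a full study cohort: `n_per_group` animals in each experimental
#' group, each contributing `rois_per_region` regions of interest (emulating
#' segmentation from both brain sides and from different sections) for every
#' configured brain region. Group- and region-specific activation is encoded
#' by multiplying the base cell density; the control group always has
#' multiplier 1.
#'
#' @param regions Character vector of unique region labels
#'   (default [cichlid_brain_regions()], 19 regions).
#' @param groups Character vector of group labels; the first element is the
#'   control group (default [experiment_groups()]).
#' @param n_per_group Number of animals per group: a single count (default
#'   10) or a vector parallel to `groups`.
#' @param rois_per_region ROIs segmented per animal and region (default 4,
#'   emulating left/right sides over two sections; with the defaults this
#'   yields 4 x 10 x 19 x 4 = 3040 ROIs, the scale of a full study).
#' @param multipliers `NULL` (all 1), or a data.frame with columns
#'   `group`, `region`, `multiplier` giving activation multipliers applied
#'   to `base_field$cell_density`; unspecified pairs default to 1. Control
#'   multipliers must be 1 and all multipliers must be positive.
#' @param base_field A [stain_field_spec()] shared by all ROIs (its `seed`
#'   is ignored; the cohort seed drives all randomness).
#' @param seed Integer seed for the whole cohort.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(regions = cichlid_brain_regions(),
                        groups = experiment_groups(),
                        n_per_group = 10L,
                        rois_per_region = 4L,
                        multipliers = NULL,
                        base_field = stain_field_spec(),
                        seed = 1L) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, length(groups))
  spec <- list(
    regions = as.character(regions),
    groups = as.character(groups),
    n_per_group = as.integer(n_per_group),
    rois_per_region = as.integer(rois_per_region),
    multipliers = multipliers,
    base_field = base_field,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (anyDuplicated(spec$regions)) stop("region labels must be unique")
  if (anyDuplicated(spec$groups)) stop("group labels must be unique")
  if (length(spec$n_per_group) != length(spec$groups)) {
    stop("n_per_group must be a single count or one count per group")
  }
  if (any(spec$n_per_group < 0)) stop("n_per_group must be >= 0")
  if (spec$rois_per_region < 1) stop("rois_per_region must be >= 1")
  validate_stain_field_spec(spec$base_field)
  m <- spec$multipliers
  if (!is.null(m)) {
    if (!is.data.frame(m) ||
        !all(c("group", "region", "multiplier") %in% names(m))) {
      stop("multipliers must be a data.frame with group, region, multiplier")
    }
    bad_r <- setdiff(m$region, spec$regions)
    if (length(bad_r)) stop("unknown region in multipliers: ",
                            paste(bad_r, collapse = ", "))
    bad_g <- setdiff(m$group, spec$groups)
    if (length(bad_g)) stop("unknown group in multipliers: ",
                            paste(bad_g, collapse = ", "))
    if (any(!is.finite(m$multiplier) | m$multiplier <= 0)) {
      stop("all activation multipliers must be positive")
    }
    control <- spec$groups[1]
    if (any(m$group == control & m$multiplier != 1)) {
      stop("control-group multipliers must equal 1")
    }
  }
  invisible(spec)
}

multiplier_for <- function(spec, group, region) {
  m <- spec$multipliers
  if (is.null(m)) return(1)
  hit <- m$group == group & m$region == region
  if (any(hit)) m$multiplier[which(hit)[1]] else 1
}

# Inset octagon ROI with continuously jittered vertices, in 0-based pixel
# coordinates. Continuous jitter keeps pixel centers off polygon edges
# (exact hits have measure zero), so pixel-center rasterization is
# unambiguous; the vertices are deterministic under the generating seed.
roi_polygon_for_frame <- function(h, w, jitter_px = 3) {
  mh <- 0.12 * h; mw <- 0.12 * w
  x <- c(mw + 0.3 * w, w - mw - 0.3 * w, w - mw, w - mw,
         w - mw - 0.3 * w, mw + 0.3 * w, mw, mw)
  y <- c(mh, mh, mh + 0.3 * h, h - mh - 0.3 * h,
         h - mh, h - mh, h - mh - 0.3 * h, mh + 0.3 * h)
  if (jitter_px > 0) {
    x <- x + stats::runif(8, -jitter_px, jitter_px)
    y <- y + stats::runif(8, -jitter_px, jitter_px)
  }
  list(x = x, y = y)
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Builds one independent section image per ROI for every
#' animal x region x ROI combination of the cohort design, with the cell
#' density scaled by the configured activation multiplier for the animal's
#' group and region. Each ROI gets a jittered octagonal polygon within its
#' frame; the ground-truth stained fraction is computed within that polygon.
#' Blinded IDs are assigned by random permutation so that ID order carries
#' no group information.
#'
#' With `out_dir`, the cohort is written in open formats: 16-bit
#' single-channel TIFFs under `images/`, ROI polygons as JSON under `rois/`
#' (0-based pixel coordinates), `metadata.csv`, `ground_truth.csv`, and the
#' generating spec as `cohort_spec.json`.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory, or `NULL` to keep the cohort in memory.
#' @param keep_images Keep image matrices in the returned object. Defaults
#'   to `TRUE` when `out_dir` is `NULL` (required, nothing is on disk) and
#'   `FALSE` otherwise; intended for small cohorts.
#' @param overwrite Overwrite an existing non-empty `out_dir`.
#'
#' @return An object of class `ps6_cohort`: list with `spec`, `metadata`
#'   (one row per ROI: `roi_id`, `animal_id`, `group`, `region`, `side`,
#'   `section_index`, `blinded_id`, `image_path`, `roi_path`),
#'   `ground_truth` (`roi_id`, `stained_px`, `roi_px`, `true_fraction`),
#'   `rois` (named list of polygons), `images` (named list of matrices or
#'   `NULL`), and `dir`.
#' @export
generate_cohort <- function(spec, out_dir = NULL,
                            keep_images = is.null(out_dir),
                            overwrite = FALSE) {
  validate_cohort_spec(spec)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
      stop("output directory exists and is not empty; use overwrite = TRUE")
    }
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "rois"), recursive = TRUE, showWarnings = FALSE)
  }
  nroi <- spec$rois_per_region
  side <- rep_len(c("L", "R"), nroi)
  section_index <- rep(seq_len(ceiling(nroi / 2)), each = 2)[seq_len(nroi)]

  rows <- list(); gt <- list(); images <- list(); rois <- list()
  withr::with_seed(spec$seed, {
    for (gi in seq_along(spec$groups)) {
      group <- spec$groups[gi]
      for (ai in seq_len(spec$n_per_group[gi])) {
        animal_id <- sprintf("%s_%02d", group, ai)
        for (region in spec$regions) {
          mult <- multiplier_for(spec, group, region)
          field <- spec$base_field
          field$cell_density <- field$cell_density * mult
          field$seed <- NULL  # draw from the cohort stream
          for (ri in seq_len(nroi)) {
            roi_id <- sprintf("%s_%s_s%d%s", animal_id, region,
                              section_index[ri], side[ri])
            sec <- generate_section(field)
            h <- field$image_shape[1]; w <- field$image_shape[2]
            poly <- roi_polygon_for_frame(h, w)
            rmask <- rasterize_polygon(poly, c(h, w))
            stained <- sum(sec$truth$mask & rmask)
            rows[[length(rows) + 1L]] <- data.frame(
              roi_id = roi_id, animal_id = animal_id, group = group,
              region = region, side = side[ri],
              section_index = section_index[ri],
              image_path = file.path("images", paste0(roi_id, ".tif")),
              roi_path = file.path("rois", paste0(roi_id, ".json")),
              stringsAsFactors = FALSE
            )
            gt[[length(gt) + 1L]] <- data.frame(
              roi_id = roi_id, stained_px = stained, roi_px = sum(rmask),
              true_fraction = stained / sum(rmask), stringsAsFactors = FALSE
            )
            rois[[roi_id]] <- poly
            if (keep_images) images[[roi_id]] <- sec$image
            if (!is.null(out_dir)) {
              tiff::writeTIFF(sec$image,
                              file.path(out_dir, "images", paste0(roi_id, ".tif")),
                              bits.per.sample = 16L, compression = "none")
              write_roi_json(poly, roi_id, region,
                             file.path(out_dir, "rois", paste0(roi_id, ".json")))
            }
          }
        }
      }
    }
    metadata <- if (length(rows)) do.call(rbind, rows) else empty_metadata()
    if (nrow(metadata)) {
      metadata$blinded_id <- sprintf("B%04d", sample(nrow(metadata)))
    } else {
      metadata$blinded_id <- character(0)
    }
  })
  metadata <- metadata[, c("roi_id", "animal_id", "group", "region", "side",
                           "section_index", "blinded_id", "image_path",
                           "roi_path")]
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(roi_id = character(0), stained_px = integer(0),
               roi_px = integer(0), true_fraction = numeric(0))
  cohort <- structure(
    list(spec = spec, metadata = metadata, ground_truth = ground_truth,
         rois = rois, images = if (keep_images) images else NULL,
         dir = out_dir),
    class = "ps6_cohort"
  )
  if (!is.null(out_dir)) {
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    utils::write.csv(ground_truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(spec_to_list(spec),
                         file.path(out_dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cohort
}

empty_metadata <- function() {
  data.frame(roi_id = character(0), animal_id = character(0),
             group = character(0), region = character(0), side = character(0),
             section_index = integer(0), image_path = character(0),
             roi_path = character(0), stringsAsFactors = FALSE)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$base_field)) out$base_field <- unclass(out$base_field)
  out
}

#' Read a cohort previously written by [generate_cohort()]
#'
#' Restores metadata, ground truth and ROI polygons from an on-disk cohort.
#' Images stay on disk and are read lazily by [measure_cohort()].
#'
#' @param dir Cohort directory.
#' @return A `ps6_cohort` object (without in-memory images).
#' @export
read_cohort <- function(dir) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"),
                        stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path))
    utils::read.csv(gt_path, stringsAsFactors = FALSE) else NULL
  spec_path <- file.path(dir, "cohort_spec.json")
  spec <- if (file.exists(spec_path))
    jsonlite::read_json(spec_path, simplifyVector = TRUE) else NULL
  rois <- lapply(md$roi_path, function(p) read_roi_json(file.path(dir, p)))
  names(rois) <- md$roi_id
  structure(
    list(spec = spec, metadata = md, ground_truth = gt, rois = rois,
         images = NULL, dir = dir),
    class = "ps6_cohort"
  )
}

#' @export
print.ps6_cohort <- function(x, ...) {
  cat("Synthetic IHC cohort:", nrow(x$metadata), "ROIs\n")
  if (nrow(x$metadata)) {
    cat("  groups: ", paste(unique(x$metadata$group), collapse = ", "), "\n")
    cat("  regions:", length(unique(x$metadata$region)),
        " animals:", length(unique(x$metadata$animal_id)), "\n")
  }
  if (!is.null(x$dir)) cat("  on disk at:", x$dir, "\n")
  invisible(x)
}
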