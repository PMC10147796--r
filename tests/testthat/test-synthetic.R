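test_that("empty field is constant at background with zero true fraction", {
  spec <- stain_field_spec(image_shape = c(40L, 50L), cell_density = 0,
                           noise_sd = 0, background_stain_sd = 0, seed = 1)
  sec <- generate_section(spec)
  expect_equal(dim(sec$image), c(40L, 50L))
  # constant up to 16-bit quantization of the background level
  expect_equal(unique(as.vector(sec$image)),
               round(0.85 * 65535) / 65535)
  expect_identical(sum(sec$truth$mask), 0L)
  expect_identical(sec$truth$fraction, 0)
})

test_that("ground-truth fraction is exactly mask count over frame pixels", {
  for (seed in 1:5) {
    sec <- generate_section(small_field(seed = seed))
    expect_identical(sec$truth$fraction,
                     sum(sec$truth$mask) / length(sec$truth$mask))
    expect_identical(dim(sec$truth$mask), dim(sec$image))
    expect_true(sec$truth$fraction >= 0 && sec$truth$fraction <= 1)
  }
})

test_that("annulus mask matches brute-force pixel distance check", {
  h <- 30L; w <- 30L; cy <- 14.3; cx <- 16.8; r_in <- 2.5; r_out <- 5
  mask <- ps6quant:::annulus_union_mask(h, w, cy, cx, r_in, r_out)
  ref <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    d2 <- (r - 0.5 - cy)^2 + (c - 0.5 - cx)^2
    ref[r, c] <- d2 <= r_out^2 && d2 > r_in^2
  }
  expect_identical(mask, ref)
})

test_that("identical spec and seed reproduce images and masks bit-for-bit", {
  spec <- small_field(seed = 99)
  a <- generate_section(spec)
  b <- generate_section(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$mask, b$truth$mask)
})

test_that("spec validation rejects degenerate fields", {
  expect_error(stain_field_spec(image_shape = c(0, 10)), "image_shape")
  expect_error(stain_field_spec(nucleus_radius_um = 9, cell_radius_um = 8),
               "nucleus_radius_um")
  expect_error(stain_field_spec(stain_level = 1.5), "stain_level")
  expect_error(stain_field_spec(noise_sd = -1), "noise_sd")
})

test_that("expected true fraction increases with cell density", {
  mean_frac <- function(density) {
    mean(vapply(1:40, function(s) {
      generate_section(small_field(cell_density = density,
                                   seed = s))$truth$fraction
    }, numeric(1)))
  }
  expect_lt(mean_frac(100), mean_frac(300))
})

test_that("cohort honors the counting contract and metadata schema", {
  spec <- cohort_spec(regions = c("NDl", "TOs", "RF"),
                      groups = c("control", "trained"),
                      n_per_group = 2, rois_per_region = 3,
                      base_field = small_field(), seed = 11)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$metadata), 2 * 2 * 3 * 3)
  expect_setequal(
    names(co$metadata),
    c("roi_id", "animal_id", "group", "region", "side", "section_index",
      "blinded_id", "image_path", "roi_path")
  )
  expect_false(anyDuplicated(co$metadata$blinded_id) > 0)
  expect_false(anyDuplicated(co$metadata$roi_id) > 0)
  # both sides represented
  expect_setequal(unique(co$metadata$side), c("L", "R"))
  # ground truth congruent with metadata and exact by construction
  expect_setequal(co$ground_truth$roi_id, co$metadata$roi_id)
  expect_equal(co$ground_truth$true_fraction,
               co$ground_truth$stained_px / co$ground_truth$roi_px)
})

test_that("empty cohort (n_per_group = 0) yields valid empty tables", {
  spec <- cohort_spec(regions = "NDl", groups = c("control", "trained"),
                      n_per_group = 0, rois_per_region = 1,
                      base_field = small_field(), seed = 1)
  co <- generate_cohort(spec)
  expect_identical(nrow(co$metadata), 0L)
  expect_identical(nrow(co$ground_truth), 0L)
  expect_true("blinded_id" %in% names(co$metadata))
})

test_that("multiplier map validation catches bad entries", {
  mk <- function(m) cohort_spec(regions = c("NDl", "TOs"),
                                multipliers = m,
                                base_field = small_field())
  expect_error(mk(data.frame(group = "trained", region = "XX",
                             multiplier = 2)), "unknown region")
  expect_error(mk(data.frame(group = "ghosts", region = "NDl",
                             multiplier = 2)), "unknown group")
  expect_error(mk(data.frame(group = "trained", region = "NDl",
                             multiplier = -1)), "positive")
  expect_error(mk(data.frame(group = "control", region = "NDl",
                             multiplier = 2)), "control")
})

test_that("activation multiplier raises mean true fraction over seeds", {
  # one-sided sign check over replicate cohorts: trained NDl (x2) vs control
  frac <- function(seed) {
    spec <- cohort_spec(
      regions = "NDl", groups = c("control", "trained"), n_per_group = 1,
      rois_per_region = 1,
      multipliers = data.frame(group = "trained", region = "NDl",
                               multiplier = 2),
      base_field = small_field(), seed = seed
    )
    gt <- merge(generate_cohort(spec)$metadata,
                generate_cohort(spec)$ground_truth, by = "roi_id")
    c(control = gt$true_fraction[gt$group == "control"],
      trained = gt$true_fraction[gt$group == "trained"])
  }
  fr <- vapply(1:100, frac, numeric(2))
  expect_gt(mean(fr["trained", ]), mean(fr["control", ]))
})

test_that("cohort writes and reads its open-format contract", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(regions = "NDl", groups = c("control", "trained"),
                      n_per_group = 1, rois_per_region = 2,
                      base_field = small_field(), seed = 3)
  co <- generate_cohort(spec, out_dir = dir, keep_images = TRUE)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(all(file.exists(file.path(dir, co$metadata$image_path))))
  expect_true(all(file.exists(file.path(dir, co$metadata$roi_path))))
  # TIFF round trip preserves the quantized image exactly
  img <- tiff::readTIFF(file.path(dir, co$metadata$image_path[1]))
  expect_identical(img, co$images[[co$metadata$roi_id[1]]])
  # re-reading restores metadata, ground truth and polygons
  back <- read_cohort(dir)
  expect_equal(back$metadata, co$metadata)
  expect_equal(back$ground_truth, co$ground_truth)
  rid <- co$metadata$roi_id[1]
  expect_equal(back$rois[[rid]]$x, co$rois[[rid]]$x)
  # refuses to clobber without overwrite
  expect_error(generate_cohort(spec, out_dir = dir), "overwrite")
})
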