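test_that("rasterized polygons match the mgcv point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(421)
  for (t in 1:20) {
    p <- ps6quant:::roi_polygon_for_frame(60, 80)
    m1 <- rasterize_polygon(p, c(60, 80))
    centers <- cbind(x = rep(seq_len(80) - 0.5, each = 60),
                     y = rep(seq_len(60) - 0.5, times = 80))
    m2 <- matrix(mgcv::in.out(cbind(c(p$x, p$x[1]), c(p$y, p$y[1])),
                              centers), 60, 80)
    expect_identical(m1, m2)
  }
})

test_that("square polygon rasterizes to the expected pixel block", {
  # rectangle [2,6) x [3,8) in 0-based pixel coords -> pixel centers
  # 2.5..5.5 (cols 3..6, 1-based) and 3.5..7.5 (rows 4..8)
  mask <- rasterize_polygon(rect_poly(2, 3, 6, 8), c(10, 10))
  ref <- matrix(FALSE, 10, 10); ref[4:8, 3:6] <- TRUE
  expect_identical(mask, ref)
  expect_error(rasterize_polygon(rect_poly(-1, 0, 5, 5), c(10, 10)),
               "outside")
})

test_that("blind order is a permutation that hides group identity", {
  records <- data.frame(
    roi_id = paste0("r", 1:8), animal_id = rep(c("a1", "a2"), 4),
    group = rep(c("control", "trained"), each = 4),
    blinded_id = sprintf("B%02d", sample(8)),
    image_path = paste0("img", 1:8, ".tif"),
    stringsAsFactors = FALSE
  )
  b <- blind_order(records, seed = 5)
  expect_setequal(b$presentation$blinded_id, records$blinded_id)
  expect_false(any(c("group", "animal_id", "roi_id") %in%
                     names(b$presentation)))
  expect_true(all(c("blinded_id", "group", "animal_id") %in% names(b$key)))
  # determinism and distinctness
  expect_identical(blind_order(records, seed = 5)$presentation,
                   b$presentation)
  # empty input
  empty <- blind_order(records[0, ], seed = 1)
  expect_identical(nrow(empty$presentation), 0L)
  # duplicate blinded ids rejected
  records$blinded_id <- "B01"
  expect_error(blind_order(records, seed = 1), "duplicate")
})

test_that("background estimate follows the median convention", {
  img <- matrix(0.8, 20, 20)
  roi <- matrix(TRUE, 20, 20)
  est <- estimate_background(img, roi)
  expect_equal(est$background, 0.2)
  expect_equal(est$mad, 0)
  img[1:10, ] <- 0.2  # half 0.2, half 0.8 -> inverted 0.8 / 0.2
  expect_equal(estimate_background(img, roi)$background, 0.5)
})

test_that("background recovery on synthetic sections is within 2 MAD", {
  hits <- vapply(1:50, function(seed) {
    sec <- generate_section(small_field(seed = seed))
    if (sec$truth$fraction >= 0.1) return(NA)  # cells must be sparse
    est <- estimate_background(sec$image, matrix(TRUE, 96, 96))
    abs(est$background - (1 - 0.85)) <= 2 * max(est$mad, 1e-6)
  }, logical(1))
  expect_true(all(hits, na.rm = TRUE))
})

test_that("noise-free stain mask recovers ground truth exactly", {
  spec <- small_field(noise_sd = 0, background_stain_sd = 0, seed = 17)
  sec <- generate_section(spec)
  roi <- matrix(TRUE, 96, 96)
  expect_identical(stain_mask(sec$image, roi), sec$truth$mask)
  m <- measure_roi(sec$image, roi)
  expect_identical(m$fraction, sec$truth$fraction)
})

test_that("huge k empties the mask; cell-free noisy ROI stays near zero", {
  sec <- generate_section(small_field(seed = 3))
  roi <- matrix(TRUE, 96, 96)
  expect_identical(sum(stain_mask(sec$image, roi, k = 1e6)), 0L)
  fracs <- vapply(1:100, function(seed) {
    s <- generate_section(small_field(cell_density = 0, seed = seed))
    measure_roi(s$image, roi, k = 5)$fraction
  }, numeric(1))
  expect_lte(mean(fracs), 0.01)
})

test_that("measure_roi reports consistent areas, units, and bounds", {
  img <- matrix(0.9, 10, 10)
  img[1, 1:10] <- 0.1  # 10 dark pixels
  roi <- matrix(TRUE, 10, 10)
  m <- measure_roi(img, roi, background = 0.1, spread = 0.01,
                   resolution_um = 1.6)
  expect_equal(m$fraction, 0.1)
  expect_equal(m$stained_px, 10)
  expect_equal(m$total_px, 100)
  expect_equal(m$stained_um2, 10 * 1.6^2)
  expect_equal(m$total_um2, 100 * 1.6^2)
  # fully stained ROI against an external background reference
  img2 <- matrix(0.3, 10, 10)
  m2 <- measure_roi(img2, roi, background = 0.1, spread = 0.01)
  expect_equal(m2$fraction, 1.0)
  # mask dimensions must match
  expect_error(measure_roi(img, matrix(TRUE, 5, 5)), "dimensions")
  expect_error(measure_roi(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("animal pooling is area-weighted, bounded, and guarded", {
  mk <- function(st, tot) data.frame(
    stained_px = st, total_px = tot,
    stained_um2 = st * 2.56, total_um2 = tot * 2.56,
    animal_id = "a1", region = "NDl", fraction = st / tot
  )
  pooled <- aggregate_animal(rbind(mk(10, 100), mk(30, 100)))
  expect_equal(pooled$fraction, 0.2)
  expect_equal(pooled$n_rois, 2)
  # single ROI is the identity
  expect_equal(aggregate_animal(mk(7, 50))$fraction, 7 / 50)
  # equal areas: pooled equals mean of fractions
  two <- rbind(mk(5, 200), mk(45, 200))
  expect_equal(aggregate_animal(two)$fraction, mean(two$fraction))
  # pooled value always between min and max ROI fraction
  set.seed(8)
  for (i in 1:20) {
    st <- sample(0:50, 3); tot <- sample(60:200, 3)
    d <- do.call(rbind, Map(mk, st, tot))
    p <- aggregate_animal(d)$fraction
    expect_gte(p, min(d$fraction)); expect_lte(p, max(d$fraction))
  }
  bad <- rbind(mk(1, 10), mk(1, 10)); bad$animal_id <- c("a1", "a2")
  expect_error(aggregate_animal(bad), "animal_id")
  expect_error(aggregate_animal(mk(1, 10)[0, ]))
})

test_that("measured fractions track ground truth on synthetic ROIs", {
  spec <- cohort_spec(regions = "NDl", groups = c("control", "trained"),
                      n_per_group = 10, rois_per_region = 2,
                      multipliers = data.frame(group = "trained",
                                               region = "NDl",
                                               multiplier = 2),
                      base_field = small_field(), seed = 77)
  co <- generate_cohort(spec)
  meas <- measure_cohort(co)
  cmp <- merge(meas, co$ground_truth, by = "roi_id")
  # truth within ROI: recompute from masks for a subset to confirm congruence
  expect_true(all(cmp$fraction >= 0 & cmp$fraction <= 1))
  expect_lte(mean(abs(cmp$fraction - cmp$true_fraction)), 0.02)
})
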