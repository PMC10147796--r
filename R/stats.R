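#' Per-group, per-region mean stained fractions
#'
#' Arithmetic mean of the per-animal pooled fractions within each
#' group x region cell.
#'
#' @param animal_measurements Data frame with columns `group`, `region`,
#'   `fraction` (one row per animal x region, as from
#'   [aggregate_animals()]).
#' @return Data frame: `group`, `region`, `n`, `mean_fraction`.
#' @export
group_means <- function(animal_measurements) {
  stopifnot(is.data.frame(animal_measurements),
            all(c("group", "region", "fraction") %in%
                  names(animal_measurements)))
  agg <- stats::aggregate(
    fraction ~ group + region, data = animal_measurements,
    FUN = function(v) c(n = length(v), mean = mean(v))
  )
  out <- data.frame(
    group = agg$group, region = agg$region,
    n = as.integer(agg$fraction[, "n"]),
    mean_fraction = agg$fraction[, "mean"],
    stringsAsFactors = FALSE
  )
  out[order(out$region, out$group), , drop = FALSE]
}

#' Log activation ratio of a group mean relative to control
#'
#' `log(group_mean / control_mean)` in the configured base (default 10):
#' the relative activation of a brain region in a learning group over the
#' control baseline. Zero or negative means are a hard error — they signal
#' a degenerate configuration (no staining at all), not a zero activation.
#'
#' @param group_mean,control_mean Positive mean stained fractions.
#' @param base Logarithm base (default 10).
#' @return Scalar log ratio (0 when the means are equal).
#' @export
#' @examples
#' activation_log_ratio(0.05, 0.01)  # log10(5) = 0.69897
activation_log_ratio <- function(group_mean, control_mean, base = 10) {
  if (any(!is.finite(group_mean)) || any(!is.finite(control_mean)) ||
      any(group_mean <= 0) || any(control_mean <= 0)) {
    stop("group and control means must be positive for a log ratio")
  }
  log(group_mean / control_mean, base = base)
}

#' Per-region activation report (group means, U tests, log ratios)
#'
#' Assembles the per-region comparison of every non-control group against
#' the control group: animal-level mean fractions per group, a two-sided
#' Mann-Whitney U test of group vs control, the log activation ratio of the
#' group mean over the control mean, and a significance flag at `alpha`.
#' P-values are uncorrected by default (per-region decisions); optional
#' Benjamini-Hochberg adjustment is available.
#'
#' @param animal_measurements Data frame with one row per animal x region
#'   (columns `animal_id`, `group`, `region`, `fraction`).
#' @param control_group Label of the reference group (default `"control"`).
#' @param alpha Significance level (default 0.05).
#' @param log_base Base for the activation log ratio (default 10).
#' @param adjust `"none"` (default) or `"BH"`; when `"BH"`, the adjusted
#'   p-values are reported in `p_adjusted` and the significance flag uses
#'   them.
#' @param exact_limit Passed to [mann_whitney_u()].
#' @return Data frame of class `ps6_report`, one row per
#'   (non-control group) x region: `region`, `group`, `n_group`,
#'   `n_control`, `mean_group`, `mean_control`, `U`, `p_value`, `method`,
#'   `log_ratio`, `significant` (and `p_adjusted` if adjusted). The full
#'   group-mean table (including the control) is attached as attribute
#'   `group_means`; `alpha` and `log_base` are attached likewise.
#' @export
build_report <- function(animal_measurements, control_group = "control",
                         alpha = 0.05, log_base = 10, adjust = c("none", "BH"),
                         exact_limit = 20) {
  adjust <- match.arg(adjust)
  df <- animal_measurements
  stopifnot(is.data.frame(df),
            all(c("animal_id", "group", "region", "fraction") %in% names(df)))
  if (!control_group %in% df$group) {
    stop("control group '", control_group, "' missing from measurements")
  }
  groups <- setdiff(unique(df$group), control_group)
  regions <- unique(df$region)
  rows <- list()
  for (region in regions) {
    ctl <- df$fraction[df$group == control_group & df$region == region]
    if (length(ctl) == 0) {
      stop("no control measurements for region ", region)
    }
    for (group in groups) {
      g <- df$fraction[df$group == group & df$region == region]
      if (length(g) == 0) next
      ut <- mann_whitney_u(g, ctl, exact_limit = exact_limit)
      rows[[length(rows) + 1L]] <- data.frame(
        region = region, group = group,
        n_group = length(g), n_control = length(ctl),
        mean_group = mean(g), mean_control = mean(ctl),
        U = ut$U_x, p_value = ut$p_value, method = ut$method,
        log_ratio = activation_log_ratio(mean(g), mean(ctl),
                                         base = log_base),
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (adjust == "BH") {
    report$p_adjusted <- stats::p.adjust(report$p_value, method = "BH")
    report$significant <- report$p_adjusted < alpha
  } else {
    report$significant <- report$p_value < alpha
  }
  attr(report, "group_means") <- group_means(df)
  attr(report, "alpha") <- alpha
  attr(report, "log_base") <- log_base
  class(report) <- c("ps6_report", "data.frame")
  report
}

#' @export
print.ps6_report <- function(x, ...) {
  cat("Activation report:", nrow(x), "group-vs-control comparisons across",
      length(unique(x$region)), "regions (alpha =",
      attr(x, "alpha"), ")\n")
  NextMethod()
}

#' Monte-Carlo error calibration of the full measurement pipeline
#'
#' Estimates the type-I error rate (with `effect_multiplier = 1`) or the
#' power (otherwise) of the per-region decision rule by simulating complete
#' two-group cohort comparisons: each replicate generates a control and a
#' treatment arm through the synthetic-histology generator, measures
#' stained fractions, pools per animal, and applies the Mann-Whitney U test
#' at `alpha`. The returned rate is the fraction of replicates rejected.
#'
#' @param n_reps Number of replicate cohorts (>= 100 for stable rates; the
#'   function runs with fewer but warns).
#' @param n1,n2 Animals in the treatment and control arms (default 10/10,
#'   the standard design).
#' @param alpha Significance level.
#' @param effect_multiplier Cell-density multiplier applied to the
#'   treatment arm (1 = null).
#' @param field [stain_field_spec()] for the simulated sections; the
#'   default uses the standard noise settings on a compact 128 x 128 px
#'   frame to keep large replicate counts fast.
#' @param rois_per_animal ROIs per animal (default 1 for calibration).
#' @param k Threshold multiplier for [measure_roi()].
#' @param seed Master seed; replicate seeds are drawn from it.
#' @return List of class `ps6_calibration`: `rate`, `p_values`, `n_reps`,
#'   `alpha`, `effect_multiplier`, `n1`, `n2`.
#' @export
error_calibration <- function(n_reps, n1 = 10, n2 = 10, alpha = 0.05,
                              effect_multiplier = 1,
                              field = stain_field_spec(image_shape = c(128L, 128L)),
                              rois_per_animal = 1, k = 5, seed = 1) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be positive")
  if (n_reps < 1) stop("n_reps must be positive")
  if (n_reps < 100) warning("n_reps < 100 gives unstable rate estimates")
  mult <- data.frame(group = "treatment", region = "R1",
                     multiplier = effect_multiplier)
  p_values <- numeric(n_reps)
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max, n_reps))
  for (i in seq_len(n_reps)) {
    spec <- cohort_spec(
      regions = "R1", groups = c("control", "treatment"),
      n_per_group = c(n2, n1), rois_per_region = rois_per_animal,
      multipliers = if (effect_multiplier != 1) mult else NULL,
      base_field = field, seed = rep_seeds[i]
    )
    cohort <- generate_cohort(spec)
    animal <- aggregate_animals(measure_cohort(cohort, k = k))
    ut <- mann_whitney_u(animal$fraction[animal$group == "treatment"],
                         animal$fraction[animal$group == "control"])
    p_values[i] <- ut$p_value
  }
  structure(
    list(rate = mean(p_values < alpha), p_values = p_values,
         n_reps = n_reps, alpha = alpha,
         effect_multiplier = effect_multiplier, n1 = n1, n2 = n2),
    class = "ps6_calibration"
  )
}

#' @export
print.ps6_calibration <- function(x, ...) {
  kind <- if (x$effect_multiplier == 1) "type-I error rate" else
    sprintf("power at multiplier %g", x$effect_multiplier)
  cat(sprintf("Pipeline calibration: %s = %.4f (%d reps, n = %d vs %d, alpha = %g)\n",
              kind, x$rate, x$n_reps, x$n1, x$n2, x$alpha))
  invisible(x)
}
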