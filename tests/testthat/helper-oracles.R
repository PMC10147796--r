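# Independent brute-force oracles used to validate the implementation.

# Exact two-sided Mann-Whitney p by full enumeration of all label
# assignments (combn over pooled indices). Tie-free inputs only.
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(N, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Sliding-window criterion oracle.
criterion_oracle <- function(n_correct, threshold = 7, window = 3) {
  if (length(n_correct) < window) return(NA_integer_)
  for (s in window:length(n_correct)) {
    if (all(n_correct[(s - window + 1):s] >= threshold)) return(s)
  }
  NA_integer_
}

# Recursive count of run-constrained balanced sequences (independent of the
# combn enumeration used by count_valid_schemes).
count_schemes_recursive <- function(n_trials, n_per_side, max_run) {
  recur <- function(left, right, last, run) {
    if (left == 0 && right == 0) return(1L)
    total <- 0L
    if (left > 0 && !(last == "L" && run >= max_run)) {
      total <- total + recur(left - 1, right, "L",
                             if (last == "L") run + 1 else 1)
    }
    if (right > 0 && !(last == "R" && run >= max_run)) {
      total <- total + recur(left, right - 1, "R",
                             if (last == "R") run + 1 else 1)
    }
    total
  }
  recur(n_per_side, n_per_side, "", 0)
}

# Small field spec for fast synthetic tests (standard noise settings,
# compact frame).
small_field <- function(..., seed = NULL) {
  stain_field_spec(image_shape = c(96L, 96L), seed = seed, ...)
}

# Copy of a field spec with a different seed.
within_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed)
  spec
}

# A simple rectangle polygon in 0-based pixel coordinates.
rect_poly <- function(x0, y0, x1, y1) {
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
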