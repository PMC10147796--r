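#' Validate a rotational scheme
#'
#' A rotational scheme is the predetermined left/right sequence of the
#' rewarded (positive) stimulus over the 10 trials of a session: balanced
#' (shown equally often on each side) and never on the same side more than
#' `max_run` times in a row.
#'
#' @param scheme Character string of side labels (e.g. `"LLRLRRLRLR"`) or a
#'   character vector of single letters.
#' @param n_per_side Required count per side (default 5).
#' @param max_run Longest allowed run of one side (default 2).
#' @return `TRUE` iff the scheme satisfies both constraints.
#' @export
#' @examples
#' validate_scheme("LLRLRRLRLR")  # TRUE
#' validate_scheme("LLLRRRLRLR")  # FALSE (run of three)
validate_scheme <- function(scheme, n_per_side = 5, max_run = 2) {
  s <- scheme_chars(scheme)
  if (length(s) != 2 * n_per_side) return(FALSE)
  if (!all(s %in% c("L", "R"))) return(FALSE)
  if (sum(s == "L") != n_per_side) return(FALSE)
  max(rle(s)$lengths) <= max_run
}

scheme_chars <- function(scheme) {
  if (length(scheme) == 1 && nchar(scheme) > 1) {
    strsplit(scheme, "")[[1]]
  } else {
    as.character(scheme)
  }
}

#' Generate rotational schemes by constrained rejection sampling
#'
#' Draws side sequences uniformly at random from the set of valid schemes
#' (balanced, run-limited) by sampling balanced permutations and rejecting
#' those that violate the run constraint. Rejection from the uniform
#' balanced distribution leaves the accepted draws uniform over the valid
#' set (84 schemes for 10 trials, 5 per side, runs of at most 2).
#'
#' @param n Number of schemes to generate.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param n_trials Trials per session (default 10).
#' @param max_run Longest allowed run (default 2).
#' @return Character vector of `n` scheme strings.
#' @export
generate_scheme <- function(n = 1, seed = NULL, n_trials = 10, max_run = 2) {
  if (n_trials %% 2 != 0) stop("n_trials must be even for a balanced scheme")
  n_per_side <- n_trials / 2
  base <- rep(c("L", "R"), each = n_per_side)
  draw <- function() {
    out <- character(n)
    for (i in seq_len(n)) {
      repeat {
        s <- sample(base)
        if (max(rle(s)$lengths) <= max_run) break
      }
      out[i] <- paste(s, collapse = "")
    }
    out
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), draw()) else draw()
}

#' Count valid rotational schemes by exhaustive enumeration
#'
#' Enumerates all balanced side sequences (`choose(n_trials, n_per_side)`
#' of them) and counts those whose longest same-side run does not exceed
#' `max_run`. Intended for the small session lengths used in practice.
#'
#' @param n_trials Total trials (must equal `2 * n_per_side`).
#' @param n_per_side Presentations per side.
#' @param max_run Longest allowed run.
#' @return Integer count of valid schemes.
#' @export
#' @examples
#' count_valid_schemes(10, 5, 2)  # 84
count_valid_schemes <- function(n_trials, n_per_side, max_run) {
  if (2 * n_per_side != n_trials) {
    stop("n_per_side * 2 must equal n_trials")
  }
  if (max_run < 1) stop("max_run must be >= 1")
  if (n_trials > 24) stop("exhaustive enumeration limited to n_trials <= 24")
  if (n_trials == 0) return(1L)
  pos <- utils::combn(n_trials, n_per_side)
  ok <- 0L
  for (j in seq_len(ncol(pos))) {
    s <- rep("R", n_trials)
    s[pos[, j]] <- "L"
    if (max(rle(s)$lengths) <= max_run) ok <- ok + 1L
  }
  ok
}

#' Assign rotational schemes to a block of sessions
#'
#' Four rotational schemes are used consecutively, cycling over every four
#' sessions; with two sessions per day this covers two days per cycle.
#'
#' @param schemes Character vector of exactly 4 scheme strings.
#' @param n_sessions Number of sessions to schedule.
#' @param sessions_per_day Sessions run per day (default 2, at fixed times).
#' @return Data frame: `session_index`, `day`, `slot_in_day`,
#'   `scheme_index` (1-4), `scheme`.
#' @export
schedule_sessions <- function(schemes, n_sessions, sessions_per_day = 2) {
  if (length(schemes) != 4) stop("exactly 4 rotational schemes are required")
  if (n_sessions < 0) stop("n_sessions must be >= 0")
  s <- seq_len(n_sessions)
  idx <- ((s - 1) %% 4) + 1
  data.frame(
    session_index = s,
    day = ((s - 1) %/% sessions_per_day) + 1,
    slot_in_day = ((s - 1) %% sessions_per_day) + 1,
    scheme_index = idx,
    scheme = schemes[idx],
    stringsAsFactors = FALSE
  )
}

#' One session's trial outcomes
#'
#' @param trials Logical vector of per-trial correctness (default length 10).
#' @param session_index Optional session number.
#' @return List of class `session_record` with `session_index`, `trials`,
#'   `n_correct`.
#' @export
session_record <- function(trials, session_index = NA_integer_) {
  trials <- as.logical(trials)
  if (any(is.na(trials))) stop("trials must be TRUE/FALSE")
  structure(
    list(session_index = session_index, trials = trials,
         n_correct = sum(trials)),
    class = "session_record"
  )
}

#' First session at which the learning criterion is reached
#'
#' The learning criterion is seven or more correct decisions out of ten
#' trials in three consecutive sessions. Evaluated online: the function
#' returns the smallest session index `s >= window` such that sessions
#' `s - window + 1, ..., s` all reach `threshold` correct, or
#' `NA_integer_` if the criterion is never met.
#'
#' @param sessions List of [session_record()]s in session order (each must
#'   have exactly `n_trials` trials), or an integer vector of per-session
#'   correct counts.
#' @param threshold Minimum correct decisions per session (default 7).
#' @param window Number of consecutive qualifying sessions (default 3).
#' @param n_trials Trials per session (default 10; enforced for records).
#' @return Integer session index, or `NA_integer_`.
#' @export
#' @examples
#' criterion_met(c(7, 7, 7))        # 3
#' criterion_met(c(7, 6, 7, 7, 7))  # 5
criterion_met <- function(sessions, threshold = 7, window = 3,
                          n_trials = 10) {
  if (is.list(sessions)) {
    nc <- vapply(sessions, function(s) {
      stopifnot(inherits(s, "session_record"))
      if (length(s$trials) != n_trials) {
        stop("session has ", length(s$trials), " trials; expected ", n_trials)
      }
      s$n_correct
    }, numeric(1))
  } else {
    nc <- as.numeric(sessions)
    if (any(nc < 0 | nc > n_trials)) {
      stop("correct counts must lie in [0, n_trials]")
    }
  }
  if (length(nc) < window) return(NA_integer_)
  hit <- nc >= threshold
  for (s in window:length(nc)) {
    if (all(hit[(s - window + 1):s])) return(as.integer(s))
  }
  NA_integer_
}

#' Simulate per-session Bernoulli trial outcomes
#'
#' Test harness for criterion detection: each session's trials are iid
#' Bernoulli with that session's success probability.
#'
#' @param p_correct_by_session Numeric vector of per-session probabilities
#'   in \[0, 1\].
#' @param seed Integer seed, or `NULL`.
#' @param n_trials Trials per session (default 10).
#' @return List of [session_record()]s.
#' @export
simulate_learner <- function(p_correct_by_session, seed = NULL,
                             n_trials = 10) {
  p <- as.numeric(p_correct_by_session)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  sim <- function() {
    lapply(seq_along(p), function(i) {
      session_record(stats::runif(n_trials) < p[i], session_index = i)
    })
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), sim()) else sim()
}

#' Habituation/dishabituation schedule
#'
#' The novelty-group schedule: during habituation, three sessions of four
#' trials each per day; on the final day a single session, followed (after
#' a long retention delay) by one 30-second presentation of the novelty
#' stimulus. Within each trial, food is released 30 s after stimulus onset,
#' the stimulus is turned off 2 min after the food delivery, and the next
#' trial starts 5 min later. The timing fields are schedule metadata, not a
#' simulation of behavior.
#'
#' @param n_days Habituation days including the final day (default 5).
#' @param trials_per_session Trials per session (default 4).
#' @param sessions_per_day Sessions per habituation day (default 3).
#' @param stimulus_to_food_s Delay from stimulus onset to food release
#'   (default 30 s).
#' @param stimulus_off_after_food_s Stimulus-off delay after food
#'   (default 120 s).
#' @param intertrial_s Inter-trial interval (default 300 s).
#' @param dishabituation_s Duration of the single novelty presentation
#'   (default 30 s).
#' @return List of class `habituation_schedule`: `trials` (data frame of
#'   `day`, `session_in_day`, `trial_in_session`, `phase`) plus the timing
#'   parameters.
#' @export
habituation_schedule <- function(n_days = 5, trials_per_session = 4,
                                 sessions_per_day = 3,
                                 stimulus_to_food_s = 30,
                                 stimulus_off_after_food_s = 120,
                                 intertrial_s = 300,
                                 dishabituation_s = 30) {
  if (n_days < 1) stop("n_days must be >= 1")
  rows <- list()
  for (d in seq_len(n_days)) {
    ns <- if (d == n_days) 1 else sessions_per_day
    for (s in seq_len(ns)) {
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, session_in_day = s,
        trial_in_session = seq_len(trials_per_session),
        phase = "habituation", stringsAsFactors = FALSE
      )
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    day = n_days, session_in_day = NA_integer_, trial_in_session = 1L,
    phase = "dishabituation", stringsAsFactors = FALSE
  )
  structure(
    list(trials = do.call(rbind, rows),
         trials_per_session = trials_per_session,
         sessions_per_day = sessions_per_day,
         stimulus_to_food_s = stimulus_to_food_s,
         stimulus_off_after_food_s = stimulus_off_after_food_s,
         intertrial_s = intertrial_s,
         dishabituation_s = dishabituation_s),
    class = "habituation_schedule"
  )
}
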