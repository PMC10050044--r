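# Task design: switch-constrained digit sequences, trial schedules, the
# per-participant time-limit calibration rule and the trial scoring rule.

ODD_DIGITS <- c(1L, 3L, 5L, 7L, 9L)
EVEN_DIGITS <- c(2L, 4L, 6L, 8L)
REWARD_POINTS <- c(3L, 6L, 9L, 12L)
EFFORT_LABELS <- c("20%", "40%", "60%", "80%")
CALIBRATION_MARGIN_MS <- 500
REJECT_TIMEOUT_MS <- 2500 # schedule metadata only; no computational effect

#' Effort levels of the Number Switching Task
#'
#' The four effort levels are labelled by nominal percentages and map onto
#' pairs of parity-switch counts: 20% -> 1 or 2 switches, 40% -> 3 or 4,
#' 60% -> 5 or 6, 80% -> 7 or 8.  On any given trial the precise switch
#' count is drawn at random from the level's pair, so sequences stay
#' unpredictable while the nominal demand is fixed.
#'
#' @return A data frame with columns `label`, `pct`, `switch_lo`, `switch_hi`.
#' @export
#' @examples
#' effort_levels()
effort_levels <- function() {
  data.frame(
    label = EFFORT_LABELS,
    pct = c(20L, 40L, 60L, 80L),
    switch_lo = c(1L, 3L, 5L, 7L),
    switch_hi = c(2L, 4L, 6L, 8L),
    stringsAsFactors = FALSE
  )
}

#' Reward levels and their monetary value
#'
#' Offers are worth 3, 6, 9 or 12 points; points convert to pence at
#' 3 points per penny (1, 2, 3, 4p).
#'
#' @param points Integer vector of reward points.
#' @return `reward_levels()` returns the four point values;
#'   `reward_pence()` converts points to pence.
#' @export
reward_levels <- function() REWARD_POINTS

#' @rdname reward_levels
#' @export
reward_pence <- function(points) {
  if (!all(points %in% REWARD_POINTS)) {
    stop_("reward points must be one of 3, 6, 9, 12")
  }
  points / 3
}

# switch set for an effort label ("20%" etc., "20" or 20 also accepted)
effort_switch_set <- function(label) {
  lev <- effort_levels()
  i <- match(normalize_effort(label), lev$pct)
  c(lev$switch_lo[i], lev$switch_hi[i])
}

normalize_effort <- function(label) {
  x <- if (is.numeric(label)) label else suppressWarnings(as.numeric(sub("%", "", as.character(label), fixed = TRUE)))
  if (anyNA(x) || !all(x %in% c(20, 40, 60, 80))) {
    stop_("out-of-grid effort level; expected one of 20%, 40%, 60%, 80%")
  }
  x
}

#' Count parity switches in a digit sequence
#'
#' A parity switch is an adjacent pair of digits whose odd/even status
#' differs; the number of switches is the effort currency of the task.
#'
#' @param digits Integer vector of digits.
#' @return Integer number of adjacent parity transitions.
#' @export
#' @examples
#' count_switches(c(1, 2, 3, 4, 5, 6, 7, 8, 9)) # 8: alternates everywhere
#' count_switches(c(5, 3, 1, 9, 7, 2, 4, 6, 8)) # 1: odd block then even block
count_switches <- function(digits) {
  if (length(digits) == 0L) stop_("empty sequence")
  if (!is.numeric(digits) || any(!is.finite(digits)) ||
      any(digits != as.integer(digits))) {
    stop_("digits must be integers")
  }
  sum(diff(as.integer(digits) %% 2L) != 0L)
}

# All C(9,5) = 126 parity patterns ("O"/"E" strings), grouped by switch count.
parity_pattern_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      odd_pos <- utils::combn(9L, 5L)
      pats <- character(ncol(odd_pos))
      k <- integer(ncol(odd_pos))
      for (j in seq_len(ncol(odd_pos))) {
        v <- rep(0L, 9L)
        v[odd_pos[, j]] <- 1L
        k[j] <- sum(diff(v) != 0L)
        pats[j] <- paste(ifelse(v == 1L, "O", "E"), collapse = "")
      }
      cache <<- split(pats, k)
    }
    cache
  }
})

#' Enumerate parity patterns with a given switch count
#'
#' Lists every length-9 odd/even pattern with exactly five odd slots, four
#' even slots, and exactly `k` parity transitions.  The union over
#' k = 1..8 has size choose(9, 5) = 126; k = 0 is impossible because a
#' single parity run cannot hold nine digits from this pool.
#'
#' @param k Target switch count, 0..8.
#' @return Character vector of patterns such as `"OEOEOEOEO"` (possibly empty).
#' @export
#' @examples
#' enumerate_parity_patterns(8) # exactly one pattern
#' enumerate_parity_patterns(1) # the two block patterns
enumerate_parity_patterns <- function(k) {
  if (!is_count(k) || k < 0 || k > 8) stop_("k must be an integer in 0..8")
  tab <- parity_pattern_table()
  out <- tab[[as.character(k)]]
  if (is.null(out)) character(0) else sort(out)
}

#' Generate a digit sequence with an exact switch count
#'
#' Draws a permutation of the digits 1..9 whose parity-switch count equals
#' `k`.  The parity pattern is drawn uniformly from all valid patterns for
#' `k`, then the five odd digits fill the odd slots in uniformly random
#' order and the four even digits fill the even slots likewise, so the
#' draw is uniform over all valid digit sequences.
#'
#' @param k Target switch count, 1..8.
#' @return List with `digits` (integer vector of length 9) and
#'   `switch_count`.
#' @export
#' @examples
#' set.seed(1)
#' s <- generate_sequence(5)
#' count_switches(s$digits) # 5
generate_sequence <- function(k) {
  if (!is_count(k) || k < 1 || k > 8) stop_("infeasible switch count")
  pats <- enumerate_parity_patterns(k)
  pat <- strsplit(pats[sample.int(length(pats), 1L)], "")[[1]]
  digits <- integer(9L)
  digits[pat == "O"] <- sample(ODD_DIGITS)
  digits[pat == "E"] <- sample(EVEN_DIGITS)
  list(digits = digits, switch_count = k)
}

#' Build a trial schedule for one task phase
#'
#' * `practice`: one sequence of the digits 1..9 in ascending order.
#' * `familiarisation`: 32 sequences, four at each switch count 1..8,
#'   in random order, with no offers and no time limit.
#' * `example`: 10 offer trials introducing the offer framing; offers are
#'   drawn uniformly from the 16 reward-by-effort combinations.
#' * `main`: 80 offer trials, exactly five at each of the 16 combinations,
#'   in random order.
#'
#' Within an offered effort level the switch count is drawn uniformly from
#' the level's two-element switch set.
#'
#' @param phase One of `"practice"`, `"familiarisation"`, `"example"`,
#'   `"main"`.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Data frame with columns `phase`, `trial_index`, `reward_points`,
#'   `effort_label`, `switch_count`, `digits` (9-character string).
#' @export
#' @examples
#' sched <- build_schedule("main", seed = 7)
#' table(sched$reward_points, sched$effort_label) # 5 everywhere
build_schedule <- function(phase, seed = NULL) {
  phases <- c("practice", "familiarisation", "example", "main")
  if (!(length(phase) == 1L && phase %in% phases)) {
    stop_("unknown phase label; expected one of ",
          paste(phases, collapse = ", "))
  }
  with_seed(seed, {
    if (phase == "practice") {
      return(schedule_df(phase, NA_integer_, NA_character_, 8L, "123456789"))
    }
    if (phase == "familiarisation") {
      ks <- sample(rep(1:8, each = 4L))
      digs <- vapply(ks, function(k) {
        paste(generate_sequence(k)$digits, collapse = "")
      }, character(1))
      return(schedule_df(phase, NA_integer_, NA_character_, ks, digs))
    }
    combos <- expand.grid(
      reward_points = REWARD_POINTS, effort_label = EFFORT_LABELS,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    idx <- if (phase == "example") {
      sample.int(nrow(combos), 10L, replace = TRUE)
    } else {
      sample(rep(seq_len(nrow(combos)), each = 5L))
    }
    off <- combos[idx, , drop = FALSE]
    ks <- vapply(off$effort_label, function(lab) {
      ss <- effort_switch_set(lab)
      ss[sample.int(2L, 1L)]
    }, integer(1))
    digs <- vapply(ks, function(k) {
      paste(generate_sequence(k)$digits, collapse = "")
    }, character(1))
    schedule_df(phase, off$reward_points, off$effort_label, ks, digs)
  })
}

schedule_df <- function(phase, reward, effort, k, digits) {
  n <- max(length(reward), length(k))
  data.frame(
    phase = rep(phase, n),
    trial_index = seq_len(n),
    reward_points = as.integer(rep(reward, length.out = n)),
    effort_label = rep(effort, length.out = n),
    switch_count = as.integer(k),
    digits = digits,
    stringsAsFactors = FALSE
  )
}

SCHEDULE_HEADER <- c("phase", "trial_index", "reward_points",
                     "effort_label", "switch_count", "digits")

#' Read or write a trial schedule CSV
#'
#' Schedules serialise with the fixed header
#' `phase,trial_index,reward_points,effort_label,switch_count,digits`.
#'
#' @param schedule Data frame from [build_schedule()].
#' @param file Path (or connection for writing).
#' @return `read_schedule()` returns the schedule data frame.
#' @export
write_schedule <- function(schedule, file) {
  if (!identical(names(schedule), SCHEDULE_HEADER)) {
    stop_("schedule columns must be exactly: ",
          paste(SCHEDULE_HEADER, collapse = ","))
  }
  utils::write.csv(schedule, file, row.names = FALSE, quote = FALSE)
  invisible(schedule)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(digits = "character"))
  if (!identical(names(x), SCHEDULE_HEADER)) {
    stop_("malformed schedule header; expected ",
          paste(SCHEDULE_HEADER, collapse = ","))
  }
  x
}

#' Calibrate the main-phase time limit from familiarisation performance
#'
#' The allowed completion time is the median time taken on the hardest,
#' 8-switch familiarisation trials plus 500 ms.  By default all completed
#' 8-switch trials enter the median, correct or not; `correct_only = TRUE`
#' restricts to trials with at most one error.
#'
#' @param familiarisation Data frame of familiarisation trials with columns
#'   `switch_count`, `elapsed_ms` and (for `correct_only`) `n_errors`.
#' @param correct_only Restrict the median to correct trials?
#' @return List of class `nst_calibration` with `allowed_time_ms` and
#'   `source_times_ms`.
#' @export
#' @examples
#' fam <- data.frame(switch_count = 8, elapsed_ms = c(7000, 8000, 9000, 10000))
#' calibrate_time_limit(fam)$allowed_time_ms # 9000
calibrate_time_limit <- function(familiarisation, correct_only = FALSE) {
  need <- c("switch_count", "elapsed_ms")
  if (!all(need %in% names(familiarisation))) {
    stop_("familiarisation trials need columns switch_count, elapsed_ms")
  }
  keep <- familiarisation$switch_count == 8L &
    is.finite(familiarisation$elapsed_ms)
  if (correct_only) {
    if (!"n_errors" %in% names(familiarisation)) {
      stop_("correct_only calibration needs an n_errors column")
    }
    keep <- keep & familiarisation$n_errors <= 1L
  }
  times <- familiarisation$elapsed_ms[keep]
  if (length(times) == 0L) stop_("calibration impossible: no 8-switch trials")
  structure(
    list(
      allowed_time_ms = stats::median(times) + CALIBRATION_MARGIN_MS,
      source_times_ms = times
    ),
    class = "nst_calibration"
  )
}

#' @export
print.nst_calibration <- function(x, ...) {
  cat(sprintf("NST time-limit calibration: %d source trial(s), allowed %.0f ms\n",
              length(x$source_times_ms), x$allowed_time_ms))
  invisible(x)
}

#' Familiarisation pass rule
#'
#' Participants progress to the main task only if at least 50% of the
#' hardest, 8-switch familiarisation trials are correct.  The phase has no
#' time limit, so correctness uses the error criterion alone: at most one
#' wrong response in the sequence.
#'
#' @param familiarisation Data frame with columns `switch_count`, `n_errors`.
#' @return Logical: did the participant pass?
#' @export
pass_familiarisation <- function(familiarisation) {
  need <- c("switch_count", "n_errors")
  if (!all(need %in% names(familiarisation))) {
    stop_("familiarisation trials need columns switch_count, n_errors")
  }
  e8 <- familiarisation$n_errors[familiarisation$switch_count == 8L]
  if (length(e8) == 0L) stop_("no 8-switch familiarisation trials")
  mean(e8 <= 1L) >= 0.5
}

#' Score a main-phase trial
#'
#' A trial succeeds when at least 8 of the 9 digits are categorised
#' correctly (at most one error) and the sequence is completed within the
#' allowed time.  Failures are classified as `fail_errors` when two or
#' more errors were made (regardless of timing), otherwise `fail_timeout`.
#'
#' @param n_errors Number of wrong responses, 0..9.  Vectorised.
#' @param elapsed_ms Completion time in milliseconds.
#' @param allowed_ms Calibrated time limit in milliseconds.
#' @return Character vector: `"success"`, `"fail_errors"` or
#'   `"fail_timeout"`.
#' @export
#' @examples
#' score_trial(1, 8000, 9000) # success
#' score_trial(2, 8000, 9000) # fail_errors
#' score_trial(0, 9001, 9000) # fail_timeout
score_trial <- function(n_errors, elapsed_ms, allowed_ms) {
  if (any(n_errors < 0) || any(n_errors > 9) ||
      any(elapsed_ms <= 0) || any(allowed_ms <= 0)) {
    stop_("n_errors must be in 0..9 and times must be positive")
  }
  n <- max(length(n_errors), length(elapsed_ms), length(allowed_ms))
  n_errors <- rep_len(n_errors, n)
  elapsed_ms <- rep_len(elapsed_ms, n)
  allowed_ms <- rep_len(allowed_ms, n)
  ifelse(n_errors >= 2, "fail_errors",
         ifelse(elapsed_ms <= allowed_ms, "success", "fail_timeout"))
}
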