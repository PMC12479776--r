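## Trial schedule for the incentivized effort-choice task.
##
## A session holds 216 binary choices between a fixed low-incentive/low-effort
## option (0.5 CHF, effort level E0) and a varying high-incentive/high-effort
## option, split into 4 blocks of 54 trials. Physical (handgrip) and mental
## (2-back) effort are segregated into alternating blocks; gain and loss
## trials are intermixed within a block. Within each block the 2 valences x 3
## incentive levels x 3 effort levels factorial is balanced (3 repetitions of
## each of the 18 cells).

N_BLOCKS <- 4L
TRIALS_PER_BLOCK <- 54L
PARAM_NAMES <- c("kR", "kP", "kEp", "kEm", "kFp", "kLm", "bias")

#' Per-subject calibration constants
#'
#' Holds the individual calibration of the effort task: maximal voluntary
#' contraction (physical effort unit), maximum number of correct 2-back
#' responses in 10 s (mental effort unit), and the monetary incentive levels
#' derived from the indifference-point procedure. The choice model operates on
#' level indices, so these amounts are carried for bookkeeping only.
#'
#' @param mvc Maximal voluntary contraction force (> 0, arbitrary units).
#' @param mncr Maximum number of correct 2-back responses in 10 s (>= 1).
#' @param indifference_incentives Named list with numeric vectors `gain` and
#'   `loss`, each of 3 strictly increasing monetary values (CHF).
#' @param low_incentive Fixed low-option amount in CHF (default 0.5).
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(mvc, mncr,
                                indifference_incentives =
                                  list(gain = c(1, 2, 3), loss = c(1, 2, 3)),
                                low_incentive = 0.5) {
  stopifnot(is.numeric(mvc), mvc > 0, mncr >= 1)
  for (v in indifference_incentives)
    stopifnot(length(v) == 3, all(diff(v) > 0))
  structure(list(mvc = mvc, mncr = as.integer(mncr),
                 indifference_incentives = indifference_incentives,
                 low_incentive = low_incentive),
            class = "calibration_profile")
}

## One balanced block: 18 cells x 3 repetitions, shuffled with a cap of 4
## same-valence trials in a row (rejection sampling) to emulate the
## gain/loss intermixing of the real task.
shuffle_block <- function(effort_type, block_index, max_run = 4L) {
  cells <- expand.grid(valence = c("gain", "loss"),
                       incentive_level = 1:3, effort_level = 1:3,
                       stringsAsFactors = FALSE)
  block <- cells[rep(seq_len(nrow(cells)), times = 3), ]
  repeat {
    ord <- sample.int(nrow(block))
    v <- block$valence[ord]
    runs <- rle(v)$lengths
    if (max(runs) <= max_run) break
  }
  block <- block[ord, ]
  block$block <- block_index
  block$trial_in_block <- seq_len(nrow(block))
  block$effort_type <- effort_type
  rownames(block) <- NULL
  block
}

#' Generate a session schedule
#'
#' Builds the 216-trial session: 4 blocks of 54 trials, alternating physical
#' and mental effort starting from `start_type`, each block a balanced
#' 2 (valence) x 3 (incentive) x 3 (effort) factorial with 3 repetitions per
#' cell, pseudorandomly ordered under `seed` (no more than 4 consecutive
#' trials of the same valence). The side of the high-effort option is
#' counterbalanced exactly (108 left / 108 right per session).
#'
#' @param seed Integer seed; identical seeds yield identical schedules.
#' @param start_type `"physical"` or `"mental"`: effort type of block 1.
#' @return A `session_schedule`: a data frame with one row per trial and
#'   columns `block`, `trial_in_block`, `effort_type`, `valence`,
#'   `incentive_level`, `effort_level`, `side`, plus attributes `seed` and
#'   `block_order`.
#' @examples
#' s <- generate_session(seed = 1, start_type = "mental")
#' nrow(s)            # 216
#' table(s$block)     # 54 per block
#' @export
generate_session <- function(seed, start_type = c("physical", "mental")) {
  start_type <- match.arg(start_type)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  block_order <- if (start_type == "physical") {
    c("physical", "mental", "physical", "mental")
  } else c("mental", "physical", "mental", "physical")
  sched <- with_seed(seed, function() {
    blocks <- lapply(seq_len(N_BLOCKS), function(b)
      shuffle_block(block_order[b], b))
    out <- do.call(rbind, blocks)
    ## exact left/right counterbalance of the high option across the session
    side <- rep(c("left", "right"), each = nrow(out) / 2)
    out$side <- sample(side)
    out
  })
  sched <- sched[, c("block", "trial_in_block", "effort_type", "valence",
                     "incentive_level", "effort_level", "side")]
  structure(sched, class = c("session_schedule", "data.frame"),
            seed = as.integer(seed), block_order = block_order)
}

#' Validate a session schedule
#'
#' Checks every structural invariant of the session design and returns the
#' violations found (an empty list means the schedule is valid). Checked
#' constraints: `n_trials` (216 trials), `block_size` (54 per block),
#' `block_alternation` (effort types alternate and are constant within block),
#' `cell_balance` (each valence x incentive x effort cell 3 times per block),
#' `side_balance` (high option left exactly 108 times), `level_range`
#' (incentive/effort levels in 1..3, valence in gain/loss).
#'
#' @param s A schedule data frame as produced by [generate_session()].
#' @return A list of violations; each element has a `constraint` name and a
#'   human-readable `detail` (with offending indices where applicable).
#' @export
validate_schedule <- function(s) {
  required <- c("block", "trial_in_block", "effort_type", "valence",
                "incentive_level", "effort_level", "side")
  missing_cols <- setdiff(required, names(s))
  if (length(missing_cols) > 0)
    stop("malformed schedule: missing columns ",
         paste(missing_cols, collapse = ", "))
  bad_row <- which(!stats::complete.cases(s[required]))
  if (length(bad_row) > 0)
    stop("malformed trial records at rows ", paste(bad_row, collapse = ", "))

  violations <- list()
  add <- function(constraint, detail)
    violations[[length(violations) + 1]] <<- list(constraint = constraint,
                                                  detail = detail)

  if (nrow(s) != N_BLOCKS * TRIALS_PER_BLOCK)
    add("n_trials", sprintf("expected %d trials, found %d",
                            N_BLOCKS * TRIALS_PER_BLOCK, nrow(s)))
  counts <- table(s$block)
  bad_blocks <- names(counts)[counts != TRIALS_PER_BLOCK]
  if (length(names(counts)) != N_BLOCKS || length(bad_blocks) > 0)
    add("block_size", paste("blocks with wrong trial count:",
                            paste(bad_blocks, collapse = ", ")))

  types <- tapply(s$effort_type, s$block, function(x) unique(x))
  if (any(lengths(types) != 1)) {
    add("block_alternation", "effort type not constant within block")
  } else {
    tv <- unlist(types)
    if (length(tv) >= 2 && any(tv[-1] == tv[-length(tv)]))
      add("block_alternation",
          paste("consecutive blocks share effort type:",
                paste(tv, collapse = " -> ")))
    if (sum(tv == "physical") != sum(tv == "mental"))
      add("block_alternation", "unequal physical/mental block counts")
  }

  bad_lvl <- which(!(s$incentive_level %in% 1:3) |
                     !(s$effort_level %in% 1:3) |
                     !(s$valence %in% c("gain", "loss")))
  if (length(bad_lvl) > 0)
    add("level_range", paste("rows outside level ranges:",
                             paste(utils::head(bad_lvl, 10), collapse = ", ")))

  for (b in unique(s$block)) {
    sb <- s[s$block == b, ]
    cell <- table(sb$valence, sb$incentive_level, sb$effort_level)
    if (nrow(sb) == TRIALS_PER_BLOCK &&
        (length(cell) != 18 || any(cell != 3)))
      add("cell_balance", sprintf("block %s not 3x balanced over 18 cells", b))
  }

  if ("side" %in% names(s) && sum(s$side == "left") != nrow(s) / 2)
    add("side_balance", sprintf("high option left %d times, expected %d",
                                sum(s$side == "left"), nrow(s) %/% 2))
  violations
}

#' Write a schedule to CSV
#'
#' @param s A `session_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE)
  invisible(path)
}

#' Read a schedule from CSV
#'
#' @param path CSV produced by [write_schedule_csv()].
#' @return A `session_schedule` data frame (unvalidated; run
#'   [validate_schedule()] to check invariants).
#' @export
read_schedule_csv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(s, class = c("session_schedule", "data.frame"))
}
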