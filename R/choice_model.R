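## Generative model of effort-based choice.
##
## Each trial offers a low-effort/low-incentive default against a high option
## with incentive level I in 1..3 and effort level E in 1..3. The subjective
## value of accepting the high option is
##
##   SV = bias + B - C
##   B  = kR * I              (gain trials)
##      = kP * I              (loss trials; value of the avoided loss)
##   C  = (kEp + kFp * fatigue)  * E   (physical trials)
##      = (kEm - kLm * learning) * E   (mental trials)
##
## with fatigue = cumulative chosen physical effort so far, normalized by the
## session maximum (3 units on each of the 108 physical trials), and
## learning = fraction of mental trials already completed. The high option is
## chosen with probability logistic(SV).

#' Behavioral parameter set
#'
#' The seven idiosyncratic sensitivities of the choice model: reward (`kR`),
#' punishment (`kP`), physical effort (`kEp`), mental effort (`kEm`),
#' physical fatigue (`kFp`), mental learning (`kLm`) and a high-effort `bias`.
#' All k-parameters are non-negative; the bias is an unconstrained real.
#'
#' @param kR,kP,kEp,kEm,kFp,kLm Non-negative finite sensitivities.
#' @param bias Finite real high-effort bias.
#' @return Named numeric vector of class `behavioral_parameters`, in the
#'   canonical order `kR, kP, kEp, kEm, kFp, kLm, bias`.
#' @examples
#' behavioral_parameters(kR = 1, kEm = 0.5)
#' @export
behavioral_parameters <- function(kR = 0, kP = 0, kEp = 0, kEm = 0,
                                  kFp = 0, kLm = 0, bias = 0) {
  p <- c(kR = kR, kP = kP, kEp = kEp, kEm = kEm, kFp = kFp, kLm = kLm,
         bias = bias)
  if (!all(is.finite(p))) stop("non-finite behavioral parameter")
  if (any(p[1:6] < 0))
    stop("k-parameters must be non-negative: ",
         paste(names(p[1:6])[p[1:6] < 0], collapse = ", "))
  structure(p, class = "behavioral_parameters")
}

#' Trial state (fatigue and learning)
#'
#' @param fatigue Cumulative chosen physical effort, normalized to `[0, 1]` of
#'   the session maximum.
#' @param learning Fraction of mental-effort trials already completed.
#' @return A list with components `fatigue` and `learning`.
#' @export
trial_state <- function(fatigue = 0, learning = 0) {
  stopifnot(fatigue >= 0, fatigue <= 1, learning >= 0, learning <= 1)
  list(fatigue = fatigue, learning = learning)
}

#' Subjective value of the high-effort option
#'
#' @param params A [behavioral_parameters()] vector.
#' @param trial A list or one-row data frame with `effort_type`, `valence`,
#'   `incentive_level`, `effort_level`.
#' @param state A [trial_state()].
#' @return The scalar subjective value (model units).
#' @examples
#' p <- behavioral_parameters(kR = 1, kEm = 0.5)
#' subjective_value(p, list(effort_type = "mental", valence = "gain",
#'                          incentive_level = 2, effort_level = 2),
#'                  trial_state())
#' @export
subjective_value <- function(params, trial, state) {
  if (!all(is.finite(unclass(params)))) stop("non-finite parameter")
  inc <- as.numeric(trial$incentive_level)
  eff <- as.numeric(trial$effort_level)
  benefit <- if (trial$valence == "gain") params[["kR"]] * inc
             else params[["kP"]] * inc
  cost <- if (trial$effort_type == "physical") {
    (params[["kEp"]] + params[["kFp"]] * state$fatigue) * eff
  } else {
    (params[["kEm"]] - params[["kLm"]] * state$learning) * eff
  }
  unname(params[["bias"]] + benefit - cost)
}

#' Softmax (logistic) choice probability
#'
#' @param sv Finite subjective value(s).
#' @return `1 / (1 + exp(-sv))`, the probability of choosing the high-effort
#'   option.
#' @export
choice_probability <- function(sv) {
  if (!all(is.finite(sv))) stop("non-finite subjective value")
  stats::plogis(sv)
}

#' Advance the trial state after a choice
#'
#' Physical trials increment fatigue by the *chosen* effort level (0 for the
#' low option E0), normalized by the maximum cumulative effort of the session
#' (`3 * n_physical`); mental trials increment learning by `1 / n_mental`
#' regardless of choice (learning tracks task exposure).
#'
#' @param state A [trial_state()].
#' @param trial Trial record (needs `effort_type`, `effort_level`).
#' @param choice `"high"` or `"low"`.
#' @param n_physical,n_mental Number of physical / mental trials in the
#'   session (108 each in the standard design).
#' @return The updated state.
#' @export
update_state <- function(state, trial, choice, n_physical = 108L,
                         n_mental = 108L) {
  if (trial$effort_type == "physical") {
    exerted <- if (choice == "high") as.numeric(trial$effort_level) else 0
    state$fatigue <- state$fatigue + exerted / (3 * n_physical)
  } else {
    state$learning <- state$learning + 1 / n_mental
  }
  state
}

## States *entering* each trial, rolled forward from a given choice vector.
## Returns a data.frame(fatigue, learning) with one row per trial.
roll_states <- function(schedule, choices) {
  n <- nrow(schedule)
  phys <- schedule$effort_type == "physical"
  n_physical <- sum(phys)
  n_mental <- n - n_physical
  exerted <- ifelse(phys & choices == "high",
                    as.numeric(schedule$effort_level), 0)
  fatigue <- c(0, cumsum(exerted)[-n]) / max(1, 3 * n_physical)
  done_mental <- c(0, cumsum(!phys)[-n]) / max(1, n_mental)
  data.frame(fatigue = fatigue, learning = done_mental)
}

## Design matrix mapping natural-scale parameters to SV: sv = X %*% theta
## with theta in canonical order. Cost columns carry the negative sign so the
## likelihood is an ordinary logistic form in theta.
choice_design_matrix <- function(schedule, states) {
  inc <- as.numeric(schedule$incentive_level)
  eff <- as.numeric(schedule$effort_level)
  gain <- schedule$valence == "gain"
  phys <- schedule$effort_type == "physical"
  X <- cbind(kR   =  inc * gain,
             kP   =  inc * !gain,
             kEp  = -eff * phys,
             kEm  = -eff * !phys,
             kFp  = -eff * phys * states$fatigue,
             kLm  =  eff * !phys * states$learning,
             bias =  1)
  X
}

#' Simulate a session of choices
#'
#' Iterates the schedule in trial order: computes the subjective value under
#' the current fatigue/learning state, samples the choice from
#' `Bernoulli(logistic(SV))`, and advances the state from the sampled choice.
#'
#' @param params A [behavioral_parameters()] vector.
#' @param schedule A [generate_session()] schedule.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param subject_id Identifier stored with the dataset.
#' @return A `choice_dataset`: list with `subject_id`, `schedule`, `records`
#'   (data frame with `sv`, `p_high`, `choice`, `confidence_pred` per trial)
#'   and `summary` (`hme`, `hpe` proportions of high-effort choices over
#'   mental / physical trials).
#' @export
simulate_choices <- function(params, schedule, seed, subject_id = "sim") {
  params <- do.call(behavioral_parameters, as.list(unclass(params)))
  n <- nrow(schedule)
  phys <- schedule$effort_type == "physical"
  n_physical <- sum(phys)
  n_mental <- n - n_physical
  u <- with_seed(seed, function() stats::runif(n))
  sv <- numeric(n); p <- numeric(n); choice <- character(n)
  state <- trial_state()
  for (t in seq_len(n)) {
    trial <- list(effort_type = schedule$effort_type[t],
                  valence = schedule$valence[t],
                  incentive_level = schedule$incentive_level[t],
                  effort_level = schedule$effort_level[t])
    sv[t] <- subjective_value(params, trial, state)
    p[t] <- choice_probability(sv[t])
    choice[t] <- if (u[t] < p[t]) "high" else "low"
    state <- update_state(state, trial, choice[t], n_physical, n_mental)
  }
  records <- data.frame(sv = sv, p_high = p, choice = choice,
                        confidence_pred = 2 * abs(p - 0.5))
  structure(list(subject_id = subject_id, schedule = schedule,
                 records = records, params = params,
                 summary = list(
                   hme = mean(choice[!phys] == "high"),
                   hpe = mean(choice[phys] == "high"))),
            class = "choice_dataset")
}

#' Summarize a choice dataset
#'
#' Computes the overall proportions of high mental (HME) and high physical
#' (HPE) effort choices, and the per-cell high-choice rates over the
#' incentive x effort grid (the data behind the choice heatmaps).
#'
#' @param ds A `choice_dataset`.
#' @return List with `hme`, `hpe` and `cells`, a data frame with columns
#'   `effort_type`, `incentive_level`, `effort_level`, `n`, `rate`.
#' @export
summarize_behavior <- function(ds) {
  s <- ds$schedule
  if (is.null(s) || nrow(s) == 0) stop("empty dataset")
  high <- ds$records$choice == "high"
  phys <- s$effort_type == "physical"
  agg <- stats::aggregate(high,
                          by = list(effort_type = s$effort_type,
                                    incentive_level = s$incentive_level,
                                    effort_level = s$effort_level),
                          FUN = function(z) c(n = length(z), rate = mean(z)))
  cells <- data.frame(agg[1:3], n = agg$x[, "n"], rate = agg$x[, "rate"])
  list(hme = mean(high[!phys]), hpe = mean(high[phys]), cells = cells)
}

#' Write a choice dataset to CSV
#'
#' One row per trial: the schedule columns plus `choice`, `p_high`, `sv`.
#'
#' @param ds A `choice_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_choices_csv <- function(ds, path) {
  out <- cbind(subject_id = ds$subject_id, as.data.frame(ds$schedule),
               ds$records[, c("choice", "p_high", "sv")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a choice dataset from CSV
#'
#' @param path CSV produced by [write_choices_csv()].
#' @return A `choice_dataset` (probabilities/SV columns optional; summary
#'   recomputed from the choices).
#' @export
read_choices_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sched_cols <- c("block", "trial_in_block", "effort_type", "valence",
                  "incentive_level", "effort_level", "side")
  sched <- structure(d[, intersect(sched_cols, names(d))],
                     class = c("session_schedule", "data.frame"))
  phys <- sched$effort_type == "physical"
  records <- data.frame(
    sv = if ("sv" %in% names(d)) d$sv else NA_real_,
    p_high = if ("p_high" %in% names(d)) d$p_high else NA_real_,
    choice = d$choice)
  records$confidence_pred <- 2 * abs(records$p_high - 0.5)
  structure(list(subject_id = if ("subject_id" %in% names(d))
                   d$subject_id[1] else "unknown",
                 schedule = sched, records = records,
                 summary = list(hme = mean(d$choice[!phys] == "high"),
                                hpe = mean(d$choice[phys] == "high"))),
            class = "choice_dataset")
}
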