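## Simulate-and-refit validation of the choice model.
##
## Parameter sets are drawn from the generative (prior) distribution, one
## 216-trial session is simulated per draw, the full model is refit, and the
## simulated and recovered parameters are compared: a 7x7 confusion matrix of
## Pearson correlations corr(simulated_i, recovered_j), an identifiability
## (autocorrelation) matrix among recovered parameters, and per-parameter
## recovery rates under a batch-correlation criterion. Correlations are
## computed on the latent (log for the k-parameters, identity for the bias)
## scale, where the generative distribution is Gaussian.

#' Recovery simulation design
#'
#' @param n_sims Total simulate-and-refit runs; must be divisible by
#'   `batch_size`.
#' @param batch_size Runs per batch for the recovery-rate criterion (>= 30).
#' @param prior Generative sampler and fitting prior, a [prior_spec()].
#' @param n_starts,tol Fitting settings passed to [fit_map()].
#' @param n_trials Trials per simulated session (216 in the standard design;
#'   other multiples of 216 are obtained by concatenating sessions).
#' @return A `recovery_design` list.
#' @export
recovery_design <- function(n_sims = 300, batch_size = 100,
                            prior = prior_spec(), n_starts = 3,
                            tol = 1e-6, n_trials = 216) {
  stopifnot(batch_size >= 30, n_sims %% batch_size == 0,
            n_trials %% 216 == 0)
  structure(list(n_sims = n_sims, batch_size = batch_size, prior = prior,
                 n_starts = n_starts, tol = tol, n_trials = n_trials),
            class = "recovery_design")
}

## Natural params -> latent scale used for all recovery correlations.
to_latent_scale <- function(tab) {
  tab <- as.data.frame(tab)[PARAM_NAMES]
  for (nm in PARAM_NAMES[1:6]) tab[[nm]] <- log(pmax(tab[[nm]], 1e-12))
  tab
}

#' Run a recovery study
#'
#' @param design A [recovery_design()].
#' @param seed Master seed; every draw, schedule, simulation and fit derives
#'   its own substream from it, so the full report is reproducible.
#' @return A `recovery_report`: `confusion` (7x7
#'   corr(simulated_i, recovered_j)), `identifiability` (7x7 correlations
#'   among recovered parameters), `recovery_rate` (named per-parameter %),
#'   `mean_rate_excl_kLm`, `sim` and `rec` latent-scale parameter tables,
#'   `n_sims`, `n_failed`.
#' @export
run_recovery <- function(design = recovery_design(), seed = 1) {
  n <- design$n_sims
  prior <- design$prior
  sim <- matrix(NA_real_, n, 7, dimnames = list(NULL, PARAM_NAMES))
  rec <- sim
  n_failed <- 0
  n_sessions <- design$n_trials / 216
  for (i in seq_len(n)) {
    zeta <- with_seed(derive_seed(seed, i), function()
      stats::rnorm(7, prior$latent_mean, prior$latent_sd))
    theta <- c(exp(zeta[1:6]), zeta[7])
    params <- do.call(behavioral_parameters,
                      as.list(stats::setNames(theta, PARAM_NAMES)))
    start <- if (i %% 2 == 0) "physical" else "mental"
    sessions <- lapply(seq_len(n_sessions), function(s) {
      sched <- generate_session(derive_seed(seed, n + i + s * 7919), start)
      simulate_choices(params, sched, derive_seed(seed, 2 * n + i + s * 104729))
    })
    ds <- if (n_sessions == 1) sessions[[1]] else concat_sessions(sessions)
    fit <- tryCatch(
      fit_map(ds, prior, n_starts = design$n_starts, tol = design$tol,
              seed = derive_seed(seed, 3 * n + i)),
      error = function(e) NULL)
    if (is.null(fit)) { n_failed <- n_failed + 1; next }
    sim[i, ] <- zeta
    rec[i, ] <- fit$map_latent
  }
  if (n_failed > 0.1 * n)
    stop("run_recovery: ", n_failed, " of ", n, " fits failed (> 10%)")
  ok <- !is.na(sim[, 1])
  sim <- as.data.frame(sim[ok, , drop = FALSE])
  rec <- as.data.frame(rec[ok, , drop = FALSE])
  rate <- recovery_rate(sim, rec, design$batch_size)
  structure(list(
    confusion = confusion_matrix(sim, rec),
    identifiability = identifiability_matrix(rec),
    recovery_rate = rate,
    mean_rate_excl_kLm = mean(rate[setdiff(PARAM_NAMES, "kLm")]),
    sim = sim, rec = rec, n_sims = n, n_failed = n_failed),
    class = "recovery_report")
}

## Concatenate several single-session datasets into one longer dataset
## (used only for the trials-per-session sensitivity check).
concat_sessions <- function(sessions) {
  sched <- do.call(rbind, lapply(sessions, function(s)
    as.data.frame(s$schedule)))
  sched$block <- rep(seq_along(sessions), each = 216) * 10 +
    sched$block
  records <- do.call(rbind, lapply(sessions, function(s) s$records))
  phys <- sched$effort_type == "physical"
  structure(list(subject_id = sessions[[1]]$subject_id,
                 schedule = structure(sched,
                   class = c("session_schedule", "data.frame")),
                 records = records,
                 summary = list(
                   hme = mean(records$choice[!phys] == "high"),
                   hpe = mean(records$choice[phys] == "high"))),
            class = "choice_dataset")
}

#' Confusion matrix of simulated vs recovered parameters
#'
#' Entry `(i, j)` is the Pearson correlation between simulated parameter `i`
#' and recovered parameter `j` across runs. A zero-variance column yields 0
#' entries with a warning.
#'
#' @param sim,rec Parameter tables with identical row counts (>= 30) and the
#'   7 canonical columns.
#' @return A 7x7 named correlation matrix.
#' @export
confusion_matrix <- function(sim, rec) {
  sim <- as.data.frame(sim)[PARAM_NAMES]
  rec <- as.data.frame(rec)[PARAM_NAMES]
  stopifnot(nrow(sim) == nrow(rec), nrow(sim) >= 30)
  m <- matrix(0, 7, 7, dimnames = list(sim = PARAM_NAMES,
                                       rec = PARAM_NAMES))
  for (i in 1:7) for (j in 1:7)
    m[i, j] <- safe_cor(sim[[i]], rec[[j]])
  m
}

#' Identifiability (autocorrelation) matrix of recovered parameters
#'
#' Pairwise Pearson correlations among the recovered parameters; large
#' off-diagonal entries indicate parameter trade-offs the data cannot
#' separate.
#'
#' @param rec Recovered parameter table (>= 30 rows, 7 canonical columns).
#' @return A 7x7 named correlation matrix with unit diagonal.
#' @export
identifiability_matrix <- function(rec) {
  rec <- as.data.frame(rec)[PARAM_NAMES]
  stopifnot(nrow(rec) >= 30)
  m <- matrix(0, 7, 7, dimnames = list(PARAM_NAMES, PARAM_NAMES))
  for (i in 1:7) for (j in 1:7)
    m[i, j] <- if (i == j) 1 else safe_cor(rec[[i]], rec[[j]])
  m
}

#' Per-parameter recovery rates under the batch-correlation criterion
#'
#' Runs are split into consecutive batches; within a batch, parameter `i`
#' counts as recovered iff `corr(sim_i, rec_i)` is the largest entry of row
#' `i` of the batch confusion matrix *and* is significant at `p < 0.05`
#' (Pearson test). The rate is the percentage of batches in which the
#' parameter was recovered.
#'
#' @param sim,rec Parameter tables (identical row counts; at least 2 batches
#'   of `batch_size >= 30`).
#' @param batch_size Runs per batch.
#' @return Named numeric vector of per-parameter recovery rates in percent.
#' @export
recovery_rate <- function(sim, rec, batch_size = 100) {
  sim <- as.data.frame(sim)[PARAM_NAMES]
  rec <- as.data.frame(rec)[PARAM_NAMES]
  stopifnot(nrow(sim) == nrow(rec))
  if (batch_size < 30) stop("batch smaller than 30")
  n_batch <- nrow(sim) %/% batch_size
  if (n_batch < 2) stop("need at least 2 batches")
  hits <- matrix(FALSE, n_batch, 7, dimnames = list(NULL, PARAM_NAMES))
  for (b in seq_len(n_batch)) {
    idx <- ((b - 1) * batch_size + 1):(b * batch_size)
    cm <- confusion_matrix(sim[idx, ], rec[idx, ])
    for (i in 1:7) {
      if (cm[i, i] < max(cm[i, ])) next
      pv <- tryCatch(
        stats::cor.test(sim[idx, i], rec[idx, i])$p.value,
        error = function(e) 1)
      hits[b, i] <- is.finite(pv) && pv < 0.05
    }
  }
  100 * colMeans(hits)
}
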