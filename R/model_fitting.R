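## Per-subject inversion of the choice model.
##
## The six sensitivity parameters are positivity-constrained through an
## exponential link from a latent Gaussian scale (the bias is identity-mapped),
## with independent Normal priors on the latent scale. Fitting maximizes the
## log-posterior by multi-start BFGS with analytic gradients; the posterior is
## then approximated by a Gaussian at the mode (Laplace), which yields the
## free energy used for model comparison. The likelihood rolls the
## fatigue/learning states forward from the *observed* choices.

#' Prior specification on the latent parameter scale
#'
#' @param latent_mean,latent_sd Numeric 7-vectors (order
#'   `kR, kP, kEp, kEm, kFp, kLm, bias`); `latent_sd` strictly positive.
#'   Defaults are weakly-informative standard Normals.
#' @return A `prior_spec` list. The parameter link is fixed: `exp` for the six
#'   k-parameters, identity for the bias.
#' @export
prior_spec <- function(latent_mean = rep(0, 7), latent_sd = rep(1, 7)) {
  stopifnot(length(latent_mean) == 7, length(latent_sd) == 7,
            all(latent_sd > 0), all(is.finite(latent_mean)))
  structure(list(latent_mean = stats::setNames(latent_mean, PARAM_NAMES),
                 latent_sd = stats::setNames(latent_sd, PARAM_NAMES),
                 mapping = c(rep("exp", 6), "identity")),
            class = "prior_spec")
}

#' Model variant (subset of free parameters)
#'
#' Parameters outside `free` are clamped to 0 on the natural scale, giving the
#' nested variants used in model comparison.
#'
#' @param name Label for the variant.
#' @param free Non-empty character vector of free parameter names.
#' @return A `model_variant` list.
#' @export
model_variant <- function(name, free = PARAM_NAMES) {
  free <- match.arg(free, PARAM_NAMES, several.ok = TRUE)
  if (length(free) == 0) stop("variant must free at least one parameter")
  structure(list(name = name, free = free), class = "model_variant")
}

## latent -> natural for the free entries; clamped entries are 0.
latent_to_natural <- function(zeta_free, free_idx) {
  theta <- stats::setNames(numeric(7), PARAM_NAMES)
  full <- numeric(7)
  full[free_idx] <- zeta_free
  theta[free_idx] <- ifelse(free_idx <= 6, exp(full[free_idx]),
                            full[free_idx])
  theta
}

## Data prepared once per dataset: design matrix from observed-choice states.
prepare_choice_data <- function(ds) {
  sched <- ds$schedule
  states <- roll_states(sched, ds$records$choice)
  list(X = choice_design_matrix(sched, states),
       y = as.numeric(ds$records$choice == "high"),
       n = nrow(sched))
}

P_FLOOR <- 1e-10

#' Log-likelihood of observed choices
#'
#' Sum over trials of `log p(choice_t | params, state_t)` with fatigue and
#' learning states rolled forward from the observed choices. Per-trial
#' probabilities are floored at `1e-10` (a warning is issued when the floor
#' binds) so saturated parameter regions stay finite.
#'
#' @param params A [behavioral_parameters()] vector.
#' @param ds A `choice_dataset`.
#' @return The log-likelihood, a scalar `<= 0`.
#' @export
log_likelihood <- function(params, ds) {
  params <- do.call(behavioral_parameters, as.list(unclass(params)))
  dat <- prepare_choice_data(ds)
  p <- stats::plogis(drop(dat$X %*% unclass(params)))
  pc <- ifelse(dat$y == 1, p, 1 - p)
  if (any(pc < P_FLOOR)) warning("likelihood floor applied on ",
                                 sum(pc < P_FLOOR), " trial(s)")
  sum(log(pmax(pc, P_FLOOR)))
}

## Negative log-posterior and its analytic gradient/Hessian over free latents.
make_objective <- function(dat, prior, free_idx) {
  X <- dat$X[, free_idx, drop = FALSE]
  y <- dat$y
  mu <- prior$latent_mean[free_idx]
  sd2 <- prior$latent_sd[free_idx]^2
  is_exp <- free_idx <= 6
  nat <- function(zf) ifelse(is_exp, exp(zf), zf)
  list(
    fn = function(zf) {
      eta <- drop(X %*% nat(zf))
      ll <- sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                       stats::plogis(-eta, log.p = TRUE)))
      lp <- sum(stats::dnorm(zf, mu, sqrt(sd2), log = TRUE))
      -(ll + lp)
    },
    gr = function(zf) {
      th <- nat(zf)
      p <- stats::plogis(drop(X %*% th))
      g_nat <- drop(crossprod(X, y - p))
      g_lat <- g_nat * ifelse(is_exp, th, 1)
      -(g_lat - (zf - mu) / sd2)
    },
    hess = function(zf) {
      th <- nat(zf)
      p <- stats::plogis(drop(X %*% th))
      w <- p * (1 - p)
      D <- ifelse(is_exp, th, 1)
      H_nat <- crossprod(X * w, X)               # - d2LL/dtheta2
      g_nat <- drop(crossprod(X, y - p))
      H <- (D %o% D) * H_nat - diag(ifelse(is_exp, g_nat * th, 0),
                                    length(zf))
      H + diag(1 / sd2, length(zf))
    },
    nat = nat)
}

#' Fit the choice model by MAP with a Laplace posterior
#'
#' Maximizes the log-posterior over the latent parameters by multi-start BFGS
#' (first start at the prior mean, the rest drawn from the prior under
#' `seed`), then approximates the posterior by a Gaussian at the mode. The
#' free energy is the Laplace approximation to the log model evidence:
#' log-posterior at the mode plus `0.5 * log det(2 * pi * posterior_cov)`.
#'
#' @param ds A `choice_dataset`.
#' @param prior A [prior_spec()].
#' @param variant A [model_variant()]; default frees all 7 parameters.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param tol Relative convergence tolerance on the objective.
#' @param seed Seed for the random restarts (fit is deterministic given
#'   data, prior and seed).
#' @return A `fit_result` list: `map_latent`, `map_params` (full 7-vector,
#'   clamped entries 0), `posterior_cov` (free parameters, SPD), `log_lik`
#'   (maximized likelihood after an unpenalized polish from the MAP start, so
#'   AIC/BIC carry their classical meaning and are monotone over nested
#'   variants), `free_energy`, `aic`, `bic`, `fit_quality` (median absolute
#'   predicted probability and observed choice, and squared correlation R2),
#'   `ridge_flag` (TRUE when the Hessian needed ridge regularization),
#'   `variant`, `n_free`, `converged`.
#' @export
fit_map <- function(ds, prior = prior_spec(),
                    variant = model_variant("full"),
                    n_starts = 5, tol = 1e-6, seed = 1) {
  free_idx <- match(variant$free, PARAM_NAMES)
  sched_types <- unique(ds$schedule$effort_type)
  if (any(c("kEp", "kFp") %in% variant$free) &&
      !"physical" %in% sched_types)
    stop("variant frees physical-effort parameters but data has no physical trials")
  if (any(c("kEm", "kLm") %in% variant$free) &&
      !"mental" %in% sched_types)
    stop("variant frees mental-effort parameters but data has no mental trials")

  dat <- prepare_choice_data(ds)
  obj <- make_objective(dat, prior, free_idx)
  kf <- length(free_idx)

  starts <- with_seed(seed, function() {
    s <- matrix(stats::rnorm((n_starts - 1) * kf,
                             mean = rep(prior$latent_mean[free_idx],
                                        each = max(0, n_starts - 1)),
                             sd = rep(prior$latent_sd[free_idx],
                                      each = max(0, n_starts - 1))),
                ncol = kf)
    rbind(prior$latent_mean[free_idx], s)
  })

  best <- NULL
  fails <- character(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj$fn, obj$gr, method = "BFGS",
                   control = list(reltol = tol, maxit = 1000)),
      error = function(e) e)
    if (inherits(res, "error")) { fails <- c(fails, conditionMessage(res)); next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("fit_map: no optimizer start converged; messages: ",
         paste(unique(fails), collapse = " | "))

  zf <- best$par
  H <- obj$hess(zf)
  H <- (H + t(H)) / 2
  ridge_flag <- FALSE
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    ridge_flag <- TRUE
    lam <- 1e-6 * max(1, max(abs(diag(H))))
    repeat {
      ch <- tryCatch(chol(H + diag(lam, kf)), error = function(e) NULL)
      if (!is.null(ch)) break
      lam <- lam * 10
      if (lam > 1e6) stop("fit_map: Hessian irreparably indefinite")
    }
    H <- H + diag(lam, kf)
  }
  cov <- chol2inv(ch)
  dimnames(cov) <- list(PARAM_NAMES[free_idx], PARAM_NAMES[free_idx])
  logdet_cov <- -2 * sum(log(diag(ch)))

  theta <- latent_to_natural(zf, free_idx)
  params <- do.call(behavioral_parameters, as.list(theta))
  p <- stats::plogis(drop(dat$X %*% unclass(params)))
  ll_map <- sum(log(pmax(ifelse(dat$y == 1, p, 1 - p), P_FLOOR)))
  log_post <- -best$value
  fe <- log_post + 0.5 * kf * log(2 * pi) + 0.5 * logdet_cov

  ## ML polish from the MAP start: AIC/BIC are defined with the *maximized*
  ## likelihood, and nested-variant monotonicity only holds for it (the MAP
  ## value is shrunk by the prior). A near-flat prior reuses the same
  ## machinery; the constant prior term cancels in the optimization.
  flat <- prior_spec(latent_sd = rep(1e6, 7))
  obj_ml <- make_objective(dat, flat, free_idx)
  ml <- tryCatch(
    stats::optim(zf, obj_ml$fn, obj_ml$gr, method = "BFGS",
                 control = list(reltol = tol, maxit = 500)),
    error = function(e) NULL)
  ll <- ll_map
  if (!is.null(ml)) {
    const <- sum(stats::dnorm(ml$par * 0, 0, 1e6, log = TRUE))
    ll <- max(ll_map, -(ml$value) - const)
  }

  map_latent <- stats::setNames(rep(NA_real_, 7), PARAM_NAMES)
  map_latent[free_idx] <- zf
  structure(list(
    map_latent = map_latent, map_params = params, posterior_cov = cov,
    log_lik = ll, free_energy = fe,
    aic = 2 * kf - 2 * ll, bic = kf * log(dat$n) - 2 * ll,
    fit_quality = list(mae = stats::median(abs(p - dat$y)),
                       r2 = if (stats::sd(p) > 0 && stats::sd(dat$y) > 0)
                         stats::cor(p, dat$y)^2 else 0),
    ridge_flag = ridge_flag, variant = variant, n_free = kf,
    converged = best$convergence == 0),
    class = "fit_result")
}

#' Compare nested model variants
#'
#' Fits each variant to the same dataset and tabulates Laplace free energy,
#' AIC and BIC, with a winner flag per criterion. Variants whose fit fails are
#' excluded from the ranking and reported in `failed`.
#'
#' @param ds A `choice_dataset`.
#' @param variants List of [model_variant()]s (length >= 2).
#' @param prior A [prior_spec()].
#' @param ... Passed to [fit_map()].
#' @return List with `table` (one row per variant, sorted by decreasing free
#'   energy, with logical columns `win_fe`, `win_aic`, `win_bic`), `fits`
#'   (named list of `fit_result`s) and `failed` (named character vector of
#'   error messages).
#' @export
compare_models <- function(ds, variants, prior = prior_spec(), ...) {
  stopifnot(length(variants) >= 2)
  fits <- list(); failed <- character(0)
  for (v in variants) {
    f <- tryCatch(fit_map(ds, prior, v, ...), error = function(e) e)
    if (inherits(f, "error")) failed[v$name] <- conditionMessage(f)
    else fits[[v$name]] <- f
  }
  if (length(fits) == 0) stop("all variants failed to fit")
  tab <- data.frame(
    name = names(fits),
    k = vapply(fits, function(f) f$n_free, 0),
    log_lik = vapply(fits, function(f) f$log_lik, 0),
    free_energy = vapply(fits, function(f) f$free_energy, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    bic = vapply(fits, function(f) f$bic, 0),
    row.names = NULL)
  tab$win_fe <- tab$free_energy == max(tab$free_energy)
  tab$win_aic <- tab$aic == min(tab$aic)
  tab$win_bic <- tab$bic == min(tab$bic)
  tab <- tab[order(-tab$free_energy), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits, failed = failed)
}

#' Box-Cox transform of a positive sample
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `log(x)` for
#' `lambda = 0`. When `lambda` is not supplied it is estimated by profile
#' maximum likelihood over a dense grid (step 0.01 on `[-3, 3]`). Zeros are
#' handled by a `1e-6` positivity shift; negative values are a domain error.
#'
#' @param values Numeric vector, non-negative (strictly positive after shift).
#' @param lambda Optional fixed exponent; estimated when `NULL` (needs
#'   `n >= 3`).
#' @param shift Positivity offset added before transforming; defaults to 0, or
#'   `1e-6` automatically when any value is exactly 0.
#' @return List with `values` (transformed), `lambda`, `shift`.
#' @export
boxcox_transform <- function(values, lambda = NULL, shift = NULL) {
  if (any(values < 0))
    stop("non-positive input without shift at index ",
         paste(which(values < 0), collapse = ", "))
  if (is.null(shift)) shift <- if (any(values == 0)) 1e-6 else 0
  x <- values + shift
  if (any(x <= 0))
    stop("non-positive input after shift at index ",
         paste(which(x <= 0), collapse = ", "))
  if (is.null(lambda)) {
    if (length(x) < 3) stop("need n >= 3 to estimate lambda")
    ## profile log-likelihood of the Box-Cox model with Gaussian errors:
    ## -n/2 log sigma^2(lambda) + (lambda - 1) sum(log x)
    n <- length(x)
    slog <- sum(log(x))
    grid <- seq(-3, 3, 0.01)
    prof <- vapply(grid, function(l) {
      y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slog
    }, 0)
    lambda <- grid[which.max(prof)]
  }
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(values = y, lambda = lambda, shift = shift)
}

#' Box-Cox transform a cohort parameter table
#'
#' Applies [boxcox_transform()] column-wise to the six sensitivity parameters
#' (the bias column is left untransformed, as it is sign-unconstrained).
#'
#' @param params_table Data frame or matrix with the 7 parameter columns.
#' @return List with `values` (transformed table), `lambda` and `shift`
#'   (named per-column vectors; `NA` for bias).
#' @export
transform_parameters <- function(params_table) {
  params_table <- as.data.frame(params_table)
  stopifnot(all(PARAM_NAMES %in% names(params_table)))
  out <- params_table[PARAM_NAMES]
  lambda <- stats::setNames(rep(NA_real_, 7), PARAM_NAMES)
  shift <- lambda
  for (nm in PARAM_NAMES[1:6]) {
    tr <- boxcox_transform(params_table[[nm]])
    out[[nm]] <- tr$values
    lambda[nm] <- tr$lambda
    shift[nm] <- tr$shift
  }
  list(values = out, lambda = lambda, shift = shift)
}
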