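## Metabolite -> behaviour prediction pipeline.
##
## Subjects x 18 metabolite features (concentrations + standard ratios)
## predicting a behavioural target (HME/HPE choice proportion or a model
## parameter such as kEm). Stages: train/test split; stage-1 univariate
## correlation filter (|r| >= 0.1 on training rows); stage-2 importance-ranked
## nested-subset selection under leave-one-out CV error of a boosted
## regressor; hyperparameter tuning of the booster by sequential model-based
## (Bayesian) optimization of the CVLOO RMSE; holdout evaluation (RMSE,
## one-tailed Pearson r); label-permutation null with frozen hyperparameters;
## exact TreeSHAP attribution; and a linear-vs-quadratic (inverted-U) single
## predictor comparison. Selection and tuning see training rows only.

#' Feature table
#'
#' @param data Data frame with a `subject_id` column, the feature columns and
#'   the target column. Feature values must be non-negative (concentrations
#'   and ratios).
#' @param target Name of the target column (no missing values allowed).
#' @param features Character vector of feature column names; defaults to all
#'   numeric columns except the target and `subject_id`.
#' @param region Optional region tag (e.g. `"dmPFC/dACC"`, `"AI"`).
#' @return A `feature_table` list with `data`, `features`, `target`, `region`.
#' @export
feature_table <- function(data, target, features = NULL, region = NA) {
  stopifnot("subject_id" %in% names(data), target %in% names(data))
  if (is.null(features)) {
    num <- names(data)[vapply(data, is.numeric, TRUE)]
    features <- setdiff(num, c(target, "subject_id"))
  }
  stopifnot(all(features %in% names(data)))
  if (anyNA(data[[target]])) stop("missing target values")
  if (any(as.matrix(data[features]) < 0, na.rm = TRUE))
    stop("negative feature values (concentrations must be >= 0)")
  structure(list(data = data, features = features, target = target,
                 region = region),
            class = "feature_table")
}

subset_table <- function(tbl, ids) {
  tbl$data <- tbl$data[tbl$data$subject_id %in% ids, , drop = FALSE]
  tbl
}

feature_matrix <- function(tbl, features = tbl$features)
  as.matrix(tbl$data[features])

#' Random train/test split
#'
#' @param tbl A [feature_table()].
#' @param ratio Training fraction in (0, 1); the train set has
#'   `floor(ratio * N)` subjects.
#' @param seed Integer seed (identical seeds give identical membership).
#' @return A `split_spec` list with `train_ids`, `test_ids`, `ratio`, `seed`.
#' @examples
#' # 80/20 on N = 69 gives 55/14; 75/25 on N = 71 gives 53/18
#' @export
split_train_test <- function(tbl, ratio = 0.8, seed = 1) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio outside (0,1)")
  ids <- tbl$data$subject_id
  n <- length(ids)
  if (n < 10) stop("need at least 10 subjects")
  n_train <- floor(ratio * n)
  train <- with_seed(seed, function() sample(ids, n_train))
  structure(list(train_ids = sort(train),
                 test_ids = sort(setdiff(ids, train)),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stage-1 univariate correlation filter
#'
#' Keeps exactly the features whose absolute Pearson correlation with the
#' target on the *training* rows is at least `threshold`. Constant features
#' correlate 0 by convention and are removed with a warning.
#'
#' @param train A [feature_table()] restricted to training rows.
#' @param threshold Absolute-correlation cutoff (default 0.1).
#' @return Character vector of kept feature names.
#' @export
stage1_filter <- function(train, threshold = 0.1) {
  stopifnot(nrow(train$data) > 0)
  y <- train$data[[train$target]]
  r <- vapply(train$features, function(f)
    safe_cor(train$data[[f]], y), 0)
  train$features[abs(r) >= threshold]
}

## Base booster configuration used for selection and as tuning fallback.
base_xgb_params <- function() list(objective = "reg:squarederror",
                                   max_depth = 3, eta = 0.1, nthread = 1)

fit_booster <- function(X, y, params = base_xgb_params(), nrounds = 100) {
  d <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = c(params, list(seed = 0)), data = d,
                     nrounds = nrounds, verbose = 0)
}

## Leave-one-out CV RMSE of a boosted regressor on (X, y).
loocv_rmse <- function(X, y, params = base_xgb_params(), nrounds = 100) {
  n <- nrow(X)
  pred <- rep(NA_real_, n)
  skipped <- 0
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_booster(X[-i, , drop = FALSE], y[-i], params, nrounds),
      error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1; next }
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  if (skipped > 0.2 * n) stop("more than 20% of LOO folds failed")
  ok <- !is.na(pred)
  rmse(y[ok], pred[ok])
}

#' Stage-2 nested-subset selection under CVLOO error
#'
#' Ranks the stage-1 features by gain importance of a boosted ensemble
#' trained on the training rows, then evaluates the nested subsets (top-1,
#' top-2, ..., all) by leave-one-out CV RMSE of the boosted regressor and
#' returns the subset with the smallest validation error.
#'
#' @param train A [feature_table()] restricted to training rows.
#' @param stage1 Character vector of stage-1 survivors (non-empty).
#' @param params,nrounds Booster settings used for ranking and evaluation.
#' @return A `selection_result` list: `stage1_kept`, `stage2_kept`,
#'   `selection_trace` (data frame of evaluated subset sizes and CVLOO RMSE),
#'   `ranking`.
#' @export
stage2_select <- function(train, stage1, params = base_xgb_params(),
                          nrounds = 100) {
  if (length(stage1) == 0) stop("no stage-1 features to select from")
  y <- train$data[[train$target]]
  if (length(stage1) == 1) {
    tr <- data.frame(k = 1, subset = stage1,
                     cv_rmse = loocv_rmse(feature_matrix(train, stage1), y,
                                          params, nrounds))
    return(structure(list(stage1_kept = stage1, stage2_kept = stage1,
                          selection_trace = tr, ranking = stage1),
                     class = "selection_result"))
  }
  X <- feature_matrix(train, stage1)
  full <- fit_booster(X, y, params, nrounds)
  imp <- xgboost::xgb.importance(model = full)
  ranking <- c(imp$Feature, setdiff(stage1, imp$Feature))
  trace <- data.frame(k = seq_along(ranking),
                      subset = vapply(seq_along(ranking), function(k)
                        paste(ranking[1:k], collapse = "+"), ""),
                      cv_rmse = NA_real_)
  for (k in seq_along(ranking)) {
    Xk <- feature_matrix(train, ranking[1:k])
    trace$cv_rmse[k] <- loocv_rmse(Xk, y, params, nrounds)
  }
  best_k <- which.min(trace$cv_rmse)
  structure(list(stage1_kept = stage1,
                 stage2_kept = ranking[1:best_k],
                 selection_trace = trace, ranking = ranking),
            class = "selection_result")
}

#' Hyperparameter search space for the boosted regressor
#'
#' Six tunable dimensions: step-size shrinkage `eta` (log scale), tree depth
#' `max_depth` (integer), `min_child_weight`, and the regularization
#' parameters `gamma`, `lambda`, `alpha`.
#'
#' @param eta,max_depth,min_child_weight,gamma,lambda,alpha Numeric bounds
#'   `c(lo, hi)` per dimension.
#' @param n_evals Total objective evaluations for the optimizer.
#' @return A `hyper_space` list.
#' @export
hyper_space <- function(eta = c(0.01, 0.3), max_depth = c(1, 6),
                        min_child_weight = c(1, 10), gamma = c(0, 5),
                        lambda = c(0.001, 10), alpha = c(0.001, 10),
                        n_evals = 30) {
  bounds <- list(eta = eta, max_depth = max_depth,
                 min_child_weight = min_child_weight, gamma = gamma,
                 lambda = lambda, alpha = alpha)
  for (b in bounds) stopifnot(length(b) == 2, all(is.finite(b)), b[1] < b[2])
  stopifnot(max_depth[1] >= 1, n_evals >= 1)
  structure(list(bounds = bounds, log_scale = c("eta", "lambda", "alpha"),
                 integer = "max_depth", n_evals = n_evals),
            class = "hyper_space")
}

## Map a unit-cube row to named hyperparameters.
decode_point <- function(u, space) {
  out <- list()
  for (j in seq_along(space$bounds)) {
    nm <- names(space$bounds)[j]
    b <- space$bounds[[nm]]
    v <- if (nm %in% space$log_scale) {
      exp(log(b[1]) + u[j] * (log(b[2]) - log(b[1])))
    } else b[1] + u[j] * (b[2] - b[1])
    if (nm %in% space$integer) v <- as.integer(round(v))
    out[[nm]] <- v
  }
  out
}

## Minimal Gaussian-process surrogate (RBF kernel, fixed length-scale) with
## expected improvement, used for the sequential search. Inputs live on the
## unit cube; objective values are standardized internally.
gp_expected_improvement <- function(Xobs, yobs, Xcand, ell = 0.4,
                                    nugget = 1e-4) {
  mu_y <- mean(yobs); sd_y <- stats::sd(yobs)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  z <- (yobs - mu_y) / sd_y
  d2 <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  K <- exp(-0.5 * d2(Xobs, Xobs) / ell^2) + diag(nugget, nrow(Xobs))
  ch <- chol(K)
  alpha <- backsolve(ch, backsolve(ch, z, transpose = TRUE))
  Ks <- exp(-0.5 * d2(Xcand, Xobs) / ell^2)
  mu <- drop(Ks %*% alpha)
  V <- backsolve(ch, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(V^2), 1e-12)
  s <- sqrt(s2)
  best <- min(z)
  imp <- best - mu - 0.01
  u <- imp / s
  imp * stats::pnorm(u) + s * stats::dnorm(u)
}

#' Tune the boosted regressor by CVLOO Bayesian optimization and refit
#'
#' Minimizes the leave-one-out CV RMSE over the six-dimensional
#' [hyper_space()] by sequential model-based optimization: a Latin-hypercube
#' initial design followed by Gaussian-process expected-improvement
#' proposals. The winning configuration is refit on all training rows.
#'
#' @param train A [feature_table()] restricted to training rows.
#' @param features Feature names to use (non-empty).
#' @param space A [hyper_space()].
#' @param nrounds Boosting rounds (fixed; `eta` is tuned instead).
#' @param seed Tuning seed (search is deterministic given it).
#' @return A `tuned_model` list: `model` (xgb.Booster refit on all training
#'   rows), `features`, `best_params`, `validation_rmse` (best CVLOO RMSE),
#'   `train_rmse`, `trace` (all evaluated configurations), `nrounds`.
#' @export
tune_and_fit <- function(train, features, space = hyper_space(),
                         nrounds = 100, seed = 1) {
  if (length(features) == 0) stop("no features supplied")
  if (space$n_evals < 1) stop("empty search budget")
  X <- feature_matrix(train, features)
  y <- train$data[[train$target]]
  d <- length(space$bounds)
  n0 <- min(max(5, d + 2), space$n_evals)

  U <- with_seed(seed, function() lhs::randomLHS(n0, d))
  evals <- data.frame()
  obj <- function(u) {
    hp <- decode_point(u, space)
    params <- c(list(objective = "reg:squarederror", nthread = 1), hp)
    loocv_rmse(X, y, params, nrounds)
  }
  vals <- apply(U, 1, obj)
  while (nrow(U) < space$n_evals) {
    cand <- with_seed(derive_seed(seed, nrow(U)), function()
      lhs::randomLHS(256, d))
    ei <- gp_expected_improvement(U, vals, cand)
    u_next <- cand[which.max(ei), ]
    U <- rbind(U, u_next)
    vals <- c(vals, obj(u_next))
  }
  best_i <- which.min(vals)
  best_hp <- decode_point(U[best_i, ], space)
  best_params <- c(list(objective = "reg:squarederror", nthread = 1), best_hp)
  model <- fit_booster(X, y, best_params, nrounds)
  trace <- as.data.frame(t(apply(U, 1, function(u)
    unlist(decode_point(u, space)))))
  trace$cv_rmse <- vals
  structure(list(model = model, features = features,
                 best_params = best_hp,
                 validation_rmse = vals[best_i],
                 train_rmse = rmse(y, predict(model, X)),
                 trace = trace, nrounds = nrounds),
            class = "tuned_model")
}

#' Evaluate a tuned model on held-out rows
#'
#' @param fit A `tuned_model` from [tune_and_fit()].
#' @param test A [feature_table()] restricted to test rows (>= 3, disjoint
#'   from training).
#' @return A `prediction_report` list: `test_rmse`, `test_pearson_r`,
#'   `test_p` (one-tailed, positive association), `variance_explained`
#'   (`r^2`), `n_test`, `predictions`, `truth`.
#' @export
evaluate_model <- function(fit, test) {
  if (nrow(test$data) < 3) stop("test set smaller than 3")
  X <- feature_matrix(test, fit$features)
  y <- test$data[[test$target]]
  pred <- predict(fit$model, X)
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    r <- 0; pv <- 1
  } else {
    ct <- stats::cor.test(y, pred, alternative = "greater")
    r <- unname(ct$estimate); pv <- ct$p.value
  }
  structure(list(test_rmse = rmse(y, pred), test_pearson_r = r,
                 test_p = pv, variance_explained = r^2,
                 n_test = length(y), predictions = pred, truth = y),
            class = "prediction_report")
}

#' Label-permutation null test of predictive performance
#'
#' For each permutation the training labels are shuffled, the booster is
#' retrained with the hyperparameters frozen at the unpermuted optimum, and
#' the test RMSE recorded. The pass threshold is the 5th percentile of the
#' permuted RMSE distribution (the model must outperform 95% of null runs),
#' taken as the `ceiling(0.05 * n_perm)`-th order statistic of the sorted
#' permuted RMSEs (the 250th of 5000).
#'
#' @param fit A `tuned_model` (frozen hyperparameters and feature set).
#' @param train,test [feature_table()]s for the two partitions.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Permutation seed.
#' @return A `permutation_result` list: `n_perm`, `permuted_rmse`,
#'   `threshold`, `observed_rmse`, `significant` (observed < threshold),
#'   `p_value` (`(1 + #(permuted <= observed)) / (n_perm + 1)`), `seed`.
#' @export
permutation_test <- function(fit, train, test, n_perm = 5000, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  Xtr <- feature_matrix(train, fit$features)
  ytr <- train$data[[train$target]]
  Xte <- feature_matrix(test, fit$features)
  yte <- test$data[[test$target]]
  params <- c(list(objective = "reg:squarederror", nthread = 1),
              fit$best_params)
  observed <- rmse(yte, predict(fit$model, Xte))
  perms <- with_seed(seed, function()
    replicate(n_perm, sample.int(length(ytr)), simplify = FALSE))
  perm_rmse <- vapply(perms, function(idx) {
    m <- fit_booster(Xtr, ytr[idx], params, fit$nrounds)
    rmse(yte, predict(m, Xte))
  }, 0)
  k <- ceiling(0.05 * n_perm)
  threshold <- sort(perm_rmse)[k]
  structure(list(n_perm = n_perm, permuted_rmse = perm_rmse,
                 threshold = threshold, observed_rmse = observed,
                 significant = observed < threshold,
                 p_value = (1 + sum(perm_rmse <= observed)) / (n_perm + 1),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' Shapley (TreeSHAP) attribution of a boosted model
#'
#' Exact tree-path Shapley values per subject and feature, with the base
#' value (expected prediction) and a ranking by mean absolute attribution.
#' Local accuracy (attributions + base = prediction) holds for every row.
#'
#' @param fit A `tuned_model` (or any xgb.Booster in `fit$model`).
#' @param tbl A [feature_table()] with the rows to explain.
#' @return A `shapley_report` list: `values` (rows x features), `base_value`,
#'   `ranking` (features by decreasing mean `|value|`), `predictions`.
#' @export
shapley_attribution <- function(fit, tbl) {
  model <- if (inherits(fit, "tuned_model")) fit$model else fit
  if (!inherits(model, "xgb.Booster"))
    stop("unsupported model: Shapley attribution requires a tree ensemble (xgb.Booster)")
  features <- if (inherits(fit, "tuned_model")) fit$features else tbl$features
  X <- feature_matrix(tbl, features)
  contrib <- predict(model, X, predcontrib = TRUE)
  base_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  base <- contrib[, base_col]
  vals <- contrib[, setdiff(colnames(contrib), base_col), drop = FALSE]
  imp <- colMeans(abs(vals))
  structure(list(values = vals, base_value = unname(base[1]),
                 ranking = names(sort(imp, decreasing = TRUE)),
                 predictions = predict(model, X)),
            class = "shapley_report")
}

#' Linear versus quadratic (inverted-U) single-predictor comparison
#'
#' Fits `y ~ x` and `y ~ (x - mean(x))^2` on identical rows and compares them
#' by AIC and BIC. The reported `r` per fit is the signed Pearson correlation
#' between the (centered-square for the quadratic fit) regressor and `y`.
#'
#' @param x Numeric predictor (non-constant, `n >= 10`).
#' @param y Numeric target.
#' @return A `curvature_comparison` list: `linear` and `quadratic` (each with
#'   `r`, `p`, `aic`, `bic`, `fit`), `winner_aic`, `winner_bic`.
#' @export
curvature_comparison <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("need n >= 10")
  if (stats::sd(x) == 0) stop("zero-variance predictor")
  csq <- (x - mean(x))^2
  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ csq)
  stat <- function(fit, reg) {
    ct <- stats::cor.test(reg, y)
    list(r = unname(ct$estimate), p = ct$p.value,
         aic = stats::AIC(fit), bic = stats::BIC(fit), fit = fit)
  }
  l <- stat(lin, x); q <- stat(quad, csq)
  structure(list(linear = l, quadratic = q,
                 winner_aic = if (l$aic <= q$aic) "linear" else "quadratic",
                 winner_bic = if (l$bic <= q$bic) "linear" else "quadratic"),
            class = "curvature_comparison")
}

#' Plasma-brain metabolite correlations
#'
#' Pearson correlation (two-tailed) between plasma and brain concentrations
#' of each requested metabolite, matching subjects by `subject_id` and
#' dropping incomplete pairs pairwise.
#'
#' @param plasma,brain Data frames with `subject_id` and metabolite columns.
#' @param metabolites Character vector of column names present in both.
#' @return Data frame with `metabolite`, `n`, `r`, `p`.
#' @export
plasma_brain_correlation <- function(plasma, brain, metabolites) {
  m <- merge(plasma, brain, by = "subject_id",
             suffixes = c(".plasma", ".brain"))
  out <- lapply(metabolites, function(met) {
    xp <- m[[paste0(met, ".plasma")]]
    xb <- m[[paste0(met, ".brain")]]
    if (is.null(xp) || is.null(xb))
      stop("metabolite absent from one table: ", met)
    ok <- stats::complete.cases(xp, xb)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ", met)
    ct <- stats::cor.test(xp[ok], xb[ok])
    data.frame(metabolite = met, n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

#' Run the full prediction pipeline under one master seed
#'
#' Convenience wrapper: split, stage-1 filter, stage-2 selection, CVLOO
#' tuning, holdout evaluation and label-permutation test, with independent
#' seed substreams for split, tuning and permutations. Selection and tuning
#' only ever see the training rows.
#'
#' @param tbl A [feature_table()].
#' @param ratio Training fraction (0.80 for choice proportions, 0.75 for
#'   parameter targets in the reference analysis).
#' @param threshold Stage-1 absolute-correlation cutoff.
#' @param space A [hyper_space()].
#' @param n_perm Permutations for the null test.
#' @param nrounds Boosting rounds.
#' @param seed Master seed.
#' @return List with `split`, `selection`, `tuned`, `report`, `permutation`,
#'   `shap`.
#' @export
run_prediction_pipeline <- function(tbl, ratio = 0.8, threshold = 0.1,
                                    space = hyper_space(), n_perm = 5000,
                                    nrounds = 100, seed = 1) {
  split <- split_train_test(tbl, ratio, derive_seed(seed, 1))
  train <- subset_table(tbl, split$train_ids)
  test <- subset_table(tbl, split$test_ids)
  stage1 <- stage1_filter(train, threshold)
  if (length(stage1) == 0)
    stop("no feature passed the stage-1 filter")
  selection <- stage2_select(train, stage1)
  tuned <- tune_and_fit(train, selection$stage2_kept, space, nrounds,
                        seed = derive_seed(seed, 2))
  report <- evaluate_model(tuned, test)
  perm <- permutation_test(tuned, train, test, n_perm,
                           seed = derive_seed(seed, 3))
  shap <- shapley_attribution(tuned, train)
  list(split = split, selection = selection, tuned = tuned,
       report = report, permutation = perm, shap = shap)
}
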