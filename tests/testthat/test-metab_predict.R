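make_noise_table <- function(n = 55, p = 18, seed = 1) {
  set.seed(seed)
  d <- data.frame(subject_id = seq_len(n))
  for (j in seq_len(p)) d[[paste0("f", j)]] <- abs(rnorm(n)) + 1
  d$target <- rnorm(n)
  feature_table(d, "target")
}

test_that("train/test split arithmetic matches the study partitions", {
  t69 <- make_noise_table(69)
  s <- split_train_test(t69, 0.80, seed = 1)
  expect_length(s$train_ids, 55)
  expect_length(s$test_ids, 14)

  t71 <- make_noise_table(71)
  s2 <- split_train_test(t71, 0.75, seed = 1)
  expect_length(s2$train_ids, 53)
  expect_length(s2$test_ids, 18)

  expect_length(intersect(s$train_ids, s$test_ids), 0)
  expect_setequal(c(s$train_ids, s$test_ids), t69$data$subject_id)
  expect_identical(split_train_test(t69, 0.8, 7)$train_ids,
                   split_train_test(t69, 0.8, 7)$train_ids)
  expect_error(split_train_test(t69, 1.2), "ratio")
})

test_that("stage-1 filter keeps exactly the |r| >= threshold features", {
  set.seed(3)
  n <- 60
  d <- data.frame(subject_id = seq_len(n), target = rnorm(n))
  d$strong <- d$target + rnorm(n, 0, 0.3) + 10   # |r| well above 0.1
  d$anti <- 2 - 0.5 * d$target + rnorm(n, 0, 0.5) + 3  # negative r kept too
  d$copy <- d$target + 10                         # r = 1
  # engineered weak feature: residualize noise against target, r ~ 0.05
  z <- rnorm(n)
  z <- residuals(lm(z ~ d$target))
  z <- z / sd(z) + 0.05 * scale(d$target)[, 1]
  d$weak <- z - min(z)
  d$flat <- 1
  tbl <- feature_table(d, "target",
                       c("strong", "anti", "copy", "weak", "flat"))
  expect_warning(kept <- stage1_filter(tbl, 0.1), "zero-variance")
  expect_true(all(c("strong", "anti", "copy") %in% kept))
  expect_false("weak" %in% kept)
  expect_false("flat" %in% kept)
  # the kept set is exactly the features passing the empirical rule
  r <- sapply(c("strong", "anti", "copy", "weak"),
              function(f) cor(d[[f]], d$target))
  expect_setequal(kept, names(r)[abs(r) >= 0.1])
})

test_that("null stage-1 survival matches the analytic t-distribution rate", {
  n <- 55
  # P(|r| >= 0.1) under the null via the exact t-transform of sample r
  t0 <- 0.1 * sqrt((n - 2) / (1 - 0.1^2))
  p_keep <- 2 * stats::pt(t0, df = n - 2, lower.tail = FALSE)
  kept <- vapply(1:40, function(s)
    length(stage1_filter(make_noise_table(n, 18, seed = 600 + s), 0.1)), 0)
  expect_equal(mean(kept), 18 * p_keep, tolerance = 0.15)
})

test_that("stage-2 selection respects the subset contract and finds signal", {
  tbl <- make_signal_table(n = 30, n_noise = 5, seed = 1)
  s1 <- stage1_filter(tbl, 0.1)
  sel <- stage2_select(tbl, s1, nrounds = 30)
  expect_true(all(sel$stage2_kept %in% sel$stage1_kept))
  expect_true(all(sel$stage1_kept %in% tbl$features))
  expect_equal(sel$selection_trace$cv_rmse[length(sel$stage2_kept)],
               min(sel$selection_trace$cv_rmse))

  # single stage-1 survivor is trivially selected
  sel1 <- stage2_select(tbl, "signal", nrounds = 30)
  expect_equal(sel1$stage2_kept, "signal")

  # the informative feature survives in nearly all replicates
  hits <- vapply(1:15, function(s) {
    tb <- make_signal_table(n = 30, n_noise = 5, r2 = 0.85, seed = 700 + s)
    sl <- stage2_select(tb, stage1_filter(tb, 0.1), nrounds = 30)
    "signal" %in% sl$stage2_kept
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("tuning minimizes CVLOO error within the declared bounds", {
  sp <- hyper_space(n_evals = 8)
  # deterministic monotone map, no noise: near-zero validation error
  set.seed(5)
  n <- 30
  d <- data.frame(subject_id = seq_len(n), x = sort(abs(rnorm(n)) + 1))
  d$target <- 2 * d$x
  tbl <- feature_table(d, "target", "x")
  fit <- tune_and_fit(tbl, "x", sp, nrounds = 80, seed = 1)
  expect_lt(fit$validation_rmse, 0.5 * sd(d$target))
  for (nm in names(sp$bounds)) {
    expect_gte(fit$best_params[[nm]], sp$bounds[[nm]][1])
    expect_lte(fit$best_params[[nm]], sp$bounds[[nm]][2])
  }
  expect_equal(nrow(fit$trace), 8)

  # constant target: zero validation RMSE and constant predictions
  d2 <- d; d2$target <- 3
  tbl2 <- feature_table(d2, "target", "x")
  fit2 <- tune_and_fit(tbl2, "x", hyper_space(n_evals = 5), nrounds = 20,
                       seed = 1)
  expect_equal(fit2$validation_rmse, 0, tolerance = 1e-6)
  expect_equal(var(predict(fit2$model, matrix(d2$x))), 0, tolerance = 1e-12)

  expect_error(tune_and_fit(tbl, character(0)), "no features")
})

test_that("holdout evaluation reports RMSE and the one-tailed t-transform p", {
  tbl <- make_signal_table(n = 50, n_noise = 2, r2 = 0.9, seed = 9)
  split <- split_train_test(tbl, 0.8, seed = 2)
  train <- effortmet:::subset_table(tbl, split$train_ids)
  test <- effortmet:::subset_table(tbl, split$test_ids)
  fit <- tune_and_fit(train, "signal", hyper_space(n_evals = 6), seed = 3)
  rep <- evaluate_model(fit, test)
  expect_gte(rep$test_rmse, 0)
  expect_gt(rep$test_pearson_r, 0)
  expect_equal(rep$variance_explained, rep$test_pearson_r^2)
  # independent closed-form oracle for the one-tailed p-value
  r <- rep$test_pearson_r; n <- rep$n_test
  p_oracle <- stats::pt(r * sqrt((n - 2) / (1 - r^2)), n - 2,
                        lower.tail = FALSE)
  expect_equal(rep$test_p, p_oracle, tolerance = 1e-10)
  expect_error(evaluate_model(fit, effortmet:::subset_table(tbl, 1:2)),
               "smaller than 3")
})

test_that("a target-copy feature clears its permutation null", {
  set.seed(11)
  n <- 40
  d <- data.frame(subject_id = seq_len(n), x = abs(rnorm(n)) + 1)
  d$target <- d$x
  tbl <- feature_table(d, "target", "x")
  split <- split_train_test(tbl, 0.75, seed = 1)
  train <- effortmet:::subset_table(tbl, split$train_ids)
  test <- effortmet:::subset_table(tbl, split$test_ids)
  fit <- tune_and_fit(train, "x", hyper_space(n_evals = 5), seed = 1)
  pm <- permutation_test(fit, train, test, n_perm = 100, seed = 1)
  expect_true(pm$significant)
  expect_lt(pm$observed_rmse, pm$threshold)
  expect_equal(pm$threshold, sort(pm$permuted_rmse)[ceiling(0.05 * 100)])
  expect_error(permutation_test(fit, train, test, n_perm = 50), ">= 100")
})

test_that("permutation p-values are uniform under the null", {
  n <- 24
  pvals <- vapply(1:60, function(s) {
    set.seed(900 + s)
    d <- data.frame(subject_id = seq_len(n), x = abs(rnorm(n)) + 1,
                    target = rnorm(n))
    tbl <- feature_table(d, "target", "x")
    split <- split_train_test(tbl, 0.75, seed = s)
    train <- effortmet:::subset_table(tbl, split$train_ids)
    test <- effortmet:::subset_table(tbl, split$test_ids)
    fit <- list(model = effortmet:::fit_booster(
                  effortmet:::feature_matrix(train, "x"),
                  train$data$target, nrounds = 8),
                features = "x", best_params = list(max_depth = 2),
                nrounds = 8)
    class(fit) <- "tuned_model"
    permutation_test(fit, train, test, n_perm = 100, seed = s)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # nominal type-I rate at the 0.05 level (binomial band for 60 replicates)
  expect_lte(mean(pvals < 0.05), 0.15)
})

test_that("Shapley attributions are locally exact and order-invariant", {
  tbl <- make_signal_table(n = 40, n_noise = 3, seed = 13)
  fit <- tune_and_fit(tbl, tbl$features, hyper_space(n_evals = 5), seed = 2)
  sh <- shapley_attribution(fit, tbl)
  recon <- rowSums(sh$values) + sh$base_value
  # single-precision tree contributions: 1e-6 relative to prediction scale
  expect_lt(max(abs(recon - sh$predictions)),
            1e-6 * max(1, max(abs(sh$predictions))))
  expect_setequal(sh$ranking, tbl$features)

  # ranking invariant to feature column order
  tbl_rev <- tbl; tbl_rev$features <- rev(tbl$features)
  fit_rev <- tune_and_fit(tbl_rev, tbl_rev$features,
                          hyper_space(n_evals = 5), seed = 2)
  sh_rev <- shapley_attribution(fit_rev, tbl_rev)
  expect_equal(sh$ranking[1], sh_rev$ranking[1])
  expect_equal(sh$ranking[1], "signal")

  expect_error(shapley_attribution(lm(target ~ signal, tbl$data), tbl),
               "unsupported model")
})

test_that("single-feature attributions equal the brute-force Shapley value", {
  # one feature: the only coalition is {x}, so the attribution must be
  # f(x) - E[f] with E[f] the (cover-weighted) training mean prediction
  set.seed(17)
  n <- 50
  d <- data.frame(subject_id = seq_len(n), x = abs(rnorm(n)) + 1)
  d$target <- d$x^2
  tbl <- feature_table(d, "target", "x")
  X <- effortmet:::feature_matrix(tbl, "x")
  m <- effortmet:::fit_booster(X, d$target,
                               params = list(objective = "reg:squarederror",
                                             max_depth = 1, eta = 0.5,
                                             nthread = 1), nrounds = 10)
  sh <- shapley_attribution(m, tbl)
  pred <- predict(m, X)
  expect_equal(drop(sh$values), pred - mean(pred), tolerance = 1e-5)
  expect_equal(sh$base_value, mean(pred), tolerance = 1e-5)

  # duplicated feature: attributions share the credit but sum unchanged
  d2 <- d; d2$x2 <- d$x
  tbl2 <- feature_table(d2, "target", c("x", "x2"))
  m2 <- effortmet:::fit_booster(effortmet:::feature_matrix(tbl2),
                                d2$target,
                                params = list(objective = "reg:squarederror",
                                              max_depth = 1, eta = 0.5,
                                              nthread = 1), nrounds = 10)
  sh2 <- shapley_attribution(m2, tbl2)
  expect_equal(rowSums(sh2$values), drop(sh$values), tolerance = 1e-5)
})

test_that("curvature comparison identifies quadratic and linear truth", {
  n <- 69
  quad_wins <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- rnorm(n, 10, 1.2)
    csq <- scale((x - mean(x))^2)[, 1]
    y <- -0.36 * csq + sqrt(1 - 0.36^2) * rnorm(n)  # effect sized to r ~ 0.36
    cc <- curvature_comparison(x, y)
    cc$winner_aic == "quadratic" && cc$winner_bic == "quadratic"
  }, TRUE)
  expect_gte(mean(quad_wins), 0.9)

  set.seed(2)
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.7)
  cc <- curvature_comparison(x, y)
  expect_equal(cc$winner_aic, "linear")
  expect_equal(cc$winner_bic, "linear")

  # pure noise: neither model strongly preferred in most draws
  weak <- vapply(1:20, function(s) {
    set.seed(1100 + s)
    cc0 <- curvature_comparison(rnorm(n), rnorm(n))
    abs(cc0$linear$bic - cc0$quadratic$bic) < 6
  }, TRUE)
  expect_gte(mean(weak), 0.8)
  expect_error(curvature_comparison(rep(1, n), rnorm(n)), "zero-variance")
  expect_error(curvature_comparison(rnorm(5), rnorm(5)), "n >= 10")
})

test_that("plasma-brain correlations handle matching, NA and degenerate input", {
  set.seed(19)
  n <- 40
  brain <- data.frame(subject_id = 1:n, Gln = abs(rnorm(n)) + 1,
                      Lac = abs(rnorm(n)) + 1)
  plasma <- data.frame(subject_id = 1:n, Gln = brain$Gln,
                       Lac = abs(rnorm(n)) + 1)
  plasma$Lac[1:5] <- NA
  out <- plasma_brain_correlation(plasma, brain, c("Gln", "Lac"))
  expect_equal(out$r[out$metabolite == "Gln"], 1)
  expect_equal(out$n[out$metabolite == "Lac"], 35)
  expect_lt(abs(out$r[out$metabolite == "Lac"]), 0.5)
  few <- plasma; few$Gln[3:n] <- NA
  expect_error(plasma_brain_correlation(few, brain, "Gln"), "fewer than 3")
})

test_that("selection and tuning read training rows only", {
  tbl <- make_signal_table(n = 40, n_noise = 4, seed = 23)
  split <- split_train_test(tbl, 0.8, seed = 5)
  scrambled <- tbl
  test_rows <- scrambled$data$subject_id %in% split$test_ids
  set.seed(99)
  for (f in scrambled$features)
    scrambled$data[[f]][test_rows] <- abs(rnorm(sum(test_rows))) + 1
  run_half <- function(t) {
    train <- effortmet:::subset_table(t, split$train_ids)
    s1 <- stage1_filter(train, 0.1)
    sel <- stage2_select(train, s1, nrounds = 30)
    fit <- tune_and_fit(train, sel$stage2_kept, hyper_space(n_evals = 5),
                        seed = 7)
    list(s1 = s1, kept = sel$stage2_kept, vrmse = fit$validation_rmse)
  }
  a <- run_half(tbl)
  b <- run_half(scrambled)
  expect_identical(a$s1, b$s1)
  expect_identical(a$kept, b$kept)
  expect_identical(a$vrmse, b$vrmse)
})
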