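# Shared fixtures and independent oracles, all built in code at test time.

make_dataset <- function(params, seed = 1, start = "mental") {
  sched <- generate_session(seed, start)
  simulate_choices(params, sched, seed = seed + 1000)
}

default_params <- function() {
  behavioral_parameters(kR = 0.8, kP = 0.6, kEp = 0.7, kEm = 0.9,
                        kFp = 0.25, kLm = 0.2, bias = 0.3)
}

# Independent MAP oracle for a 2-parameter variant: coarse-to-fine dense grid
# over the latent box of the *same* negative log-posterior that fit_map
# minimizes (pure function evaluations, no gradients or quasi-Newton steps).
grid_map_oracle <- function(ds, prior, free = c("kEm", "bias"),
                            box = c(-2.5, 2.5), final_step = 0.01) {
  free_idx <- match(free, c("kR", "kP", "kEp", "kEm", "kFp", "kLm", "bias"))
  dat <- effortmet:::prepare_choice_data(ds)
  obj <- effortmet:::make_objective(dat, prior, free_idx)
  centre <- c(0, 0); half <- diff(box) / 2; step <- 0.1
  repeat {
    g1 <- seq(centre[1] - half, centre[1] + half, by = step)
    g2 <- seq(centre[2] - half, centre[2] + half, by = step)
    grid <- as.matrix(expand.grid(g1, g2))
    vals <- apply(grid, 1, obj$fn)
    centre <- grid[which.min(vals), ]
    if (step <= final_step) break
    half <- 2.5 * step
    step <- step / 10
  }
  stats::setNames(centre, free)
}

# Small feature table with one informative feature among noise.
make_signal_table <- function(n = 40, n_noise = 9, r2 = 0.8, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- sqrt(r2) * x + sqrt(1 - r2) * rnorm(n)
  d <- data.frame(subject_id = seq_len(n), signal = abs(x) + 1)
  for (j in seq_len(n_noise)) d[[paste0("noise", j)]] <- abs(rnorm(n)) + 1
  d$target <- sqrt(r2) * d$signal + sqrt(1 - r2) * rnorm(n)
  feature_table(d, "target")
}

# One 300-run recovery study shared by the acceptance tests (computed once).
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_recovery <- function() {
  if (is.null(.acceptance_cache$recovery)) {
    .acceptance_cache$recovery <- run_recovery(
      recovery_design(n_sims = 300, batch_size = 100), seed = 1)
  }
  .acceptance_cache$recovery
}
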