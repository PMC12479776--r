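## Synthetic study cohorts with known ground truth.
##
## Emulates the statistical structure of the 7T MRS effort study: per-subject
## brain metabolite profiles in two regions (dmPFC/dACC and anterior insula)
## plus plasma counterparts, drawn from a Gaussian copula with log-normal
## margins; seven behavioural parameters with skewed (log-normal-like)
## distributions; and one simulated 216-trial choice session per subject.
## Planted generative links (defaults follow the reference associations):
##   corr(dmPFC Asp, kEm)            ~  0.42
##   corr(dmPFC Asp, HME)            ~ -0.37   (via the kEm path)
##   corr((Glu - mean)^2, HME)       ~ -0.36   (inverted-U glutamate effect)
##   corr(Glu, HME)                  ~ -0.19   (emergent linear component of
##                                              the skewed quadratic path)
##   corr(plasma Gln, dmPFC Gln)     ~  0.54
##   corr(plasma Lac, dmPFC Lac)     ~  0.27
##   corr(HME, HPE)                  ~  0.22   (shared bias)
## The loading constants were calibrated once by large-N simulation (see
## analysis/00_calibrate_generator.R) and are frozen here. The anterior
## insula region carries no behavioural links (its metabolites are noise with
## respect to behaviour), mirroring the reference study's null AI findings.

BRAIN_METS <- c(Glu = 10, Gln = 3, NAA = 11, NAAG = 1.5, Asp = 2.5,
                Lac = 1.0, GSH = 1.5, GABA = 1.5, PCrCr = 8,
                Tau = 1.5, mI = 6)
BRAIN_CV <- c(Glu = 0.12, Gln = 0.15, NAA = 0.08, NAAG = 0.15, Asp = 0.15,
              Lac = 0.15, GSH = 0.12, GABA = 0.15, PCrCr = 0.08,
              Tau = 0.15, mI = 0.10)
PLASMA_METS <- c(Glu = 50, Gln = 550, Asp = 8, Lac = 1200)  # umol/L scale
PLASMA_CV <- c(Glu = 0.25, Gln = 0.15, Asp = 0.25, Lac = 0.30)
RATIO_METS <- c("Glu", "Gln", "NAA", "Lac", "GSH", "Asp")

#' The 18 synthetic metabolite feature names
#'
#' Twelve concentrations (including the derived composite `Glx = Glu + Gln`)
#' and six standard ratios to total creatine (`PCrCr`). This list is a
#' stated synthetic stand-in for the feature sets such MRS studies quantify.
#'
#' @return Character vector of length 18.
#' @export
metabolite_features <- function() {
  c(names(BRAIN_METS)[1:2], "Glx", names(BRAIN_METS)[3:11],
    paste0(RATIO_METS, "_PCrCr"))
}

#' Planted generative links of the synthetic cohort
#'
#' Target Pearson associations the generator is calibrated to reproduce.
#' Setting an entry to 0 removes the corresponding generative path (a fully
#' null cohort is obtained by zeroing all of them).
#'
#' @param asp_kem Linear association dmPFC aspartate with kEm.
#' @param asp_hme Expected aspartate-HME association (emerges through the
#'   kEm path; recorded for QC, not an independent dial).
#' @param glu_quad_hme Association of the mean-centered squared dmPFC
#'   glutamate score with HME (negative = inverted U).
#' @param glu_lin_hme Linear glutamate-HME association (the reference
#'   relation is dominated by the inverted U but carries this weak linear
#'   component as well).
#' @param plasma_brain_gln,plasma_brain_lac Plasma-brain correlations
#'   (dmPFC/dACC region).
#' @param hme_hpe Weak HME-HPE coupling through the shared high-effort bias.
#' @param ai_plasma_gln Plasma-AI glutamine correlation.
#' @return A `link_spec` list.
#' @export
link_spec <- function(asp_kem = 0.42, asp_hme = -0.37,
                      glu_quad_hme = -0.36, glu_lin_hme = -0.19,
                      plasma_brain_gln = 0.54,
                      plasma_brain_lac = 0.27, hme_hpe = 0.22,
                      ai_plasma_gln = 0.34) {
  structure(list(asp_kem = asp_kem, asp_hme = asp_hme,
                 glu_quad_hme = glu_quad_hme, glu_lin_hme = glu_lin_hme,
                 plasma_brain_gln = plasma_brain_gln,
                 plasma_brain_lac = plasma_brain_lac,
                 hme_hpe = hme_hpe, ai_plasma_gln = ai_plasma_gln),
            class = "link_spec")
}

## Gaussian-scale correlation needed for two log-normal margins (sigmas s1,
## s2 on the log scale) to show Pearson correlation r on the natural scale.
lognormal_rho <- function(r, s1, s2) {
  if (r == 0) return(0)
  v <- 1 + r * sqrt(expm1(s1^2) * expm1(s2^2))
  if (v <= 0) stop("target correlation infeasible for these margins")
  log(v) / (s1 * s2)
}

log_sigma <- function(cv) sqrt(log(1 + cv^2))

## Correlation matrix of the Gaussian copula scores:
## order = plasma (4) | dmPFC brain (11) | AI brain (11).
copula_correlation <- function(links) {
  nb <- length(BRAIN_METS)
  nm <- c(paste0("pl_", names(PLASMA_METS)),
          paste0("dm_", names(BRAIN_METS)),
          paste0("ai_", names(BRAIN_METS)))
  R <- diag(length(nm)); dimnames(R) <- list(nm, nm)
  set <- function(i, j, v) { R[i, j] <<- v; R[j, i] <<- v }
  ## mild within-region metabolite inter-correlations (TCA-cycle neighbours
  ## correlated, lactate decoupled from glutamate)
  within <- rbind(c("Glu", "Gln", 0.35), c("Glu", "Asp", 0.35),
                  c("Gln", "Asp", 0.30), c("Glu", "NAA", 0.20),
                  c("Asp", "Lac", 0.15), c("NAA", "NAAG", 0.20),
                  c("Glu", "GABA", 0.15), c("Glu", "GSH", 0.15))
  for (pre in c("dm_", "ai_"))
    for (k in seq_len(nrow(within)))
      set(paste0(pre, within[k, 1]), paste0(pre, within[k, 2]),
          as.numeric(within[k, 3]))
  ## same metabolite across brain regions
  for (met in names(BRAIN_METS)) set(paste0("dm_", met),
                                     paste0("ai_", met), 0.30)
  ## plasma-brain links, converted to the Gaussian scale
  set("pl_Gln", "dm_Gln", lognormal_rho(links$plasma_brain_gln,
                                        log_sigma(PLASMA_CV["Gln"]),
                                        log_sigma(BRAIN_CV["Gln"])))
  set("pl_Lac", "dm_Lac", lognormal_rho(links$plasma_brain_lac,
                                        log_sigma(PLASMA_CV["Lac"]),
                                        log_sigma(BRAIN_CV["Lac"])))
  set("pl_Gln", "ai_Gln", lognormal_rho(links$ai_plasma_gln,
                                        log_sigma(PLASMA_CV["Gln"]),
                                        log_sigma(BRAIN_CV["Gln"])))
  R
}

## Behavioural-parameter latent distribution (log-normal sensitivities).
## Means/CVs chosen for mixed choice behaviour on the 216-trial design;
## spread constants calibrated once by simulation (analysis script).
BEHAV_LATENT <- list(
  kR = c(mu = -0.71, sd = 0.25), kP = c(mu = -0.71, sd = 0.25),
  kEp = c(mu = -0.44, sd = 0.40), kEm = c(mu = -0.23, sd = 0.50),
  kFp = c(mu = -1.69, sd = 0.40), kLm = c(mu = -1.19, sd = 1.00))
BIAS_MEAN <- 0.35
BIAS_SD_CAL <- 0.34        # bias spread at the default hme_hpe link of 0.22
GLU_QUAD_CAL <- 0.40       # kEm-latent loading of the centered Glu^2 score
                           # at the default glu_quad_hme link of -0.36
GLU_LIN_CAL <- 0.0         # linear Glu loading beyond the skew leak of the
                           # quadratic path, at the default glu_lin_hme
                           # link of -0.19
ASP_KEM_CAL <- 1.12        # corrects the log-normal-rho mapping for the
                           # non-Gaussian (chi-square) share of the kEm latent
RHO_GLU_ASP <- 0.35        # copula correlation Glu-Asp (kept in sync with
                           # copula_correlation below)

## Per-region feature table (12 concentrations + 6 ratios) from the copula
## scores of that region.
region_features <- function(Z, prefix) {
  conc <- sapply(names(BRAIN_METS), function(met) {
    s <- log_sigma(BRAIN_CV[[met]])
    exp(log(BRAIN_METS[[met]]) - s^2 / 2 + s * Z[, paste0(prefix, met)])
  })
  conc <- as.data.frame(conc)
  out <- data.frame(Glu = conc$Glu, Gln = conc$Gln,
                    Glx = conc$Glu + conc$Gln,
                    conc[, c("NAA", "NAAG", "Asp", "Lac", "GSH", "GABA",
                             "PCrCr", "Tau", "mI")])
  for (met in RATIO_METS)
    out[[paste0(met, "_PCrCr")]] <- conc[[met]] / conc$PCrCr
  out
}

#' Generate a synthetic cohort
#'
#' Samples metabolite profiles (dmPFC/dACC, AI and plasma) from a Gaussian
#' copula with log-normal margins, derives the `Glx = Glu + Gln` composite
#' and the creatine ratios, draws behavioural parameters with the planted
#' metabolite links, and simulates one 216-trial session per subject through
#' the choice model.
#'
#' @param N Number of subjects (>= 10).
#' @param links A [link_spec()].
#' @param seed Master seed (cohort fully reproducible from it).
#' @param simulate_sessions If `FALSE`, skip the per-subject choice
#'   simulations (HME/HPE then unavailable); used for metabolite-only QC.
#' @return A `synthetic_cohort` list: `brain` and `ai` (18-feature data
#'   frames with `subject_id`), `plasma` (4 metabolites), `params` (true
#'   behavioural parameters), `hme`, `hpe`, `choices` (list of
#'   `choice_dataset`s), `links`, `seed`.
#' @export
generate_cohort <- function(N, links = link_spec(), seed = 1,
                            simulate_sessions = TRUE) {
  stopifnot(N >= 10)
  R <- copula_correlation(links)
  ch <- tryCatch(chol(R), error = function(e)
    stop("link correlation matrix is not positive definite"))
  Z <- with_seed(derive_seed(seed, 1), function()
    matrix(stats::rnorm(N * ncol(R)), N) %*% ch)
  colnames(Z) <- colnames(R)

  plasma <- sapply(names(PLASMA_METS), function(met) {
    s <- log_sigma(PLASMA_CV[[met]])
    exp(log(PLASMA_METS[[met]]) - s^2 / 2 + s * Z[, paste0("pl_", met)])
  })
  plasma <- data.frame(subject_id = seq_len(N), as.data.frame(plasma))
  brain <- data.frame(subject_id = seq_len(N), region_features(Z, "dm_"))
  ai <- data.frame(subject_id = seq_len(N), region_features(Z, "ai_"))

  ## behavioural latents with planted links
  eps <- with_seed(derive_seed(seed, 2), function()
    matrix(stats::rnorm(N * 7), N))
  zA <- Z[, "dm_Asp"]; zG <- Z[, "dm_Glu"]
  ## loading of the Asp copula score on the kEm latent: the Gaussian-scale
  ## correlation that yields the target Pearson r between the two log-normal
  ## observables (exact for the linear path, checked by QC for the rest)
  a <- if (links$asp_kem == 0) 0 else
    ASP_KEM_CAL * lognormal_rho(links$asp_kem, log_sigma(BRAIN_CV[["Asp"]]),
                                BEHAV_LATENT$kEm[["sd"]])
  cq <- GLU_QUAD_CAL * (-links$glu_quad_hme) / 0.36
  gl <- GLU_LIN_CAL * (-links$glu_lin_hme) / 0.19
  ## the linear Glu path leaks into corr(Asp, kEm) through the Glu-Asp
  ## copula correlation; shrink the direct Asp loading to compensate
  a_load <- max(0, a - gl * RHO_GLU_ASP)
  v_lin <- a_load^2 + gl^2 + 2 * a_load * gl * RHO_GLU_ASP
  resid <- sqrt(max(0, 1 - v_lin - cq^2))
  z_kEm <- a_load * zA + gl * zG + cq * (zG^2 - 1) / sqrt(2) +
    resid * eps[, 4]

  lat <- function(nm, z) BEHAV_LATENT[[nm]][["mu"]] +
    BEHAV_LATENT[[nm]][["sd"]] * z
  bias_sd <- BIAS_SD_CAL * links$hme_hpe / 0.22
  params <- data.frame(
    kR = exp(lat("kR", eps[, 1])), kP = exp(lat("kP", eps[, 2])),
    kEp = exp(lat("kEp", eps[, 3])), kEm = exp(lat("kEm", z_kEm)),
    kFp = exp(lat("kFp", eps[, 5])), kLm = exp(lat("kLm", eps[, 6])),
    bias = BIAS_MEAN + bias_sd * eps[, 7])

  hme <- hpe <- rep(NA_real_, N)
  choices <- NULL
  if (simulate_sessions) {
    choices <- vector("list", N)
    for (i in seq_len(N)) {
      p <- do.call(behavioral_parameters, as.list(params[i, ]))
      start <- if (i %% 2 == 0) "physical" else "mental"
      sched <- generate_session(derive_seed(seed, 100 + i), start)
      ds <- simulate_choices(p, sched, derive_seed(seed, 20000 + i),
                             subject_id = i)
      choices[[i]] <- ds
      hme[i] <- ds$summary$hme
      hpe[i] <- ds$summary$hpe
    }
  }
  structure(list(brain = brain, ai = ai, plasma = plasma, params = params,
                 hme = hme, hpe = hpe, choices = choices, links = links,
                 seed = as.integer(seed), N = N),
            class = "synthetic_cohort")
}

#' Build a feature table from a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param region `"dmPFC/dACC"` or `"AI"`.
#' @param target One of `"HME"`, `"HPE"` (high-effort choice proportions, in
#'   percent) or a behavioural parameter name (`"kEm"`, `"kR"`, ...).
#' @return A [feature_table()] with the 18 metabolite features and the
#'   requested target column.
#' @export
cohort_feature_table <- function(cohort, region = c("dmPFC/dACC", "AI"),
                                 target = "HME") {
  region <- match.arg(region)
  d <- if (region == "AI") cohort$ai else cohort$brain
  tgt <- switch(target,
                HME = 100 * cohort$hme,
                HPE = 100 * cohort$hpe,
                cohort$params[[target]])
  if (is.null(tgt) || anyNA(tgt))
    stop("target unavailable for this cohort: ", target)
  d[[target]] <- tgt
  feature_table(d, target, metabolite_features(), region)
}

fisher_z_dev <- function(r_hat, r_target, n)
  abs(atanh(r_hat) - atanh(r_target)) * sqrt(n - 3)

#' QC of a synthetic cohort against its planted links
#'
#' Recomputes every targeted association from the generated data and flags
#' deviations beyond `tol` Fisher-z standard errors, together with the
#' structural checks (exact `Glx = Glu + Gln`, ratio consistency, positivity).
#'
#' @param cohort A `synthetic_cohort` (with simulated sessions for the
#'   behavioural links).
#' @param links The [link_spec()] to check against (defaults to the cohort's
#'   own).
#' @param tol Allowed deviation in Fisher-z standard errors (default 3).
#' @return List with `associations` (data frame: link, target, estimate,
#'   z_dev, pass), `structure` (named logical checks) and `pass` (overall).
#' @export
emulation_check <- function(cohort, links = cohort$links, tol = 3) {
  b <- cohort$brain
  n <- cohort$N
  csq <- (b$Glu - mean(b$Glu))^2
  est <- c(
    asp_kem = stats::cor(b$Asp, cohort$params$kEm),
    asp_hme = if (!anyNA(cohort$hme)) stats::cor(b$Asp, cohort$hme) else NA,
    glu_quad_hme = if (!anyNA(cohort$hme)) stats::cor(csq, cohort$hme) else NA,
    glu_lin_hme = if (!anyNA(cohort$hme))
      stats::cor(b$Glu, cohort$hme) else NA,
    plasma_brain_gln = stats::cor(cohort$plasma$Gln, b$Gln),
    plasma_brain_lac = stats::cor(cohort$plasma$Lac, b$Lac),
    hme_hpe = if (!anyNA(cohort$hme))
      stats::cor(cohort$hme, cohort$hpe) else NA,
    ai_plasma_gln = stats::cor(cohort$plasma$Gln, cohort$ai$Gln))
  target <- unlist(links[names(est)])
  zd <- mapply(function(e, t) if (is.na(e)) NA else fisher_z_dev(e, t, n),
               est, target)
  assoc <- data.frame(link = names(est), target = target, estimate = est,
                      z_dev = zd,
                      pass = is.na(zd) | zd <= tol, row.names = NULL)
  structure_checks <- c(
    glx_sum = max(abs(b$Glx - (b$Glu + b$Gln))) < 1e-12,
    ratios = max(abs(b$Glu_PCrCr - b$Glu / b$PCrCr)) < 1e-12,
    positive = all(as.matrix(b[metabolite_features()]) > 0) &&
      all(as.matrix(cohort$plasma[names(PLASMA_METS)]) > 0))
  list(associations = assoc, structure = structure_checks,
       pass = all(assoc$pass) && all(structure_checks))
}

#' Write a cohort to CSV files
#'
#' Emits the CSV dialects consumed by the fitting and prediction modules:
#' `features_dmpfc.csv`, `features_ai.csv`, `plasma.csv`, `params.csv`,
#' `behavior.csv` (subject HME/HPE) and `choices.csv` (all trials, long).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$brain, file.path(dir, "features_dmpfc.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ai, file.path(dir, "features_ai.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$plasma, file.path(dir, "plasma.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(subject_id = seq_len(cohort$N), cohort$params),
                   file.path(dir, "params.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = seq_len(cohort$N),
                              hme = cohort$hme, hpe = cohort$hpe),
                   file.path(dir, "behavior.csv"), row.names = FALSE)
  if (!is.null(cohort$choices)) {
    long <- do.call(rbind, lapply(cohort$choices, function(ds)
      cbind(subject_id = ds$subject_id, as.data.frame(ds$schedule),
            choice = ds$records$choice)))
    utils::write.csv(long, file.path(dir, "choices.csv"), row.names = FALSE)
  }
  invisible(dir)
}
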