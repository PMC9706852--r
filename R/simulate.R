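#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate a mid-size European population cohort with methylation
#' typed on a blood draw: age 52.5 (SD 15.5) years, BMI 25.6 (SD 4.7) kg/m2,
#' about a quarter current smokers and a third past smokers, roughly 30%
#' non-drinkers with gamma-distributed weekly units among drinkers, ~20% CVD
#' prevalence and ~68% availability of epigenetic data.
#'
#' Exposure effects are applied additively on the M-value (logit) scale so
#' generated beta values stay strictly inside (0, 1) after the inverse logit.
#' Current smokers receive the full `effect_size_m` shift at tobacco-causal
#' CpGs and past smokers `past_effect_frac` of it; drinkers receive
#' `effect_size_m` at alcohol-causal CpGs plus `alcohol_dose_effect_m` per
#' weekly unit. A `mqtl_fraction` of pool CpGs carries a SNP whose dosage
#' shifts methylation by `mqtl_effect_m` per allele. CVD odds and
#' cause-specific mortality hazards depend on the standardized causal
#' methylation burden (see [generate_cohort()]).
#'
#' @param n_samples cohort size.
#' @param n_cpgs_pool number of CpGs in the candidate pool.
#' @param n_causal_tobacco,n_causal_alcohol causal CpGs per trait
#'   (disjoint subsets of the pool).
#' @param effect_size_m exposure shift at causal CpGs, M-value scale.
#' @param past_effect_frac fraction of the tobacco shift retained by
#'   past smokers.
#' @param alcohol_dose_effect_m additional M-value shift per weekly alcohol
#'   unit at alcohol-causal CpGs.
#' @param mqtl_fraction fraction of pool CpGs with a methylation-QTL SNP.
#' @param mqtl_effect_m per-allele M-value shift at mQTL CpGs.
#' @param noise_sd_m residual SD on the M-value scale.
#' @param missing_rate completely-at-random probe missingness in \[0, 1).
#' @param smoking_prevalence,past_smoking_prevalence current / past smoker
#'   fractions (remainder never-smokers).
#' @param alcohol_zero_prob probability of consuming < 1 unit/week.
#' @param alcohol_units_shape,alcohol_units_scale gamma parameters for weekly
#'   units among drinkers.
#' @param cvd_baseline_logodds,cvd_exposure_logor CVD model: intercept and
#'   log-odds-ratio per 1 SD of tobacco methylation burden.
#' @param hazard_rates named baseline yearly hazards for causes
#'   `lung_cancer`, `cvd`, `other`.
#' @param hazard_loghr_signature log hazard ratio per 1 SD of tobacco burden
#'   on the lung-cancer cause (other causes null unless `hazard_loghr` given).
#' @param hazard_loghr optional named log-HR vector per cause, overriding the
#'   default `c(lung_cancer = hazard_loghr_signature, cvd = 0, other = 0)`.
#' @param follow_up_years administrative censoring horizon.
#' @param censoring_rate yearly rate of random loss to follow-up.
#' @param selection_logodds named coefficients of the availability model on
#'   `intercept`, `age` (per 10 years, centred), `sex` (male = 1) and
#'   `smoking` (current smoker indicator); an optional `cvd` coefficient
#'   (CVD-history indicator) makes availability outcome-dependent, the
#'   regime where unweighted analyses of the available subset are biased.
#' @param age_mean,age_sd,bmi_mean,bmi_sd covariate distributions.
#' @param age_smoking_logodds optional confounding: log-odds of current
#'   smoking per 10 years of age (default 0, off).
#' @param n_centers number of recruitment centres.
#' @param seed integer seed controlling every random draw.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 500, n_cpgs_pool = 100,
                       n_causal_tobacco = 5, n_causal_alcohol = 3,
                       effect_size_m = 1.5, past_effect_frac = 0.5,
                       alcohol_dose_effect_m = 0.03,
                       mqtl_fraction = 0.1, mqtl_effect_m = 0.5,
                       noise_sd_m = 1, missing_rate = 0,
                       smoking_prevalence = 0.25,
                       past_smoking_prevalence = 0.33,
                       alcohol_zero_prob = 0.3,
                       alcohol_units_shape = 1.2, alcohol_units_scale = 7.5,
                       cvd_baseline_logodds = -1.4,
                       cvd_exposure_logor = log(1.3),
                       hazard_rates = c(lung_cancer = 0.004, cvd = 0.010,
                                        other = 0.018),
                       hazard_loghr_signature = log(2),
                       hazard_loghr = NULL,
                       follow_up_years = 15, censoring_rate = 0.02,
                       selection_logodds = c(intercept = 0.75, age = 0,
                                             sex = 0, smoking = 0),
                       age_mean = 52.5, age_sd = 15.5,
                       bmi_mean = 25.6, bmi_sd = 4.7,
                       age_smoking_logodds = 0,
                       n_centers = 3, seed = 1L) {
  cfg <- as.list(environment())
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop(sprintf("invalid '%s': %s", field, msg),
                          call. = FALSE)
  chk(n_samples >= 2, "n_samples", "need at least 2 samples")
  chk(n_cpgs_pool >= 1, "n_cpgs_pool", "must be positive")
  chk(n_causal_tobacco + n_causal_alcohol <= n_cpgs_pool,
      "n_causal_tobacco", "causal CpGs exceed the pool size")
  chk(mqtl_fraction >= 0 && mqtl_fraction <= 1, "mqtl_fraction",
      "must lie in [0, 1]")
  chk(noise_sd_m > 0, "noise_sd_m", "must be strictly positive")
  chk(missing_rate >= 0 && missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(smoking_prevalence > 0 && smoking_prevalence < 1,
      "smoking_prevalence", "must lie in (0, 1)")
  chk(smoking_prevalence + past_smoking_prevalence < 1,
      "past_smoking_prevalence", "smoking fractions exceed 1")
  chk(alcohol_zero_prob >= 0 && alcohol_zero_prob < 1, "alcohol_zero_prob",
      "must lie in [0, 1)")
  chk(alcohol_units_shape > 0 && alcohol_units_scale > 0,
      "alcohol_units_shape", "gamma parameters must be positive")
  chk(all(hazard_rates > 0), "hazard_rates", "baseline rates must be positive")
  chk(all(c("lung_cancer", "cvd", "other") %in% names(hazard_rates)),
      "hazard_rates", "must name causes lung_cancer, cvd, other")
  chk(follow_up_years > 0, "follow_up_years", "must be positive")
  chk(censoring_rate >= 0, "censoring_rate", "must be non-negative")
  chk(all(c("intercept", "age", "sex", "smoking") %in%
            names(selection_logodds)),
      "selection_logodds", "must name intercept, age, sex, smoking")
  chk(age_sd > 0 && bmi_sd > 0, "age_sd", "covariate SDs must be positive")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "must be a single integer")
  if (is.null(hazard_loghr)) {
    cfg$hazard_loghr <- c(lung_cancer = hazard_loghr_signature,
                          cvd = 0, other = 0)
  } else {
    chk(all(names(hazard_rates) %in% names(hazard_loghr)), "hazard_loghr",
        "must cover every cause in hazard_rates")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic cohort with methylation, genotypes and outcomes
#'
#' Draws, deterministically for a given seed, a full study data set:
#'
#' * a phenotype table (`cohort`): age, sex, BMI, education, centre and
#'   family identifiers, smoking status (never / past / current), weekly
#'   alcohol units, CVD history, survival time with cause of death, and an
#'   availability indicator for epigenetic data;
#' * a beta-scale methylation matrix (`methylation`) built on the M-value
#'   scale as CpG baseline + exposure effects + mQTL dosage effects +
#'   Gaussian noise, then inverse-logit transformed;
#' * a SNP dosage matrix (`genotypes`, 0/1/2);
#' * a `ground_truth` list recording causal CpG identities and effects, the
#'   mQTL map, the per-sample standardized causal methylation burdens, and
#'   the true disease log-OR and cause-specific log-HRs, for recovery tests.
#'
#' Disease and death depend on the *tobacco methylation burden*: the mean
#' noiseless M-value shift at tobacco-causal CpGs, z-scored across the
#' cohort. CVD odds follow a logistic model in that burden; each cause of
#' death has an exponential hazard `rate * exp(loghr * burden)`, the earliest
#' latent time wins, and follow-up is censored by random drop-out and an
#' administrative horizon.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort`, `methylation`, `genotypes`,
#'   `ground_truth`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be built with sim_config()")
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  # --- covariates ---------------------------------------------------------
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  age <- pmin(pmax(age, 18), 95)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  bmi <- pmax(stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 15)
  education <- pmin(pmax(round(stats::rnorm(n, 13, 3)), 6), 22)
  center <- sample(sprintf("C%d", seq_len(cfg$n_centers)), n, replace = TRUE)
  family_id <- sprintf("F%04d", cumsum(stats::runif(n) < 0.6))

  # --- exposures ----------------------------------------------------------
  # optional age -> smoking confounding on the log-odds scale
  base_lo <- stats::qlogis(cfg$smoking_prevalence)
  lo_cur <- base_lo + cfg$age_smoking_logodds * (age - cfg$age_mean) / 10
  p_cur <- stats::plogis(lo_cur)
  u <- stats::runif(n)
  smoking_status <- ifelse(u < p_cur, "current smoker",
                           ifelse(u < p_cur + cfg$past_smoking_prevalence,
                                  "past smoker", "non-smoker"))
  is_drinker <- stats::runif(n) >= cfg$alcohol_zero_prob
  units <- ifelse(is_drinker,
                  1 + stats::rgamma(n, shape = cfg$alcohol_units_shape,
                                    scale = cfg$alcohol_units_scale),
                  stats::runif(n, 0, 0.99))

  # --- CpG pool, causal sets, mQTLs --------------------------------------
  cpg_ids <- sprintf("cg%08d", sample.int(99999999, cfg$n_cpgs_pool))
  causal_tob <- cpg_ids[seq_len(cfg$n_causal_tobacco)]
  causal_alc <- cpg_ids[cfg$n_causal_tobacco + seq_len(cfg$n_causal_alcohol)]
  n_mqtl <- round(cfg$mqtl_fraction * cfg$n_cpgs_pool)
  mqtl_cpgs <- if (n_mqtl > 0) sample(cpg_ids, n_mqtl) else character(0)
  snp_ids <- if (n_mqtl > 0) sprintf("rs%07d", sample.int(9999999, n_mqtl))
             else character(0)
  maf <- stats::runif(max(n_mqtl, 1), 0.1, 0.5)[seq_len(n_mqtl)]
  genotypes <- matrix(0L, nrow = n_mqtl, ncol = n,
                      dimnames = list(snp_ids, ids))
  for (s in seq_len(n_mqtl))
    genotypes[s, ] <- stats::rbinom(n, 2, maf[s])

  # --- methylation on the M-value scale ----------------------------------
  baseline <- stats::rnorm(cfg$n_cpgs_pool, 0, 2)
  smoke_expo <- ifelse(smoking_status == "current smoker", 1,
                       ifelse(smoking_status == "past smoker",
                              cfg$past_effect_frac, 0))
  alc_expo <- as.numeric(units >= 1)
  signal <- matrix(0, nrow = cfg$n_cpgs_pool, ncol = n,
                   dimnames = list(cpg_ids, ids))
  signal[causal_tob, ] <- rep(cfg$effect_size_m * smoke_expo,
                              each = length(causal_tob))
  signal[causal_alc, ] <- rep(cfg$effect_size_m * alc_expo +
                                cfg$alcohol_dose_effect_m * units,
                              each = length(causal_alc))
  if (n_mqtl > 0)
    signal[mqtl_cpgs, ] <- signal[mqtl_cpgs, , drop = FALSE] +
      cfg$mqtl_effect_m * genotypes
  mvals <- baseline + signal +
    matrix(stats::rnorm(cfg$n_cpgs_pool * n, 0, cfg$noise_sd_m),
           nrow = cfg$n_cpgs_pool)
  beta <- stats::plogis(mvals)
  methylation <- meth_matrix(beta, scale = "beta", dialect = "EPIC")

  # --- causal methylation burdens (noiseless, standardized) --------------
  std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                     else x * 0
  tob_burden <- std(colMeans(signal[causal_tob, , drop = FALSE]))
  alc_burden <- std(colMeans(signal[causal_alc, , drop = FALSE]))

  # --- CVD history --------------------------------------------------------
  p_cvd <- stats::plogis(cfg$cvd_baseline_logodds +
                           cfg$cvd_exposure_logor * tob_burden)
  cvd_history <- ifelse(stats::runif(n) < p_cvd, "yes", "no")

  # --- survival: competing exponential cause-specific hazards -------------
  causes <- names(cfg$hazard_rates)
  latent <- sapply(causes, function(cs) {
    rate <- cfg$hazard_rates[[cs]] * exp(cfg$hazard_loghr[[cs]] * tob_burden)
    stats::rexp(n, rate)
  })
  death_time <- apply(latent, 1, min)
  death_cause <- causes[apply(latent, 1, which.min)]
  cens <- if (cfg$censoring_rate > 0) stats::rexp(n, cfg$censoring_rate)
          else rep(Inf, n)
  cens <- pmin(cens, cfg$follow_up_years)
  status <- as.integer(death_time <= cens)
  time <- pmax(pmin(death_time, cens), 1e-4)
  cause <- ifelse(status == 1, death_cause, NA_character_)

  # --- availability of epigenetic data ------------------------------------
  sl <- cfg$selection_logodds
  lo_av <- sl[["intercept"]] + sl[["age"]] * (age - cfg$age_mean) / 10 +
    sl[["sex"]] * (sex == "male") +
    sl[["smoking"]] * (smoking_status == "current smoker")
  if ("cvd" %in% names(sl))
    lo_av <- lo_av + sl[["cvd"]] * (cvd_history == "yes")
  available <- ifelse(stats::runif(n) < stats::plogis(lo_av), "yes", "no")

  cohort <- data.frame(
    id = ids, age = age, sex = sex, bmi = bmi, education = education,
    center = center, family_id = family_id,
    smoking_status = smoking_status,
    alcohol_units_week = units,
    alcohol_status = categorize_alcohol(units, sex),
    cvd_history = cvd_history,
    time_years = time, status = status, cause = cause,
    available = available,
    stringsAsFactors = FALSE)

  ground_truth <- list(
    causal_cpgs = list(smoking = causal_tob, alcohol = causal_alc),
    effect_size_m = cfg$effect_size_m,
    mqtl_map = data.frame(cpg_id = mqtl_cpgs, snp_id = snp_ids,
                          effect = rep(cfg$mqtl_effect_m, n_mqtl),
                          maf = maf, stringsAsFactors = FALSE),
    tobacco_burden = stats::setNames(tob_burden, ids),
    alcohol_burden = stats::setNames(alc_burden, ids),
    cvd_logor_per_sd = cfg$cvd_exposure_logor,
    hazard_loghr = cfg$hazard_loghr)

  out <- list(cohort = cohort, methylation = methylation,
              genotypes = genotypes, ground_truth = ground_truth,
              config = cfg)
  if (cfg$missing_rate > 0)
    out$methylation <- inject_missingness(out$methylation, cfg$missing_rate,
                                          seed = cfg$seed + 1L)
  out
}

#' Set matrix entries missing completely at random
#'
#' Each entry is independently set to `NA` with probability `rate`; observed
#' entries are unchanged. Used to emulate probe drop-out ahead of imputation.
#'
#' @param m a [meth_matrix()].
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed for the mask.
#' @export
inject_missingness <- function(m, rate, seed = 1L) {
  stopifnot(inherits(m, "meth_matrix"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("'rate' must lie in [0, 1)")
  if (rate == 0) return(m)
  set.seed(seed)
  mask <- matrix(stats::runif(length(m)) < rate, nrow = nrow(m))
  vals <- unclass(m)
  vals[mask] <- NA_real_
  set_meth_attrs(structure(vals, class = class(m)))
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `cohort.csv`, `methylation.csv`, `genotypes.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param sim result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             methylation = file.path(dir, "methylation.csv"),
             genotypes = file.path(dir, "genotypes.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  utils::write.csv(sim$cohort, paths["cohort"], row.names = FALSE)
  write_meth_matrix(sim$methylation, paths["methylation"])
  gt <- sim$genotypes
  utils::write.csv(data.frame(snp_id = rownames(gt), gt,
                              check.names = FALSE),
                   paths["genotypes"], row.names = FALSE)
  jsonlite::write_json(sim$ground_truth, paths["ground_truth"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
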