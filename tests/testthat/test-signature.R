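test_that("alcohol categories follow the sex-specific unit thresholds", {
  expect_identical(categorize_alcohol(25, "male"), "heavy")
  expect_identical(categorize_alcohol(21, "male"), "moderate")
  expect_identical(categorize_alcohol(21.5, "male"), "heavy")
  expect_identical(categorize_alcohol(14, "female"), "moderate")
  expect_identical(categorize_alcohol(14.5, "female"), "heavy")
  expect_identical(categorize_alcohol(0.9, "male"), "non-drinker")
  expect_identical(categorize_alcohol(0.9, "female"), "non-drinker")
  expect_identical(categorize_alcohol(1, "female"), "moderate")
  expect_error(categorize_alcohol(-1, "male"), "negative")
  expect_identical(categorize_alcohol(c(2, 30), c("male", "male")),
                   c("moderate", "heavy"))
})

test_that("outcome coding contrasts the right groups", {
  co <- data.frame(id = c("a", "b", "c", "d"),
                   smoking_status = c("current smoker", "non-smoker",
                                      "past smoker", "non-smoker"),
                   alcohol_units_week = c(0.5, 3, 1, 0))
  sm <- code_outcome(co, "smoking")
  expect_identical(sm$ids, c("a", "b", "d"))      # past smoker excluded
  expect_identical(unname(sm$labels), c(1L, 0L, 0L))
  al <- code_outcome(co, "alcohol")
  expect_identical(unname(al$labels), c(0L, 1L, 1L, 0L))

  all_never <- data.frame(id = "x", smoking_status = "non-smoker",
                          alcohol_units_week = 2)
  expect_error(code_outcome(all_never, "smoking"), "single class")
})

test_that("random spec enumeration is deterministic and well-formed", {
  pool <- sprintf("cg%08d", 1:20)
  mqtl <- structure(data.frame(cpg_id = pool[1:3],
                               snp_id = c("rs3", "rs1", "rs2"),
                               effect = 1, p_value = 1e-8),
                    class = c("mqtl_map", "data.frame"))
  a <- enumerate_random_specs(pool, mqtl, 50, seed = 9)
  b <- enumerate_random_specs(pool, mqtl, 50, seed = 9)
  expect_identical(a, b)
  keys <- vapply(a, function(s) paste(s$cpg_ids, collapse = "|"), "")
  expect_false(anyDuplicated(keys) > 0)
  for (s in a) {
    expect_length(s$cpg_ids, 7)
    expect_true(all(s$cpg_ids %in% pool))
    # each included CpG with a partner contributes its SNP
    expected <- sort(mqtl$snp_id[mqtl$cpg_id %in% s$cpg_ids])
    expect_identical(s$snp_ids, expected)
  }
})

test_that("a pool of exactly seven CpGs admits a single spec", {
  pool <- sprintf("cg%08d", 1:7)
  specs <- enumerate_random_specs(pool, NULL, 10, seed = 1)
  expect_identical(length(specs), 1L)
  expect_identical(specs[[1]]$cpg_ids, sort(pool))
  expect_error(enumerate_random_specs(pool[1:5], NULL, 10), "at least 7")
})

test_that("every pool CpG is covered by some spec at search scale", {
  pool <- sprintf("cg%08d", 1:60)
  specs <- enumerate_random_specs(pool, NULL, 2000, seed = 2)
  seen <- unique(unlist(lapply(specs, `[[`, "cpg_ids")))
  expect_setequal(seen, pool)
})

test_that("a saturated 2x2 logistic fit returns the table log-odds-ratio", {
  # exposed: 8 cases / 2 controls; unexposed: 2 cases / 8 controls
  x <- c(rep(1, 10), rep(0, 10))
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  ids <- sprintf("S%03d", 1:20)
  m <- meth_matrix(matrix(x, 1, dimnames = list("cg00000001", ids)),
                   scale = "mvalue")
  fit <- fit_logistic(list(cpg_ids = "cg00000001", snp_ids = character(0)),
                      m, NULL, stats::setNames(y, ids), min_events = 2)
  expect_equal(unname(fit$coefficients["cg00000001"]), log(16),
               tolerance = 1e-6)
  expect_true(fit$converged)
  # nested-model likelihood ordering
  ll0 <- sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y))
  expect_gte(fit$loglik, ll0)
  expect_equal(fit$bic, bic(fit$loglik, 2, 20))
})

test_that("fitted coefficients match an independent Newton oracle", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 50
    X <- matrix(stats::rnorm(n * 3), n,
                dimnames = list(NULL, c("cg00000001", "cg00000002",
                                        "cg00000003")))
    y <- stats::rbinom(n, 1, stats::plogis(0.3 + X %*% c(0.8, -0.5, 0)))
    ids <- sprintf("S%03d", 1:n)
    tx <- t(X)
    colnames(tx) <- ids
    m <- meth_matrix(tx, scale = "mvalue")
    fit <- fit_logistic(list(cpg_ids = colnames(X), snp_ids = character(0)),
                        m, NULL, stats::setNames(y, ids), min_events = 5)
    oracle <- oracle_logistic_newton(X, y)
    expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
                 tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("separated and collinear fits are flagged, not raised", {
  ids <- sprintf("S%03d", 1:40)
  x <- c(rep(0, 20), rep(1, 20))
  y <- stats::setNames(x, ids)               # perfect separation
  m <- meth_matrix(matrix(x, 1, dimnames = list("cg00000001", ids)),
                   scale = "mvalue")
  fit <- suppressWarnings(
    fit_logistic(list(cpg_ids = "cg00000001", snp_ids = character(0)),
                 m, NULL, y, min_events = 2))
  expect_false(fit$converged)
  expect_true(fit$separated)

  set.seed(11)
  x1 <- stats::rnorm(40)
  mm <- rbind(cg00000001 = x1, cg00000002 = 2 * x1)   # exact collinearity
  colnames(mm) <- ids
  y2 <- stats::setNames(stats::rbinom(40, 1, stats::plogis(x1)), ids)
  expect_warning(
    fit2 <- fit_logistic(list(cpg_ids = rownames(mm),
                              snp_ids = character(0)),
                         meth_matrix(mm, scale = "mvalue"), NULL, y2,
                         min_events = 2),
    "collinear")
  expect_identical(fit2$dropped, "cg00000002")
})

test_that("BIC follows its defining formula", {
  expect_identical(bic(0, 0, 10), 0)
  expect_equal(bic(-10, 3, 100), 3 * log(100) + 20, tolerance = 1e-12)
  expect_error(bic(-1, 1, 0), "positive")
})

test_that("adding a pure-noise predictor typically increases BIC", {
  set.seed(12)
  deltas <- numeric(100)
  for (s in 1:100) {
    n <- 400
    x <- stats::rnorm(n)
    noise <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(x))
    f1 <- oracle_logistic_newton(cbind(x), y)
    f2 <- oracle_logistic_newton(cbind(x, noise), y)
    deltas[s] <- bic(f2$loglik, 3, n) - bic(f1$loglik, 2, n)
  }
  expect_gt(stats::median(deltas), 0)
})

test_that("selection takes the minimal-BIC fit and pruning drops noise", {
  set.seed(13)
  n <- 500
  ids <- sprintf("S%04d", 1:n)
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rnorm(n)
  y <- stats::setNames(stats::rbinom(n, 1, stats::plogis(1.5 * x1)), ids)
  mm <- rbind(cg00000001 = x1, cg00000002 = x2, cg00000003 = x3)
  colnames(mm) <- ids
  m <- meth_matrix(mm, scale = "mvalue")
  specs <- list(list(cpg_ids = c("cg00000001", "cg00000002"),
                     snp_ids = character(0)),
                list(cpg_ids = c("cg00000002", "cg00000003"),
                     snp_ids = character(0)))
  fits <- lapply(specs, fit_logistic, m = m, genotypes = NULL, labels = y)
  model <- select_and_prune(fits, m, NULL, y, trait = "smoking")
  # the signal-bearing spec wins on BIC...
  expect_lte(min(fits[[1]]$bic, fits[[2]]$bic), fits[[2]]$bic)
  # ...and the noise CpG is pruned away
  expect_identical(model$cpgs$id, "cg00000001")
  expect_identical(nrow(model$snps), 0L)
  expect_gt(model$sigma, 0)

  # a single all-significant fit is returned unchanged
  one <- fit_logistic(list(cpg_ids = "cg00000001", snp_ids = character(0)),
                      m, NULL, y)
  m1 <- select_and_prune(list(one), m, NULL, y)
  expect_identical(m1$cpgs$id, "cg00000001")
  expect_equal(m1$cpgs$coef, unname(one$coefficients["cg00000001"]))
})

test_that("the selected model minimizes BIC over converged candidates", {
  sim <- generate_cohort(sim_config(n_samples = 400, n_cpgs_pool = 15,
                                    seed = 21))
  mv <- beta_to_mvalue(sim$methylation)
  oc <- code_outcome(sim$cohort, "smoking")
  specs <- enumerate_random_specs(rownames(mv), NULL, 40, seed = 5)
  fits <- lapply(specs, function(sp)
    suppressWarnings(fit_logistic(sp, mv, NULL, oc$labels)))
  model <- select_and_prune(fits, mv, NULL, oc$labels)
  conv_bics <- vapply(Filter(function(f) f$converged, fits), `[[`,
                      numeric(1), "bic")
  expect_equal(model$selection_bic, min(conv_bics))
})

test_that("scoring is linear, standardized and demands its probes", {
  set.seed(14)
  sim <- generate_cohort(sim_config(n_samples = 300, n_cpgs_pool = 12,
                                    seed = 22))
  mv <- beta_to_mvalue(sim$methylation)
  model <- suppressWarnings(
    build_signature(mv, NULL, sim$cohort, "smoking",
                    pool_cpgs = rownames(mv), n_models = 100, seed = 6))
  oc <- code_outcome(sim$cohort, "smoking")
  sc <- score_samples(model, mv[, oc$ids])
  # standardization identity on the training set
  expect_lt(abs(mean(sc$standardized)), 1e-10)
  expect_lt(abs(stats::sd(sc$standardized) - 1), 1e-10)

  # two samples differing at one CpG by dM differ by b_j * dM exactly
  cg <- model$cpgs$id[1]
  m2 <- unclass(mv)[, 1:2]
  m2[, 2] <- m2[, 1]
  m2[cg, 2] <- m2[cg, 1] + 0.37
  m2 <- meth_matrix(m2, scale = "mvalue")
  s2 <- score_samples(model, m2)
  expect_equal(s2$raw[2] - s2$raw[1], model$cpgs$coef[1] * 0.37,
               tolerance = 1e-12)

  expect_error(score_samples(model, mv[setdiff(rownames(mv), cg), ]),
               cg)
})

test_that("a noise-free single-cause signature ranks samples like its CpG", {
  set.seed(15)
  n <- 200
  ids <- sprintf("S%04d", 1:n)
  x <- stats::rnorm(n)
  y <- stats::setNames(as.integer(x + stats::rnorm(n) > 0), ids)
  mm <- rbind(cg00000001 = x,
              cg00000002 = stats::rnorm(n),
              cg00000003 = stats::rnorm(n))
  colnames(mm) <- ids
  m <- meth_matrix(mm, scale = "mvalue")
  model <- suppressWarnings(
    build_signature(m, NULL,
                    data.frame(id = ids,
                               smoking_status = ifelse(y == 1,
                                                       "current smoker",
                                                       "non-smoker"),
                               alcohol_units_week = 0),
                    "smoking", pool_cpgs = rownames(m), n_models = 10,
                    max_cpgs = 3, seed = 7))
  sc <- score_samples(model, m)
  rho <- stats::cor(sc$raw, x, method = "spearman")
  expect_equal(abs(rho), 1, tolerance = 0.02)
})

test_that("signature models survive a JSON round trip and scoring", {
  sim <- generate_cohort(sim_config(n_samples = 300, n_cpgs_pool = 12,
                                    seed = 23))
  mv <- beta_to_mvalue(sim$methylation)
  model <- suppressWarnings(
    build_signature(mv, NULL, sim$cohort, "smoking",
                    pool_cpgs = rownames(mv), n_models = 100, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(model, path)
  model2 <- read_signature(path)
  expect_equal(model2$cpgs, model$cpgs, tolerance = 1e-12)
  expect_equal(model2$mu, model$mu, tolerance = 1e-12)
  s1 <- score_samples(model, mv)
  s2 <- score_samples(model2, mv)
  expect_equal(s1$standardized, s2$standardized, tolerance = 1e-12)
})

test_that("the bundled placeholder signatures load and score a cohort", {
  path <- system.file("extdata", "epitob_placeholder_signature.json",
                      package = "episig")
  model <- read_signature(path)
  expect_identical(nrow(model$cpgs), 5L)
  set.seed(16)
  vals <- matrix(stats::runif(5 * 4, 0.1, 0.9), 5,
                 dimnames = list(model$cpgs$id, sprintf("S%03d", 1:4)))
  sc <- score_samples(model, beta_to_mvalue(meth_matrix(vals)))
  expect_identical(nrow(sc), 4L)
  expect_true(all(is.finite(sc$standardized)))
})
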