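# Table-2-style generating scenario used throughout: causal RR 2 on disease,
# exposure tilt 1.5, baseline risk 0.05, unexposed stratum = untilted joint.
t2_config <- function(n, seed, convention = "baseline_unexposed",
                      exposure_prev = 0.3) {
  sim_config(n, table1_joint(),
             causal_glm("log", log(0.05), betaD = log(2)),
             theta = 1.5, exposure_prev = exposure_prev,
             convention = convention, seed = seed)
}

test_that("identical config and seed give identical tables", {
  a <- simulate_cohort(t2_config(5000, seed = 31))
  b <- simulate_cohort(t2_config(5000, seed = 31))
  expect_identical(as.data.frame(a), as.data.frame(b))
  cc1 <- simulate_case_control(t2_config(1, seed = 8), 500, 500)
  cc2 <- simulate_case_control(t2_config(1, seed = 8), 500, 500)
  expect_identical(as.data.frame(cc1), as.data.frame(cc2))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_cohort(t2_config(5000, 32)))))
})

test_that("sampled marginals match the scenario", {
  n <- 2e5
  dat <- simulate_cohort(t2_config(n, seed = 101, convention = "marginal"))
  # marker allele frequency ~ 0.1
  se_maf <- sqrt(0.1 * 0.9 / (2 * n))
  expect_lt(abs(mean(dat$marker_dosage) / 2 - 0.1), 3 * se_maf)
  # exposure prevalence ~ 0.3
  expect_lt(abs(mean(dat$exposure) - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("theta = 1 leaves genotype and exposure uncorrelated", {
  cfg <- sim_config(1e5, table1_joint(),
                    causal_glm("log", log(0.05), betaD = log(2)),
                    theta = 1, exposure_prev = 0.3, seed = 5)
  dat <- simulate_cohort(cfg)
  expect_lt(abs(cor(dat$causal_dosage, dat$exposure)), 3 / sqrt(nrow(dat)))
})

test_that("fit on exact expected cells equals the analytic eta grid", {
  set.seed(37)
  for (i in 1:25) {
    rj <- random_joint()
    th <- exp(runif(1, log(0.5), log(2)))
    model <- causal_glm("log", log(runif(1, 0.02, 0.2)),
                        betaD = runif(1, -0.6, 0.6),
                        betaX = runif(1, -0.4, 0.4),
                        betaDX = runif(1, -0.3, 0.3))
    jdmx <- build_joint_dmx(rj$joint, th)
    grid <- marker_eta_grid(model, jdmx)
    # allele-level expected cells: weight = Pr(m, x), response = E[Y|m, x]
    cells <- expand.grid(marker_dosage = 0:1, exposure = 0:1)
    w <- y <- numeric(4)
    a <- unclass(jdmx)
    for (k in seq_len(4)) {
      m <- cells$marker_dosage[k]; x <- cells$exposure[k]
      w[k] <- sum(a[, m + 1, x + 1])
      y[k] <- exp(grid$eta[m + 1, x + 1])
    }
    fit <- fit_interaction_glm(cbind(cells, outcome = y), link = "log",
                               weights = w)
    expect_equal(unname(fit$coefficients),
                 c(grid$beta0, grid$beta_M, grid$beta_X, grid$beta_MX),
                 tolerance = 1e-8)
  }
})

test_that("the simulated cohort reproduces the stratified marker risk ratios", {
  dat <- simulate_cohort(t2_config(3e5, seed = 55))
  fit <- fit_interaction_glm(dat, link = "log", coding = "allele_dosage")
  expect_true(fit$converged)
  # unexposed-stratum per-allele marker RR 1.5, exposed 1.6
  expect_lt(abs(fit$coefficients["marker"] - log(1.5)),
            3 * fit$se["marker"])
  bmx <- fit$coefficients["marker:exposure"]
  expect_lt(abs(bmx - log(1.6 / 1.5)), 3 * fit$se["marker:exposure"])
})

test_that("IRLS agrees with a reference logistic fit", {
  dat <- simulate_cohort(t2_config(3e4, seed = 77))
  ours <- fit_interaction_glm(dat, link = "logit")
  ref <- stats::glm(outcome ~ marker_dosage * exposure,
                    family = stats::binomial(), data = dat)
  expect_equal(unname(ours$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-7)
  # glm's vcov uses the weights of its penultimate IRLS step, ours is
  # recomputed at the final coefficients, so agreement is a shade looser
  expect_equal(unname(ours$se),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
})

test_that("model-based standard errors match the replicate spread", {
  true_bmx <- log(1.6 / 1.5)
  B <- 200
  cover <- 0
  for (b in seq_len(B)) {
    dat <- simulate_cohort(t2_config(4000, seed = 1000 + b))
    fit <- suppressWarnings(fit_interaction_glm(dat, link = "log"))
    ci <- fit$coefficients["marker:exposure"] +
      c(-1.96, 1.96) * fit$se["marker:exposure"]
    if (ci[1] <= true_bmx && true_bmx <= ci[2]) cover <- cover + 1
  }
  # binomial error band around nominal 95% over 200 replicates
  expect_gte(cover / B, 0.90)
  expect_lte(cover / B, 0.99)
})

test_that("case-control sampling hits the requested counts and null OR", {
  cfg <- sim_config(1, table1_joint(),
                    causal_glm("log", log(0.05)),  # no genetic effect
                    theta = 1, exposure_prev = 0.3, seed = 13)
  cc <- simulate_case_control(cfg, 3000, 3000)
  expect_equal(sum(cc$outcome), 3000)
  expect_equal(sum(1 - cc$outcome), 3000)
  fit <- fit_interaction_glm(cc, link = "logit")
  expect_lt(abs(fit$coefficients["marker"]), 3 * fit$se["marker"])
  expect_lt(abs(fit$coefficients["marker:exposure"]),
            3 * fit$se["marker:exposure"])
})

test_that("case-control interaction odds ratio matches the forward tables", {
  cc <- simulate_case_control(t2_config(1, seed = 21), 20000, 20000)
  fit <- fit_interaction_glm(cc, link = "logit")
  bmx <- fit$coefficients["marker:exposure"]
  expect_lt(abs(bmx - log(1.6 / 1.5)), 3 * fit$se["marker:exposure"])
})

test_that("infeasible configurations fail before any sampling", {
  expect_error(sim_config(100, table1_joint(),
                          causal_glm("log", log(0.3), betaD = log(1.9)),
                          theta = 1.5),
               "rescale beta0|out of range")
  expect_error(sim_config(100, table1_joint(),
                          causal_glm("log", log(0.05)),
                          theta = 4, exposure_prev = 0.6,
                          convention = "marginal"),
               "infeasible")
  cfg <- sim_config(1, table1_joint(),
                    causal_glm("log", log(1e-5), betaD = log(2)),
                    theta = 1.5, exposure_prev = 0.3, seed = 3)
  expect_error(simulate_case_control(cfg, 5000, 100, max_batches = 2L),
               "budget")
})

test_that("separation is flagged, not silently returned", {
  dat <- data.frame(marker_dosage = c(0, 0, 1, 1, 2, 2),
                    exposure = c(0, 1, 0, 1, 0, 1),
                    outcome = c(0, 1, 0, 1, 0, 1))
  expect_warning(fit_interaction_glm(dat, link = "logit"),
                 "separation|converge")
})

test_that("subject tables round-trip through TSV with a config comment", {
  dat <- simulate_cohort(t2_config(200, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subject_table(dat, path)
  expect_match(readLines(path, n = 1), "^# markerGxE .*seed=2")
  back <- read_subject_table(path)
  expect_equal(back, as.data.frame(dat), ignore_attr = TRUE)
})
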