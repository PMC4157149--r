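test_that("link functions invert each other", {
  for (nm in c("identity", "log", "logit")) {
    l <- link_function(nm)
    x <- seq(-3, if (nm == "identity") 3 else -0.1, length.out = 20)
    expect_equal(l$linkfun(l$linkinv(x)), x, tolerance = 1e-12)
  }
  expect_error(link_function("probit"), "arg")
})

test_that("causal GLM rejects out-of-range means", {
  expect_error(causal_glm("log", beta0 = log(0.6), betaD = log(2)),
               "out of range")
  expect_silent(causal_glm("log", beta0 = log(0.1), betaD = log(2)))
  expect_error(causal_glm("identity", beta0 = NA), "finite")
})

test_that("exposed-stratum conditionals match the tilted table", {
  jdmx <- build_joint_dmx(table1_joint(), theta = 1.5)
  pd <- markerGxE:::pr_d_given_mx(jdmx)
  # tilted M=1 class: masses 0.05 and 0.05*1.5, so Pr(D=1|M=1,X=1) = 0.6
  expect_equal(pd["1", "1"], 0.075 / 0.125, tolerance = 1e-12,
               ignore_attr = TRUE)
  # unexposed stratum is the untilted joint
  expect_equal(pd["1", "0"], 0.5, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pd["0", "0"], 0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("theta = 1 removes gene-environment dependence", {
  jdmx <- build_joint_dmx(gwas_joint(), theta = 1)
  pd <- markerGxE:::pr_d_given_mx(jdmx)
  expect_equal(pd[, 1], pd[, 2], tolerance = 1e-12)
})

test_that("marginal convention reproduces the input marginal as a mixture", {
  j <- gwas_joint()
  jdmx <- build_joint_dmx(j, theta = 1.5, exposure_prev = 0.3,
                          convention = "marginal")
  a <- unclass(jdmx)
  mix <- a[, , 1] + a[, , 2]
  dm <- matrix(c(j["h_dm"], j["h_Dm"], j["h_dM"], j["h_DM"]), 2, 2)
  expect_equal(mix, dm, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(a[, , 2]), 0.3, tolerance = 1e-12)
  expect_error(build_joint_dmx(j, theta = 5, exposure_prev = 0.9,
                               convention = "marginal"),
               "infeasible prevalence")
})

test_that("no causal main effect kills the marker interaction on any link", {
  jdmx <- build_joint_dmx(table1_joint(), theta = 1.5)
  for (nm in c("identity", "log", "logit")) {
    b0 <- if (nm == "identity") 0.3 else log(0.2)
    g <- marker_eta_grid(causal_glm(nm, b0, betaD = 0, betaX = 0.2), jdmx)
    expect_equal(g$beta_MX, 0, tolerance = 1e-12)
  }
})

test_that("a perfect proxy passes the causal interaction through", {
  j <- haplotypes_from_ld(0.2, 0.2, "dprime", 1)  # D = M
  jdmx <- build_joint_dmx(j, theta = 1.7)
  cc <- 0.31
  g <- marker_eta_grid(causal_glm("log", log(0.05), betaD = log(1.4),
                                  betaX = log(1.2), betaDX = cc), jdmx)
  expect_equal(g$beta_MX, cc, tolerance = 1e-12)
})

test_that("log-link marginalization equals the risk-ratio engine", {
  j <- table1_joint()
  g <- marker_eta_grid(causal_glm("log", log(0.1), betaD = log(2)),
                       build_joint_dmx(j, theta = 1.5))
  expect_equal(g$beta_MX, log(1.6 / 1.5), tolerance = 1e-12)
  # randomized cross-module agreement
  set.seed(11)
  for (i in 1:100) {
    rj <- random_joint()
    rr <- exp(runif(1, log(0.3), log(3)))
    th <- exp(runif(1, log(0.3), log(3)))
    se <- stratum_marker_rrs(rj$joint, rr, th)
    g <- marker_eta_grid(causal_glm("log", log(0.05), betaD = log(rr)),
                         build_joint_dmx(rj$joint, th))
    expect_lt(abs(g$beta_MX - log(se$interaction_ratio)), 1e-12)
  }
})

test_that("identity-link marginalization is the brute-force cell double difference", {
  set.seed(13)
  for (i in 1:100) {
    rj <- random_joint()
    th <- exp(runif(1, log(0.5), log(2)))
    model <- causal_glm("identity", runif(1), betaD = runif(1, -1, 1),
                        betaX = runif(1, -1, 1), betaDX = runif(1, -1, 1))
    jdmx <- build_joint_dmx(rj$joint, th)
    pd <- markerGxE:::pr_d_given_mx(jdmx)
    cellmean <- function(m, x) {
      p1 <- pd[m + 1, x + 1]
      (1 - p1) * (model$beta0 + model$betaX * x) +
        p1 * (model$beta0 + model$betaD + model$betaX * x +
                model$betaDX * x)
    }
    brute <- cellmean(1, 1) - cellmean(0, 1) - cellmean(1, 0) + cellmean(0, 0)
    expect_lt(abs(marker_eta_grid(model, jdmx)$beta_MX - brute), 1e-12)
  }
})

test_that("condition report flags the right conditions", {
  model <- causal_glm("log", log(0.1), betaD = log(2))
  # theta = 1: D independent of X given anything
  rep4 <- lemma_conditions(model, build_joint_dmx(table1_joint(), 1))
  expect_true(rep4$cond4)
  expect_false(rep4$cond2)
  # D = M joint
  repDM <- lemma_conditions(model,
                            build_joint_dmx(haplotypes_from_ld(0.2, 0.2,
                                                               "dprime", 1),
                                            1.5))
  expect_true(repDM$cond2)
  # linkage equilibrium: D independent of M given X (baseline convention)
  rep3 <- lemma_conditions(model,
                           build_joint_dmx(haplotypes_from_ld(0.2, 0.3,
                                                              "dprime", 0),
                                           1.5))
  expect_true(rep3$cond3)
  # the spurious-interaction configuration satisfies none of them
  repT2 <- lemma_conditions(model, build_joint_dmx(table1_joint(), 1.5))
  expect_false(any(repT2$cond1, repT2$cond2, repT2$cond3, repT2$cond4))
  expect_gt(abs(repT2$beta_MX), 1e-3)
})

test_that("whenever a reported condition holds, beta_MX vanishes", {
  set.seed(17)
  links <- c("identity", "log", "logit")
  n_checked <- 0
  for (i in 1:300) {
    kind <- sample(c("cond1", "cond2", "cond3", "cond4"), 1)
    nm <- sample(links, 1)
    th <- if (kind == "cond4") 1 else exp(runif(1, log(0.4), log(2.5)))
    joint <- switch(kind,
                    cond2 = {
                      p <- runif(1, 0.05, 0.5)
                      haplotypes_from_ld(p, p, "dprime", 1)
                    },
                    cond3 = {
                      p <- runif(2, 0.05, 0.5)
                      haplotypes_from_ld(p[1], p[2], "dprime", 0)
                    },
                    random_joint()$joint)
    bD <- if (kind == "cond1") 0 else runif(1, -0.7, 0.7)
    b0 <- if (nm == "identity") runif(1, 0.1, 0.5) else log(runif(1, 0.01, 0.2))
    model <- causal_glm(nm, b0, betaD = bD, betaX = runif(1, -0.3, 0.3),
                        betaDX = 0)
    rep <- lemma_conditions(model, build_joint_dmx(joint, th))
    holds <- (rep$cond1 || rep$cond2 || rep$cond3 ||
                (rep$cond4 && rep$link_guarantees_cond4))
    if (holds) {
      n_checked <- n_checked + 1
      expect_lt(abs(rep$beta_MX), 1e-10)
    }
  }
  expect_gt(n_checked, 200)
})

test_that("under logit, condition 4 kills the interaction only in the rare-outcome limit", {
  jdmx <- build_joint_dmx(table1_joint(), 1)  # condition (4) holds
  b0s <- c(-2, -5, -10, -20)
  bmx <- vapply(b0s, function(b0) {
    abs(marker_eta_grid(causal_glm("logit", b0, betaD = log(3),
                                   betaX = 0.5), jdmx)$beta_MX)
  }, numeric(1))
  expect_true(all(diff(bmx) < 0))
  expect_lt(bmx[length(bmx)], 1e-6)
  # but it is not zero away from the limit
  expect_gt(bmx[1], 1e-4)
})

test_that("empty strata are rejected", {
  model <- causal_glm("log", log(0.1), betaD = log(2))
  j <- haplotypes_from_ld(0.2, 0.2, "dprime", 1)  # no (d=1, m=0) mass
  jdmx <- build_joint_dmx(j, 1.5)
  # all four (m, x) cells still have mass here; break one artificially
  broken <- unclass(jdmx)
  broken[, 1, ] <- 0
  class(broken) <- "joint_dmx"
  expect_error(marker_eta_grid(model, broken), "empty")
})
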