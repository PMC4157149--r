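# Seeded individual-level simulator and in-package IRLS fitter.  This is the
# brute-force empirical counterpart of the analytic machinery: haplotype
# pairs are drawn under HWE, exposure depends on causal dosage, the outcome
# follows the causal GLM, and a marker-by-exposure GLM is fitted to confirm
# the analytic stratum risk ratios and induced interaction.

#' Simulation configuration
#'
#' @param n number of subjects (cohort) -- for case-control use
#'   [simulate_case_control()] with explicit counts.
#' @param joint a [haplotype_joint()].
#' @param model a [causal_glm()]; the linear predictor uses causal *dosage*
#'   (0/1/2), so for the log link the risk at dosage 2 must not exceed 1.
#' @param theta per-allele exposure risk ratio.  Under the `marginal`
#'   convention exposure is assigned at the diploid level with
#'   `Pr(X=1|dosage) = kappa * theta^dosage`, `kappa` solved so the exposure
#'   marginal equals `exposure_prev`.  Under `baseline_unexposed`, exposure
#'   is drawn first with probability `exposure_prev` and haplotypes are then
#'   drawn from the untilted (unexposed) or tilted (exposed) haplotype
#'   distribution; this makes the unexposed stratum exactly the input joint,
#'   matching the stratified forward tables, so the fitted log-link
#'   interaction converges exactly to the analytic value.
#' @param exposure_prev population exposure prevalence.
#' @param convention exposure-assignment convention, see `theta`.
#' @param seed integer seed; every draw is reproducible given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n, joint, model, theta, exposure_prev = 0.5,
                       convention = c("marginal", "baseline_unexposed"),
                       seed = 1L) {
  convention <- match.arg(convention)
  stopifnot(inherits(joint, "haplotype_joint"),
            inherits(model, "causal_glm"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive subject count", call. = FALSE)
  }
  if (!is.finite(theta) || theta <= 0) {
    stop("theta must be positive", call. = FALSE)
  }
  if (exposure_prev <= 0 || exposure_prev >= 1) {
    stop("exposure_prev must lie in (0, 1)", call. = FALSE)
  }
  # config errors before any sampling: risk must be a probability at the
  # extreme (dosage, exposure) cell
  lp <- model$beta0 + model$betaD * c(0, 2) + model$betaX * c(0, 1) +
    model$betaDX * c(0, 2)
  mu <- model$link$linkinv(lp)
  if (model$link$name %in% c("log", "identity") &&
      (any(mu < 0) || any(mu > 1))) {
    stop(sprintf(
      "risk exceeds [0, 1] under %s link at the extreme cell (mu = %g); rescale beta0",
      model$link$name, max(mu)), call. = FALSE)
  }
  p_D <- attr(joint, "p_D")
  kappa <- NA_real_
  if (convention == "marginal") {
    kappa <- exposure_prev / sum(stats::dbinom(0:2, 2, p_D) * theta^(0:2))
    if (kappa * max(1, theta)^2 > 1) {
      stop("infeasible exposure model: Pr(X=1 | dosage 2) exceeds 1",
           call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), joint = joint, model = model,
                 theta = theta, exposure_prev = exposure_prev,
                 convention = convention, kappa = kappa,
                 seed = as.integer(seed)),
            class = "sim_config")
}

subject_risk <- function(model, d, x) {
  model$link$linkinv(model$beta0 + model$betaD * d + model$betaX * x +
                       model$betaDX * d * x)
}

draw_subjects <- function(cfg, n) {
  probs <- as.numeric(cfg$joint)[1:4]
  d_al <- c(1, 1, 0, 0)
  m_al <- c(1, 0, 1, 0)
  if (cfg$convention == "marginal") {
    h1 <- sample.int(4, n, replace = TRUE, prob = probs)
    h2 <- sample.int(4, n, replace = TRUE, prob = probs)
    d <- d_al[h1] + d_al[h2]
    m <- m_al[h1] + m_al[h2]
    x <- stats::rbinom(n, 1, cfg$kappa * cfg$theta^d)
  } else {
    # exposure first, then haplotypes from the stratum-specific
    # distribution: untilted for unexposed, per-allele tilted for exposed
    x <- stats::rbinom(n, 1, cfg$exposure_prev)
    tilted <- probs * cfg$theta^d_al
    tilted <- tilted / sum(tilted)
    h1 <- h2 <- integer(n)
    n0 <- sum(x == 0)
    h1[x == 0] <- sample.int(4, n0, replace = TRUE, prob = probs)
    h2[x == 0] <- sample.int(4, n0, replace = TRUE, prob = probs)
    h1[x == 1] <- sample.int(4, n - n0, replace = TRUE, prob = tilted)
    h2[x == 1] <- sample.int(4, n - n0, replace = TRUE, prob = tilted)
    d <- d_al[h1] + d_al[h2]
    m <- m_al[h1] + m_al[h2]
  }
  y <- stats::rbinom(n, 1, subject_risk(cfg$model, d, x))
  data.frame(causal_dosage = d, marker_dosage = m, exposure = x,
             outcome = y)
}

#' Simulate a cohort
#'
#' Draws `n` subjects: two haplotypes each (HWE), exposure dependent on
#' causal dosage, outcome from the causal GLM.  Fully reproducible given the
#' seed in the configuration.
#'
#' @param cfg a [sim_config()].
#' @return A `data.frame` of class `subject_table` with columns
#'   `causal_dosage`, `marker_dosage`, `exposure`, `outcome`; the
#'   configuration is attached as attribute `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  out <- draw_subjects(cfg, cfg$n)
  structure(out, config = cfg, class = c("subject_table", "data.frame"))
}

#' Simulate a case-control sample
#'
#' Rejection-samples cohort subjects until the requested numbers of cases
#' and controls are reached, in draw order; errors out if the sampling
#' budget is exhausted (e.g., prevalence too small for the requested case
#' count).
#'
#' @param cfg a [sim_config()]; its `n` is ignored.
#' @param n_cases,n_controls requested counts.
#' @param max_batches sampling budget: maximum number of batches (of size
#'   `max(1e5, n_cases + n_controls)`) drawn before giving up.
#' @return A `subject_table` with `n_cases + n_controls` rows, cases first.
#' @export
simulate_case_control <- function(cfg, n_cases, n_controls,
                                  max_batches = 1000L) {
  stopifnot(inherits(cfg, "sim_config"), n_cases >= 1, n_controls >= 1)
  set.seed(cfg$seed)
  batch <- as.integer(max(1e5, n_cases + n_controls))
  cases <- controls <- vector("list", max_batches)
  nca <- nco <- 0L
  for (b in seq_len(max_batches)) {
    dat <- draw_subjects(cfg, batch)
    if (nca < n_cases) {
      cases[[b]] <- dat[dat$outcome == 1L, , drop = FALSE]
      nca <- nca + nrow(cases[[b]])
    }
    if (nco < n_controls) {
      controls[[b]] <- dat[dat$outcome == 0L, , drop = FALSE]
      nco <- nco + nrow(controls[[b]])
    }
    if (nca >= n_cases && nco >= n_controls) {
      out <- rbind(
        utils::head(do.call(rbind, cases[!vapply(cases, is.null, TRUE)]),
                    n_cases),
        utils::head(do.call(rbind, controls[!vapply(controls, is.null, TRUE)]),
                    n_controls))
      rownames(out) <- NULL
      return(structure(out, config = cfg,
                       class = c("subject_table", "data.frame")))
    }
  }
  stop(sprintf(
    "sampling budget exhausted: %d cases / %d controls found after %d batches (requested %d / %d); prevalence may be too small",
    nca, nco, max_batches, n_cases, n_controls), call. = FALSE)
}

#' Fit the marker-by-exposure interaction GLM
#'
#' Iteratively reweighted least squares fit of
#' `outcome ~ marker + exposure + marker:exposure` with binomial variance
#' and the requested link.  Implemented in-package so the simulation oracle
#' carries no external fitting dependency; accepts fractional responses
#' with prior weights, which allows fitting on expected cell counts.
#'
#' @param data a `subject_table` or any data frame with columns
#'   `marker_dosage`, `exposure`, `outcome`.
#' @param link a link name or [link_function()].
#' @param coding `"allele_dosage"` (marker enters as 0/1/2) or `"carrier"`
#'   (0/1, any risk allele).
#' @param weights optional prior weights (e.g., expected cell counts).
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter maximum IRLS iterations.
#' @return An object of class `interaction_fit`: `coefficients` (named:
#'   `(Intercept)`, `marker`, `exposure`, `marker:exposure`), `se`, `vcov`,
#'   `converged`, `iterations`, `separation`.
#' @export
fit_interaction_glm <- function(data, link = "log",
                                coding = c("allele_dosage", "carrier"),
                                weights = NULL, tol = 1e-10,
                                max_iter = 100L) {
  coding <- match.arg(coding)
  if (is.character(link)) link <- link_function(link)
  stopifnot(inherits(link, "link_fn"))
  need <- c("marker_dosage", "exposure", "outcome")
  if (!all(need %in% names(data))) {
    stop("data must have columns marker_dosage, exposure, outcome",
         call. = FALSE)
  }
  m <- if (coding == "carrier") as.numeric(data$marker_dosage >= 1)
       else as.numeric(data$marker_dosage)
  x <- as.numeric(data$exposure)
  y <- as.numeric(data$outcome)
  if (any(y < 0 | y > 1)) {
    stop("outcome must lie in [0, 1] (binary or fractional)", call. = FALSE)
  }
  w0 <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  stopifnot(length(w0) == length(y), all(w0 >= 0))
  X <- cbind(`(Intercept)` = 1, marker = m, exposure = x,
             `marker:exposure` = m * x)

  eps <- 1e-12
  mu <- pmin(1 - eps, pmax(eps, (w0 * y + 0.5) / (w0 + 1)))
  eta <- switch(link$name,
                identity = mu,
                log = log(mu),
                logit = log(mu / (1 - mu)))
  beta <- rep(0, 4)
  converged <- FALSE
  it <- 0L
  dmu_deta <- function(eta, mu) switch(link$name,
                                       identity = rep(1, length(eta)),
                                       log = mu,
                                       logit = mu * (1 - mu))
  repeat {
    it <- it + 1L
    mu <- pmin(1 - eps, pmax(eps, link$linkinv(eta)))
    dd <- dmu_deta(eta, mu)
    varf <- mu * (1 - mu)
    w <- w0 * dd^2 / varf
    z <- eta + (y - mu) / dd
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(is.na(beta_new))) {
      stop("design is rank deficient (constant marker or exposure?)",
           call. = FALSE)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (link$name == "log") eta <- pmin(eta, -eps)  # keep mu <= 1
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  mu <- pmin(1 - eps, pmax(eps, link$linkinv(eta)))
  w <- w0 * dmu_deta(eta, mu)^2 / (mu * (1 - mu))
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, 4, 4))
  separation <- any(w0 > 0 & (mu <= 2 * eps | mu >= 1 - 2 * eps))
  if (!converged || separation) {
    warning(sprintf(
      "IRLS %s after %d iterations%s; estimates may be unreliable",
      if (converged) "converged" else "did not converge", it,
      if (separation) " (quasi-separation detected)" else ""),
      call. = FALSE)
  }
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = sqrt(diag(vcov)), vcov = vcov,
                 converged = converged, iterations = it,
                 separation = separation, link = link$name,
                 coding = coding),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Interaction GLM (%s link, %s coding)%s\n", x$link, x$coding,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Write and read subject tables
#'
#' Tab-delimited with a `#`-prefixed header comment recording the
#' generating configuration and seed.
#'
#' @param data a `subject_table`.
#' @param path file path.
#' @return `write_subject_table` returns `path` invisibly;
#'   `read_subject_table` returns a data frame.
#' @export
write_subject_table <- function(data, path) {
  cfg <- attr(data, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    writeLines(sprintf(
      "# markerGxE %s cohort: n=%d seed=%d theta=%g exposure_prev=%g link=%s",
      as.character(utils::packageVersion("markerGxE")),
      cfg$n, cfg$seed, cfg$theta, cfg$exposure_prev, cfg$model$link$name),
      con)
  }
  utils::write.table(data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  utils::read.delim(path, comment.char = "#")
}
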