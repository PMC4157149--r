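# Marginalization of the causal-variant GLM to the marker scale.
#
# The observable model is E(Y|M,X) = h^{-1}(b0 + bM*M + bX*X + bMX*M*X) and
# the latent model is E(Y|D,X) = h^{-1}(b0* + bD*D + bX*X + bDX*D*X).  When
# the marker has no effect conditional on the causal variant,
#   h^{-1}(eta_{m,x}) = sum_d h^{-1}(b0* + bD*d + bX*x + bDX*dx) Pr(d|m,x),
# and the marker interaction coefficient is the double difference
#   bMX = eta_{1,1} - eta_{0,1} - eta_{1,0} + eta_{0,0}.
# All variables are binary allele-level codes here; diploid dosage analysis
# is handled by the simulator's regression fit.

#' Link functions
#'
#' Thin wrapper around [stats::make.link()] restricted to the three links
#' for which the marginalization results hold: identity, log and logit.
#'
#' @param name one of `"identity"`, `"log"`, `"logit"`.
#' @return An object of class `link_fn` with elements `name`, `linkfun`
#'   (h) and `linkinv` (h^-1).
#' @export
link_function <- function(name = c("identity", "log", "logit")) {
  name <- match.arg(name)
  l <- stats::make.link(name)
  structure(list(name = name, linkfun = l$linkfun, linkinv = l$linkinv),
            class = "link_fn")
}

#' Causal-variant generalized linear model
#'
#' Coefficients on the link scale for the latent model in the causal allele
#' `D` and exposure `X`: intercept, main effects and interaction.  For the
#' log link the coefficients are log risk ratios; for logit, log odds
#' ratios.
#'
#' @param link a [link_function()] or a link name.
#' @param beta0,betaD,betaX,betaDX coefficients on the link scale.
#' @return An object of class `causal_glm`.
#' @examples
#' causal_glm("log", beta0 = log(0.05), betaD = log(2), betaX = 0)
#' @export
causal_glm <- function(link, beta0, betaD = 0, betaX = 0, betaDX = 0) {
  if (is.character(link)) link <- link_function(link)
  stopifnot(inherits(link, "link_fn"))
  b <- c(beta0, betaD, betaX, betaDX)
  if (any(!is.finite(b))) stop("coefficients must be finite", call. = FALSE)
  # the inverse link must give a valid mean over the four (d, x) cells
  if (link$name %in% c("log", "logit")) {
    lp <- beta0 + betaD * c(0, 1, 0, 1) + betaX * c(0, 0, 1, 1) +
      betaDX * c(0, 0, 0, 1)
    mu <- link$linkinv(lp)
    hi <- if (link$name == "log") 1 else 1 - 1e-15
    if (any(mu <= 0) || any(mu > hi)) {
      stop(sprintf(
        "inverse-link mean out of range for %s link (max mu = %g over the (d, x) grid)",
        link$name, max(mu)), call. = FALSE)
    }
  }
  structure(list(link = link, beta0 = beta0, betaD = betaD,
                 betaX = betaX, betaDX = betaDX),
            class = "causal_glm")
}

#' Joint distribution of causal allele, marker allele and exposure
#'
#' Builds the 2x2x2 probability mass over `(d, m, x)` from a haplotype joint
#' and a per-allele exposure tilt `theta` (the risk ratio of the causal
#' allele on the exposure).
#'
#' Two stratification conventions are supported:
#' * `baseline_unexposed`: the haplotype joint describes the *unexposed*
#'   stratum, `Pr(d,m|X=0) = joint`, and the exposed stratum is the tilted,
#'   renormalized joint `Pr(d,m|X=1)` proportional to `joint * theta^d`.
#'   Only the per-stratum conditionals are defined by this convention;
#'   `exposure_prev` is ignored and the two strata are stored with equal
#'   weight, which leaves every conditional `Pr(d|m,x)` unchanged.
#' * `marginal`: the haplotype joint is the population marginal of `(d,m)`
#'   and exposure is assigned by `Pr(X=1|d) = kappa * theta^d` with `kappa`
#'   solved so that the exposure marginal equals `exposure_prev`.
#'
#' @param joint a [haplotype_joint()].
#' @param theta exposure risk ratio per causal allele; positive.
#' @param exposure_prev population exposure prevalence in (0,1); used only
#'   under the `marginal` convention.
#' @param convention `"baseline_unexposed"` (default; matches the worked
#'   unexposed/exposed tables) or `"marginal"`.
#' @return An object of class `joint_dmx`: a 2x2x2 array with dimensions
#'   `d`, `m`, `x` (levels 0/1), masses summing to 1.
#' @examples
#' j <- haplotype_joint(0.05, 0, 0.05, 0.9)
#' build_joint_dmx(j, theta = 1.5)
#' @export
build_joint_dmx <- function(joint, theta, exposure_prev = 0.5,
                            convention = c("baseline_unexposed", "marginal")) {
  stopifnot(inherits(joint, "haplotype_joint"))
  convention <- match.arg(convention)
  if (!is.finite(theta) || theta <= 0) {
    stop("theta must be a positive exposure risk ratio", call. = FALSE)
  }
  # (d, m) mass matrix: rows d = 0/1, cols m = 0/1
  dm <- matrix(c(joint["h_dm"], joint["h_Dm"],
                 joint["h_dM"], joint["h_DM"]), 2, 2,
               dimnames = list(d = 0:1, m = 0:1))
  a <- array(0, dim = c(2, 2, 2), dimnames = list(d = 0:1, m = 0:1, x = 0:1))
  if (convention == "baseline_unexposed") {
    tilted <- dm * theta^c(0, 1)          # recycles down rows (d index)
    tilted <- tilted / sum(tilted)
    a[, , 1] <- dm * 0.5
    a[, , 2] <- tilted * 0.5
  } else {
    if (!is.finite(exposure_prev) || exposure_prev <= 0 || exposure_prev >= 1) {
      stop("exposure_prev must lie in (0, 1)", call. = FALSE)
    }
    p_D <- attr(joint, "p_D")
    kappa <- exposure_prev / ((1 - p_D) + theta * p_D)
    if (kappa * max(1, theta) > 1) {
      stop(sprintf(paste0(
        "infeasible prevalence: Pr(X=1|d=1) = kappa*theta = %g exceeds 1 ",
        "(theta = %g, exposure_prev = %g)"),
        kappa * theta, theta, exposure_prev), call. = FALSE)
    }
    px1 <- kappa * theta^c(0, 1)          # Pr(X=1|d), d = 0, 1
    a[, , 1] <- dm * (1 - px1)
    a[, , 2] <- dm * px1
  }
  structure(a, convention = convention, theta = theta, class = "joint_dmx")
}

# Conditional Pr(D=1 | M=m, X=x) for all four (m, x) cells; 2x2 matrix with
# rows m = 0/1, cols x = 0/1.
pr_d_given_mx <- function(jdmx) {
  stopifnot(inherits(jdmx, "joint_dmx"))
  tot <- apply(unclass(jdmx), c(2, 3), sum)      # (m, x) cell masses
  d1 <- unclass(jdmx)[2, , ]                     # mass with d = 1
  if (any(tot <= 0)) {
    stop("empty (m, x) stratum: conditional Pr(d|m,x) undefined",
         call. = FALSE)
  }
  d1 / tot
}

#' Marker-scale linear predictors and the induced interaction coefficient
#'
#' Marginalizes the causal-variant GLM over `Pr(D|M,X)` to obtain the four
#' marker-scale linear predictors `eta[m,x]` and the marker-by-exposure
#' interaction coefficient (the double difference of the `eta` grid).
#'
#' @param model a [causal_glm()].
#' @param jdmx a [build_joint_dmx()] result.
#' @return An object of class `eta_grid`: list with `eta` (2x2 matrix, rows
#'   marker `m` = 0/1, columns exposure `x` = 0/1), `beta0`, `beta_M`,
#'   `beta_X` and `beta_MX`.
#' @examples
#' j <- haplotype_joint(0.05, 0, 0.05, 0.9)
#' g <- marker_eta_grid(causal_glm("log", log(0.1), betaD = log(2)),
#'                      build_joint_dmx(j, theta = 1.5))
#' exp(g$beta_MX)   # the induced multiplicative interaction, 1.6/1.5
#' @export
marker_eta_grid <- function(model, jdmx) {
  stopifnot(inherits(model, "causal_glm"))
  pd <- pr_d_given_mx(jdmx)               # Pr(D=1|m,x)
  link <- model$link
  eta <- matrix(NA_real_, 2, 2, dimnames = list(m = 0:1, x = 0:1))
  for (m in 0:1) {
    for (x in 0:1) {
      lp <- model$beta0 + model$betaD * c(0, 1) + model$betaX * x +
        model$betaDX * c(0, 1) * x
      mu <- sum(link$linkinv(lp) * c(1 - pd[m + 1, x + 1], pd[m + 1, x + 1]))
      if (!is.finite(mu)) {
        stop("non-finite cell mean during marginalization", call. = FALSE)
      }
      if (link$name == "log" && mu <= 0) {
        stop("log link requires positive cell means", call. = FALSE)
      }
      if (link$name == "logit" && (mu <= 0 || mu >= 1)) {
        stop("logit link requires cell means in (0, 1)", call. = FALSE)
      }
      eta[m + 1, x + 1] <- link$linkfun(mu)
    }
  }
  structure(list(eta = eta,
                 beta0 = eta[1, 1],
                 beta_M = eta[2, 1] - eta[1, 1],
                 beta_X = eta[1, 2] - eta[1, 1],
                 beta_MX = eta[2, 2] - eta[1, 2] - eta[2, 1] + eta[1, 1],
                 link = link$name),
            class = "eta_grid")
}

#' @export
print.eta_grid <- function(x, ...) {
  cat(sprintf("Marker-scale eta grid (%s link)\n", x$link))
  print(x$eta)
  cat(sprintf("beta_M = %.6g, beta_X = %.6g, beta_MX = %.6g\n",
              x$beta_M, x$beta_X, x$beta_MX))
  invisible(x)
}

#' Check the no-interaction conditions
#'
#' With no causal-variant-by-exposure interaction (`betaDX = 0`), the
#' marker-by-exposure interaction vanishes when any of four conditions
#' holds: (1) no causal main effect; (2) the marker equals the causal
#' variant; (3) the causal variant is independent of the marker given the
#' exposure; or, under the identity or log link only, (4) the causal
#' variant is independent of the exposure given the marker.
#'
#' @param model a [causal_glm()].
#' @param jdmx a [build_joint_dmx()] result.
#' @param tol numeric tolerance for the condition checks.
#' @return An object of class `lemma_report`: logical flags `cond1`...
#'   `cond4`, whether `betaDX` is zero, whether the link guarantees
#'   condition 4 (`link_guarantees_cond4`), and the computed `beta_MX`.
#' @export
lemma_conditions <- function(model, jdmx, tol = 1e-9) {
  stopifnot(inherits(model, "causal_glm"), inherits(jdmx, "joint_dmx"))
  a <- unclass(jdmx)
  pd <- pr_d_given_mx(jdmx)                      # Pr(D=1|m,x), rows m
  # Pr(D=1|x): collapse over m within each x stratum
  px <- apply(a, 3, sum)
  pd_x <- apply(a[2, , ], 2, sum) / px
  # Pr(D=1|m): collapse over x within each m level
  pm <- apply(a, 2, sum)
  pd_m <- apply(a[2, , ], 1, sum) / pm

  cond1 <- abs(model$betaD) <= tol
  cond2 <- (a[1, 2, 1] + a[1, 2, 2] + a[2, 1, 1] + a[2, 1, 2]) <= tol
  cond3 <- max(abs(sweep(pd, 2, pd_x))) <= tol
  cond4 <- max(abs(sweep(pd, 1, pd_m))) <= tol
  structure(list(cond1 = cond1, cond2 = cond2, cond3 = cond3, cond4 = cond4,
                 betaDX_zero = abs(model$betaDX) <= tol,
                 link = model$link$name,
                 link_guarantees_cond4 = model$link$name %in%
                   c("identity", "log"),
                 beta_MX = marker_eta_grid(model, jdmx)$beta_MX,
                 tol = tol),
            class = "lemma_report")
}

#' @export
print.lemma_report <- function(x, ...) {
  cat("No-interaction conditions (given betaDX = 0):\n")
  cat(sprintf("  (1) no causal main effect:            %s\n", x$cond1))
  cat(sprintf("  (2) marker == causal variant:         %s\n", x$cond2))
  cat(sprintf("  (3) D indep. of M given X:            %s\n", x$cond3))
  cat(sprintf("  (4) D indep. of X given M:            %s (guaranteed under %s link: %s)\n",
              x$cond4, x$link, x$link_guarantees_cond4))
  cat(sprintf("  betaDX = 0: %s;  induced beta_MX = %.6g\n",
              x$betaDX_zero, x$beta_MX))
  invisible(x)
}
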