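# Inverse sensitivity analysis: given stratum-specific marker effects and an
# assumed causal minor allele frequency, recover the causal risk ratios on
# disease (R) and on exposure (theta) that reproduce the observed marker
# effects exactly under maximal LD (or a supplied D').
#
# Stratum convention: rr_stratum0 is the marker effect in the baseline
# (untilted) exposure stratum, rr_stratum1 in the tilted stratum.  For the
# published CYP3A / age-at-menarche example the baseline stratum is
# menarche > 12 years (marker OR 0.906) and the tilted stratum is <= 12
# years (OR 0.979); the reverse assignment admits no positive solution.
#
# Identifiability: the baseline-stratum equation is linear in R, so the
# disease-side solution is always unique.  The tilted-stratum equation is
# linear in theta when h_Dm = 0 (unique tilt) but quadratic when h_Dm > 0:
# the exposed-stratum marker RR tends to 1 both as theta -> 0 and as
# theta -> Inf (in either limit the exposed stratum becomes monomorphic at
# the causal locus), so two positive tilts generally reproduce the same
# observed effects.  Both roots are returned; the primary solution is the
# one with the smaller |log theta| -- the weakest gene-environment
# dependence consistent with the observations.

#' Recover causal risk ratios from observed stratum marker effects
#'
#' Solves for the causal-variant risk ratio on disease (`R`) and the
#' per-allele exposure tilt (`theta`) such that the forward calculation
#' [stratum_marker_rrs()] reproduces the observed marker effects in both
#' exposure strata, for an assumed causal MAF and LD.
#'
#' The baseline-stratum equation is linear in `R` and solved exactly.  When
#' the causal allele occurs only on marker-allele haplotypes (`h_Dm = 0`,
#' the case for `d_prime = 1` with `p_D <= p_M`) the tilted-stratum
#' equation is linear in `theta` and the tilt is unique; otherwise it is
#' quadratic and can admit two positive tilts that reproduce the
#' observations exactly.  The primary solution is the tilt with smaller
#' `|log theta|` (the weakest gene-environment dependence consistent with
#' the data); any second root is reported in `rr_exposure_causal_alt`.
#' A damped two-dimensional Newton iteration (with a staged bisection
#' fallback) is available via `method = "newton"` as an independent path.
#'
#' Observed odds ratios are treated on the risk-ratio scale (the
#' rare-disease convention).
#'
#' @param p_M marker minor allele frequency, in (0,1).
#' @param rr_stratum0 observed marker effect (ratio scale) in the baseline
#'   (untilted) exposure stratum.
#' @param rr_stratum1 observed marker effect in the tilted stratum.
#' @param p_D assumed causal minor allele frequency, in (0,1).
#' @param d_prime assumed LD between causal variant and marker; default 1
#'   (maximum correlation given the MAFs).
#' @param method `"auto"` (exact algebraic solution), `"closed_form"`
#'   (algebraic, but errors unless `h_Dm = 0` so the tilt is the unique
#'   sequential closed form) or `"newton"` (damped 2-D Newton).
#' @return An object of class `sensitivity_solution`: list with
#'   `rr_disease_causal`, `rr_exposure_causal`, `rr_exposure_causal_alt`
#'   (second quadratic root, `NA` when the tilt is unique), `converged`,
#'   `residual` (max absolute error of the reproduced stratum effects) and
#'   `identifiable`.
#' @examples
#' invert_marker_effects(p_M = 0.09, rr_stratum0 = 0.906,
#'                       rr_stratum1 = 0.979, p_D = 0.05)
#' @export
invert_marker_effects <- function(p_M, rr_stratum0, rr_stratum1, p_D,
                                  d_prime = 1,
                                  method = c("auto", "closed_form",
                                             "newton")) {
  method <- match.arg(method)
  if (!is.finite(p_M) || p_M <= 0 || p_M >= 1 ||
      !is.finite(p_D) || p_D <= 0 || p_D >= 1) {
    stop("allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  if (!all(is.finite(c(rr_stratum0, rr_stratum1))) ||
      rr_stratum0 <= 0 || rr_stratum1 <= 0) {
    stop("observed marker effects must be positive ratios", call. = FALSE)
  }
  joint <- haplotypes_from_ld(p_D, p_M, "dprime", d_prime)
  h <- as.numeric(joint)  # DM, Dm, dM, dm
  q <- p_M / (1 - p_M)

  if (rr_stratum0 == 1 && rr_stratum1 == 1) {
    return(solution(1, NA_real_, converged = TRUE, residual = 0,
                    identifiable = FALSE))
  }
  if (h[1] <= 0) {
    stop("causal and marker alleles never co-occur (h_DM = 0): observed marker effects cannot be inverted",
         call. = FALSE)
  }
  if (method == "closed_form" && h[2] > 1e-12) {
    stop("closed_form method requires h_Dm = 0 (d_prime = 1 with p_D <= p_M)",
         call. = FALSE)
  }

  # Baseline-stratum equation, linear in R for any joint:
  #   (h_dM + h_DM R) / p_M = rr0 * (h_dm + h_Dm R) / (1 - p_M)
  R <- (rr_stratum0 * q * h[4] - h[3]) / (h[1] - rr_stratum0 * q * h[2])
  if (!is.finite(R) || R <= 0) {
    stop(sprintf(
      "infeasible observation: no positive causal disease risk ratio reproduces baseline effect %g at causal MAF %g",
      rr_stratum0, p_D), call. = FALSE)
  }

  if (method == "newton") {
    par <- newton_invert(joint, R, rr_stratum0, rr_stratum1)
    # polish the tilt by sign-change bracketing at the exact linear R:
    # Newton residuals can sit below tolerance over a wide theta range when
    # the tilted-stratum equation is flat
    g <- function(th) {
      marker_rr_masses(h * th^c(1, 1, 0, 0), par[1]) - rr_stratum1
    }
    lo <- par[2] / 2; hi <- par[2] * 2
    if (is.finite(g(lo)) && is.finite(g(hi)) && g(lo) * g(hi) < 0) {
      par[2] <- stats::uniroot(g, c(lo, hi), tol = 1e-15)$root
    }
    res <- residual_at(joint, par[1], par[2], rr_stratum0, rr_stratum1)
    return(solution(par[1], par[2], converged = res < 1e-10,
                    residual = res))
  }

  # Tilted-stratum equation: cross-multiplied,
  #   (h_dM + h_DM R t)(h_dm + h_Dm t) = rr1 (h_dM + h_DM t)(h_dm + h_Dm R t)
  # a quadratic a t^2 + b t + c = 0 (linear when h_Dm = 0)
  a <- h[1] * h[2] * R * (1 - rr_stratum1)
  b <- h[3] * h[2] + h[1] * h[4] * R -
    rr_stratum1 * (h[3] * h[2] * R + h[1] * h[4])
  c0 <- h[3] * h[4] * (1 - rr_stratum1)
  roots <- if (abs(a) <= 1e-12 * (abs(b) + abs(c0))) {
    # effectively linear (h_Dm = 0 up to roundoff): the unique finite root
    if (abs(b) < 1e-300) numeric(0) else -c0 / b
  } else {
    disc <- b^2 - 4 * a * c0
    if (disc < 0) {
      numeric(0)
    } else if (b == 0) {
      c(-1, 1) * sqrt(-c0 / a)
    } else {
      # cancellation-stable form: q/a and c0/q
      qq <- -0.5 * (b + sign(b) * sqrt(disc))
      c(qq / a, c0 / qq)
    }
  }
  roots <- sort(unique(roots[is.finite(roots) & roots > 0]))
  if (length(roots) == 0) {
    stop(sprintf(
      "infeasible observation: no positive exposure tilt reproduces tilted-stratum effect %g at causal MAF %g",
      rr_stratum1, p_D), call. = FALSE)
  }
  # primary root: weakest gene-environment dependence
  ord <- order(abs(log(roots)))
  theta <- roots[ord[1]]
  theta_alt <- if (length(roots) > 1) roots[ord[2]] else NA_real_
  res <- residual_at(joint, R, theta, rr_stratum0, rr_stratum1)
  solution(R, theta, converged = res < 1e-10, residual = res,
           theta_alt = theta_alt)
}

# Damped 2-D Newton on the forward system, with a staged bisection fallback
# (linear R, then root bracketing in theta).  Kept as an independent solution
# path; agrees with the algebraic solution on unique-tilt instances.
newton_invert <- function(joint, R_lin, rr0, rr1) {
  f <- function(par) {
    se <- stratum_marker_rrs(joint, par[1], par[2])
    c(se$rr_unexposed - rr0, se$rr_exposed - rr1)
  }
  par <- c(R_lin, max(rr1 / rr0, 1e-6))
  fval <- tryCatch(f(par), error = function(e) c(NA_real_, NA_real_))
  if (all(is.finite(fval))) {
    for (it in seq_len(200)) {
      if (max(abs(fval)) < 1e-14) return(par)
      J <- matrix(0, 2, 2)
      for (k in 1:2) {
        hstep <- max(1e-8, 1e-8 * abs(par[k]))
        pk <- par; pk[k] <- pk[k] + hstep
        J[, k] <- (f(pk) - fval) / hstep
      }
      step <- tryCatch(solve(J, -fval), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      improved <- FALSE
      while (lambda >= 1e-12) {
        cand <- par + lambda * step
        if (all(cand > 0)) {
          fc <- tryCatch(f(cand), error = function(e) c(NA_real_, NA_real_))
          if (all(is.finite(fc)) && sum(fc^2) < sum(fval^2)) {
            par <- cand; fval <- fc; improved <- TRUE; break
          }
        }
        lambda <- lambda / 2
      }
      if (!improved) break
    }
    if (max(abs(fval)) < 1e-10) return(par)
  }
  # bisection fallback in theta at the exact linear R
  h <- as.numeric(joint)
  g <- function(th) marker_rr_masses(h * th^c(1, 1, 0, 0), R_lin) - rr1
  grid <- 10^seq(-8, 8, length.out = 161)
  vals <- vapply(grid, g, numeric(1))
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0) {
    stop(sprintf(
      "infeasible observation: no positive exposure tilt reproduces tilted-stratum effect %g",
      rr1), call. = FALSE)
  }
  th <- stats::uniroot(g, c(grid[idx[1]], grid[idx[1] + 1]), tol = 1e-15)$root
  c(R_lin, th)
}

residual_at <- function(joint, R, theta, rr0, rr1) {
  se <- stratum_marker_rrs(joint, R, theta)
  max(abs(se$rr_unexposed - rr0), abs(se$rr_exposed - rr1))
}

solution <- function(R, theta, converged, residual, identifiable = TRUE,
                     theta_alt = NA_real_) {
  structure(list(rr_disease_causal = unname(R),
                 rr_exposure_causal = unname(theta),
                 rr_exposure_causal_alt = unname(theta_alt),
                 converged = converged, residual = unname(residual),
                 identifiable = identifiable),
            class = "sensitivity_solution")
}

#' @export
print.sensitivity_solution <- function(x, ...) {
  if (!x$identifiable) {
    cat("Non-identifiable: both stratum effects are 1 (R = 1, theta undetermined)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Causal RR on disease: %.3f (1/%.2f); on exposure: %.3f (1/%.2f)\n",
    x$rr_disease_causal, 1 / x$rr_disease_causal,
    x$rr_exposure_causal, 1 / x$rr_exposure_causal))
  if (!is.na(x$rr_exposure_causal_alt)) {
    cat(sprintf("  (second exposure-tilt root: %.4g)\n",
                x$rr_exposure_causal_alt))
  }
  cat(sprintf("converged: %s, residual %.3g\n", x$converged, x$residual))
  invisible(x)
}

#' Sensitivity scan over assumed causal MAFs
#'
#' Runs [invert_marker_effects()] for each causal MAF in a grid and tabulates
#' the recovered causal risk ratios.  Infeasible MAFs are flagged in the
#' `status` column rather than dropped.
#'
#' @inheritParams invert_marker_effects
#' @param p_D_grid numeric vector of assumed causal MAFs.
#' @return A data frame with one row per MAF: `maf`, `rr_disease`,
#'   `rr_exposure`, `inv_rr_disease`, `inv_rr_exposure`, `rr_exposure_alt`
#'   (second tilt root, `NA` when unique), `residual`, `status` (`"ok"`,
#'   `"non-identifiable"` or the error message).
#' @examples
#' sensitivity_scan(0.09, 0.906, 0.979, c(0.05, 0.02, 0.01))
#' @export
sensitivity_scan <- function(p_M, rr_stratum0, rr_stratum1, p_D_grid,
                             d_prime = 1) {
  if (length(p_D_grid) == 0) {
    return(data.frame(maf = numeric(0), rr_disease = numeric(0),
                      rr_exposure = numeric(0), inv_rr_disease = numeric(0),
                      inv_rr_exposure = numeric(0),
                      rr_exposure_alt = numeric(0), residual = numeric(0),
                      status = character(0)))
  }
  rows <- lapply(p_D_grid, function(p_D) {
    sol <- tryCatch(
      invert_marker_effects(p_M, rr_stratum0, rr_stratum1, p_D, d_prime),
      error = function(e) e)
    if (inherits(sol, "error")) {
      data.frame(maf = p_D, rr_disease = NA_real_, rr_exposure = NA_real_,
                 inv_rr_disease = NA_real_, inv_rr_exposure = NA_real_,
                 rr_exposure_alt = NA_real_, residual = NA_real_,
                 status = conditionMessage(sol))
    } else {
      data.frame(maf = p_D,
                 rr_disease = sol$rr_disease_causal,
                 rr_exposure = sol$rr_exposure_causal,
                 inv_rr_disease = 1 / sol$rr_disease_causal,
                 inv_rr_exposure = 1 / sol$rr_exposure_causal,
                 rr_exposure_alt = sol$rr_exposure_causal_alt,
                 residual = sol$residual,
                 status = if (!sol$identifiable) "non-identifiable"
                          else if (sol$converged) "ok" else "not-converged")
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
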