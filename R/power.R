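# Sample-size and power calculation for a multiplicative marker-by-exposure
# interaction in a case-control design, via the Wald test with expected
# Fisher information.
#
# The marker is carrier-coded (any copy of the risk allele) by default; with
# binary marker, exposure and outcome the logistic interaction model is
# saturated, so the expected-information variance of the interaction
# coefficient equals the classic sum of reciprocal cell probabilities over
# the eight (marker, exposure, status) cells.

#' Case-control design specification
#'
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param case_control_ratio controls per case.
#' @param exposure_prev population exposure prevalence.
#' @param disease_prev baseline disease risk (unexposed non-carrier), used
#'   to form the population cell probabilities from which the case-control
#'   cells are derived.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(alpha = 0.05, power = 0.8, case_control_ratio = 1,
                        exposure_prev = 0.5, disease_prev = 0.01) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            case_control_ratio > 0, exposure_prev > 0, exposure_prev < 1,
            disease_prev > 0, disease_prev < 1)
  structure(list(alpha = alpha, power = power,
                 case_control_ratio = case_control_ratio,
                 exposure_prev = exposure_prev,
                 disease_prev = disease_prev),
            class = "design_spec")
}

# Expected 2x2x2 case-control cell probabilities (marker carrier, exposure,
# case status) for a scenario.  Returns a named list with the 2x2x2 array
# `p` (dims carrier, exposure, status 0/1) and the interaction log-OR of
# the table.
cc_cell_probs <- function(joint, rr_disease, theta, design) {
  stopifnot(inherits(joint, "haplotype_joint"),
            inherits(design, "design_spec"))
  dip <- diploid_expansion(joint)          # 3x3, (causal dosage, marker dosage)
  pd <- rowSums(dip)                       # Pr(causal dosage)
  # exposure tied to causal dosage: Pr(X=1|d) = kappa * theta^d
  kappa <- design$exposure_prev / sum(pd * theta^(0:2))
  px1 <- kappa * theta^(0:2)
  if (any(px1 > 1)) {
    stop(sprintf(
      "degenerate cells: Pr(X=1 | causal dosage 2) = %g exceeds 1; lower exposure_prev or theta",
      max(px1)), call. = FALSE)
  }
  risk <- design$disease_prev * rr_disease^(0:2)
  if (any(risk > 1)) {
    stop(sprintf(
      "degenerate cells: disease risk %g exceeds 1 for causal dosage 2; lower disease_prev or rr_disease",
      max(risk)), call. = FALSE)
  }
  # population joint over (carrier, exposure, outcome)
  pop <- array(0, dim = c(2, 2, 2),
               dimnames = list(carrier = 0:1, exposure = 0:1, status = 0:1))
  for (d in 0:2) {
    for (m in 0:2) {
      pdm <- dip[d + 1, m + 1]
      if (pdm == 0) next
      carrier <- as.integer(m >= 1)
      for (x in 0:1) {
        pdx <- pdm * (if (x == 1) px1[d + 1] else 1 - px1[d + 1])
        pop[carrier + 1, x + 1, 2] <- pop[carrier + 1, x + 1, 2] +
          pdx * risk[d + 1]
        pop[carrier + 1, x + 1, 1] <- pop[carrier + 1, x + 1, 1] +
          pdx * (1 - risk[d + 1])
      }
    }
  }
  prev <- sum(pop[, , 2])
  fc <- 1 / (1 + design$case_control_ratio)   # sampling fraction of cases
  p <- array(0, dim = dim(pop), dimnames = dimnames(pop))
  p[, , 2] <- fc * pop[, , 2] / prev
  p[, , 1] <- (1 - fc) * pop[, , 1] / (1 - prev)
  if (any(p <= 0)) {
    stop("degenerate cells: some (marker, exposure, status) cell has zero expected probability",
         call. = FALSE)
  }
  or <- function(x) (x[2, 2] * x[1, 1]) / (x[1, 2] * x[2, 1])
  log_or_int <- log(or(p[, , 2]) / or(p[, , 1]))
  list(p = p, log_or_interaction = log_or_int)
}

#' Per-subject Fisher information for the interaction coefficient
#'
#' Builds the expected 2x2x2 (marker carrier, exposure, case status) cell
#' probabilities implied by the scenario, evaluates the expected information
#' matrix of the logistic model `status ~ carrier * exposure` at the cell
#' probabilities, and returns the reciprocal of the variance entry of the
#' interaction coefficient (per subject).
#'
#' @param joint a [haplotype_joint()] describing marker and causal variant.
#' @param rr_disease per-allele causal risk ratio on disease.
#' @param theta per-allele causal risk ratio on the exposure.
#' @param design a [design_spec()].
#' @return Per-subject information (scalar), with attributes `cells` (the
#'   2x2x2 expected probabilities) and `log_or_interaction` (the
#'   carrier-coded interaction log odds ratio of the expected table).
#' @export
interaction_information <- function(joint, rr_disease, theta,
                                    design = design_spec()) {
  cc <- cc_cell_probs(joint, rr_disease, theta, design)
  p <- cc$p
  info <- matrix(0, 4, 4)
  for (m in 0:1) {
    for (x in 0:1) {
      n_mx <- p[m + 1, x + 1, 1] + p[m + 1, x + 1, 2]
      mu <- p[m + 1, x + 1, 2] / n_mx
      z <- c(1, m, x, m * x)
      info <- info + n_mx * mu * (1 - mu) * tcrossprod(z)
    }
  }
  v <- solve(info)[4, 4]
  structure(1 / v, cells = p, log_or_interaction = cc$log_or_interaction)
}

#' Sample size to detect a multiplicative interaction
#'
#' Wald-test sample size for the marker-by-exposure interaction in a
#' case-control study: `n = (z_{1-alpha/2} + z_power)^2 /
#' (log(IR)^2 * info)` where `info` is the per-subject information from
#' [interaction_information()], rounded up.
#'
#' @param interaction_ratio the multiplicative interaction to detect
#'   (ratio of stratum-specific marker effects); must differ from 1.
#' @inheritParams interaction_information
#' @return A list of class `interaction_sample_size`: `n_total`, `n_cases`,
#'   `n_controls`, `per_subject_information` and the resolved `assumptions`.
#' @examples
#' j <- haplotypes_from_ld(0.2, 0.2, "r2", 0.8)
#' se <- stratum_marker_rrs(j, 1.1, 1.1)
#' sample_size_for_interaction(se$interaction_ratio, j, 1.1, 1.1)
#' @export
sample_size_for_interaction <- function(interaction_ratio, joint,
                                        rr_disease, theta,
                                        design = design_spec()) {
  if (!is.finite(interaction_ratio) || interaction_ratio <= 0) {
    stop("interaction_ratio must be a positive ratio", call. = FALSE)
  }
  if (interaction_ratio == 1) {
    stop("interaction_ratio = 1: no effect to detect, required sample size is infinite",
         call. = FALSE)
  }
  info <- interaction_information(joint, rr_disease, theta, design)
  zq <- stats::qnorm(1 - design$alpha / 2) + stats::qnorm(design$power)
  n <- ceiling(zq^2 / (log(interaction_ratio)^2 * as.numeric(info)))
  fc <- 1 / (1 + design$case_control_ratio)
  structure(list(n_total = n,
                 n_cases = ceiling(n * fc),
                 n_controls = n - ceiling(n * fc),
                 per_subject_information = as.numeric(info),
                 assumptions = c(
                   list(interaction_ratio = interaction_ratio,
                        marker_coding = "carrier"),
                   unclass(design))),
            class = "interaction_sample_size")
}

#' @export
print.interaction_sample_size <- function(x, ...) {
  cat(sprintf("Total subjects: %s (%s cases, %s controls)\n",
              format(x$n_total, big.mark = ",", scientific = FALSE),
              format(x$n_cases, big.mark = ",", scientific = FALSE),
              format(x$n_controls, big.mark = ",", scientific = FALSE)))
  cat(sprintf("Interaction ratio %.6g, alpha %.3g, power %.2f\n",
              x$assumptions$interaction_ratio, x$assumptions$alpha,
              x$assumptions$power))
  invisible(x)
}

#' Analytic power at a given sample size
#'
#' Power of the two-sided Wald test of the interaction coefficient at total
#' sample size `n`, under the same expected-information approximation as
#' [sample_size_for_interaction()].
#'
#' @param n total subjects (cases plus controls).
#' @inheritParams sample_size_for_interaction
#' @return Power in (0,1).
#' @export
interaction_power <- function(n, interaction_ratio, joint, rr_disease,
                              theta, design = design_spec()) {
  stopifnot(n > 0)
  info <- as.numeric(interaction_information(joint, rr_disease, theta,
                                             design))
  z <- sqrt(n * info) * abs(log(interaction_ratio))
  za <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm(z - za) + stats::pnorm(-z - za)
}
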