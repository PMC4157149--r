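# Forward bias calculator on the risk-ratio scale.
#
# All ratios are computed from unnormalized haplotype masses: the disease
# baseline and any exposure-stratum normalization cancel in the marker risk
# ratio, so outputs are invariant to rescaling the masses and carry no
# dependence on disease or exposure prevalence.

# Core ratio on raw (possibly unnormalized) masses m = c(DM, Dm, dM, dm):
# within each marker class, risk-weighted mass over unweighted mass.
marker_rr_masses <- function(masses, rr_disease) {
  dM <- masses[3]; DM <- masses[1]; dm <- masses[4]; Dm <- masses[2]
  m1 <- dM + DM
  m0 <- dm + Dm
  if (m1 <= 0 || m0 <= 0) {
    stop("empty marker class: marker risk ratio undefined", call. = FALSE)
  }
  unname(((dM + DM * rr_disease) / m1) / ((dm + Dm * rr_disease) / m0))
}

#' Risk-weighted haplotype masses
#'
#' Multiplies each haplotype cell by the per-allele disease risk ratio
#' raised to its causal-allele count: cell `(d, m)` carries
#' `joint(d, m) * rr_disease^d`.  The masses are proportional to
#' `Pr(Y=1, d, m)` relative to a baseline risk that cancels in every ratio,
#' so no normalization is applied.
#'
#' @param joint a [haplotype_joint()].
#' @param rr_disease per-allele risk ratio of the causal allele on disease;
#'   positive.
#' @return Named numeric vector of the four weighted masses.
#' @export
risk_weighted_masses <- function(joint, rr_disease) {
  stopifnot(inherits(joint, "haplotype_joint"))
  if (!is.finite(rr_disease) || rr_disease <= 0) {
    stop("rr_disease must be positive", call. = FALSE)
  }
  w <- unclass(joint)[1:4] * rr_disease^c(1, 1, 0, 0)
  attributes(w) <- list(names = names(unclass(joint)[1:4]))
  w
}

#' Per-allele marker risk ratio
#'
#' The risk ratio of the marker allele induced purely by its linkage
#' disequilibrium with the causal allele: the risk-weighted mass of each
#' marker class divided by its unweighted mass, compared between classes.
#'
#' @inheritParams risk_weighted_masses
#' @return A single risk ratio.
#' @examples
#' marker_rr(haplotype_joint(0.05, 0, 0.05, 0.9), rr_disease = 2)  # 1.5
#' @export
marker_rr <- function(joint, rr_disease) {
  stopifnot(inherits(joint, "haplotype_joint"))
  if (!is.finite(rr_disease) || rr_disease <= 0) {
    stop("rr_disease must be positive", call. = FALSE)
  }
  marker_rr_masses(as.numeric(joint)[1:4], rr_disease)
}

#' Per-allele marker risk ratio from the diploid genotype distribution
#'
#' Computes the marker risk ratio from the 3x3 diploid dosage distribution
#' under multiplicative per-allele risks, as the ratio of expected risks
#' between adjacent marker-dosage classes.  Under Hardy-Weinberg haplotype
#' draws this factorizes and equals the haploid [marker_rr()] for every
#' adjacent pair.
#'
#' @inheritParams risk_weighted_masses
#' @param dosage_pair which adjacent marker dosages to compare: `c(1, 0)`
#'   (default) or `c(2, 1)`.
#' @return A single risk ratio.
#' @export
marker_rr_diploid <- function(joint, rr_disease, dosage_pair = c(1, 0)) {
  dip <- diploid_expansion(joint)
  stopifnot(all(dosage_pair %in% 0:2), length(dosage_pair) == 2)
  # expected relative risk within a marker-dosage class: E[rr^d | m = g]
  erisk <- function(g) {
    col <- dip[, g + 1]
    sum(col * rr_disease^(0:2)) / sum(col)
  }
  erisk(dosage_pair[1]) / erisk(dosage_pair[2])
}

#' Stratum-specific marker risk ratios and the induced interaction
#'
#' Applies the exposure tilt to the haplotype masses (`joint * theta^d`,
#' unnormalized -- the normalization cancels) and computes the marker risk
#' ratio in the unexposed (untilted) and exposed (tilted) strata.  Their
#' ratio is the multiplicative marker-by-exposure interaction induced by
#' imperfect LD plus gene-environment dependence, even though the causal
#' variant itself has no interaction with the exposure.
#'
#' @inheritParams risk_weighted_masses
#' @param theta exposure risk ratio per causal allele; positive.
#' @return An object of class `stratum_effects`: list with `rr_unexposed`,
#'   `rr_exposed` and `interaction_ratio = rr_exposed / rr_unexposed`.
#' @examples
#' j <- haplotype_joint(0.05, 0, 0.05, 0.9)
#' stratum_marker_rrs(j, rr_disease = 2, theta = 1.5)  # 1.5, 1.6
#' @export
stratum_marker_rrs <- function(joint, rr_disease, theta) {
  stopifnot(inherits(joint, "haplotype_joint"))
  if (!is.finite(theta) || theta <= 0) {
    stop("theta must be positive", call. = FALSE)
  }
  m <- as.numeric(joint)[1:4]
  rr0 <- marker_rr_masses(m, rr_disease)
  rr1 <- marker_rr_masses(m * theta^c(1, 1, 0, 0), rr_disease)
  structure(list(rr_unexposed = rr0, rr_exposed = rr1,
                 interaction_ratio = rr1 / rr0),
            class = "stratum_effects")
}

#' @export
print.stratum_effects <- function(x, ...) {
  cat(sprintf("Marker RR: %.6g (unexposed), %.6g (exposed); interaction ratio %.8g\n",
              x$rr_unexposed, x$rr_exposed, x$interaction_ratio))
  invisible(x)
}
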