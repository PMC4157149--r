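# Shared fixtures, built in code.

# Worked example: marker MAF 0.1, causal allele on half the minor-marker
# chromosomes and nowhere else (causal MAF 0.05, D' = 1).
table1_joint <- function() haplotype_joint(0.05, 0, 0.05, 0.9)

# GWAS-scale scenario: both MAFs 0.2, r2 = 0.8, positive association.
gwas_joint <- function() haplotypes_from_ld(0.2, 0.2, "r2", 0.8)

# Observed stratum marker effects for the CYP3A / age-at-menarche example:
# baseline (untilted) stratum is menarche > 12 (OR 0.906), tilted is <= 12.
cyp3a <- list(p_M = 0.09, rr0 = 0.906, rr1 = 0.979)

# Random feasible (p_D, p_M, D') triples and the implied joint.
random_joint <- function() {
  p_D <- runif(1, 0.02, 0.6)
  p_M <- runif(1, 0.02, 0.6)
  dp <- runif(1, -0.95, 0.95)
  list(p_D = p_D, p_M = p_M, d_prime = dp,
       joint = haplotypes_from_ld(p_D, p_M, "dprime", dp))
}

# Random feasible joint with positive LD strong enough that inversion of
# stratum effects is well conditioned.
random_positive_joint <- function() {
  p_D <- runif(1, 0.03, 0.4)
  p_M <- runif(1, 0.03, 0.4)
  dp <- runif(1, 0.3, 1)
  list(p_D = p_D, p_M = p_M, d_prime = dp,
       joint = haplotypes_from_ld(p_D, p_M, "dprime", dp))
}
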