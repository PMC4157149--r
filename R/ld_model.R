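# Haplotype-frequency algebra for a biallelic causal variant D and a
# biallelic marker M.  The haploid (allele-level) joint distribution is the
# canonical representation throughout the package; diploid genotype views
# are derived under Hardy-Weinberg equilibrium, never stored.

#' Construct a haplotype joint distribution
#'
#' Joint distribution of the alleles carried on one chromosome at an
#' unmeasured causal locus (allele `D` vs `d`) and a genotyped marker locus
#' (allele `M` vs `m`).  The four masses are the frequencies of the
#' haplotypes `DM`, `Dm`, `dM` and `dm`, where upper case denotes the risk
#' (minor) allele.
#'
#' @param h_DM,h_Dm,h_dM,h_dm haplotype frequencies; non-negative, summing
#'   to 1 within `1e-9`.
#' @return An object of class `haplotype_joint`: a named numeric vector of
#'   the four masses with attributes `p_D` and `p_M` (allele frequencies of
#'   the causal and marker risk alleles).
#' @examples
#' # causal allele on half the minor-marker chromosomes, nowhere else
#' haplotype_joint(0.05, 0, 0.05, 0.9)
#' @export
haplotype_joint <- function(h_DM, h_Dm, h_dM, h_dm) {
  h <- c(h_DM = h_DM, h_Dm = h_Dm, h_dM = h_dM, h_dm = h_dm)
  if (any(!is.finite(h))) {
    stop("haplotype masses must be finite numbers", call. = FALSE)
  }
  if (any(h < 0)) {
    stop("haplotype masses must be non-negative, got: ",
         paste(sprintf("%s=%g", names(h)[h < 0], h[h < 0]), collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(h) - 1) > 1e-9) {
    stop(sprintf("haplotype masses must sum to 1 (got %.12g); not rescaling",
                 sum(h)), call. = FALSE)
  }
  structure(h,
            p_D = unname(h["h_DM"] + h["h_Dm"]),
            p_M = unname(h["h_DM"] + h["h_dM"]),
            class = "haplotype_joint")
}

#' @export
print.haplotype_joint <- function(x, ...) {
  cat("Haplotype joint distribution (causal D x marker M)\n")
  print(unclass(x)[1:4])
  cat(sprintf("p_D = %.6g, p_M = %.6g\n", attr(x, "p_D"), attr(x, "p_M")))
  invisible(x)
}

# Fréchet bounds on the DM haplotype mass given the two allele frequencies.
frechet_bounds <- function(p_D, p_M) {
  c(lower = max(0, p_D + p_M - 1), upper = min(p_D, p_M))
}

# Normalizing constant for D': the sign-appropriate extreme of delta.
dmax_for <- function(delta, p_D, p_M) {
  if (delta >= 0) {
    min(p_D * (1 - p_M), (1 - p_D) * p_M)
  } else {
    min(p_D * p_M, (1 - p_D) * (1 - p_M))
  }
}

#' Build a haplotype joint from allele frequencies and an LD measure
#'
#' Inverts either D' or r-squared to the haplotype scale:
#' `h_DM = p_D * p_M + delta`.  Because r-squared is sign-blind, that route
#' requires an explicit sign; positive delta means the causal allele is
#' enriched on the minor-marker background.
#'
#' @param p_D,p_M allele frequencies of the causal and marker risk alleles,
#'   both in (0,1).
#' @param measure `"dprime"` or `"r2"`.
#' @param value the LD value: D' in `[-1,1]` (carries its own sign) or
#'   r-squared in `[0,1]`.
#' @param sign `"+"` or `"-"`; direction of the allelic association, used
#'   only for the r-squared route.
#' @return A [haplotype_joint()].
#' @examples
#' haplotypes_from_ld(0.05, 0.1, "dprime", 1)
#' haplotypes_from_ld(0.2, 0.2, "r2", 0.8)
#' @export
haplotypes_from_ld <- function(p_D, p_M, measure = c("dprime", "r2"),
                               value, sign = "+") {
  measure <- match.arg(measure)
  stopifnot(length(p_D) == 1, length(p_M) == 1, length(value) == 1)
  if (!is.finite(p_D) || p_D <= 0 || p_D >= 1 ||
      !is.finite(p_M) || p_M <= 0 || p_M >= 1) {
    stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!sign %in% c("+", "-")) stop("sign must be '+' or '-'", call. = FALSE)
  sgn <- if (sign == "+") 1 else -1

  if (measure == "dprime") {
    if (abs(value) > 1) {
      stop("D' must lie in [-1, 1]", call. = FALSE)
    }
    delta <- value * dmax_for(value, p_D, p_M)
  } else {
    if (value < 0 || value > 1) {
      stop("r-squared must lie in [0, 1]", call. = FALSE)
    }
    denom <- p_D * (1 - p_D) * p_M * (1 - p_M)
    delta <- sgn * sqrt(value * denom)
    # feasibility: delta cannot exceed its sign-appropriate extreme
    dmax <- dmax_for(delta, p_D, p_M)
    if (abs(delta) > dmax + 1e-12) {
      r2_max <- dmax^2 / denom
      stop(sprintf(paste0(
        "infeasible LD: r2 = %g with sign '%s' requires |delta| = %g, but ",
        "the Frechet bound on h_DM caps |delta| at %g (max feasible r2 = %g ",
        "for p_D = %g, p_M = %g)"),
        value, sign, abs(delta), dmax, r2_max, p_D, p_M), call. = FALSE)
    }
    delta <- max(-dmax, min(dmax, delta))  # snap boundary roundoff only
  }

  h_DM <- p_D * p_M + delta
  fb <- frechet_bounds(p_D, p_M)
  if (h_DM < fb["lower"] - 1e-12 || h_DM > fb["upper"] + 1e-12) {
    stop(sprintf(paste0(
      "infeasible haplotype mass: h_DM = %g violates the Frechet bounds ",
      "[%g, %g] for p_D = %g, p_M = %g"),
      h_DM, fb["lower"], fb["upper"], p_D, p_M), call. = FALSE)
  }
  h_DM <- max(fb["lower"], min(fb["upper"], h_DM))
  haplotype_joint(h_DM, p_D - h_DM, p_M - h_DM, 1 - p_D - p_M + h_DM)
}

#' Linkage-disequilibrium statistics of a haplotype joint
#'
#' @param joint a [haplotype_joint()].
#' @return An object of class `ld_stats`: list with `delta` (covariance-scale
#'   LD coefficient), `d_prime` (normalized, in `[-1,1]`) and `r2` (squared
#'   allelic correlation).
#' @examples
#' ld_stats(haplotype_joint(0.05, 0, 0.05, 0.9))  # D' = 1, r2 = 0.474
#' @export
ld_stats <- function(joint) {
  stopifnot(inherits(joint, "haplotype_joint"))
  p_D <- attr(joint, "p_D")
  p_M <- attr(joint, "p_M")
  if (p_D <= 0 || p_D >= 1 || p_M <= 0 || p_M >= 1) {
    stop("LD is undefined when either locus is monomorphic", call. = FALSE)
  }
  delta <- unname(joint["h_DM"]) - p_D * p_M
  d_prime <- if (delta == 0) 0 else delta / dmax_for(delta, p_D, p_M)
  r2 <- delta^2 / (p_D * (1 - p_D) * p_M * (1 - p_M))
  structure(list(delta = delta, d_prime = d_prime, r2 = r2),
            class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: delta = %.6g, D' = %.6g, r2 = %.6g\n",
              x$delta, x$d_prime, x$r2))
  invisible(x)
}

#' Expand a haplotype joint to diploid genotype dosages
#'
#' Two haplotypes are drawn independently (Hardy-Weinberg equilibrium at the
#' haplotype level), giving the joint distribution of causal-allele dosage
#' and marker-allele dosage.
#'
#' @param joint a [haplotype_joint()].
#' @return A 3x3 matrix of probabilities; rows are causal dosage 0/1/2,
#'   columns marker dosage 0/1/2.  Marginals are HWE at each locus.
#' @export
diploid_expansion <- function(joint) {
  stopifnot(inherits(joint, "haplotype_joint"))
  # haplotype index -> (d, m) allele pair
  d_al <- c(1, 1, 0, 0)
  m_al <- c(1, 0, 1, 0)
  p <- as.numeric(joint)[1:4]
  out <- matrix(0, 3, 3, dimnames = list(causal = 0:2, marker = 0:2))
  for (i in 1:4) {
    for (j in 1:4) {
      out[d_al[i] + d_al[j] + 1, m_al[i] + m_al[j] + 1] <-
        out[d_al[i] + d_al[j] + 1, m_al[i] + m_al[j] + 1] + p[i] * p[j]
    }
  }
  out
}

#' Read and write haplotype joints
#'
#' Serializes the four haplotype masses to a single-record TSV (header plus
#' one data row) or a JSON object keyed by `h_DM`, `h_Dm`, `h_dM`, `h_dm`.
#'
#' @param joint a [haplotype_joint()].
#' @param path file path; format inferred from the extension (`.json` vs
#'   anything else = TSV) unless `format` is given.
#' @param format `"tsv"` or `"json"`.
#' @return `write_haplotypes` returns `path` invisibly; `read_haplotypes`
#'   returns a [haplotype_joint()].
#' @export
write_haplotypes <- function(joint, path, format = NULL) {
  stopifnot(inherits(joint, "haplotype_joint"))
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  x <- as.list(unclass(joint)[1:4])
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(x)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  x <- if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    as.list(utils::read.delim(path, check.names = FALSE))
  }
  need <- c("h_DM", "h_Dm", "h_dM", "h_dm")
  if (!all(need %in% names(x))) {
    stop("haplotype record must contain fields h_DM, h_Dm, h_dM, h_dm",
         call. = FALSE)
  }
  haplotype_joint(x$h_DM, x$h_Dm, x$h_dM, x$h_dm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
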