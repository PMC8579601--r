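#' Per-variant association of a residualized trait
#'
#' Simple linear regression of the residualized trait on allele dosage,
#' one variant at a time, with two-sided p-values from the t reference
#' with n − 2 degrees of freedom. Betas are oriented to the a1 (effect)
#' allele. Monomorphic variants (zero dosage variance among complete
#' cases) are emitted with missing statistics and a `monomorphic` flag
#' rather than dropped. Per-variant missing dosages are handled
#' complete-case.
#'
#' This is the deliberate desk-scale stand-in for a mixed-model GWAS: on
#' unrelated samples with the trait pre-residualized on covariates, OLS and
#' the mixed model coincide in expectation.
#'
#' @param residuals data.frame (participant_id, residual), e.g. from
#'   [residualize()].
#' @param genotypes a `genotype_matrix` (see [simulate_genotypes()] or
#'   [read_genotypes()]); samples are matched to `residuals` by id.
#' @param stratum label recorded in the output
#'   (`"combined"`, `"male"`, `"female"`).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @return data.frame with one row per variant: stratum, chrom, pos,
#'   variant_id, a1, a0, a1_freq, beta, se, p, n,
#'   genome_wide_significant, flag.
#' @export
run_assoc <- function(residuals, genotypes, stratum = "combined",
                      p_threshold = 5e-8) {
  .assert(inherits(genotypes, "genotype_matrix"),
          "genotypes must be a genotype_matrix")
  ids <- intersect(residuals$participant_id, colnames(genotypes$dosage))
  .assert(length(ids) >= 3, "fewer than 3 overlapping samples")
  y <- residuals$residual[match(ids, residuals$participant_id)]
  G <- genotypes$dosage[, ids, drop = FALSE]
  map <- genotypes$map
  nv <- nrow(G)

  beta <- se <- p <- freq <- rep(NA_real_, nv)
  nobs <- integer(nv)
  flag <- character(nv)
  for (v in seq_len(nv)) {
    g <- G[v, ]
    ok <- !is.na(g) & !is.na(y)
    n <- sum(ok)
    nobs[v] <- n
    if (n < 3) { flag[v] <- "too_few_calls"; next }
    gv <- g[ok]; yv <- y[ok]
    freq[v] <- mean(gv) / 2
    sxx <- sum((gv - mean(gv))^2)
    if (sxx == 0) { flag[v] <- "monomorphic"; next }
    b1 <- sum((gv - mean(gv)) * (yv - mean(yv))) / sxx
    res <- yv - mean(yv) - b1 * (gv - mean(gv))
    s2 <- sum(res^2) / (n - 2)
    beta[v] <- b1
    se[v] <- sqrt(s2 / sxx)
    p[v] <- 2 * pt(-abs(b1 / se[v]), df = n - 2)
  }
  data.frame(stratum = stratum, chrom = map$chrom, pos = map$pos,
             variant_id = map$variant_id, a1 = map$a1, a0 = map$a0,
             a1_freq = freq, beta = beta, se = se, p = p, n = nobs,
             genome_wide_significant = !is.na(p) & p < p_threshold,
             flag = flag, stringsAsFactors = FALSE)
}
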