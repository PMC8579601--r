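#' Pairwise LD between two variants
#'
#' Squared Pearson correlation of allele dosages in the reference sample.
#' Undefined (NA) when either variant is monomorphic.
#'
#' @param genotypes a `genotype_matrix`.
#' @param i,j variant ids (or row indices) of the pair.
#' @return r-squared in `[0, 1]`, or NA.
#' @export
ld_r2 <- function(genotypes, i, j) {
  g1 <- genotypes$dosage[i, ]
  g2 <- genotypes$dosage[j, ]
  ok <- !is.na(g1) & !is.na(g2)
  if (sd(g1[ok]) == 0 || sd(g2[ok]) == 0) return(NA_real_)
  cor(g1[ok], g2[ok])^2
}

#' P-value-informed greedy LD clumping
#'
#' Reduces association results to independent signals: variants below the
#' significance threshold are visited in ascending p-value order (ties
#' broken by chromosome, position, then variant id); each still-unassigned
#' variant seeds a clump and absorbs every unassigned significant variant
#' on the same chromosome within the window whose dosage correlation with
#' the index reaches the r-squared threshold. Defaults follow the PLINK
#' convention: r-squared 0.2 or greater within +/- 500 kb of the index.
#'
#' Variants absent from the LD reference genotypes cannot be clumped; they
#' are excluded and listed separately in `unavailable`.
#'
#' @param assoc association table from [run_assoc()] (needs variant_id,
#'   chrom, pos, p).
#' @param genotypes a `genotype_matrix` serving as the LD reference.
#' @param p_threshold clumping significance threshold (default 5e-8).
#' @param r2_threshold minimum r-squared with the index (default 0.2).
#' @param window_kb half-window around the index in kb (default 500).
#' @return object of class `clump_result`: list with `clumps` (list of
#'   per-clump lists: index_variant, chrom, span, members data.frame with
#'   r2), `summary` (one row per clump) and `unavailable` (variant ids not
#'   in the reference). Empty when nothing is significant.
#' @export
greedy_clump <- function(assoc, genotypes, p_threshold = 5e-8,
                         r2_threshold = 0.2, window_kb = 500) {
  sig <- assoc[!is.na(assoc$p) & assoc$p < p_threshold, , drop = FALSE]
  unavailable <- setdiff(sig$variant_id, rownames(genotypes$dosage))
  sig <- sig[!sig$variant_id %in% unavailable, , drop = FALSE]
  empty <- list(clumps = list(),
                summary = data.frame(index_variant = character(),
                                     chrom = integer(), span_lo = integer(),
                                     span_hi = integer(), n_members = integer(),
                                     p_index = numeric()),
                unavailable = unavailable)
  class(empty) <- "clump_result"
  if (nrow(sig) == 0) return(empty)

  sig <- sig[order(sig$p, sig$chrom, sig$pos, sig$variant_id), , drop = FALSE]
  assigned <- rep(FALSE, nrow(sig))
  clumps <- list()
  for (k in seq_len(nrow(sig))) {
    if (assigned[k]) next
    idx <- sig[k, ]
    assigned[k] <- TRUE
    cand <- which(!assigned & sig$chrom == idx$chrom &
                    abs(sig$pos - idx$pos) <= window_kb * 1000)
    member_rows <- integer()
    r2s <- numeric()
    for (m in cand) {
      r2 <- ld_r2(genotypes, idx$variant_id, sig$variant_id[m])
      if (!is.na(r2) && r2 >= r2_threshold) {
        assigned[m] <- TRUE
        member_rows <- c(member_rows, m)
        r2s <- c(r2s, r2)
      }
    }
    members <- data.frame(variant_id = sig$variant_id[member_rows],
                          p = sig$p[member_rows], r2 = r2s,
                          stringsAsFactors = FALSE)
    span <- range(c(idx$pos, sig$pos[member_rows]))
    clumps[[length(clumps) + 1]] <-
      list(index_variant = idx$variant_id, chrom = idx$chrom,
           p_index = idx$p, span = span, members = members)
  }
  summary <- data.frame(
    index_variant = vapply(clumps, `[[`, character(1), "index_variant"),
    chrom = vapply(clumps, `[[`, numeric(1), "chrom"),
    span_lo = vapply(clumps, function(cl) cl$span[1], numeric(1)),
    span_hi = vapply(clumps, function(cl) cl$span[2], numeric(1)),
    n_members = vapply(clumps, function(cl) nrow(cl$members), integer(1)),
    p_index = vapply(clumps, `[[`, numeric(1), "p_index"),
    stringsAsFactors = FALSE)
  structure(list(clumps = clumps, summary = summary,
                 unavailable = unavailable), class = "clump_result")
}
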