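# Independent oracles and small fixture builders shared across tests.

# Explicit normal-equations OLS: beta = (X'X)^-1 X'y with an intercept.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  list(beta = unname(as.numeric(beta)), se = unname(as.numeric(se)),
       p_slope = unname(2 * pt(-abs(beta[2] / se[2]), n - 2)))
}

# Straightforward reference clumper, written independently of the package
# implementation: repeated scans for the best remaining p-value, pairwise
# r2 by plain correlation.
oracle_clump <- function(assoc, geno, p_thr = 5e-8, r2_thr = 0.2, kb = 500) {
  d <- assoc[!is.na(assoc$p) & assoc$p < p_thr, ]
  d <- d[d$variant_id %in% rownames(geno$dosage), ]
  taken <- character()
  out <- list()
  while (nrow(d) > 0) {
    # best p, ties by chrom then pos then id
    best <- d
    best <- best[best$p == min(best$p), ]
    best <- best[best$chrom == min(best$chrom), ]
    best <- best[best$pos == min(best$pos), ]
    best <- best[order(best$variant_id), ][1, ]
    members <- character()
    for (k in seq_len(nrow(d))) {
      v <- d[k, ]
      if (v$variant_id == best$variant_id) next
      if (v$chrom != best$chrom) next
      if (abs(v$pos - best$pos) > kb * 1000) next
      r2 <- cor(geno$dosage[best$variant_id, ], geno$dosage[v$variant_id, ])^2
      if (!is.na(r2) && r2 >= r2_thr) members <- c(members, v$variant_id)
    }
    out[[length(out) + 1]] <- list(index = best$variant_id,
                                   members = sort(members))
    d <- d[!d$variant_id %in% c(best$variant_id, members), ]
  }
  out
}

# Quiet simulation settings used where determinism of session content
# matters (no noise, no artefacts, ramp-only cohort).
quiet_config <- function(...) {
  sim_config(hr_noise_sd = 0, spike_prob = 0, cadence_out_prob = 0,
             bike_other_prob = 0,
             risk_probs = c(minimal = 0.5, small = 0.5, medium = 0, high = 0),
             ...)
}

# A hand-built exercise session: `wl` workload vector, optional heart rate
# and cadence; defaults make HR linear in workload.
make_session <- function(wl, hr = 60 + 0.4 * wl, cadence = 60,
                         pid = "P000001") {
  data.frame(participant_id = pid, phase = "exercise",
             trend = seq_along(wl), heart_rate = hr, workload = wl,
             cadence = rep_len(cadence, length(wl)),
             stringsAsFactors = FALSE)
}

# Random clumping instance: LD-blocked genotypes plus synthetic p-values
# concentrated below the threshold so several clumps form.
clump_instance <- function(seed, n_variants = 50, n_samples = 120) {
  geno <- simulate_genotypes(n_samples, n_variants, max(2, n_variants %/% 10),
                             seed = seed, copy_prob = 0.9, n_chrom = 3)
  set.seed(seed + 1000)
  p <- 10^runif(n_variants, -12, -4)
  assoc <- data.frame(stratum = "combined", chrom = geno$map$chrom,
                      pos = geno$map$pos, variant_id = geno$map$variant_id,
                      p = p, stringsAsFactors = FALSE)
  list(geno = geno, assoc = assoc)
}

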