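test_that("cohort simulation is deterministic and validates its inputs", {
  a <- simulate_cohort(10, seed = 1)
  b <- simulate_cohort(10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a$cohort, simulate_cohort(10, seed = 2)$cohort))
  expect_error(simulate_cohort(0, seed = 1), "n must be")
  expect_error(sim_config(risk_probs = c(minimal = 0.9, small = 0.9,
                                         medium = 0, high = 0)),
               "proper distribution")
  expect_false(anyDuplicated(a$cohort$participant_id) > 0)
  expect_true(all(a$cohort$age >= 40 & a$cohort$age <= 69))
  expect_true(all(a$cohort$weight > 0))
})

test_that("configured age distribution and analytic truth are honoured", {
  sim <- simulate_cohort(1000, seed = 7)
  se <- (29 / sqrt(12)) / sqrt(1000)  # SD of Uniform(40, 69) over sqrt(n)
  expect_lt(abs(mean(sim$cohort$age) - 54.5), 3 * se)
  with(merge(sim$cohort, sim$truth), {
    expect_equal(true_vo2max,
                 ((208 - 0.7 * age) - hr_rest) / hr_per_watt / weight)
    expect_true(all(is.finite(true_vo2max) & true_vo2max > 0))
  })
})

test_that("noiseless sessions have exactly linear heart rate and a compliant protocol", {
  cfg <- quiet_config()
  sim <- simulate_cohort(4, seed = 3, cfg)
  for (i in seq_len(4)) {
    ses <- simulate_ergo_session(sim$cohort[i, ], sim$truth[i, ], seed = i,
                                 config = cfg)
    ex <- ses[ses$phase == "exercise", ]
    expect_gte(nrow(ex), 20)
    expect_equal(ex$heart_rate,
                 sim$truth$hr_rest[i] + sim$truth$hr_per_watt[i] * ex$workload)
    # 2-min constant segment then strictly increasing ramp
    n_const <- sum(ex$workload == ex$workload[1])
    expect_equal(n_const, round(120 / cfg$sampling_interval))
    ramp <- ex$workload[(n_const + 1):nrow(ex)]
    expect_true(all(diff(ramp) > 0))
    expect_true(all(diff(ex$trend) == 1))
  }
  # medium risk: constant workload throughout the exercise phase
  cfgm <- sim_config(hr_noise_sd = 0, spike_prob = 0, cadence_out_prob = 0,
                     risk_probs = c(minimal = 0, small = 0, medium = 1,
                                    high = 0))
  simm <- simulate_cohort(1, seed = 5, cfgm)
  sesm <- simulate_ergo_session(simm$cohort[1, ], simm$truth[1, ], seed = 1,
                                config = cfgm)
  exm <- sesm[sesm$phase == "exercise", ]
  expect_equal(var(exm$workload), 0)
  bad <- simm$cohort[1, ]; bad$risk_category <- "unknown"
  expect_error(simulate_ergo_session(bad, simm$truth[1, ], 1, cfgm),
               "unknown risk")
})

test_that("spike artefact frequency matches the configured probability", {
  cfg <- sim_config(hr_noise_sd = 0, spike_prob = 0.05, cadence_out_prob = 0,
                    risk_probs = c(minimal = 1, small = 0, medium = 0,
                                   high = 0))
  sim <- simulate_cohort(50, seed = 11, cfg)
  n_spike <- 0; n_tot <- 0
  for (i in seq_len(50)) {
    ses <- simulate_ergo_session(sim$cohort[i, ], sim$truth[i, ], seed = i,
                                 config = cfg)
    ex <- ses[ses$phase == "exercise", ]
    dev <- abs(ex$heart_rate -
                 (sim$truth$hr_rest[i] + sim$truth$hr_per_watt[i] * ex$workload))
    n_spike <- n_spike + sum(dev > 1e-9)
    n_tot <- n_tot + nrow(ex)
  }
  p_hat <- n_spike / n_tot
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("genotype generator spans the LD limits and recovers allele frequencies", {
  # perfect copying: adjacent variants within a block in complete LD
  g1 <- simulate_genotypes(150, 12, 3, seed = 21, copy_prob = 1)
  for (b in unique(g1$map$block)) {
    idx <- which(g1$map$block == b)
    for (k in seq_along(idx)[-1])
      expect_equal(ld_r2(g1, idx[k - 1], idx[k]), 1)
  }
  # no copying: near-independent variants
  g0 <- simulate_genotypes(300, 30, 1, seed = 22, copy_prob = 0)
  r2s <- c()
  for (i in 1:29) r2s <- c(r2s, ld_r2(g0, i, i + 1))
  expect_lt(mean(r2s), 0.02)  # E[r2] ~ 1/(n-1) under independence
  # explicit allele frequency is recovered
  g3 <- simulate_genotypes(500, 1, 1, seed = 23, copy_prob = 0,
                           maf = 0.3)
  freq <- mean(g3$dosage) / 2
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 500)))
  # structural invariants
  expect_true(all(g1$dosage %in% 0:2))
  for (ch in unique(g1$map$chrom))
    expect_true(all(diff(g1$map$pos[g1$map$chrom == ch]) > 0))
  expect_error(simulate_genotypes(10, 5, 6, seed = 1), "n_blocks")
  expect_error(simulate_genotypes(10, 5, 2, maf_range = c(0, 0.6), seed = 1),
               "maf_range")
  expect_identical(simulate_genotypes(50, 10, 2, seed = 9),
                   simulate_genotypes(50, 10, 2, seed = 9))
})

test_that("planted genetic and disease effects propagate into the phenotypes", {
  sim <- simulate_cohort(2000, seed = 31)
  geno <- simulate_genotypes(2000, 10, 10, seed = 31, copy_prob = 0)
  colnames(geno$dosage) <- sim$cohort$participant_id
  causal <- data.frame(variant_id = "var00001", beta_male = 0.3,
                       beta_female = 0.3)
  out <- simulate_phenotypes_and_outcomes(sim$cohort, geno, sim$truth,
                                          seed = 31, causal = causal)
  fit <- summary(lm(out$phenotypes$sim_trait ~
                      geno$dosage["var00001", ] + sim$cohort$sex +
                      sim$cohort$age))
  est <- fit$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 0.3), 4 * est["Std. Error"])

  expect_error(
    simulate_phenotypes_and_outcomes(sim$cohort, geno, sim$truth, seed = 1,
                                     causal = data.frame(variant_id = "nope",
                                                         beta_male = 1,
                                                         beta_female = 1)),
    "absent from genotype matrix")

  # deterministic given the seed
  out2 <- simulate_phenotypes_and_outcomes(sim$cohort, geno, sim$truth,
                                           seed = 31, causal = causal)
  expect_identical(out, out2)

  # null disease slope: diagnosis frequency flat across trait deciles
  cfg0 <- sim_config(disease_slope = 0)
  sim0 <- simulate_cohort(5000, seed = 33, cfg0)
  out0 <- simulate_phenotypes_and_outcomes(sim0$cohort, geno, sim0$truth,
                                           seed = 33, config = cfg0,
                                           code_map = default_code_map()["CAD"])
  dec <- assign_deciles(data.frame(participant_id = sim0$cohort$participant_id,
                                   residual = out0$phenotypes$sim_trait))
  hits <- tapply(out0$disease[, "CAD"], dec$decile, sum)
  ns <- tapply(out0$disease[, "CAD"], dec$decile, length)
  tt <- prop.trend.test(hits, ns)
  expect_gt(tt$p.value, 0.05)
})
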