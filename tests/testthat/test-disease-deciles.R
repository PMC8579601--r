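resid_df <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%06d", 1:n), residual = rnorm(n),
             stringsAsFactors = FALSE)
}

test_that("decile groups are balanced and deterministic", {
  d100 <- assign_deciles(resid_df(100))
  expect_equal(as.integer(table(d100$decile)), rep(10L, 10))
  d105 <- assign_deciles(resid_df(105))
  sizes <- as.integer(table(d105$decile))
  expect_equal(sort(sizes), c(rep(10L, 5), rep(11L, 5)))
  expect_true(max(sizes) - min(sizes) <= 1)
  # decile 1 holds the lowest values
  expect_lt(max(d105$residual[d105$decile == 1]),
            min(d105$residual[d105$decile == 10]))
  expect_error(assign_deciles(resid_df(9)), "at least 10")
})

test_that("tied phenotypes break by participant id, independent of input order", {
  d <- resid_df(40)
  d$residual <- rep(c(1, 2), 20)  # heavy ties
  base <- assign_deciles(d)
  set.seed(2)
  perm <- assign_deciles(d[sample(40), ])
  m <- merge(base, perm, by = "participant_id")
  expect_equal(m$decile.x, m$decile.y)
  # sort-based oracle: order by (residual, id), then chunk
  ord <- order(d$residual, d$participant_id)
  expect_equal(base$decile[ord], rep(1:10, each = 4))
})

test_that("diagnosis frequencies count each participant once per disease group", {
  d <- resid_df(100)
  d <- assign_deciles(d)
  d$sex <- rep(c("male", "female"), 50)
  # no diagnoses: all frequencies zero
  empty <- data.frame(participant_id = character(), icd10_code = character())
  f0 <- disease_frequency(d, empty)
  expect_true(all(f0$frequency == 0))
  expect_true(all(f0$n_in_decile > 0))
  # everyone diagnosed (with repeats): all frequencies one for that group
  dx <- data.frame(participant_id = rep(d$participant_id, 2),
                   icd10_code = "I21")
  f1 <- disease_frequency(d, dx)
  cad <- f1[f1$disease_group == "CAD", ]
  expect_true(all(cad$frequency == 1))
  expect_true(all(f1$frequency[f1$disease_group != "CAD"] == 0))
  # denominator conservation within each sex and group
  agg <- aggregate(cbind(n_in_decile, n_diagnosed) ~ sex + disease_group,
                   f1, sum)
  expect_true(all(agg$n_in_decile == 50))
  expect_equal(agg$n_diagnosed[agg$disease_group == "CAD"], c(50, 50))
  # unmapped codes warn and are counted
  dxu <- rbind(dx, data.frame(participant_id = d$participant_id[1],
                              icd10_code = "Z99"))
  expect_warning(fu <- disease_frequency(d, dxu), "matched no disease group")
  expect_equal(attr(fu, "n_unmapped"), 1)
})

test_that("the default ICD-10 map routes codes to the expected groups", {
  map <- default_code_map()
  codes <- c("I219", "I60", "G30", "C34", "J449", "J12", "C18", "E11",
             "N18", "C50")
  got <- ergogwas:::.match_code_group(codes, map)
  expect_equal(got, c("CAD", "STR", "ALZ", "LCX", "COPD", "LRTI", "CCX",
                      "DIA", "KID", "BCX"))
  expect_true(is.na(ergogwas:::.match_code_group("I10", map)))  # hypertension unmapped
})

test_that("a planted liability gradient produces decreasing decile frequencies", {
  cfg <- sim_config(disease_slope = -0.5)
  sim <- simulate_cohort(5000, seed = 41, cfg)
  out <- simulate_phenotypes_and_outcomes(sim$cohort, NULL, sim$truth,
                                          seed = 41, config = cfg,
                                          code_map = default_code_map()["CAD"])
  dec <- list()
  for (sx in c("male", "female")) {
    idx <- sim$cohort$sex == sx
    dd <- assign_deciles(data.frame(
      participant_id = sim$cohort$participant_id[idx],
      residual = out$phenotypes$sim_trait[idx]))
    dd$sex <- sx
    dec[[sx]] <- dd
  }
  freq <- disease_frequency(do.call(rbind, dec), out$diagnoses,
                            code_map = default_code_map()["CAD"])
  rho <- cor(freq$decile, freq$frequency, method = "spearman")
  expect_lt(rho, 0)
  # top decile should be substantially healthier than the bottom
  expect_lt(mean(freq$frequency[freq$decile == 10]),
            mean(freq$frequency[freq$decile == 1]))
})
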