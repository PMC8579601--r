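#' Simulation configuration
#'
#' Collects every tunable of the synthetic cohort generator with defaults
#' chosen to emulate a UK-Biobank-like study population: ages uniform on
#' 40–69 years, four exercise-test risk categories with a small 'high' tail,
#' a linear heart-rate/workload response per participant, AR(1) beat-to-beat
#' noise with occasional spike artefacts, cadence centred on the instructed
#' 60 RPM, LD-blocked genotypes, and logistic disease liability driven by a
#' planted quantitative trait.
#'
#' @param age_range numeric length 2, years; participants drawn uniformly.
#' @param risk_probs named probabilities for risk categories
#'   `minimal`, `small`, `medium`, `high` (must sum to 1).
#' @param n_centres number of assessment centres.
#' @param bike_other_prob probability a session used a non-bicycle method
#'   (such sessions are excluded downstream).
#' @param hr_rest_mean,hr_rest_sd resting heart rate distribution (bpm).
#' @param hr_per_watt_mean,hr_per_watt_sd heart-rate response slope
#'   distribution (bpm per watt), truncated to stay positive.
#' @param sampling_interval seconds between trace observations (default 4 s,
#'   giving ~90 exercise-phase observations over the 6-min exercise phase).
#' @param phase_durations named seconds for `pretest`, `exercise`,
#'   `recovery` (defaults 15, 360, 60).
#' @param hr_noise_sd marginal SD of the AR(1) heart-rate noise (bpm).
#' @param ar_rho AR(1) autocorrelation of the heart-rate noise.
#' @param spike_prob per-observation probability of a spike artefact.
#' @param spike_amp numeric length 2: spike magnitude range (bpm), sign random.
#' @param cadence_sd SD of cadence around 60 RPM.
#' @param cadence_out_prob probability an observation is an out-of-range
#'   cadence excursion (outside the 35–125 RPM QC band).
#' @param workload named list of per-risk protocol parameters; for
#'   `minimal`/`small` a `start` watts constant segment (`constant_s`
#'   seconds) followed by a linear ramp to `end` watts; `medium` holds
#'   `constant` watts for the whole exercise phase.
#' @param pa_log_mean,pa_log_sd log-scale parameters of the lognormal
#'   7-day-average acceleration (milligravities).
#' @param pa_fail_wear,pa_fail_calib,pa_fail_problem accelerometer QC flag
#'   failure probabilities.
#' @param trait_sex_effect,trait_age_effect,trait_noise_sd covariate effects
#'   and residual SD of the planted quantitative trait.
#' @param disease_slope log-odds change in disease liability per SD of the
#'   planted trait (applied to every disease group; named vector to vary).
#' @param disease_baseline named baseline log-odds per disease group;
#'   defaults give prevalences roughly 0.5–8%.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(age_range = c(40, 69),
                       risk_probs = c(minimal = 0.35, small = 0.35,
                                      medium = 0.25, high = 0.05),
                       n_centres = 22,
                       bike_other_prob = 0.02,
                       hr_rest_mean = 65, hr_rest_sd = 8,
                       hr_per_watt_mean = 0.40, hr_per_watt_sd = 0.08,
                       sampling_interval = 4,
                       phase_durations = c(pretest = 15, exercise = 360,
                                           recovery = 60),
                       hr_noise_sd = 3, ar_rho = 0.6,
                       spike_prob = 0.01, spike_amp = c(20, 40),
                       cadence_sd = 4, cadence_out_prob = 0.02,
                       workload = list(
                         minimal = list(start = 40, end = 115, constant_s = 120),
                         small   = list(start = 30, end = 95,  constant_s = 120),
                         medium  = list(constant = 30)),
                       pa_log_mean = log(27), pa_log_sd = 0.25,
                       pa_fail_wear = 0.03, pa_fail_calib = 0.01,
                       pa_fail_problem = 0.01,
                       trait_sex_effect = 0.5, trait_age_effect = -0.02,
                       trait_noise_sd = 1,
                       disease_slope = -0.4,
                       disease_baseline = NULL) {
  .assert(length(age_range) == 2 && age_range[1] < age_range[2] &&
            age_range[1] > 0, "age_range must be increasing and positive")
  .assert(all(risk_probs >= 0) && abs(sum(risk_probs) - 1) < 1e-8,
          "risk_probs must be a proper distribution")
  .assert(sampling_interval > 0, "sampling_interval must be positive")
  .assert(hr_noise_sd >= 0 && hr_per_watt_sd >= 0 && hr_rest_sd >= 0,
          "scale parameters must be non-negative")
  .assert(abs(ar_rho) < 1, "ar_rho must be in (-1, 1)")
  if (is.null(disease_baseline)) {
    disease_baseline <- c(CAD = -2.6, STR = -4.4, ALZ = -5.5, LCX = -5.0,
                          COPD = -4.4, LRTI = -3.9, CCX = -4.6, DIA = -3.3,
                          KID = -4.3, BCX = -3.7)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Draws `n` participants with demographics, covariates and per-participant
#' heart-rate response parameters. The analytic true fitness value is
#' computed from the generated response: the workload at which the linear
#' heart-rate response reaches the age-predicted maximum heart rate
#' (208 − 0.7·age), divided by body weight.
#'
#' @param n number of participants (>= 1).
#' @param seed integer seed; identical `(n, seed, config)` give identical
#'   output.
#' @param config a [sim_config()].
#' @return list with elements `cohort` (one row per participant: id, sex,
#'   age, weight, SES, centre, array, pc1..pc10, risk_category, bike method,
#'   smoking, drinking) and `truth` (hr_rest, hr_per_watt, true_vo2max).
#' @export
simulate_cohort <- function(n, seed, config = sim_config()) {
  .assert(is.numeric(n) && length(n) == 1 && n >= 1, "n must be >= 1")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  n <- as.integer(n)
  set.seed(seed)
  id <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- runif(n, config$age_range[1], config$age_range[2])
  weight <- ifelse(sex == "male", rnorm(n, 85, 13), rnorm(n, 71, 12))
  weight <- pmin(pmax(weight, 40), 160)
  ses <- rnorm(n, 0, 3)
  centre <- sprintf("centre%02d", sample.int(config$n_centres, n, replace = TRUE))
  array <- sample(c("A", "B"), n, replace = TRUE)
  pcs <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  risk <- sample(names(config$risk_probs), n, replace = TRUE,
                 prob = config$risk_probs)
  bike_method <- ifelse(runif(n) < config$bike_other_prob, "Other", "Bicycle")
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.55, 0.35, 0.10))
  drinking <- sample(c("never", "former", "current"), n, replace = TRUE,
                     prob = c(0.08, 0.04, 0.88))

  hr_rest <- pmin(pmax(rnorm(n, config$hr_rest_mean, config$hr_rest_sd), 40), 100)
  hr_per_watt <- pmax(rnorm(n, config$hr_per_watt_mean, config$hr_per_watt_sd),
                      0.15)
  true_vo2max <- ((208 - 0.7 * age) - hr_rest) / hr_per_watt / weight
  .assert(all(is.finite(true_vo2max)) && all(true_vo2max > 0),
          "generated true_vo2max must be finite and positive")

  cohort <- data.frame(participant_id = id, sex = sex, age = age,
                       weight = weight, ses = ses, centre = centre,
                       array = array, pcs, risk_category = risk,
                       bike_method = bike_method, smoking = smoking,
                       drinking = drinking, stringsAsFactors = FALSE)
  truth <- data.frame(participant_id = id, hr_rest = hr_rest,
                      hr_per_watt = hr_per_watt, true_vo2max = true_vo2max,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

# Internal: workload profile over the exercise phase for one risk category.
.workload_profile <- function(risk, n_obs, dt, config) {
  wl <- config$workload
  if (risk %in% c("minimal", "small")) {
    p <- wl[[risk]]
    n_const <- round(p$constant_s / dt)
    n_ramp <- n_obs - n_const
    .assert(n_ramp >= 2, "exercise phase too short for a ramp")
    c(rep(p$start, n_const),
      p$start + (p$end - p$start) * seq_len(n_ramp) / n_ramp)
  } else if (risk == "medium") {
    rep(wl$medium$constant, n_obs)
  } else {
    stop("unknown risk category: ", risk, call. = FALSE)
  }
}

# Internal: AR(1) noise with marginal SD `sd` and autocorrelation `rho`.
.ar1 <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + e[i + 1]
  x
}

#' Simulate one participant's cycle ramp-test trace
#'
#' Produces a long-format trace with pre-test, exercise and recovery phases
#' (defaults ~15 s, 6 min, 1 min at a 4-s sampling interval). For
#' minimal/small risk the exercise phase is a 2-min constant segment
#' followed by a 4-min strictly increasing workload ramp; medium risk holds
#' a constant workload. Heart rate follows
#' `hr_rest + hr_per_watt * workload` plus AR(1) noise and optional spike
#' artefacts; cadence is Normal(60, sd) with configurable out-of-range
#' excursions.
#'
#' @param row single-row data.frame from `simulate_cohort()$cohort`.
#' @param truth matching single row of `$truth`.
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @return data.frame with columns participant_id, phase, trend,
#'   heart_rate, workload, cadence. `trend` restarts at 1 in each phase.
#' @export
simulate_ergo_session <- function(row, truth, seed, config = sim_config()) {
  .assert(nrow(row) == 1 && nrow(truth) == 1, "one participant at a time")
  risk <- row$risk_category
  if (!risk %in% c("minimal", "small", "medium", "high"))
    stop("unknown risk category: ", risk, call. = FALSE)
  set.seed(seed)
  dt <- config$sampling_interval
  n_pre <- max(1, round(config$phase_durations[["pretest"]] / dt))
  n_ex <- round(config$phase_durations[["exercise"]] / dt)
  n_rec <- max(1, round(config$phase_durations[["recovery"]] / dt))

  # High-risk participants did not pedal against a ramp; emulate a short
  # constant low-load session (they are excluded downstream anyway).
  wl_ex <- if (risk == "high") rep(20, n_ex) else
    .workload_profile(risk, n_ex, dt, config)

  hr_true <- c(rep(truth$hr_rest, n_pre),
               truth$hr_rest + truth$hr_per_watt * wl_ex,
               truth$hr_rest + truth$hr_per_watt * wl_ex[n_ex] *
                 exp(-seq_len(n_rec) * dt / 30))
  n_all <- n_pre + n_ex + n_rec
  hr <- hr_true + .ar1(n_all, config$hr_noise_sd, config$ar_rho)
  spikes <- runif(n_all) < config$spike_prob
  if (any(spikes)) {
    amp <- runif(sum(spikes), config$spike_amp[1], config$spike_amp[2])
    hr[spikes] <- hr[spikes] + amp * sample(c(-1, 1), sum(spikes), replace = TRUE)
  }
  cad <- rnorm(n_all, 60, config$cadence_sd)
  out <- runif(n_all) < config$cadence_out_prob
  if (any(out)) {
    lo <- runif(sum(out)) < 0.5
    cad[out] <- ifelse(lo, runif(sum(out), 10, 34.5), runif(sum(out), 125.5, 150))
  }
  cad[seq_len(n_pre)] <- 0  # not pedalling before the test

  data.frame(
    participant_id = row$participant_id,
    phase = rep(c("pretest", "exercise", "recovery"), c(n_pre, n_ex, n_rec)),
    trend = c(seq_len(n_pre), seq_len(n_ex), seq_len(n_rec)),
    heart_rate = hr,
    workload = c(rep(0, n_pre), wl_ex, rep(0, n_rec)),
    cadence = cad,
    stringsAsFactors = FALSE)
}

#' Simulate ramp-test traces for a whole cohort
#'
#' @param cohort,truth as returned by [simulate_cohort()].
#' @param seed integer seed (per-participant sub-seeds are derived from it).
#' @param config a [sim_config()].
#' @return one long data.frame of stacked [simulate_ergo_session()] traces.
#' @export
simulate_traces <- function(cohort, truth, seed, config = sim_config()) {
  .assert(identical(cohort$participant_id, truth$participant_id),
          "cohort and truth must align")
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    out[[i]] <- simulate_ergo_session(cohort[i, , drop = FALSE],
                                      truth[i, , drop = FALSE],
                                      seed = .stage_seed(seed, paste0("trace", i)),
                                      config = config)
  }
  do.call(rbind, out)
}

#' Simulate LD-blocked genotype dosages
#'
#' Haplotypes are generated block-wise by a copying process: within a block,
#' the allele at each variant copies the allele at the previous variant with
#' probability `copy_prob`, otherwise it is drawn fresh at that variant's
#' allele frequency. `copy_prob = 1` gives perfect LD within a block;
#' `copy_prob = 0` gives independent variants. Blocks are distributed over
#' chromosomes with ~1 Mb gaps between same-chromosome blocks so that blocks
#' are unlinked at clumping windows of a few hundred kb.
#'
#' @param n_samples,n_variants,n_blocks sizes; `n_blocks <= n_variants`.
#' @param maf_range minor-allele-frequency range, a subset of (0, 0.5].
#' @param seed integer seed.
#' @param copy_prob haplotype-copying probability in `[0, 1]`.
#' @param n_chrom number of chromosomes to spread blocks over (<= 22).
#' @param maf optional explicit per-variant allele frequencies (length
#'   `n_variants`), overriding `maf_range`.
#' @return object of class `genotype_matrix`: list with `dosage` (variants x
#'   samples matrix, values in `[0, 2]`) and `map` (chrom, pos, variant_id,
#'   a1, a0, maf, block).
#' @export
simulate_genotypes <- function(n_samples, n_variants, n_blocks,
                               maf_range = c(0.05, 0.5), seed,
                               copy_prob = 0.9, n_chrom = NULL, maf = NULL) {
  .assert(n_blocks >= 1 && n_blocks <= n_variants,
          "need 1 <= n_blocks <= n_variants")
  .assert(length(maf_range) == 2 && maf_range[1] > 0 &&
            maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
          "maf_range must be a non-degenerate subset of (0, 0.5]")
  .assert(copy_prob >= 0 && copy_prob <= 1, "copy_prob must be in [0, 1]")
  set.seed(seed)
  if (is.null(n_chrom)) n_chrom <- min(n_blocks, 22L)
  if (is.null(maf)) maf <- runif(n_variants, maf_range[1], maf_range[2])
  .assert(length(maf) == n_variants, "maf must have length n_variants")

  block <- sort(rep_len(seq_len(n_blocks), n_variants))
  chrom <- ((seq_len(n_blocks) - 1) %% n_chrom) + 1L

  # positions: strictly increasing per chromosome, ~1 Mb between blocks
  pos <- integer(n_variants)
  chrom_v <- chrom[block]
  for (ch in unique(chrom)) {
    blocks_here <- which(chrom == ch)
    cursor <- 0L
    for (b in blocks_here) {
      idx <- which(block == b)
      steps <- sample(2000:50000, length(idx), replace = TRUE)
      pos[idx] <- cursor + cumsum(steps)
      cursor <- pos[idx[length(idx)]] + 1000000L
    }
  }

  # two haplotypes per sample, copying process within blocks
  hap <- function() {
    h <- matrix(0L, n_variants, n_samples)
    for (b in seq_len(n_blocks)) {
      idx <- which(block == b)
      h[idx[1], ] <- rbinom(n_samples, 1, maf[idx[1]])
      for (k in seq_along(idx)[-1]) {
        j <- idx[k]
        copy <- runif(n_samples) < copy_prob
        fresh <- rbinom(n_samples, 1, maf[j])
        h[j, ] <- ifelse(copy, h[idx[k - 1], ], fresh)
      }
    }
    h
  }
  dosage <- hap() + hap()
  sample_ids <- sprintf("P%06d", seq_len(n_samples))
  dimnames(dosage) <- list(sprintf("var%05d", seq_len(n_variants)), sample_ids)

  alleles <- t(vapply(seq_len(n_variants),
                      function(i) sample(c("A", "C", "G", "T"), 2),
                      character(2)))
  map <- data.frame(chrom = chrom_v, pos = pos,
                    variant_id = rownames(dosage),
                    a1 = alleles[, 1], a0 = alleles[, 2],
                    maf = maf, block = block, stringsAsFactors = FALSE)
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' Simulate phenotypes, activity summaries and diagnoses
#'
#' Generates (a) a planted quantitative trait
#' `sim_trait = covariate effects + sum(beta_sex * dosage) + noise` with
#' optionally sex-specific causal effects, (b) accelerometer summary records
#' with configurable QC-flag failure rates, and (c) an ICD-10-coded
#' diagnosis table where each disease group's liability is
#' `logistic(alpha_g + disease_slope * standardized trait)`.
#'
#' @param cohort,truth from [simulate_cohort()].
#' @param genotypes a `genotype_matrix` (samples must cover the cohort).
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @param causal data.frame with columns `variant_id`, `beta_male`,
#'   `beta_female` (empty by default: no genetic effects).
#' @param code_map disease-group to ICD-10-prefix map, see
#'   [default_code_map()].
#' @return list with `phenotypes` (participant_id, sim_trait), `pa`
#'   (participant_id, mean_accel, good_wear_time, good_calibration,
#'   problem_indicators), `diagnoses` (participant_id, icd10_code) and
#'   `disease` (logical matrix participants x disease groups, the ground
#'   truth indicators).
#' @export
simulate_phenotypes_and_outcomes <- function(cohort, genotypes, truth, seed,
                                             config = sim_config(),
                                             causal = NULL,
                                             code_map = default_code_map()) {
  set.seed(seed)
  n <- nrow(cohort)
  if (is.null(causal))
    causal <- data.frame(variant_id = character(), beta_male = numeric(),
                         beta_female = numeric())
  g_score <- numeric(n)
  if (nrow(causal) > 0) {
    missing <- setdiff(causal$variant_id, rownames(genotypes$dosage))
    if (length(missing) > 0)
      stop("causal variant(s) absent from genotype matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    G <- genotypes$dosage[causal$variant_id, cohort$participant_id,
                          drop = FALSE]
    bm <- as.numeric(crossprod(G, causal$beta_male))
    bf <- as.numeric(crossprod(G, causal$beta_female))
    g_score <- ifelse(cohort$sex == "male", bm, bf)
  }
  sim_trait <- config$trait_sex_effect * (cohort$sex == "male") +
    config$trait_age_effect * (cohort$age - mean(cohort$age)) +
    g_score + rnorm(n, 0, config$trait_noise_sd)

  pa <- data.frame(
    participant_id = cohort$participant_id,
    mean_accel = exp(rnorm(n, config$pa_log_mean, config$pa_log_sd)),
    good_wear_time = runif(n) >= config$pa_fail_wear,
    good_calibration = runif(n) >= config$pa_fail_calib,
    problem_indicators = ifelse(runif(n) < config$pa_fail_problem,
                                "interrupted_recording", ""),
    stringsAsFactors = FALSE)

  z <- as.numeric(scale(sim_trait))
  groups <- names(code_map)
  slope <- config$disease_slope
  if (length(slope) == 1 && is.null(names(slope)))
    slope <- setNames(rep(slope, length(groups)), groups)
  disease <- matrix(FALSE, n, length(groups),
                    dimnames = list(cohort$participant_id, groups))
  dx <- list()
  for (g in groups) {
    p <- plogis(config$disease_baseline[[g]] + slope[[g]] * z)
    hit <- runif(n) < p
    disease[, g] <- hit
    idx <- which(hit)
    if (length(idx) > 0) {
      reps <- 1 + rpois(length(idx), 0.5)  # repeat admissions
      pid <- rep(cohort$participant_id[idx], reps)
      prefix <- sample(code_map[[g]], length(pid), replace = TRUE)
      sub <- ifelse(runif(length(pid)) < 0.3,
                    as.character(sample.int(9, length(pid), replace = TRUE)), "")
      dx[[g]] <- data.frame(participant_id = pid,
                            icd10_code = paste0(prefix, sub),
                            stringsAsFactors = FALSE)
    }
  }
  diagnoses <- if (length(dx) > 0) do.call(rbind, c(dx, make.row.names = FALSE))
  else data.frame(participant_id = character(), icd10_code = character())

  list(phenotypes = data.frame(participant_id = cohort$participant_id,
                               sim_trait = sim_trait,
                               stringsAsFactors = FALSE),
       pa = pa, diagnoses = diagnoses, disease = disease)
}
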