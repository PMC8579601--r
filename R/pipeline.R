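#' Pipeline configuration
#'
#' One configuration object drives the full synthetic study: cohort size,
#' genotype panel, per-stage parameters, and the root seed from which every
#' stage derives an independent named sub-seed. Defaults give the reference
#' desk-scale run: 2000 participants, 500 variants in 50 LD blocks, five
#' causal variants for the planted trait (one with a male-only effect).
#'
#' @param seed root integer seed.
#' @param n cohort size.
#' @param n_variants,n_blocks,maf_range,copy_prob genotype panel, see
#'   [simulate_genotypes()].
#' @param causal data.frame (variant_id, beta_male, beta_female), or NULL
#'   for the default five-variant architecture.
#' @param sim a [sim_config()].
#' @param crf a [crf_config()].
#' @param p_threshold genome-wide significance threshold.
#' @param r2_threshold,window_kb clumping parameters.
#' @param n_decile_groups phenotype decile count.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n = 2000, n_variants = 500,
                            n_blocks = 50, maf_range = c(0.05, 0.5),
                            copy_prob = 0.9, causal = NULL,
                            sim = sim_config(), crf = crf_config(),
                            p_threshold = 5e-8, r2_threshold = 0.2,
                            window_kb = 500, n_decile_groups = 10) {
  .assert(p_threshold > 0 && r2_threshold > 0 && window_kb > 0 &&
            n_decile_groups > 0, "all thresholds must be positive")
  structure(list(seed = seed, n = n, n_variants = n_variants,
                 n_blocks = n_blocks, maf_range = maf_range,
                 copy_prob = copy_prob, causal = causal, sim = sim,
                 crf = crf, p_threshold = p_threshold,
                 r2_threshold = r2_threshold, window_kb = window_kb,
                 n_decile_groups = n_decile_groups),
            class = "pipeline_config")
}

# Internal: default planted genetic architecture — first variant of five
# evenly spaced blocks; the first effect is male-specific.
.default_causal <- function(map) {
  blocks <- unique(map$block)
  pick <- blocks[round(seq(1, length(blocks), length.out = min(5, length(blocks))))]
  vid <- vapply(pick, function(b) map$variant_id[map$block == b][1], character(1))
  k <- length(vid)
  data.frame(variant_id = vid,
             beta_male = c(0.30, 0.20, 0.15, -0.20, 0.00)[seq_len(k)],
             beta_female = c(0.00, 0.20, 0.15, -0.20, 0.25)[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Save / load a pipeline configuration
#'
#' YAML serialization; `load_config()` rebuilds the classed configuration
#' so a round trip is lossless.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config()` returns the path invisibly; `load_config()`
#'   returns a `pipeline_config`.
#' @export
save_config <- function(config, path) {
  .assert(inherits(config, "pipeline_config"), "not a pipeline_config")
  plain <- rapply(unclass(config), unclass, how = "replace")
  plain$causal <- if (is.null(config$causal)) NULL else as.list(config$causal)
  plain$sim <- lapply(unclass(config$sim), unclass)
  plain$crf <- unclass(config$crf)
  # named numeric vectors must serialize as maps, not sequences
  for (f in c("risk_probs", "phase_durations", "disease_baseline"))
    plain$sim[[f]] <- as.list(plain$sim[[f]])
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  sim_args <- raw$sim
  for (f in c("age_range", "risk_probs", "phase_durations", "spike_amp",
              "disease_baseline", "disease_slope"))
    sim_args[[f]] <- num(sim_args[[f]])
  crf_args <- raw$crf
  crf_args$cadence_range <- num(crf_args$cadence_range)
  pipeline_config(
    seed = raw$seed, n = raw$n, n_variants = raw$n_variants,
    n_blocks = raw$n_blocks, maf_range = num(raw$maf_range),
    copy_prob = raw$copy_prob,
    causal = if (is.null(raw$causal)) NULL else
      as.data.frame(raw$causal, stringsAsFactors = FALSE),
    sim = do.call(sim_config, sim_args),
    crf = do.call(crf_config, crf_args),
    p_threshold = raw$p_threshold, r2_threshold = raw$r2_threshold,
    window_kb = raw$window_kb, n_decile_groups = raw$n_decile_groups)
}

# Internal: configuration hash for output provenance stamps.
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  save_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full synthetic-study pipeline
#'
#' Stages in dependency order: cohort and genotype simulation, trace
#' simulation, phenotype/outcome simulation, CRF derivation, activity QC,
#' covariate residualization, per-stratum association, LD clumping of
#' combined results, male/female heterogeneity meta-analysis of
#' sex-specific hits, and disease-frequency deciles. Every stage draws its
#' own named sub-seed from the root seed, so runs are fully reproducible
#' and individual stages can be re-run in isolation.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, each stage's table is
#'   written as a stage-stamped TSV (plus a VCF of the genotypes) and the
#'   manifest as JSON.
#' @return list with `manifest` (per-stage row counts, seeds, file hashes)
#'   and `results` (all in-memory stage outputs).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  hash <- .config_hash(config)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  results <- list()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note <- function(name, n_in, n_out, seed = NA, file = NULL) {
    entry <- list(n_in = n_in, n_out = n_out, seed = seed)
    if (!is.null(file)) {
      entry$file <- basename(file)
      entry$md5 <- unname(tools::md5sum(file))
    }
    manifest$stages[[name]] <<- entry
  }
  emit <- function(df, name) {
    if (is.null(outdir)) return(NULL)
    write_stage_tsv(df, file.path(outdir, paste0(name, ".tsv")), name, hash)
  }

  # --- simulation ---------------------------------------------------------
  s <- function(stage) .stage_seed(config$seed, stage)
  cohort_sim <- run_stage("cohort", function()
    simulate_cohort(config$n, s("cohort"), config$sim))
  cohort <- cohort_sim$cohort
  note("cohort", config$n, nrow(cohort), s("cohort"), emit(cohort, "cohort"))

  geno <- run_stage("genotypes", function()
    simulate_genotypes(config$n, config$n_variants, config$n_blocks,
                       config$maf_range, s("genotypes"), config$copy_prob))
  colnames(geno$dosage) <- cohort$participant_id
  geno_file <- if (!is.null(outdir)) {
    f <- file.path(outdir, "genotypes.vcf"); write_vcf(geno, f); f
  }
  note("genotypes", config$n, nrow(geno$map), s("genotypes"), geno_file)

  traces <- run_stage("traces", function()
    simulate_traces(cohort, cohort_sim$truth, s("traces"), config$sim))
  note("traces", nrow(cohort), nrow(traces), s("traces"),
       emit(traces, "traces"))

  causal <- if (is.null(config$causal)) .default_causal(geno$map)
  else config$causal
  outcomes <- run_stage("outcomes", function()
    simulate_phenotypes_and_outcomes(cohort, geno, cohort_sim$truth,
                                     s("outcomes"), config$sim,
                                     causal = causal))
  note("outcomes", nrow(cohort), nrow(outcomes$diagnoses), s("outcomes"),
       emit(outcomes$diagnoses, "diagnoses"))

  # --- phenotype derivation ----------------------------------------------
  crf <- run_stage("crf", function()
    derive_crf_phenotypes(traces, cohort, config$crf))
  note("crf", nrow(cohort), nrow(crf$records), NA,
       emit(crf$records, "crf_records"))

  pa <- run_stage("pa_qc", function() qc_pa(outcomes$pa))
  note("pa_qc", nrow(outcomes$pa), pa$n_included, NA,
       emit(pa$records, "pa_records"))

  # --- residualization and association ------------------------------------
  tab <- merge(cohort, crf$records[, c("participant_id", "crf_vo2max",
                                       "crf_slope", "n_trend")],
               by = "participant_id", all.x = TRUE)
  pa_inc <- pa$records[pa$records$included, c("participant_id", "mean_accel")]
  names(pa_inc)[2] <- "pa"
  tab <- merge(tab, pa_inc, by = "participant_id", all.x = TRUE)
  tab <- merge(tab, outcomes$phenotypes, by = "participant_id", all.x = TRUE)

  traits <- c("crf_vo2max", "crf_slope", "pa", "sim_trait")
  strata <- c("combined", "male", "female")
  assoc_tables <- list()
  residual_tables <- list()
  for (trait in traits) {
    if (all(is.na(tab[[trait]]))) next
    for (st in strata) {
      d <- if (st == "combined") tab else tab[tab$sex == st, , drop = FALSE]
      if (sum(!is.na(d[[trait]])) < 30) next
      spec <- covariate_spec("gwas", include_sex = (st == "combined"),
                             crf_extras = trait %in% c("crf_vo2max", "crf_slope"))
      res <- run_stage(paste0("residualize_", trait, "_", st), function()
        residualize(d, trait, spec))
      residual_tables[[paste(trait, st, sep = ".")]] <- res
      a <- run_stage(paste0("assoc_", trait, "_", st), function()
        run_assoc(res, geno, stratum = st, p_threshold = config$p_threshold))
      a$trait <- trait
      assoc_tables[[paste(trait, st, sep = ".")]] <- a
    }
  }
  assoc_all <- .rbind_all(assoc_tables)
  note("assoc", length(assoc_tables),
       if (is.null(assoc_all)) 0L else nrow(assoc_all), NA,
       if (!is.null(assoc_all)) emit(assoc_all, "assoc"))

  # --- clumping (combined stratum, per trait) -----------------------------
  clumps <- list()
  for (trait in traits) {
    a <- assoc_tables[[paste(trait, "combined", sep = ".")]]
    if (is.null(a)) next
    clumps[[trait]] <- run_stage(paste0("clump_", trait), function()
      greedy_clump(a, geno, config$p_threshold, config$r2_threshold,
                   config$window_kb))
  }
  n_clumps <- sum(vapply(clumps, function(cl) nrow(cl$summary), integer(1)))
  note("clump", length(clumps), n_clumps)

  # --- sex heterogeneity of stratum-specific hits -------------------------
  het <- list()
  for (trait in traits) {
    am <- assoc_tables[[paste(trait, "male", sep = ".")]]
    af <- assoc_tables[[paste(trait, "female", sep = ".")]]
    if (is.null(am) || is.null(af)) next
    hits <- union(am$variant_id[am$genome_wide_significant],
                  af$variant_id[af$genome_wide_significant])
    if (length(hits) == 0) next
    im <- match(hits, am$variant_id)
    iff <- match(hits, af$variant_id)
    h <- meta_two_groups(am$beta[im], am$se[im], af$beta[iff], af$se[iff],
                         variant_id = hits)
    h$trait <- trait
    # opposite-sex follow-up: the stratum where the hit was NOT found
    p_other <- ifelse(am$genome_wide_significant[im], af$p[iff], am$p[im])
    h$follow_up_significant <- follow_up_flag(p_other, length(hits))
    het[[trait]] <- h
  }
  het_all <- .rbind_all(het)
  note("het", length(het), if (is.null(het_all)) 0L else nrow(het_all), NA,
       if (!is.null(het_all)) emit(het_all, "heterogeneity"))

  # --- disease-frequency deciles (age+SES residuals, per sex) -------------
  decile_freq <- list()
  for (trait in c("sim_trait", "pa")) {
    if (!trait %in% names(tab) || all(is.na(tab[[trait]]))) next
    per_sex <- list()
    for (sx in c("male", "female")) {
      d <- tab[tab$sex == sx & !is.na(tab[[trait]]), , drop = FALSE]
      if (nrow(d) < config$n_decile_groups) next
      res <- residualize(d, trait, covariate_spec("decile"))
      dd <- assign_deciles(res, config$n_decile_groups)
      dd$sex <- sx
      per_sex[[sx]] <- dd
    }
    if (length(per_sex) == 0) next
    decile_freq[[trait]] <- run_stage(paste0("deciles_", trait), function()
      disease_frequency(do.call(rbind, c(per_sex, make.row.names = FALSE)),
                        outcomes$diagnoses))
  }
  note("deciles", length(decile_freq),
       sum(vapply(decile_freq, nrow, integer(1))))

  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(manifest = manifest,
       results = list(cohort = cohort, truth = cohort_sim$truth,
                      genotypes = geno, traces = traces, outcomes = outcomes,
                      crf = crf, pa = pa, residuals = residual_tables,
                      assoc = assoc_tables, clumps = clumps, het = het_all,
                      deciles = decile_freq, causal = causal))
}
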