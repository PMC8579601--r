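#' Covariate specifications for residualization
#'
#' Two presets mirror the study's conventions:
#' \describe{
#'   \item{gwas}{age, age squared, sex (sex-combined analyses only), array,
#'     centre and the first 10 principal components; for CRF traits also
#'     risk category and the number of trend entries (`crf_extras`).}
#'   \item{decile}{age and socioeconomic status only — the correction used
#'     before ranking participants for disease-frequency deciles.}
#' }
#' Smoking/drinking status are deliberately not in the defaults (adjusting
#' for heritable covariates can bias genetic estimates) but can be added
#' via `extras`.
#'
#' @param preset `"gwas"`, `"decile"` or `"custom"`.
#' @param include_sex include sex as a covariate (set FALSE for
#'   sex-stratified analyses).
#' @param crf_extras add risk_category and n_trend (CRF traits).
#' @param extras additional covariate column names (e.g. smoking).
#' @param formula for `preset = "custom"`, a one-sided formula.
#' @return object of class `covariate_spec`.
#' @export
covariate_spec <- function(preset = c("gwas", "decile", "custom"),
                           include_sex = TRUE, crf_extras = FALSE,
                           extras = character(), formula = NULL) {
  preset <- match.arg(preset)
  terms <- switch(preset,
    gwas = c("age", "I(age^2)", if (include_sex) "sex", "array", "centre",
             paste0("pc", 1:10),
             if (crf_extras) c("risk_category", "n_trend")),
    decile = c("age", "ses"),
    custom = NULL)
  if (preset == "custom") {
    .assert(inherits(formula, "formula"), "custom preset needs a formula")
    fml <- formula
  } else {
    fml <- stats::reformulate(c(terms, extras))
  }
  structure(list(preset = preset, formula = fml), class = "covariate_spec")
}

#' Residualize a trait on a covariate specification
#'
#' Regresses the trait on the expanded covariate design (categorical
#' columns become indicator contrasts) and returns the residuals. Rows with
#' missing trait or covariate values are dropped and logged. The design
#' must be full rank; a rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param data data.frame containing the trait and all covariate columns
#'   (plus `participant_id`).
#' @param trait name of the trait column.
#' @param spec a [covariate_spec()].
#' @return data.frame (participant_id, residual) with attribute
#'   `"dropped"` listing the ids of incomplete rows. Residuals have mean
#'   ~0 and are orthogonal to every design column.
#' @export
residualize <- function(data, trait, spec) {
  .assert(inherits(spec, "covariate_spec"), "spec must be a covariate_spec")
  .assert(trait %in% names(data), paste("no column", trait))
  vars <- all.vars(spec$formula)
  .assert(all(vars %in% names(data)),
          paste("missing covariate column(s):",
                paste(setdiff(vars, names(data)), collapse = ", ")))
  use <- complete.cases(data[, c(trait, vars), drop = FALSE])
  d <- droplevels(data[use, , drop = FALSE])
  X <- stats::model.matrix(spec$formula, d)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, d[[trait]])
  out <- data.frame(participant_id = d$participant_id,
                    residual = unname(fit$residuals),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- data$participant_id[!use]
  out
}

#' Descriptive summary of phenotype columns
#'
#' Means, SDs and pairwise Pearson correlations with p-values, optionally
#' split by sex. Zero-variance columns give undefined correlations,
#' reported as NA.
#'
#' @param data data.frame of phenotypes (plus optionally `sex`).
#' @param vars phenotype column names to summarize.
#' @param by_sex split by a `sex` column.
#' @return list (or per-sex list of lists) with `stats` (var, n, mean, sd),
#'   `cor` (symmetric correlation matrix, unit diagonal) and `cor_p`
#'   (p-value matrix).
#' @export
descriptive_summary <- function(data, vars, by_sex = FALSE) {
  one <- function(d) {
    m <- as.matrix(d[, vars, drop = FALSE])
    k <- length(vars)
    cm <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
    pm <- cm
    diag(cm) <- 1
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i >= j) next
      ok <- complete.cases(m[, c(i, j)])
      if (sum(ok) < 3 || sd(m[ok, i]) == 0 || sd(m[ok, j]) == 0) next
      ct <- cor.test(m[ok, i], m[ok, j])
      cm[i, j] <- cm[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
    }
    stats <- data.frame(var = vars,
                        n = colSums(!is.na(m)),
                        mean = colMeans(m, na.rm = TRUE),
                        sd = apply(m, 2, sd, na.rm = TRUE),
                        row.names = NULL)
    list(stats = stats, cor = cm, cor_p = pm)
  }
  if (!by_sex) return(one(data))
  .assert("sex" %in% names(data), "by_sex needs a sex column")
  lapply(split(data, data$sex), one)
}
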