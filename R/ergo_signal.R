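#' CRF derivation configuration
#'
#' @param butter_order Butterworth filter order.
#' @param butter_cutoff low-pass cutoff as a fraction of Nyquist.
#' @param cadence_range inclusive RPM band for retained observations.
#' @param min_obs minimum surviving exercise observations per session.
#' @param mode `"regression"` (least-squares workload~HR line, the default)
#'   or `"endpoints"` (line through the first/last filtered observation).
#' @return list of class `crf_config`.
#' @export
crf_config <- function(butter_order = 4, butter_cutoff = 0.1,
                       cadence_range = c(35, 125), min_obs = 20,
                       mode = c("regression", "endpoints")) {
  .assert(butter_order >= 1, "butter_order must be >= 1")
  .assert(butter_cutoff > 0 && butter_cutoff < 1,
          "butter_cutoff must be in (0, 1) of Nyquist")
  .assert(min_obs >= 2, "min_obs must be >= 2")
  mode <- match.arg(mode)
  structure(list(butter_order = butter_order, butter_cutoff = butter_cutoff,
                 cadence_range = cadence_range, min_obs = min_obs,
                 mode = mode), class = "crf_config")
}

#' Age-predicted maximum heart rate
#'
#' The widely used linear estimate `208 - 0.7 * age` (bpm).
#'
#' @param age age in years, positive.
#' @return predicted maximum heart rate in bpm.
#' @export
age_predicted_max_hr <- function(age) {
  .assert(all(is.finite(age)) && all(age > 0), "age must be positive")
  208 - 0.7 * age
}

#' Select the modelling window of an exercise session
#'
#' For minimal/small risk the modelled window is the workload ramp: the
#' longest contiguous exercise-phase run of non-decreasing workload with an
#' overall strict increase, with the leading constant-workload segment (the
#' pre-ramp steady load, identified by a repeated initial workload value)
#' removed. For medium risk the whole constant-workload exercise phase is
#' used. High-risk and non-bicycle sessions are excluded.
#'
#' @param session one participant's long-format trace (columns phase,
#'   trend, heart_rate, workload, cadence).
#' @param risk_category one of minimal/small/medium/high.
#' @param method test method string; anything other than `"Bicycle"` is
#'   excluded.
#' @return list with `observations` (data.frame, possibly NULL) and
#'   `reason` (NULL, or one of `bad_risk`, `bad_method`, `no_ramp`,
#'   `no_exercise_phase`).
#' @export
select_exercise_window <- function(session, risk_category,
                                   method = "Bicycle") {
  if (!identical(method, "Bicycle"))
    return(list(observations = NULL, reason = "bad_method"))
  if (!risk_category %in% c("minimal", "small", "medium"))
    return(list(observations = NULL, reason = "bad_risk"))
  ex <- session[session$phase == "exercise", , drop = FALSE]
  if (nrow(ex) == 0)
    return(list(observations = NULL, reason = "no_exercise_phase"))
  ex <- ex[order(ex$trend), , drop = FALSE]
  if (risk_category == "medium")
    return(list(observations = ex, reason = NULL))

  # maximal non-decreasing workload runs
  run_id <- cumsum(c(TRUE, diff(ex$workload) < 0))
  runs <- split(seq_len(nrow(ex)), run_id)
  increasing <- vapply(runs, function(i)
    ex$workload[i[length(i)]] > ex$workload[i[1]], logical(1))
  if (!any(increasing))
    return(list(observations = NULL, reason = "no_ramp"))
  cand <- runs[increasing]
  len <- lengths(cand)
  pick <- cand[[max(which(len == max(len)))]]  # ties -> latest run
  w <- ex$workload[pick]
  lead_ties <- match(TRUE, w != w[1], nomatch = length(w) + 1L) - 1L
  if (lead_ties >= 2) pick <- pick[-seq_len(lead_ties)]
  list(observations = ex[pick, , drop = FALSE], reason = NULL)
}

#' Cadence and observation-count QC
#'
#' Observations with cadence outside the inclusive band (default 35–125
#' RPM, the ergometer's guaranteed workload-accuracy range) are removed; a
#' session with fewer than `min_obs` (default 20) surviving observations is
#' excluded.
#'
#' @param observations data.frame from [select_exercise_window()].
#' @param cadence_range inclusive RPM bounds.
#' @param min_obs minimum surviving observation count.
#' @return list with `observations` (filtered rows), `n_removed`, and
#'   `reason` (`"low_cadence_n"` when the survivor count is below
#'   `min_obs`, else NULL).
#' @export
apply_qc_filters <- function(observations, cadence_range = c(35, 125),
                             min_obs = 20) {
  if (is.null(observations) || nrow(observations) == 0)
    return(list(observations = NULL, n_removed = 0L, reason = "low_cadence_n"))
  keep <- observations$cadence >= cadence_range[1] &
    observations$cadence <= cadence_range[2]
  obs <- observations[keep, , drop = FALSE]
  reason <- if (nrow(obs) < min_obs) "low_cadence_n" else NULL
  list(observations = obs, n_removed = sum(!keep), reason = reason)
}

# Internal: steady-state initial filter state (direct form II transposed)
# for a step of unit height, the standard lfilter_zi construction.
.filter_zi <- function(b, a) {
  n <- length(a)
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))  # companion matrix of a
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Internal: direct-form-II-transposed IIR filter with initial state zi.
.df2t_filter <- function(b, a, x, zi) {
  m <- length(b) - 1
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (m > 1)
      for (k in seq_len(m - 1))
        z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * y[i]
    z[m] <- b[m + 1] * x[i] - a[m + 1] * y[i]
  }
  y
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward–backward (zero-phase) Butterworth filtering of a heart-rate
#' sequence, so the trend is not lagged. The sequence is linearly detrended
#' before filtering and the trend restored afterwards, with mirror-reflection
#' padding and steady-state initial conditions on each pass; this removes
#' boundary transients and makes the filter exact on affine signals
#' (constants and straight trends pass through unchanged).
#'
#' Sequences shorter than `max(20, 3 * order)` are returned unfiltered in a
#' degraded mode, recorded in the `"filtered"` attribute.
#'
#' @param x numeric heart-rate sequence.
#' @param order Butterworth order (default 4).
#' @param cutoff cutoff frequency as a fraction of Nyquist in (0, 1),
#'   default 0.1.
#' @return numeric vector of the same length, with attribute `"filtered"`
#'   (logical) indicating whether filtering was applied.
#' @export
lowpass_filter <- function(x, order = 4, cutoff = 0.1) {
  .assert(cutoff > 0 && cutoff < 1, "cutoff must be in (0, 1) of Nyquist")
  n <- length(x)
  if (n < max(20, 3 * order)) {
    attr(x, "filtered") <- FALSE
    return(x)
  }
  bf <- signal::butter(order, cutoff, type = "low")
  b <- bf$b; a <- bf$a
  idx <- seq_len(n)
  line <- .ols2(idx, x)
  trend <- line[1] + line[2] * idx
  r <- x - trend

  # mirror (even) padding of the detrended residual: continuous at the
  # joints and injects no spurious offset for oscillatory residuals
  L <- min(n - 1, ceiling(6 / cutoff))
  rp <- c(r[(L + 1):2], r, r[(n - 1):(n - L)])
  zi <- .filter_zi(b, a)
  y <- .df2t_filter(b, a, rp, zi * rp[1])
  y <- rev(.df2t_filter(b, a, rev(y), zi * y[length(y)]))
  out <- y[(L + 1):(L + n)] + trend
  attr(out, "filtered") <- TRUE
  out
}

#' Extrapolate workload to the age-predicted maximum heart rate
#'
#' Fits the workload–heart-rate relation over the (filtered) exercise
#' window and evaluates it at [age_predicted_max_hr()]; relative power
#' `vo2max = wl_hr_max / weight` (W/kg) is the submaximal fitness proxy. In
#' `"regression"` mode the line is the least-squares fit of workload on
#' heart rate; in `"endpoints"` mode it passes through the first and last
#' observation. A constant-workload window (the medium-risk protocol) has
#' no slope to extrapolate: the constant workload is emitted with the
#' `degenerate_workload` flag.
#'
#' @param heart_rate filtered heart-rate values (bpm).
#' @param workload workload values (W), same length.
#' @param age years; @param weight kg (> 0).
#' @param mode `"regression"` or `"endpoints"`.
#' @return list with `vo2max`, `wl_hr_max`, `hr_age_max`, `hr_start`,
#'   `hr_end`, `flags` (character), `reason` (NULL or an exclusion reason:
#'   `equal_endpoints`, `constant_hr`).
#' @export
derive_vo2max <- function(heart_rate, workload, age, weight,
                          mode = c("regression", "endpoints")) {
  mode <- match.arg(mode)
  .assert(length(heart_rate) >= 2 && length(heart_rate) == length(workload),
          "need >= 2 paired observations")
  .assert(weight > 0, "weight must be positive")
  hr_max <- age_predicted_max_hr(age)
  hr_start <- heart_rate[1]
  hr_end <- heart_rate[length(heart_rate)]
  flags <- character()

  if (var(workload) == 0) {
    wl <- workload[1]
    flags <- "degenerate_workload"
  } else if (mode == "regression") {
    fit <- .ols2(heart_rate, workload)
    if (is.na(fit[2]))
      return(list(vo2max = NA_real_, wl_hr_max = NA_real_,
                  hr_age_max = hr_max, hr_start = hr_start, hr_end = hr_end,
                  flags = flags, reason = "constant_hr"))
    wl <- fit[1] + fit[2] * hr_max
  } else {
    if (hr_end == hr_start)
      return(list(vo2max = NA_real_, wl_hr_max = NA_real_,
                  hr_age_max = hr_max, hr_start = hr_start, hr_end = hr_end,
                  flags = flags, reason = "equal_endpoints"))
    slope <- (workload[length(workload)] - workload[1]) / (hr_end - hr_start)
    wl <- workload[1] + slope * (hr_max - hr_start)
  }
  list(vo2max = wl / weight, wl_hr_max = wl, hr_age_max = hr_max,
       hr_start = hr_start, hr_end = hr_end, flags = flags, reason = NULL)
}

#' Heart-rate slope over the exercise window
#'
#' Ordinary least squares of (filtered) heart rate on the trend index:
#' `HR ~ b0 + b1 * trend`. Sessions with a negative slope are excluded from
#' the slope phenotype downstream; a zero slope is retained.
#'
#' @param heart_rate filtered heart-rate values.
#' @param trend ordinal time index, not all identical.
#' @return list with `intercept`, `slope`, `negative` (logical).
#' @export
derive_slope <- function(heart_rate, trend) {
  .assert(length(heart_rate) >= 2 && length(heart_rate) == length(trend),
          "need >= 2 paired observations")
  fit <- .ols2(trend, heart_rate)
  if (is.na(fit[2])) stop("all trend values identical", call. = FALSE)
  list(intercept = fit[1], slope = fit[2], negative = fit[2] < 0)
}

#' Derive CRF phenotypes for a cohort of ramp-test traces
#'
#' Runs the full per-session pipeline — window selection, cadence and
#' observation-count QC, zero-phase Butterworth filtering, workload
#' extrapolation to the age-predicted maximum heart rate, and heart-rate
#' slope — and returns one record per eligible session plus a per-reason
#' exclusion log. Sessions failing a hard rule (risk category, method,
#' observation count, non-positive extrapolated workload) are excluded;
#' a negative heart-rate slope voids only the slope phenotype
#' (flag `negative_slope`, `crf_slope = NA`).
#'
#' @param traces long-format trace table for any number of participants.
#' @param cohort cohort table with participant_id, age, weight,
#'   risk_category and (optionally) bike_method columns.
#' @param config a [crf_config()].
#' @return list with `records` (participant_id, crf_vo2max, crf_slope,
#'   intercept, hr_age_max, wl_hr_max, n_trend, hr_start, hr_end,
#'   qc_flags), `excluded` (participant_id, reason) and `exclusions`
#'   (per-reason counts). `nrow(cohort) == nrow(records) + nrow(excluded)`.
#' @export
derive_crf_phenotypes <- function(traces, cohort, config = crf_config()) {
  .assert(inherits(config, "crf_config"), "config must be a crf_config")
  method <- if ("bike_method" %in% names(cohort)) cohort$bike_method
  else rep("Bicycle", nrow(cohort))
  trace_split <- split(traces, traces$participant_id)

  recs <- vector("list", nrow(cohort))
  excl <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$participant_id[i]
    session <- trace_split[[pid]]
    if (is.null(session)) {
      excl[[i]] <- data.frame(participant_id = pid, reason = "no_trace")
      next
    }
    win <- select_exercise_window(session, cohort$risk_category[i], method[i])
    if (!is.null(win$reason)) {
      excl[[i]] <- data.frame(participant_id = pid, reason = win$reason)
      next
    }
    qc <- apply_qc_filters(win$observations, config$cadence_range,
                           config$min_obs)
    if (!is.null(qc$reason)) {
      excl[[i]] <- data.frame(participant_id = pid, reason = qc$reason)
      next
    }
    obs <- qc$observations
    hr_f <- lowpass_filter(obs$heart_rate, config$butter_order,
                           config$butter_cutoff)
    flags <- if (isTRUE(attr(hr_f, "filtered"))) character() else "unfiltered"

    v <- derive_vo2max(as.numeric(hr_f), obs$workload, cohort$age[i],
                       cohort$weight[i], mode = config$mode)
    if (!is.null(v$reason)) {
      excl[[i]] <- data.frame(participant_id = pid, reason = v$reason)
      next
    }
    if (!is.finite(v$vo2max) || v$vo2max <= 0) {
      excl[[i]] <- data.frame(participant_id = pid,
                              reason = "nonpositive_vo2max")
      next
    }
    s <- derive_slope(as.numeric(hr_f), obs$trend)
    crf_slope <- s$slope
    flags <- c(flags, v$flags)
    if (s$negative) {
      crf_slope <- NA_real_
      flags <- c(flags, "negative_slope")
    }
    recs[[i]] <- data.frame(
      participant_id = pid, crf_vo2max = v$vo2max, crf_slope = crf_slope,
      intercept = s$intercept, hr_age_max = v$hr_age_max,
      wl_hr_max = v$wl_hr_max, n_trend = nrow(obs),
      hr_start = v$hr_start, hr_end = v$hr_end,
      qc_flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
  }
  records <- .rbind_all(recs)
  excluded <- .rbind_all(excl)
  if (is.null(records))
    records <- data.frame(participant_id = character(), crf_vo2max = numeric(),
                          crf_slope = numeric(), intercept = numeric(),
                          hr_age_max = numeric(), wl_hr_max = numeric(),
                          n_trend = integer(), hr_start = numeric(),
                          hr_end = numeric(), qc_flags = character())
  if (is.null(excluded))
    excluded <- data.frame(participant_id = character(), reason = character())
  cnt <- table(excluded$reason)
  exclusions <- data.frame(reason = names(cnt), n = as.integer(cnt),
                           stringsAsFactors = FALSE)
  list(records = records, excluded = excluded, exclusions = exclusions)
}
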