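#' QC plot of one session's heart-rate processing
#'
#' Raw heart rate, the zero-phase Butterworth-filtered signal and the
#' fitted linear trend over the modelled exercise window for a single
#' participant.
#'
#' @param session one participant's trace data.frame.
#' @param risk_category,method passed to [select_exercise_window()].
#' @param config a [crf_config()].
#' @return a ggplot object.
#' @export
plot_session_qc <- function(session, risk_category, method = "Bicycle",
                            config = crf_config()) {
  win <- select_exercise_window(session, risk_category, method)
  .assert(is.null(win$reason), paste("session excluded:", win$reason))
  qc <- apply_qc_filters(win$observations, config$cadence_range,
                         config$min_obs)
  obs <- qc$observations
  hr_f <- as.numeric(lowpass_filter(obs$heart_rate, config$butter_order,
                                    config$butter_cutoff))
  fit <- .ols2(obs$trend, hr_f)
  d <- rbind(
    data.frame(trend = obs$trend, hr = obs$heart_rate, signal = "raw"),
    data.frame(trend = obs$trend, hr = hr_f, signal = "Butterworth filtered"),
    data.frame(trend = obs$trend, hr = fit[1] + fit[2] * obs$trend,
               signal = "linear model"))
  ggplot2::ggplot(d, ggplot2::aes(x = trend, y = hr, colour = signal)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trend (observation index)", y = "heart rate (bpm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Faceted disease-frequency-by-decile plot
#'
#' @param freq_table output of [disease_frequency()].
#' @return a ggplot object, one facet per disease group, coloured by sex.
#' @export
plot_decile_frequency <- function(freq_table) {
  ggplot2::ggplot(freq_table,
                  ggplot2::aes(x = decile, y = 100 * frequency,
                               colour = sex)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~disease_group, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = c(1, 5, 10)) +
    ggplot2::labs(x = "phenotype decile (1 = lowest)",
                  y = "diagnosis frequency (%)", colour = NULL) +
    ggplot2::theme_minimal()
}
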