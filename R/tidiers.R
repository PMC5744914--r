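# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a simulation result
#'
#' @param x an `lso_sim` object.
#' @param ... unused.
#' @return the output spike times as a tibble (`time`, s).
#' @export
tidy.lso_sim <- function(x, ...) x$spikes

#' One-row summary of a simulation result
#'
#' @param x an `lso_sim` object.
#' @param duration duration used for the rate, s; defaults to the largest
#'   spike time (0 rate for an empty train).
#' @param ... unused.
#' @return tibble with `model`, `n_spikes`, `rate` (spikes/s), `min_isi` (s).
#' @export
glance.lso_sim <- function(x, duration = NULL, ...) {
  tt <- x$spikes$time
  dur <- duration %||% if (length(tt)) max(tt) else NA_real_
  tibble(model = x$model, n_spikes = length(tt),
         rate = if (is.na(dur) || dur <= 0) 0 else length(tt) / dur,
         min_isi = if (length(tt) > 1) min(diff(tt)) else NA_real_)
}

#' Tidy a tuning curve
#'
#' @param x an `lso_tuning` tibble.
#' @param ... unused.
#' @return a plain tibble with the protocol and model attached as columns.
#' @export
tidy.lso_tuning <- function(x, ...) {
  out <- as_tibble(unclass(x)[names(x)])
  out$protocol <- attr(x, "protocol")
  out$model <- attr(x, "model")
  out
}

#' Peak/trough/depth summary of a tuning curve
#'
#' @param x an `lso_tuning` tibble with a `rate` column.
#' @param ... unused.
#' @return one-row tibble: `model`, `protocol`, `peak`, `trough`, `depth`.
#' @export
glance.lso_tuning <- function(x, ...) {
  if (!"rate" %in% names(x)) {
    return(tibble(model = attr(x, "model"), protocol = attr(x, "protocol")))
  }
  dplyr::bind_cols(tibble(model = attr(x, "model"),
                          protocol = attr(x, "protocol")),
                   tuning_stats(x))
}

#' Tidy a range score
#'
#' @param x an `lso_score` from [score_against_ranges()].
#' @param ... unused.
#' @return per-measure tibble with value and range membership.
#' @export
tidy.lso_score <- function(x, ...) as_tibble(unclass(x)[names(x)])

#' Attained-range counts of a score
#'
#' @param x an `lso_score`.
#' @param ... unused.
#' @return one-row tibble: `n_targeted`, `n_accepted` (out of `n_measures`).
#' @export
glance.lso_score <- function(x, ...) {
  tibble(n_targeted = sum(x$in_targeted), n_accepted = sum(x$in_accepted),
         n_measures = nrow(x))
}

tuning_xlab <- function(protocol) {
  switch(protocol,
    rate_mtf = "modulation frequency (Hz)",
    phase_tuning = "phase difference (cycles, + = inhibition leads)",
    ild_tuning = "ILD (dB, contra - ipsi)",
    impedance = "frequency (Hz)",
    "x")
}

#' Plot a tuning curve
#'
#' @param object an `lso_tuning` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lso_tuning <- function(object, ...) {
  proto <- attr(object, "protocol")
  ycol <- if ("rate" %in% names(object)) "rate" else "impedance"
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$x, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = tuning_xlab(proto),
                  y = if (ycol == "rate") "spike rate (spikes/s)" else "impedance (MOhm)",
                  title = paste0(attr(object, "model"), ": ", proto)) +
    ggplot2::theme_minimal()
  if (proto %in% c("rate_mtf", "impedance")) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a membrane or virtual-potential trace
#'
#' @param object an `lso_sim` with a recorded trace.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lso_sim <- function(object, ...) {
  if (is.null(object$trace)) abort("no trace recorded; rerun with `record = TRUE`")
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)",
                  y = if (object$model %in% c("coincidence", "stein_exp", "stein_alpha"))
                        "virtual potential (input units)" else "membrane potential (mV)",
                  title = object$model) +
    ggplot2::theme_minimal()
}

#' Plot an I-V relationship
#'
#' @param object an `lso_iv` from [iv_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lso_iv <- function(object, ...) {
  ggplot2::ggplot(object$iv, ggplot2::aes(x = .data$I_pA, y = .data$V_ss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "steady-state potential (mV)",
                  title = paste0(object$model, ": I-V (R_DC = ",
                                 round(object$R_DC_MOhm, 1), " MOhm)")) +
    ggplot2::theme_minimal()
}
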