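#' Forest-style plot of adverse-event signal estimates
#'
#' Point estimates and 95% intervals from [screen_ae_signals()] on a log
#' scale, one row per exposure, faceted by event set and statistic.
#'
#' @param screen Tibble from [screen_ae_signals()].
#' @param statistic `"ror"` (log scale, reference 1) or `"ic"`
#'   (bits, reference 0).
#' @return A ggplot object.
#' @export
plot_ae_signals <- function(screen, statistic = c("ror", "ic")) {
  statistic <- match.arg(statistic)
  cols <- paste0(statistic, c("", "_low", "_high"))
  dat <- screen %>%
    dplyr::rename(est = !!cols[1], lo = !!cols[2], hi = !!cols[3]) %>%
    filter(!is.na(.data$est))
  ref <- if (statistic == "ror") 1 else 0
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$est, y = .data$exposure)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dashed") +
    ggplot2::facet_wrap(~event) +
    ggplot2::labs(x = toupper(statistic), y = NULL) +
    ggplot2::theme_minimal()
  if (statistic == "ror") p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot drug-drug interaction statistics against their thresholds
#'
#' Dot plot of the four interaction statistics per partner exposure with
#' each model's decision threshold (omega025 0, additive 0, multiplicative
#' 1, chi 2) drawn as a dashed line, faceted by model and event.
#'
#' @param screen Tibble from [screen_ddi_signals()].
#' @return A ggplot object.
#' @export
plot_ddi_signals <- function(screen) {
  long <- screen %>%
    select("partner", "event", "omega025", "am", "mm", "chi") %>%
    tidyr::pivot_longer(c("omega025", "am", "mm", "chi"),
                        names_to = "model", values_to = "value")
  thresholds <- tibble(
    model = c("omega025", "am", "mm", "chi"),
    threshold = c(0, 0, 1, 2)
  )
  long <- left_join(long, thresholds, by = "model")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$partner)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(event ~ model, scales = "free_x") +
    ggplot2::labs(x = "statistic", y = NULL) +
    ggplot2::theme_minimal()
}
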