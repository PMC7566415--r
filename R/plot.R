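#' Plot a simulation trace
#'
#' Faceted time-series view of a membrane trace: measured potential,
#' gating variables, and ionic branch currents.
#'
#' @param object An `hh_trace` from [simulate_hh()].
#' @param panels Which panels to draw, any of `"voltage"`, `"gates"`,
#'   `"currents"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hh_trace
#' @export
autoplot.hh_trace <- function(object,
                              panels = c("voltage", "gates", "currents"),
                              ...) {
  panels <- match.arg(panels, several.ok = TRUE)
  long <- list()
  if ("voltage" %in% panels && "Vm_mV" %in% names(object)) {
    long$voltage <- tibble::tibble(
      time_ms = object$time_ms, panel = "membrane potential (mV)",
      series = "Vm", value = object$Vm_mV)
  }
  if ("gates" %in% panels && all(c("n", "m", "h") %in% names(object))) {
    long$gates <- tidyr::pivot_longer(
      dplyr::select(object, "time_ms", "n", "m", "h"),
      cols = c("n", "m", "h"), names_to = "series", values_to = "value")
    long$gates$panel <- "gating variables (open fraction)"
  }
  if ("currents" %in% panels && "iNa_uAcm2" %in% names(object)) {
    cur <- dplyr::select(object, "time_ms", "iNa_uAcm2", "iK_uAcm2",
                         "iL_uAcm2")
    names(cur) <- c("time_ms", "Na", "K", "leak")
    long$currents <- tidyr::pivot_longer(
      cur, cols = c("Na", "K", "leak"),
      names_to = "series", values_to = "value")
    long$currents$panel <- "branch currents (uA/cm2)"
  }
  df <- dplyr::bind_rows(long)
  if (!nrow(df)) stop("trace has none of the requested panels", call. = FALSE)
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.hh_trace <- function(x, ...) {
  print(autoplot.hh_trace(x, ...))
  invisible(x)
}
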