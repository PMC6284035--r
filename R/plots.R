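#' Plot a simulated reactor run
#'
#' Three stacked panels: VFA concentrations (gCOD/L), pH together with free
#' ammonia (g N/L, rescaled), and the relative abundances of the
#' ammonia-tolerant populations. Vertical lines mark the ammonia step and the
#' pulse disturbances.
#'
#' @param object an `adm1_sim`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.adm1_sim <- function(object, ...) {
  ts <- object$timeseries
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::select(ts, "time", acetate = "S_ac", propionate = "S_pro",
                    butyrate = "S_bu"),
      -"time", names_to = "series", values_to = "value"
    ) |> dplyr::mutate(panel = "VFA (gCOD/L)"),
    tidyr::pivot_longer(
      dplyr::select(ts, "time", pH = "pH", `NH3 (g N/L) x 10` = "S_nh3_gN") |>
        dplyr::mutate(`NH3 (g N/L) x 10` = .data$`NH3 (g N/L) x 10` * 10),
      -"time", names_to = "series", values_to = "value"
    ) |> dplyr::mutate(panel = "pH / free ammonia"),
    tidyr::pivot_longer(
      dplyr::select(ts, "time", `X_ac1 / methanogens` = "abund_ac1",
                    `X_pro1 / bacteria` = "abund_pro1"),
      -"time", names_to = "series", values_to = "value"
    ) |> dplyr::mutate(panel = "relative abundance")
  )
  marks <- tibble::tibble(
    x = c(21, object$schedule$pulses$day),
    kind = c("step", rep("pulse", nrow(object$schedule$pulses)))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$x,
                                     linetype = .data$kind),
                        colour = "grey40", show.legend = FALSE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic observation set against its generating truth
#'
#' @param object an `adm1_obs`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.adm1_obs <- function(object, ...) {
  conc <- object$concentrations
  ggplot2::ggplot(conc, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$value, colour = .data$censored),
                        size = 1) +
    ggplot2::facet_wrap(~acid, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = "concentration (gCOD/L)",
                  colour = "censored") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
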