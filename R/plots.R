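#' Plot a processed hemoglobin trace with its protocol segmentation
#'
#' Total hemoglobin and tissue oxygen saturation over time, with press
#' epochs shaded.
#'
#' @param hemo Tibble from [mbll_process()].
#' @param seg Optional [segment_protocol()] result for epoch shading.
#' @return A ggplot.
#' @export
plot_hemo <- function(hemo, seg = NULL) {
  long <- hemo |>
    dplyr::select("time_s", "d_hbt", "d_sto2") |>
    tidyr::pivot_longer(-"time_s", names_to = "signal", values_to = "value") |>
    dplyr::mutate(signal = dplyr::recode(.data$signal,
                                         d_hbt = "HbT (signal units)",
                                         d_sto2 = "StO2 (%)"))
  p <- ggplot(long, aes(x = .data$time_s, y = .data$value))
  if (!is.null(seg)) {
    shade <- tibble(xmin = seg$cycles$press_onset_s,
                    xmax = seg$cycles$press_offset_s)
    p <- p + geom_rect(data = shade,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "grey85")
  }
  p + geom_line(color = "firebrick") +
    facet_wrap(~signal, ncol = 1, scales = "free_y") +
    labs(x = "Time (s)", y = NULL,
         title = "Hemoglobin response to the press-release protocol") +
    theme_minimal()
}

#' @rdname segment_protocol
#' @param object A `protocol_segmentation`.
#' @param trace The pressure trace it came from.
#' @param ... Unused.
#' @method autoplot protocol_segmentation
#' @export
autoplot.protocol_segmentation <- function(object, trace, ...) {
  shade <- tibble(xmin = object$cycles$press_onset_s,
                  xmax = object$cycles$press_offset_s)
  ggplot(trace, aes(x = .data$time_s, y = .data$pressure)) +
    geom_rect(data = shade,
              aes(xmin = .data$xmin, xmax = .data$xmax,
                  ymin = -Inf, ymax = Inf),
              inherit.aes = FALSE, fill = "grey85") +
    geom_line(color = "steelblue") +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    labs(x = "Time (s)", y = "Pressure (sensor units)",
         title = "Detected press epochs") +
    theme_minimal()
}

#' Fuzzy classifier output by group
#'
#' Distribution of the RBF network output for each perfusion group; the
#' output is expected to rise from the good-perfusion group (I) toward the
#' poor-perfusion group (IV).
#'
#' @param features Feature tibble with a `group` column.
#' @param model A fitted `rbfnn`.
#' @return A ggplot.
#' @export
plot_group_outputs <- function(features, model) {
  df <- features |> dplyr::mutate(output = predict(model, features))
  ggplot(df, aes(x = .data$group, y = .data$output)) +
    geom_boxplot(fill = "grey90") +
    geom_hline(yintercept = model$threshold, linetype = "dashed",
               color = "firebrick") +
    labs(x = "Group", y = "RBFNN output",
         title = "Classifier output by perfusion group") +
    theme_minimal()
}
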