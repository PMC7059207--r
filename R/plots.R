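# ggplot2 displays for curves, fits and study reports.

#' @export
autoplot.afroc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpf, y = .data$tpf)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive fraction (1 - specificity)",
                  y = "True-positive fraction",
                  title = sprintf("Empirical AFROC curve (FOM = %.3f)",
                                  attr(object, "fom"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.proproc_fit <- function(object, fpf_grid = seq(0, 1, by = 0.005), ...) {
  crv <- proproc_curve(object, fpf_grid)
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$fpf, y = .data$tpf)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$cutpoints, shape = 1, size = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive fraction", y = "True-positive fraction",
                  title = sprintf("Proper binormal fit (c = %.2f, d_a = %.2f, AUC = %.3f)",
                                  object$c, object$d_a, full_auc(object))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.study_report <- function(object, fom = "auc", ...) {
  m <- object$mrmc[[fom]]
  if (is.null(m)) stop_input(sprintf("no figure of merit named '%s'.", fom))
  td <- tidy(m)
  td$reader_id <- factor(td$reader_id, levels = c("pooled",
                                                  sort(setdiff(unique(td$reader_id), "pooled"))))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$reader_id, y = .data$estimate,
                                   colour = .data$modality)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = fom,
                  title = sprintf("%s by reader (P = %.3f, pooled difference %.3f)",
                                  fom, m$difference$p_value,
                                  m$difference$estimate)) +
    ggplot2::theme_minimal()
}

#' Plot pooled AFROC curves for both reading conditions
#'
#' Overlays the reader-pooled empirical AFROC curves of the unaided and
#' CAD-validated conditions, with the pAUC interval marked.
#'
#' @param report A `study_report` from [analyze_study()].
#' @return A ggplot object.
#' @export
plot_afroc_comparison <- function(report) {
  crv <- purrr::imap_dfr(report$scores, function(sc, arm) {
    pooled <- afroc_curve(sc)  # all readers pooled as one score set
    dplyr::mutate(as_tibble(pooled), modality = arm)
  })
  lim <- report$settings$pauc_interval[2]
  ggplot2::ggplot(crv, ggplot2::aes(x = .data$fpf, y = .data$tpf,
                                    colour = .data$modality)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_vline(xintercept = lim, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive fraction (1 - specificity)",
                  y = "True-positive fraction") +
    ggplot2::theme_minimal()
}
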