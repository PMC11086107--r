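#' Plot training and validation loss curves
#'
#' Shows the composite deeply supervised loss per epoch for the training and
#' validation sets, and optionally the per-head validation MAEs.
#'
#' @param object A `ppgbp_fit`.
#' @param heads If `TRUE`, add one curve per supervision head.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @importFrom ggplot2 autoplot
autoplot.ppgbp_fit <- function(object, heads = FALSE, ...) {
  h <- object$history
  df <- tidyr::pivot_longer(h[, c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "set", values_to = "loss")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                        colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "composite MAE loss", colour = NULL) +
    ggplot2::theme_minimal()
  if (heads) {
    hd <- tidy(object)
    p <- p + ggplot2::geom_line(
      data = hd,
      ggplot2::aes(.data$epoch, .data$val_head_mae, group = .data$head),
      linetype = "dashed", inherit.aes = FALSE, alpha = 0.6
    )
  }
  p
}

#' Plot an evaluation report
#'
#' @param object A `bp_evaluation`.
#' @param type `"bland_altman"` (differences vs means with the 95% limits of
#'   agreement), `"error_hist"` (absolute-error histogram with the BHS
#'   thresholds), or `"regression"` (predicted vs true with the identity and
#'   fitted lines).
#' @param parameter `"sbp"`, `"dbp"` or `"mbp"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_evaluation <- function(object,
                                   type = c("bland_altman", "error_hist",
                                            "regression"),
                                   parameter = c("sbp", "dbp", "mbp"), ...) {
  type <- match.arg(type)
  parameter <- match.arg(parameter)
  yt <- object$pairs[[paste0(parameter, "_true")]]
  yp <- object$pairs[[paste0(parameter, "_pred")]]
  lab <- toupper(parameter)
  if (type == "bland_altman") {
    ba <- bland_altman(yt, yp)
    df <- tibble::tibble(mean = (yt + yp) / 2, diff = yp - yt)
    ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::labs(x = paste(lab, "mean of true and predicted (mmHg)"),
                    y = "predicted - true (mmHg)") +
      ggplot2::theme_minimal()
  } else if (type == "error_hist") {
    df <- tibble::tibble(abs_error = abs(yt - yp))
    ggplot2::ggplot(df, ggplot2::aes(.data$abs_error)) +
      ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
      ggplot2::geom_vline(xintercept = c(5, 10, 15), linetype = "dashed") +
      ggplot2::labs(x = paste(lab, "absolute error (mmHg)"), y = "count") +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(true = yt, pred = yp)
    ggplot2::ggplot(df, ggplot2::aes(.data$true, .data$pred)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkgreen") +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "firebrick", linetype = "dashed") +
      ggplot2::labs(x = paste("true", lab, "(mmHg)"),
                    y = paste("predicted", lab, "(mmHg)")) +
      ggplot2::theme_minimal()
  }
}
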