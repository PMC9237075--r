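# broom-style accessors and ggplot2 views of fitted models and study tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy the training history of a fitted model
#'
#' @param x an `ennet_fit`.
#' @param ... unused.
#' @return tibble with one row per epoch: `epoch`, `lr`, `train_loss`,
#'   `train_dice`, `val_loss`, `val_dice` (validation columns are `NA` on
#'   epochs without validation).
#' @export
tidy.ennet_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x an `ennet_fit`.
#' @param ... unused.
#' @return tibble: `combo`, `epochs`, `n_parameters`, `best_epoch`,
#'   `best_val_dice`, `final_train_loss`, `final_train_dice`.
#' @export
glance.ennet_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(combo = x$combo$code, epochs = nrow(h),
                 n_parameters = count_parameters(x$net),
                 best_epoch = x$best_epoch, best_val_dice = x$best_val_dice,
                 final_train_loss = h$train_loss[nrow(h)],
                 final_train_dice = h$train_dice[nrow(h)])
}

#' Training curves
#'
#' Dice and loss traces over epochs (training every epoch, validation at its
#' cadence), the standard view of training progress.
#'
#' @param object an `ennet_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ennet_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_dice, series = "train",
                   measure = "dice"),
    tibble::tibble(epoch = h$epoch, value = h$train_loss, series = "train",
                   measure = "loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_dice, series = "validation",
                   measure = "dice"),
    tibble::tibble(epoch = h$epoch, value = h$val_loss, series = "validation",
                   measure = "loss"))
  long <- long[!is.na(long$value), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Modality-combination comparison plot
#'
#' Mean test Dice (with one-standard-deviation error bars) per modality
#' combination from [run_combination_study()].
#'
#' @param study tibble returned by [run_combination_study()].
#' @return a ggplot object.
#' @export
plot_combination_study <- function(study) {
  stopifnot(all(c("combo", "dice_mean", "dice_sd") %in% names(study)))
  ord <- study$combo[order(study$dice_mean)]
  study$combo <- factor(study$combo, levels = ord)
  ggplot2::ggplot(study, ggplot2::aes(x = .data$combo, y = .data$dice_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dice_mean - .data$dice_sd,
                                        ymax = .data$dice_mean + .data$dice_sd),
                           width = 0.3) +
    ggplot2::coord_cartesian(ylim = c(min(study$dice_mean) * 0.95, 1)) +
    ggplot2::labs(x = "modality combination", y = "test Dice (mean ± sd)") +
    ggplot2::theme_minimal()
}
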