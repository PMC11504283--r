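# Tidy summaries and plots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold cross-validation results
#'
#' @param x A `mercl_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold: `fold`, `accuracy`, `f1_macro`,
#'   `n_test`.
#' @method tidy mercl_cv
#' @export
tidy.mercl_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x A `mercl_cv`.
#' @param ... Unused.
#' @return Tibble with fold count and mean/sd accuracy and macro F1.
#' @method glance mercl_cv
#' @export
glance.mercl_cv <- function(x, ...) {
  tibble::tibble(k = x$k, mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy, mean_f1 = x$mean_f1,
                 sd_f1 = x$sd_f1)
}

#' Pre-training loss curve as a tibble
#'
#' @param x A `mercl_encoder`.
#' @param ... Unused.
#' @return The per-epoch loss log (total and unweighted term means).
#' @method tidy mercl_encoder
#' @export
tidy.mercl_encoder <- function(x, ...) {
  if (is.null(x$loss_log)) stopf("encoder has not been pre-trained")
  x$loss_log
}

#' Fine-tuning loss curve as a tibble
#'
#' @param x A `mercl_model`.
#' @param ... Unused.
#' @return Per-epoch cross-entropy and training accuracy.
#' @method tidy mercl_model
#' @export
tidy.mercl_model <- function(x, ...) x$loss_log

#' Plot per-fold cross-validation accuracy and F1
#'
#' @param object A `mercl_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mercl_cv
#' @export
autoplot.mercl_cv <- function(object, ...) {
  df <- object$folds
  long <- rbind(
    data.frame(fold = df$fold, metric = "accuracy", value = df$accuracy),
    data.frame(fold = df$fold, metric = "macro F1", value = df$f1_macro))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = NULL,
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the pre-training loss curves
#'
#' @param object A pre-trained `mercl_encoder`.
#' @param ... Unused.
#' @return A ggplot object with the total and per-term losses by epoch.
#' @method autoplot mercl_encoder
#' @export
autoplot.mercl_encoder <- function(object, ...) {
  ll <- tidy(object)
  long <- do.call(rbind, lapply(c("total", "amcl", "emcl", "smcl"),
                                function(tm) data.frame(epoch = ll$epoch,
                                                        term = tm,
                                                        loss = ll[[tm]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "contrastive pre-training",
                  y = "loss (unweighted terms)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
#' @keywords internal
NULL
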