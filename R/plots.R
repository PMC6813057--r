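#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An `reo_roc` tibble from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reo_roc
#' @export
autoplot.reo_roc <- function(object, ...) {
  auc <- attr(object, "auc")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC of signature vote counts",
                  subtitle = sprintf("AUC = %.4f", auc)) +
    ggplot2::theme_minimal()
}

#' Plot the vote-count distribution of predictions
#'
#' Histogram of per-sample signature votes, filled by predicted status, with
#' the vote threshold marked. Samples at or right of the line are called MSI.
#'
#' @param object An `reo_prediction` tibble from [predict.reo_signature()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reo_prediction
#' @export
autoplot.reo_prediction <- function(object, ...) {
  k <- attr(object, "vote_threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$votes, fill = .data$predicted)) +
    ggplot2::geom_bar(width = 0.9) +
    ggplot2::geom_vline(xintercept = k - 0.5, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(MSI = "#b2182b", MSS = "#2166ac"),
                               drop = FALSE, name = "Predicted") +
    ggplot2::labs(x = "MSI votes (pairs with gene1 > gene2)", y = "Samples",
                  title = sprintf("Signature votes (threshold k = %d)", k)) +
    ggplot2::theme_minimal()
}

#' Plot per-threshold training metrics
#'
#' Sensitivity, specificity and F-score as functions of the vote threshold
#' `k`, as evaluated by [select_vote_threshold()].
#'
#' @param per_k Tibble with columns `k`, `sensitivity`, `specificity`,
#'   `f_score`.
#' @return A ggplot object.
#' @export
plot_threshold_metrics <- function(per_k) {
  long <- tibble(
    k = rep(per_k$k, 3),
    metric = rep(c("sensitivity", "specificity", "f_score"),
                 each = nrow(per_k)),
    value = c(per_k$sensitivity, per_k$specificity, per_k$f_score)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Vote threshold k", y = NULL, colour = NULL,
                  title = "Classification metrics across vote thresholds") +
    ggplot2::theme_minimal()
}
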