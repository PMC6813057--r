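#' Confusion counts with MSI as the positive class
#'
#' @param predictions Predicted statuses (`MSI`/`MSS`, factor or character),
#'   or an `reo_prediction` tibble (its `predicted` column is used, matched
#'   to `truths` by `sample_id` when `truths` is a label table).
#' @param truths True statuses, same length, or a label table
#'   (`sample_id`, `status`).
#' @return One-row tibble with integer columns `tp`, `fn`, `fp`, `tn`
#'   (`tp + fn` = true MSI, `fp + tn` = true MSS).
#' @export
confusion <- function(predictions, truths) {
  al <- align_pred_truth(predictions, truths)
  tibble(
    tp = sum(al$pred == "MSI" & al$truth == "MSI"),
    fn = sum(al$pred == "MSS" & al$truth == "MSI"),
    fp = sum(al$pred == "MSI" & al$truth == "MSS"),
    tn = sum(al$pred == "MSS" & al$truth == "MSS")
  )
}

align_pred_truth <- function(predictions, truths) {
  truth_tbl <- NULL
  if (is.data.frame(truths) && all(c("sample_id", "status") %in% names(truths))) {
    truth_tbl <- tibble::as_tibble(truths)
  }
  if (inherits(predictions, "reo_prediction") ||
      (is.data.frame(predictions) &&
       all(c("sample_id", "predicted") %in% names(predictions)))) {
    pred_tbl <- tibble::as_tibble(predictions)
    if (is.null(truth_tbl)) {
      stop_data("when predictions carry sample ids, truths must be a label table")
    }
    common <- intersect(pred_tbl$sample_id, truth_tbl$sample_id)
    if (length(common) == 0) {
      stop_data("predictions and truth labels share no sample ids")
    }
    only_p <- setdiff(pred_tbl$sample_id, truth_tbl$sample_id)
    only_t <- setdiff(truth_tbl$sample_id, pred_tbl$sample_id)
    if (length(only_p) > 0 || length(only_t) > 0) {
      stop_data(sprintf(
        "sample id mismatch between predictions and truths (only in predictions: %s; only in truths: %s)",
        paste(head(only_p, 5), collapse = ",") %||% "-",
        paste(head(only_t, 5), collapse = ",") %||% "-"))
    }
    pred <- as.character(pred_tbl$predicted)
    names(pred) <- pred_tbl$sample_id
    pred <- pred[truth_tbl$sample_id]
    truth <- normalize_status(truth_tbl$status)
  } else {
    if (length(predictions) == 0) {
      stop_data("empty predictions")
    }
    tr <- if (is.null(truth_tbl)) truths else truth_tbl$status
    if (length(predictions) != length(tr)) {
      stop_data(sprintf("length mismatch: %d predictions vs %d truths",
                        length(predictions), length(tr)))
    }
    pred <- normalize_status(predictions)
    truth <- normalize_status(tr)
  }
  list(pred = pred, truth = truth)
}

#' Sensitivity, specificity and F-score from confusion counts
#'
#' The F-score here is the harmonic mean of sensitivity and specificity,
#' `2 * sens * spec / (sens + spec)` — not the precision/recall F1 — so a
#' classifier must do well on both classes to score well.
#'
#' @param cm One-row tibble (or named list/vector) with `tp`, `fn`, `fp`,
#'   `tn`.
#' @return One-row tibble: `sensitivity`, `specificity`, `f_score`.
#' @examples
#' metrics_from_confusion(tibble::tibble(tp = 13, fn = 1, fp = 0, tn = 14))
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.list(cm)
  need <- c("tp", "fn", "fp", "tn")
  if (!all(need %in% names(cm))) {
    stop_validation("confusion input must carry tp, fn, fp, tn")
  }
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  if (tp + fn == 0 || fp + tn == 0) {
    stop_data("both classes must be represented (tp+fn > 0 and fp+tn > 0)")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  tibble(sensitivity = sens, specificity = spec,
         f_score = harmonic_f(sens, spec))
}

#' Area under the ROC curve from vote-count scores
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that
#' a random MSI sample scores above a random MSS sample, ties counting 1/2.
#' Identical to the trapezoidal area under the ROC curve swept across all
#' thresholds of an integer score.
#'
#' @param scores Numeric scores (e.g. signature votes), higher = more
#'   MSI-like.
#' @param truths True statuses aligned with `scores` (`MSI`/`MSS`).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truths) {
  truth <- normalize_status(truths)
  if (length(scores) != length(truth)) {
    stop_data("scores and truths must have the same length")
  }
  n1 <- sum(truth == "MSI"); n0 <- sum(truth == "MSS")
  if (n1 == 0 || n0 == 0) {
    stop_data("both classes must be present to compute an AUC")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == "MSI"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from vote-count scores
#'
#' Sweeps the decision threshold across all observed score values and
#' records (1 - specificity, sensitivity) at each, for plotting with
#' [ggplot2::autoplot()].
#'
#' @inheritParams roc_auc
#' @return Tibble of class `reo_roc` with columns `threshold`, `sensitivity`,
#'   `specificity`, `fpr`; AUC attached as attribute `auc`.
#' @export
roc_points <- function(scores, truths) {
  truth <- normalize_status(truths)
  if (length(scores) != length(truth)) {
    stop_data("scores and truths must have the same length")
  }
  is_msi <- truth == "MSI"
  if (!any(is_msi) || all(is_msi)) {
    stop_data("both classes must be present to compute a ROC curve")
  }
  thr <- c(sort(unique(scores)), Inf)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(threshold = t,
           sensitivity = sum(pred & is_msi) / sum(is_msi),
           specificity = sum(!pred & !is_msi) / sum(!is_msi))
  })
  pts$fpr <- 1 - pts$specificity
  pts <- dplyr::arrange(pts, .data$fpr, .data$sensitivity)
  attr(pts, "auc") <- roc_auc(scores, truths)
  class(pts) <- c("reo_roc", class(pts))
  pts
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper joining [confusion()], [metrics_from_confusion()] and,
#' when vote counts are available, [roc_auc()].
#'
#' @param predictions An `reo_prediction` tibble (from
#'   [predict.reo_signature()]) or a status vector.
#' @param truths Label table or status vector (see [confusion()]).
#' @param digits Rounding (half-up) applied to the reported metrics; `NULL`
#'   for full precision. Default 4, the conventional printed precision.
#' @return One-row tibble: `tp`, `fn`, `fp`, `tn`, `sensitivity`,
#'   `specificity`, `f_score`, and `auc` when scores were available.
#' @export
evaluate_predictions <- function(predictions, truths, digits = 4) {
  cm <- confusion(predictions, truths)
  met <- metrics_from_confusion(cm)
  out <- dplyr::bind_cols(cm, met)
  if (is.data.frame(predictions) && "votes" %in% names(predictions) &&
      is.data.frame(truths) && "sample_id" %in% names(truths)) {
    pt <- tibble::as_tibble(predictions)
    tt <- tibble::as_tibble(truths)
    scores <- setNames(pt$votes, pt$sample_id)[tt$sample_id]
    out$auc <- roc_auc(scores, tt$status)
  }
  if (!is.null(digits)) {
    num <- setdiff(names(out), c("tp", "fn", "fp", "tn"))
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  out
}

#' Cluster-based assessment of signature-disconfirmed samples
#'
#' When the signature's call contradicts a sample's recorded status, the
#' transcriptome itself can arbitrate: genes differentially expressed between
#' the signature-confirmed MSI and MSS samples are selected (Student's t, BH
#' FDR), the top `n_top` (by ascending q, then p, then gene id) are used to
#' cluster all samples (complete linkage, Euclidean distance, tree cut into
#' two), each cluster is labeled by the majority class of its confirmed
#' members, and each query sample's cluster membership is reported.
#'
#' @param matrix Genes-by-samples expression matrix containing confirmed and
#'   query samples.
#' @param confirmed_labels Label table for the signature-confirmed samples
#'   only.
#' @param query_ids Sample ids to assess (must be columns of `matrix`).
#' @param n_top Number of top DE genes to cluster on (default 100); if fewer
#'   are significant, all available are used with a warning.
#' @param fdr_cutoff BH q cutoff for the DE screen (default 0.01).
#' @return A tibble with one row per query: `sample_id`, `cluster` (1 or 2),
#'   `cluster_class` (`MSI`, `MSS` or `unassigned` when a cluster has no
#'   confirmed members or its confirmed classes tie). Attributes
#'   `genes_used` (character vector) and `cluster_classes` record the
#'   clustering basis.
#' @export
cluster_assessment <- function(matrix, confirmed_labels, query_ids,
                               n_top = 100, fdr_cutoff = 0.01) {
  matrix <- as_expression_matrix(matrix)
  confirmed_labels <- align_labels(matrix, confirmed_labels)
  query_ids <- as.character(query_ids)
  missing <- setdiff(query_ids, colnames(matrix))
  if (length(missing) > 0) {
    stop_data(sprintf("query sample(s) absent from matrix: %s",
                      paste(missing, collapse = ", ")))
  }
  if (nlevels(droplevels(confirmed_labels$status)) < 2) {
    stop_data("confirmed samples must span both MSI and MSS")
  }
  de <- screen_de_genes(matrix, confirmed_labels, fdr_cutoff = fdr_cutoff)
  sig <- de[de$retained, , drop = FALSE]
  if (nrow(sig) == 0) {
    stop_data(sprintf("no DE genes at FDR < %g between confirmed classes", fdr_cutoff))
  }
  if (nrow(sig) < n_top) {
    warn(sprintf("only %d DE genes available (requested top %d); using all",
                 nrow(sig), n_top))
  }
  sig <- dplyr::arrange(sig, .data$q_value, .data$p_value, .data$gene_id)
  genes <- head(sig$gene_id, n_top)

  ids <- sort(colnames(matrix))  # order-invariant clustering input
  sub <- t(matrix[genes, ids, drop = FALSE])
  cl <- cutree(hclust(dist(sub, method = "euclidean"), method = "complete"), k = 2)
  conf_cl <- cl[confirmed_labels$sample_id]
  cluster_class <- vapply(1:2, function(g) {
    members <- confirmed_labels$status[conf_cl == g]
    if (length(members) == 0) return("unassigned")
    n_msi <- sum(members == "MSI"); n_mss <- sum(members == "MSS")
    if (n_msi > n_mss) "MSI" else if (n_mss > n_msi) "MSS" else "unassigned"
  }, character(1))

  out <- tibble(
    sample_id = query_ids,
    cluster = as.integer(cl[query_ids]),
    cluster_class = cluster_class[cl[query_ids]]
  )
  attr(out, "genes_used") <- genes
  attr(out, "cluster_classes") <- cluster_class
  out
}

#' Write an evaluation report
#'
#' TSV (one row per dataset tag) and optionally JSON.
#'
#' @param metrics Tibble as returned by [evaluate_predictions()], with an
#'   optional `dataset` column.
#' @param path Output TSV path.
#' @param json_path Optional JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(metrics, path, json_path = NULL) {
  metrics <- tibble::as_tibble(metrics)
  readr::write_tsv(metrics, path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  invisible(path)
}
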