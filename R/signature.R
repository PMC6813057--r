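#' Construct a gene-pair signature
#'
#' A signature is an ordered list of oriented gene pairs together with a vote
#' threshold `k`: a sample is called MSI when the within-sample ordering
#' `E[gene1] > E[gene2]` holds for at least `k` of the pairs, otherwise MSS.
#' Orderings are invariant to any strictly increasing per-sample transform,
#' so the rule needs no normalisation and applies to a single profile.
#'
#' @param pairs Two-column data frame (`gene1`, `gene2`) or a pair-statistics
#'   tibble; the pattern `gene1 > gene2` votes MSI.
#' @param vote_threshold Integer `k`, `1 <= k <= nrow(pairs)`.
#' @param metadata Optional named list of provenance (thresholds used,
#'   per-stage counts, training metrics).
#' @return An object of class `reo_signature`.
#' @export
new_signature <- function(pairs, vote_threshold, metadata = list()) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("gene1", "gene2") %in% names(pairs))) {
    stop_validation("pairs must have columns gene1 and gene2")
  }
  pairs$gene1 <- as.character(pairs$gene1)
  pairs$gene2 <- as.character(pairs$gene2)
  if (nrow(pairs) == 0) {
    stop_validation("a signature needs at least one gene pair")
  }
  if (any(pairs$gene1 == pairs$gene2)) {
    stop_validation("a pair cannot compare a gene with itself")
  }
  genes <- c(pairs$gene1, pairs$gene2)
  if (anyDuplicated(genes)) {
    stop_validation(sprintf("each gene may appear in only one pair; duplicated: %s",
                            paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  k <- as.integer(vote_threshold)
  if (is.na(k) || k < 1 || k > nrow(pairs)) {
    stop_validation(sprintf("vote_threshold must be an integer in [1, %d]", nrow(pairs)))
  }
  structure(list(pairs = pairs[, c("gene1", "gene2")],
                 vote_threshold = k,
                 metadata = metadata),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("REO gene-pair signature: %d pairs, vote threshold k = %d\n",
              nrow(x$pairs), x$vote_threshold))
  cat(sprintf("Rule: call MSI when E[gene1] > E[gene2] for >= %d pairs\n",
              x$vote_threshold))
  for (r in seq_len(nrow(x$pairs))) {
    cat(sprintf("  pair%-2d  %s > %s\n", r, x$pairs$gene1[r], x$pairs$gene2[r]))
  }
  if (length(x$metadata) > 0) {
    cat("Provenance:",
        paste(names(x$metadata),
              vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @method tidy reo_signature
#' @export
tidy.reo_signature <- function(x, ...) {
  dplyr::mutate(x$pairs, pair = dplyr::row_number(), .before = 1)
}

#' @method glance reo_signature
#' @export
glance.reo_signature <- function(x, ...) {
  md <- x$metadata
  tibble(
    n_pairs = nrow(x$pairs),
    vote_threshold = x$vote_threshold,
    fd_min = md$fd_min %||% NA_real_,
    n_de_genes = md$n_de_genes %||% NA_integer_,
    n_candidate_pairs = md$n_candidate_pairs %||% NA_integer_,
    n_after_redundancy = md$n_after_redundancy %||% NA_integer_,
    training_f_score = md$training_f_score %||% NA_real_
  )
}

#' The published 10-gene-pair MSI signature for right-sided colon cancer
#'
#' Ten oriented gene pairs with vote threshold k = 7: a right-sided colon
#' tumor is called MSI when, within its own profile, `E[gene1] > E[gene2]`
#' holds for at least 7 of the 10 pairs.
#'
#' @return An `reo_signature` with 10 pairs and `vote_threshold = 7`.
#' @examples
#' builtin_10gps()
#' @export
builtin_10gps <- function() {
  pairs <- tibble(
    gene1 = c("HNRNPL", "MTA2", "CALR", "RASL11A", "LYG1",
              "STRN3", "HPSE", "PRPF39", "CCRN4L", "AMFR"),
    gene2 = c("CDC16", "VGF", "SEC22B", "CAB39L", "DHRS12",
              "TMEM192", "BCAS3", "ATF6", "GRM8", "DUSP18")
  )
  new_signature(pairs, vote_threshold = 7,
                metadata = list(name = "10-GPS",
                                cohort = "right-sided colon cancer"))
}

#' Filter pair statistics by minimum frequency difference
#'
#' Keeps pairs whose `fd` is at least `fd_min` ("at least", i.e. the boundary
#' is inclusive), preserving order. Returns an empty tibble rather than
#' erroring when nothing survives, so callers can decide.
#'
#' @param pairs Pair-statistics tibble with an `fd` column.
#' @param fd_min Minimum FD in \[0, 1\].
#' @return Filtered tibble.
#' @export
filter_by_fd <- function(pairs, fd_min) {
  if (!is.numeric(fd_min) || length(fd_min) != 1 || fd_min < 0 || fd_min > 1) {
    stop_validation("fd_min must be a single value in [0, 1]")
  }
  pairs <- tibble::as_tibble(pairs)
  if (!"fd" %in% names(pairs)) {
    stop_validation("pairs must carry an fd column")
  }
  pairs[pairs$fd >= fd_min, , drop = FALSE]
}

#' Count signature votes in one sample
#'
#' A pair votes MSI when strictly `value[gene1] > value[gene2]`; a tie is not
#' a vote. With `missing_policy = "drop"`, pairs whose genes are absent from
#' the profile are excluded and `pairs_used` reduced accordingly (e.g. when
#' applying a fixed signature to a platform missing a gene).
#'
#' @param sample_expression Named numeric vector (names are gene ids), or a
#'   one-column matrix with gene rownames.
#' @param signature An `reo_signature`.
#' @param missing_policy `"error"` (default): all signature genes must be
#'   present; `"drop"`: skip pairs with missing genes.
#' @return A list with `votes` and `pairs_used` (both integers).
#' @export
count_votes <- function(sample_expression, signature,
                        missing_policy = c("error", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(signature, "reo_signature"))
  v <- as_profile(sample_expression)
  p <- signature$pairs
  have <- p$gene1 %in% names(v) & p$gene2 %in% names(v)
  if (missing_policy == "error" && !all(have)) {
    miss <- setdiff(unique(c(p$gene1, p$gene2)), names(v))
    stop_data(sprintf("signature gene(s) missing from profile: %s",
                      paste(miss, collapse = ", ")))
  }
  p <- p[have, , drop = FALSE]
  votes <- sum(v[p$gene1] > v[p$gene2])
  list(votes = as.integer(votes), pairs_used = as.integer(nrow(p)))
}

as_profile <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 1) stop_validation("profile matrix must have a single column")
    x <- setNames(x[, 1], rownames(x))
  }
  if (!is.numeric(x) || is.null(names(x))) {
    stop_validation("sample expression must be a named numeric vector")
  }
  x
}

#' Classify one sample's MSI status
#'
#' Applies the signature's majority-vote rule to a single profile: MSI when
#' the votes reach the (possibly rescaled) threshold, otherwise MSS. When
#' pairs are dropped for missing genes the threshold is rescaled to
#' `ceiling(k * pairs_used / n_pairs)` (minimum 1) so the required vote
#' fraction is preserved.
#'
#' @inheritParams count_votes
#' @return `"MSI"` or `"MSS"`.
#' @examples
#' sig <- builtin_10gps()
#' prof <- setNames(c(rep(2, 10), rep(1, 10)),
#'                  c(sig$pairs$gene1, sig$pairs$gene2))
#' classify(prof, sig)
#' @export
classify <- function(sample_expression, signature,
                     missing_policy = c("error", "drop")) {
  cv <- count_votes(sample_expression, signature, missing_policy)
  if (cv$pairs_used == 0) {
    stop_data("no signature pair is usable in this profile")
  }
  k_eff <- effective_threshold(signature$vote_threshold, cv$pairs_used,
                               nrow(signature$pairs))
  if (cv$votes >= k_eff) "MSI" else "MSS"
}

effective_threshold <- function(k, pairs_used, n_pairs) {
  max(1L, as.integer(ceiling(k * pairs_used / n_pairs)))
}

#' Predict MSI status for every sample of a matrix
#'
#' @param object An `reo_signature`.
#' @param newdata Genes-by-samples expression matrix.
#' @param missing_policy See [count_votes()].
#' @param ... Unused.
#' @return A tibble of class `reo_prediction` with columns `sample_id`,
#'   `votes`, `pairs_used`, `predicted` (factor MSI/MSS); the signature's
#'   threshold is attached as attribute `vote_threshold`.
#' @export
predict.reo_signature <- function(object, newdata,
                                  missing_policy = c("error", "drop"), ...) {
  missing_policy <- match.arg(missing_policy)
  newdata <- as_expression_matrix(newdata)
  rows <- purrr::map(colnames(newdata), function(s) {
    cv <- count_votes(setNames(newdata[, s], rownames(newdata)), object,
                      missing_policy)
    if (cv$pairs_used == 0) {
      stop_data(sprintf("no signature pair is usable in sample %s", s))
    }
    k_eff <- effective_threshold(object$vote_threshold, cv$pairs_used,
                                 nrow(object$pairs))
    tibble(sample_id = s, votes = cv$votes, pairs_used = cv$pairs_used,
           predicted = if (cv$votes >= k_eff) "MSI" else "MSS")
  })
  out <- dplyr::bind_rows(rows)
  out$predicted <- factor(out$predicted, levels = c("MSI", "MSS"))
  attr(out, "vote_threshold") <- object$vote_threshold
  class(out) <- c("reo_prediction", class(out))
  out
}

#' Choose the vote threshold maximising the F-score
#'
#' Evaluates every threshold `k = 1..n_pairs` against the training labels,
#' predicting MSI when `votes >= k`, and returns the `k` with the largest
#' F-score (harmonic mean of sensitivity and specificity). Ties are broken
#' toward larger `k`, the more specific classifier.
#'
#' @param vote_counts Integer votes per sample, aligned with `labels` (either
#'   named by sample id or in the same order).
#' @param labels Label table (`sample_id`, `status`).
#' @param n_pairs Number of pairs in the signature.
#' @return A list with `k` (selected threshold) and `per_k` (tibble: `k`,
#'   `sensitivity`, `specificity`, `f_score`).
#' @export
select_vote_threshold <- function(vote_counts, labels, n_pairs) {
  labels <- tibble::as_tibble(labels)
  status <- factor(normalize_status(labels$status), levels = c("MSI", "MSS"))
  if (length(vote_counts) != nrow(labels)) {
    stop_data("vote_counts and labels must have the same length")
  }
  if (!is.null(names(vote_counts))) {
    if (!setequal(names(vote_counts), labels$sample_id)) {
      stop_data("vote_counts names do not match label sample ids")
    }
    vote_counts <- vote_counts[labels$sample_id]
  }
  if (nlevels(droplevels(status)) < 2) {
    stop_data("both MSI and MSS must be present to select a threshold")
  }
  is_msi <- status == "MSI"
  per_k <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    pred_msi <- vote_counts >= k
    sens <- sum(pred_msi & is_msi) / sum(is_msi)
    spec <- sum(!pred_msi & !is_msi) / sum(!is_msi)
    tibble(k = k, sensitivity = sens, specificity = spec,
           f_score = harmonic_f(sens, spec))
  })
  best <- max(per_k$f_score)
  k <- max(per_k$k[per_k$f_score == best])
  list(k = as.integer(k), per_k = per_k)
}

harmonic_f <- function(sensitivity, specificity) {
  s <- sensitivity + specificity
  ifelse(s == 0, 0, 2 * sensitivity * specificity / s)
}

#' Fit a gene-pair signature from labeled training data
#'
#' Runs the full discovery pipeline: (1) Student's t DE screen at
#' `de_fdr`; (2) one-sided Fisher screen over all DE-gene pairs at
#' `pair_fdr`; (3) redundancy removal keeping each gene's largest-FD pair;
#' (4) FD filter at `fd_min`; (5) vote-threshold selection maximising the
#' training F-score. The pipeline is fully deterministic.
#'
#' @inheritParams screen_de_genes
#' @param de_fdr BH q cutoff for the DE screen (default 0.01).
#' @param pair_fdr BH q cutoff for the Fisher pair screen (default 0.01).
#' @param fd_min Minimum FD for signature pairs (default 0.8; 0.9 is the
#'   analogous published choice for left-sided tumors).
#' @param max_de_genes Optional cap on DE genes entering the pair screen
#'   (ranked by t-test p); `NULL` = all.
#' @return An `reo_signature` whose `metadata` records every threshold and
#'   per-stage count plus the training metrics at the chosen `k`.
#' @examples
#' sim <- simulate_dataset(seed = 7)
#' sig <- fit_signature(sim$expression, sim$labels)
#' glance(sig)
#' @export
fit_signature <- function(matrix, labels, de_fdr = 0.01, pair_fdr = 0.01,
                          fd_min = 0.8, max_de_genes = NULL) {
  matrix <- as_expression_matrix(matrix)
  labels <- align_labels(matrix, labels)
  de <- screen_de_genes(matrix, labels, fdr_cutoff = de_fdr)
  de_genes <- de$gene_id[de$retained]
  if (length(de_genes) < 2) {
    stop_data(sprintf(
      "stage screen_de_genes produced %d gene(s) at FDR < %g; need >= 2",
      length(de_genes), de_fdr))
  }
  cand <- select_candidate_pairs(matrix, labels, de_genes,
                                 fdr_cutoff = pair_fdr,
                                 max_genes = max_de_genes)
  if (nrow(cand) == 0) {
    stop_data(sprintf(
      "stage select_candidate_pairs produced an empty set at FDR < %g", pair_fdr))
  }
  kept <- remove_redundant_pairs(cand)
  sig_pairs <- filter_by_fd(kept, fd_min)
  if (nrow(sig_pairs) == 0) {
    stop_data(sprintf(
      "stage filter_by_fd produced an empty set at fd_min = %g (max available FD %.3f)",
      fd_min, max(kept$fd)))
  }
  votes <- vapply(labels$sample_id, function(s) {
    sum(matrix[sig_pairs$gene1, s] > matrix[sig_pairs$gene2, s])
  }, numeric(1))
  sel <- select_vote_threshold(votes, labels, n_pairs = nrow(sig_pairs))
  at_k <- sel$per_k[sel$per_k$k == sel$k, ]
  new_signature(
    sig_pairs, vote_threshold = sel$k,
    metadata = list(
      de_fdr = de_fdr, pair_fdr = pair_fdr, fd_min = fd_min,
      n_de_genes = length(de_genes),
      n_candidate_pairs = nrow(cand),
      n_after_redundancy = nrow(kept),
      n_signature_pairs = nrow(sig_pairs),
      training_sensitivity = at_k$sensitivity,
      training_specificity = at_k$specificity,
      training_f_score = at_k$f_score
    )
  )
}

#' Write / read a signature as JSON
#'
#' The JSON holds `pairs` (array of two-element arrays), `vote_threshold`
#' and `metadata`; round-trips exactly.
#'
#' @param signature An `reo_signature`.
#' @param path File path.
#' @return `write_signature`: `path` invisibly; `read_signature`: an
#'   `reo_signature`.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "reo_signature"))
  obj <- list(
    pairs = unname(purrr::map2(signature$pairs$gene1, signature$pairs$gene2, c)),
    vote_threshold = signature$vote_threshold,
    metadata = signature$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) {
    stop_data(sprintf("signature file not found: %s", path))
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$pairs) || is.null(obj$vote_threshold)) {
    stop_data(sprintf("malformed signature file %s: need pairs and vote_threshold", path))
  }
  pairs <- tibble(
    gene1 = purrr::map_chr(obj$pairs, 1),
    gene2 = purrr::map_chr(obj$pairs, 2)
  )
  new_signature(pairs, obj$vote_threshold, metadata = obj$metadata %||% list())
}

#' Read a signature from a two-column pair table
#'
#' Reads a TSV in the published-table layout: columns `gene1`, `gene2`
#' (header required), one pair per row, with the vote threshold given either
#' as a `# vote_threshold: k` comment line or via the `vote_threshold`
#' argument.
#'
#' @param path File path.
#' @param vote_threshold Threshold override; required if the file carries no
#'   threshold header line.
#' @return An `reo_signature`.
#' @export
read_signature_tsv <- function(path, vote_threshold = NULL) {
  if (!file.exists(path)) {
    stop_data(sprintf("signature file not found: %s", path))
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  k_line <- grep("vote_threshold", hdr, value = TRUE)
  if (length(k_line) > 0 && is.null(vote_threshold)) {
    vote_threshold <- as.integer(sub(".*vote_threshold[:= ]+([0-9]+).*", "\\1",
                                     k_line[1]))
  }
  if (is.null(vote_threshold) || is.na(vote_threshold)) {
    stop_data("vote threshold not found in file header and not supplied")
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("gene1", "gene2") %in% names(df))) {
    stop_data(sprintf("signature table %s must have columns gene1, gene2", path))
  }
  new_signature(df[, c("gene1", "gene2")], vote_threshold)
}
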