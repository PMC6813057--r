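#' Screen differentially expressed genes between MSI and MSS samples
#'
#' Classic (equal-variance, two-sided) Student's t-test per gene between the
#' two classes, with Benjamini-Hochberg FDR control across all genes. Genes
#' with zero variance in both classes get p = 1 (no evidence of difference)
#' rather than an error.
#'
#' @param matrix Genes-by-samples numeric matrix (see
#'   [as_expression_matrix()]).
#' @param labels Label table (`sample_id`, `status`); see [read_labels()].
#' @param fdr_cutoff BH-adjusted q-value cutoff in (0, 1) deciding the
#'   `retained` flag (default 0.01).
#' @return A tibble with one row per gene: `gene_id`, `t_statistic`,
#'   `p_value`, `q_value`, `retained`, ordered by ascending p-value.
#' @examples
#' sim <- simulate_dataset(n_genes = 50, n_planted_pairs = 2, seed = 1)
#' head(screen_de_genes(sim$expression, sim$labels))
#' @export
screen_de_genes <- function(matrix, labels, fdr_cutoff = 0.01) {
  matrix <- as_expression_matrix(matrix)
  labels <- align_labels(matrix, labels)
  if (!(fdr_cutoff > 0 && fdr_cutoff < 1)) {
    stop_validation("fdr_cutoff must lie in (0, 1)")
  }
  cls <- split(labels$sample_id, labels$status)
  n1 <- length(cls$MSI); n2 <- length(cls$MSS)
  if (n1 < 2 || n2 < 2) {
    stop_data(sprintf("each class needs at least 2 samples (MSI: %d, MSS: %d)", n1, n2))
  }
  x1 <- matrix[, cls$MSI, drop = FALSE]
  x2 <- matrix[, cls$MSS, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  pooled <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / pooled
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  # zero pooled variance: identical values within both classes
  degen <- pooled == 0
  if (any(degen)) {
    same_mean <- degen & (m1 == m2)
    tstat[same_mean] <- 0
    p[same_mean] <- 1
    tstat[degen & !same_mean] <- sign(m1 - m2)[degen & !same_mean] * Inf
    p[degen & !same_mean] <- 0
    if (any(same_mean)) {
      inform(sprintf("%d gene(s) with zero variance in both classes assigned p = 1",
                     sum(same_mean)))
    }
  }
  q <- bh_adjust(p)
  res <- tibble(gene_id = rownames(matrix), t_statistic = unname(tstat),
                p_value = unname(p), q_value = unname(q),
                retained = unname(q < fdr_cutoff))
  dplyr::arrange(res, .data$p_value, .data$gene_id)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`, returned
#' order-aligned with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_validation("p-values must be in [0, 1] with no missing entries")
  }
  p.adjust(p, method = "BH")
}

#' Count the order pattern of one gene pair per class
#'
#' For the oriented pair (`gene1`, `gene2`), counts samples in each class
#' where strictly `E[gene1] > E[gene2]` within the sample. Ties count as
#' non-pattern: a tie is never evidence for the MSI-associated ordering.
#'
#' @inheritParams screen_de_genes
#' @param gene1,gene2 Gene identifiers present in `matrix`.
#' @return A 2x2 integer matrix, rows `pattern`/`non_pattern`, columns
#'   `MSI`/`MSS`.
#' @export
pair_reo_counts <- function(matrix, labels, gene1, gene2) {
  matrix <- as_expression_matrix(matrix)
  labels <- align_labels(matrix, labels)
  for (g in c(gene1, gene2)) {
    if (!g %in% rownames(matrix)) {
      stop_data(sprintf("gene '%s' not present in expression matrix", g))
    }
  }
  e1 <- matrix[gene1, labels$sample_id]
  e2 <- matrix[gene2, labels$sample_id]
  pat <- e1 > e2
  tab <- vapply(split(pat, labels$status), function(x) {
    c(pattern = sum(x), non_pattern = sum(!x))
  }, integer(2))
  tab[c("pattern", "non_pattern"), c("MSI", "MSS"), drop = FALSE]
}

#' One-sided Fisher's exact p-value for pattern enrichment in MSI
#'
#' Probability, under the hypergeometric null with the table's margins fixed,
#' of seeing at least as many pattern-carrying MSI samples as observed — the
#' one-sided ("greater in MSI") Fisher's exact test.
#'
#' @param counts 2x2 matrix as returned by [pair_reo_counts()]:
#'   rows pattern/non-pattern, columns MSI/MSS.
#' @return A single p-value.
#' @export
fisher_exact_p <- function(counts) {
  counts <- validate_counts(counts)
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  # P(X >= a), X ~ Hypergeometric(pattern total, non-pattern total, MSI total)
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Frequency difference (FD) of a pair's order pattern
#'
#' The difference between the pattern frequencies in the two classes,
#' `FD = p_MSI - p_MSS` where `p_c` is the fraction of class-`c` samples with
#' `E[gene1] > E[gene2]`. FD near 1 means the ordering is almost always
#' observed in MSI and almost never in MSS.
#'
#' @inheritParams fisher_exact_p
#' @return A value in \[-1, 1\].
#' @export
compute_fd <- function(counts) {
  counts <- validate_counts(counts)
  n1 <- counts[1, 1] + counts[2, 1]
  n2 <- counts[1, 2] + counts[2, 2]
  if (n1 == 0 || n2 == 0) {
    stop_data("both classes must have at least one sample to compute FD")
  }
  counts[1, 1] / n1 - counts[1, 2] / n2
}

validate_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) {
    stop_validation("counts must be a 2x2 table")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_validation("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Screen all gene pairs for MSI-enriched order patterns
#'
#' For every unordered pair of candidate genes, both orientations are
#' considered and the one whose pattern is more frequent in MSI (FD >= 0) is
#' kept; that oriented pattern is tested with the one-sided Fisher's exact
#' test, and BH adjustment is applied across all tested pairs in a single
#' family. Pairs with q below `fdr_cutoff` are returned.
#'
#' @inheritParams screen_de_genes
#' @param genes Character vector of candidate (usually DE) gene ids.
#' @param fdr_cutoff BH q-value cutoff for the Fisher screen (default 0.01).
#' @param max_genes Optional cap on the number of candidate genes (first
#'   `max_genes` of `genes` are used) for desk-scale runs; `NULL` = no cap.
#' @return A tibble of pair statistics, one row per significant oriented
#'   pair: `gene1`, `gene2` (pattern is `E[gene1] > E[gene2]`, the
#'   MSI-associated ordering), per-class counts `n1_pattern`, `n1_total`,
#'   `n2_pattern`, `n2_total`, frequencies `p1`, `p2`, `fd`, `fisher_p`,
#'   `fisher_q`; sorted by descending `fd` then ascending `fisher_p`.
#' @export
select_candidate_pairs <- function(matrix, labels, genes, fdr_cutoff = 0.01,
                                   max_genes = NULL) {
  matrix <- as_expression_matrix(matrix)
  labels <- align_labels(matrix, labels)
  genes <- as.character(genes)
  if (!is.null(max_genes)) {
    genes <- head(genes, max_genes)
  }
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing) > 0) {
    stop_data(sprintf("gene(s) not present in expression matrix: %s",
                      paste(head(missing, 5), collapse = ", ")))
  }
  if (length(genes) < 2) {
    stop_data("need at least 2 candidate genes to form pairs")
  }
  cls <- split(labels$sample_id, labels$status)
  n1 <- length(cls$MSI); n2 <- length(cls$MSS)
  if (n1 == 0 || n2 == 0) {
    stop_data("both classes must be present in labels")
  }
  c1 <- pattern_count_matrix(matrix[genes, cls$MSI, drop = FALSE])
  c2 <- pattern_count_matrix(matrix[genes, cls$MSS, drop = FALSE])

  idx <- which(upper.tri(c1), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  fd_fwd <- c1[idx] / n1 - c2[idx] / n2
  ridx <- cbind(j, i)
  fd_rev <- c1[ridx] / n1 - c2[ridx] / n2
  flip <- fd_rev > fd_fwd
  g1 <- ifelse(flip, j, i)
  g2 <- ifelse(flip, i, j)
  ori <- cbind(g1, g2)
  a <- c1[ori]; b <- c2[ori]
  p <- phyper(a - 1, a + b, (n1 - a) + (n2 - b), n1, lower.tail = FALSE)
  q <- bh_adjust(p)

  res <- tibble(
    gene1 = genes[g1], gene2 = genes[g2],
    n1_pattern = as.integer(a), n1_total = n1,
    n2_pattern = as.integer(b), n2_total = n2,
    p1 = a / n1, p2 = b / n2,
    fd = a / n1 - b / n2,
    fisher_p = p, fisher_q = q
  )
  res <- dplyr::filter(res, .data$fisher_q < fdr_cutoff)
  dplyr::arrange(res, dplyr::desc(.data$fd), .data$fisher_p,
                 .data$gene1, .data$gene2)
}

# m x m matrix of strict greater-than counts across samples:
# out[i, j] = number of samples with X[i, s] > X[j, s]
pattern_count_matrix <- function(x) {
  m <- nrow(x)
  out <- matrix(0L, m, m)
  for (s in seq_len(ncol(x))) {
    v <- x[, s]
    out <- out + outer(v, v, ">")
  }
  out
}

#' Remove redundant pairs so each gene appears at most once
#'
#' Genes shared between pairs make votes correlated, so the signature keeps
#' only the most discriminative pair per gene: a greedy pass over pairs
#' sorted by descending FD (ties broken by ascending Fisher p, then
#' lexicographic gene1, gene2) keeps a pair iff neither of its genes occurs
#' in an already-kept pair. A discarded pair does not block its genes from
#' later pairs.
#'
#' @param pairs Tibble of pair statistics (needs `gene1`, `gene2`, `fd`;
#'   `fisher_p` used for tie-breaking when present).
#' @return The kept subset, sorted by descending `fd`.
#' @export
remove_redundant_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) return(pairs)
  if (!all(c("gene1", "gene2", "fd") %in% names(pairs))) {
    stop_validation("pairs must have columns gene1, gene2, fd")
  }
  fp <- if ("fisher_p" %in% names(pairs)) pairs$fisher_p else rep(0, nrow(pairs))
  ord <- order(-pairs$fd, fp, pairs$gene1, pairs$gene2)
  pairs <- pairs[ord, , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    g <- c(pairs$gene1[r], pairs$gene2[r])
    if (!any(g %in% used)) {
      keep[r] <- TRUE
      used <- c(used, g)
    }
  }
  pairs[keep, , drop = FALSE]
}

#' Write / read a pair-statistics table
#'
#' TSV round-trip for the output of [select_candidate_pairs()].
#'
#' @param pairs Pair-statistics tibble.
#' @param path File path.
#' @return `write_pair_stats`: `path` invisibly; `read_pair_stats`: a tibble.
#' @export
write_pair_stats <- function(pairs, path) {
  readr::write_tsv(tibble::as_tibble(pairs), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_stats
#' @export
read_pair_stats <- function(path) {
  if (!file.exists(path)) {
    stop_data(sprintf("pair-statistics file not found: %s", path))
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
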