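#' Simulate a two-class expression matrix with planted gene-pair structure
#'
#' Generates a labeled MSI/MSS expression matrix whose statistical structure
#' matches what the discovery pipeline assumes: a background of genes with
#' class-independent means, plus planted gene pairs whose within-sample
#' ordering `gene1 > gene2` holds with probability `p_pattern_msi` in MSI
#' samples and `p_pattern_mss` in MSS samples (so the pair's expected FD is
#' `p_pattern_msi - p_pattern_mss`). Planted genes also shift in mean between
#' classes by `de_shift` standard deviations, so they pass the
#' differential-expression screen as real signature genes must.
#'
#' Values are on a log2-like scale: per-gene baselines are uniform on
#' \[4, 12\] with Gaussian noise (`noise_sd`), i.e. log-normal on the raw
#' scale. The pattern probability is hit exactly by drawing the two planted
#' values and then assigning the larger one to `gene1` with the target
#' probability (ties have probability zero).
#'
#' Defaults describe the validation conditions used throughout the package's
#' own tests: 60 samples per class, 10 planted pairs at pattern
#' probabilities 0.95/0.05 (expected FD 0.9), a 2-SD expression shift, and
#' 200 genes in total.
#'
#' @param n_msi,n_mss Samples per class (default 60/60).
#' @param n_genes Total gene count including planted genes (default 200).
#' @param n_planted_pairs Number of planted pairs (default 10); uses
#'   `2 * n_planted_pairs` of the `n_genes` genes, all distinct.
#' @param p_pattern_msi,p_pattern_mss Probability of the `gene1 > gene2`
#'   ordering per class (defaults 0.95 / 0.05).
#' @param de_shift Between-class mean shift of planted genes, in units of
#'   `noise_sd` (default 2).
#' @param noise_sd Within-gene standard deviation (default 1).
#' @param seed Integer seed; the output is a deterministic function of the
#'   arguments. `NULL` uses the current RNG state.
#' @return A list with `expression` (genes-by-samples matrix), `labels`
#'   (tibble `sample_id`, `status`) and `planted` (tibble `gene1`, `gene2`,
#'   `p_msi`, `p_mss` — the generating pattern probabilities).
#' @examples
#' sim <- simulate_dataset(n_msi = 5, n_mss = 5, n_genes = 20,
#'                         n_planted_pairs = 2, seed = 1)
#' dim(sim$expression)
#' @export
simulate_dataset <- function(n_msi = 60, n_mss = 60, n_genes = 200,
                             n_planted_pairs = 10,
                             p_pattern_msi = 0.95, p_pattern_mss = 0.05,
                             de_shift = 2, noise_sd = 1, seed = NULL) {
  if (n_msi < 1 || n_mss < 1 || n_genes < 1 || n_planted_pairs < 0) {
    stop_validation("sample, gene and pair counts must be positive")
  }
  for (p in c(p_pattern_msi, p_pattern_mss)) {
    if (p < 0 || p > 1) stop_validation("pattern probabilities must lie in [0, 1]")
  }
  if (2 * n_planted_pairs > n_genes) {
    stop_validation(sprintf(
      "need 2 genes per planted pair: 2 * %d > n_genes = %d",
      n_planted_pairs, n_genes))
  }
  if (!is.null(seed)) set.seed(seed)

  n <- n_msi + n_mss
  sample_ids <- c(sprintf("MSI_%03d", seq_len(n_msi)),
                  sprintf("MSS_%03d", seq_len(n_mss)))
  labels <- tibble(sample_id = sample_ids,
                   status = factor(rep(c("MSI", "MSS"), c(n_msi, n_mss)),
                                   levels = c("MSI", "MSS")))
  is_msi <- labels$status == "MSI"

  planted_g1 <- sprintf("PG%03d_A", seq_len(n_planted_pairs))
  planted_g2 <- sprintf("PG%03d_B", seq_len(n_planted_pairs))
  n_bg <- n_genes - 2 * n_planted_pairs
  bg <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  gene_ids <- c(rbind(planted_g1, planted_g2), bg)

  mat <- matrix(0, nrow = n_genes, ncol = n,
                dimnames = list(gene_ids, sample_ids))
  if (n_bg > 0) {
    base <- runif(n_bg, 4, 12)
    mat[bg, ] <- base + matrix(rnorm(n_bg * n, sd = noise_sd), n_bg, n)
  }
  delta <- de_shift * noise_sd
  for (k in seq_len(n_planted_pairs)) {
    b <- runif(1, 4, 12)
    # gene1 high / gene2 low in MSI; reversed in MSS -> DE in both genes
    mu1 <- ifelse(is_msi, b + delta, b)
    mu2 <- ifelse(is_msi, b, b + delta)
    v1 <- rnorm(n, mean = mu1, sd = noise_sd)
    v2 <- rnorm(n, mean = mu2, sd = noise_sd)
    hi <- pmax(v1, v2); lo <- pmin(v1, v2)
    p_target <- ifelse(is_msi, p_pattern_msi, p_pattern_mss)
    g1_wins <- runif(n) < p_target
    mat[planted_g1[k], ] <- ifelse(g1_wins, hi, lo)
    mat[planted_g2[k], ] <- ifelse(g1_wins, lo, hi)
  }

  planted <- tibble(gene1 = planted_g1, gene2 = planted_g2,
                    p_msi = p_pattern_msi, p_mss = p_pattern_mss)
  list(expression = mat, labels = labels, planted = planted)
}

#' Apply a random strictly increasing transform per sample
#'
#' Each sample's values are passed through an independently drawn strictly
#' increasing map `a + b (x - m) + c (x - m)^3` (with `b, c > 0` and `m` the
#' sample median), emulating arbitrary monotone batch/scale effects. Within
#' every sample, the rank order of values is unchanged, so all REO-based
#' results must be identical before and after — the central robustness
#' property of rank-only signatures.
#'
#' @param matrix Genes-by-samples numeric matrix.
#' @param seed Integer seed for the transform draws; `NULL` uses the current
#'   RNG state.
#' @return Transformed matrix of the same shape and dimnames.
#' @export
apply_monotone_distortion <- function(matrix, seed = NULL) {
  matrix <- as_expression_matrix(matrix)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    a <- runif(1, -2, 2)
    b <- runif(1, 0.25, 4)
    cc <- runif(1, 0.01, 0.5)
    m <- median(matrix[, j])
    x <- matrix[, j] - m
    out[, j] <- a + b * x + cc * x^3
  }
  out
}

#' Attenuate a random subset of genes per sample
#'
#' Multiplies a per-sample random subset of genes (a `fraction_genes`
#' proportion) by attenuation factors drawn uniformly from
#' `attenuation_range`, mimicking the 3'-biased signal loss of partial RNA
#' degradation. Unlike [apply_monotone_distortion()] this is NOT
#' rank-preserving; it is used to measure how stable signature orderings and
#' calls are under measurement degradation.
#'
#' @param matrix Genes-by-samples numeric matrix.
#' @param fraction_genes Proportion of genes attenuated per sample, in
#'   \[0, 1\].
#' @param attenuation_range Length-2 numeric range of multiplicative
#'   factors (default `c(0.7, 0.95)`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Perturbed matrix of the same shape and dimnames.
#' @export
apply_degradation <- function(matrix, fraction_genes,
                              attenuation_range = c(0.7, 0.95), seed = NULL) {
  matrix <- as_expression_matrix(matrix)
  if (fraction_genes < 0 || fraction_genes > 1) {
    stop_validation("fraction_genes must lie in [0, 1]")
  }
  if (length(attenuation_range) != 2) {
    stop_validation("attenuation_range must be a length-2 numeric range")
  }
  if (!is.null(seed)) set.seed(seed)
  if (fraction_genes == 0) return(matrix)
  out <- matrix
  n_hit <- round(fraction_genes * nrow(matrix))
  for (j in seq_len(ncol(matrix))) {
    hit <- sample.int(nrow(matrix), n_hit)
    out[hit, j] <- out[hit, j] *
      runif(n_hit, attenuation_range[1], attenuation_range[2])
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the expression matrix and label TSVs plus a planted-truth TSV
#' (`gene1`, `gene2`, `p_msi`, `p_mss`).
#'
#' @param sim List from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(sim$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(sim$labels, file.path(dir, "labels.tsv"), progress = FALSE)
  readr::write_tsv(sim$planted, file.path(dir, "planted_pairs.tsv"),
                   progress = FALSE)
  invisible(dir)
}
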