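# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (phyper, p.adjust, rank) they test.

# one-sided "greater in column 1" exact p for a 2x2 table via explicit
# enumeration of all tables with the observed margins
oracle_fisher_greater <- function(a, b, c, d) {
  row1 <- a + b   # pattern total
  row2 <- c + d   # non-pattern total
  col1 <- a + c   # class-1 total
  n <- row1 + row2
  xs <- max(0, col1 - row2):min(row1, col1)
  probs <- choose(row1, xs) * choose(row2, col1 - xs) / choose(n, col1)
  sum(probs[xs >= a])
}

# BH step-up from first principles
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# all-pairs Mann-Whitney AUC, ties = 1/2
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# independent round-half-up at 4 decimals (printed metric precision)
round_half_up_test <- function(x, digits = 4) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# per-gene equal-variance two-sided t via stats::t.test
oracle_t_p <- function(x1, x2) {
  t.test(x1, x2, var.equal = TRUE)$p.value
}

# tiny deterministic two-class matrix with one perfectly separating pair
# (g1 > g2 in all MSI, reversed in all MSS) on top of fixed background
tiny_fixture <- function(n_msi = 4, n_mss = 4) {
  ids <- c(sprintf("msi%d", seq_len(n_msi)), sprintf("mss%d", seq_len(n_mss)))
  mat <- rbind(
    g1 = c(rep(5, n_msi), rep(1, n_mss)),
    g2 = c(rep(1, n_msi), rep(5, n_mss)),
    g3 = seq_len(n_msi + n_mss),          # uninformative
    g4 = rep(2, n_msi + n_mss)            # constant
  )
  colnames(mat) <- ids
  labels <- make_label_table(ids, rep(c("MSI", "MSS"), c(n_msi, n_mss)))
  list(expression = mat, labels = labels)
}

# random pair-stats table for redundancy-removal property tests
random_pair_stats <- function(n_pairs, n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  g1 <- character(n_pairs); g2 <- character(n_pairs)
  for (r in seq_len(n_pairs)) {
    gg <- sample(genes, 2)
    g1[r] <- gg[1]; g2[r] <- gg[2]
  }
  tibble::tibble(
    gene1 = g1, gene2 = g2,
    fd = round(runif(n_pairs), 2),        # rounded to force fd ties
    fisher_p = round(runif(n_pairs), 2)
  )
}
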