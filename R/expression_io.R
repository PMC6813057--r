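#' Read a gene expression matrix from delimited text
#'
#' Reads a genes-by-samples expression table (TSV or CSV) into a numeric
#' matrix. The first column holds gene (or probe) identifiers and the header
#' row holds sample identifiers; set `genes_in = "columns"` for transposed
#' files. Because downstream classification uses only within-sample orderings,
#' any monotone expression scale (raw intensities, log2, RSEM) is acceptable
#' and no normalisation is applied.
#'
#' Duplicate gene rows are averaged (the same rule used for probe collapsing),
#' and rows containing any missing value are dropped with a warning.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter; `"\t"` (default) or `","`.
#' @param genes_in Orientation of the file: `"rows"` (default) if genes are
#'   rows, `"columns"` if samples are rows.
#' @return A numeric matrix, genes in rows (rownames = gene ids) and samples
#'   in columns (colnames = sample ids).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"), tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, delimiter = "\t",
                                   genes_in = c("rows", "columns")) {
  genes_in <- match.arg(genes_in)
  if (!file.exists(path)) {
    stop_data(sprintf("expression file not found: %s", path))
  }
  df <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(),
                          show_col_types = FALSE, progress = FALSE,
                          name_repair = "minimal")
  if (ncol(df) < 2) {
    stop_data(sprintf("malformed header in %s: need an id column plus at least one sample column", path))
  }
  ids <- as.character(df[[1]])
  vals <- df[-1]
  col_ids <- names(vals)
  if (anyDuplicated(col_ids)) {
    dup <- unique(col_ids[duplicated(col_ids)])
    stop_data(sprintf("duplicate sample id in header of %s: %s",
                      path, paste(dup, collapse = ", ")))
  }
  # locate non-numeric cells before coercion so the error can name them
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad) > 0) {
        stop_data(sprintf(
          "non-numeric cell in %s: row '%s', column '%s' (value '%s')",
          path, ids[bad[1]], col_ids[j], v[bad[1]]))
      }
      vals[[j]] <- as.numeric(v)
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  if (genes_in == "columns") {
    mat <- t(mat)
  }
  mat <- drop_missing_rows(mat)
  average_duplicate_rows(mat)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]: writes a genes-in-rows table with a
#' `gene_id` header column.
#'
#' @param matrix Numeric genes-by-samples matrix with row and column names.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path, delimiter = "\t") {
  matrix <- as_expression_matrix(matrix)
  df <- tibble::as_tibble(matrix, rownames = "gene_id")
  readr::write_delim(df, path, delim = delimiter, progress = FALSE)
  invisible(path)
}

#' Coerce to a genes-by-samples expression matrix
#'
#' Accepts a numeric matrix with row/column names, or a data frame whose
#' first column holds gene identifiers (as produced by tidy readers).
#'
#' @param x Matrix or data frame.
#' @return Numeric matrix with unique rownames (genes) and colnames (samples).
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2 || !is.character(x[[1]]) && !is.factor(x[[1]])) {
      stop_data("data-frame input must have a character gene-id first column")
    }
    ids <- as.character(x[[1]])
    m <- as.matrix(x[-1])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_data("expression input must be a numeric matrix or a gene-id data frame")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_data("expression matrix must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(colnames(x))) {
    stop_data(sprintf("duplicate sample ids: %s",
                      paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  x
}

drop_missing_rows <- function(mat) {
  bad <- rowSums(is.na(mat)) > 0
  if (any(bad)) {
    warn(sprintf("dropped %d row(s) with missing values: %s",
                 sum(bad), paste(head(rownames(mat)[bad], 5), collapse = ", ")))
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}

average_duplicate_rows <- function(mat) {
  ids <- rownames(mat)
  if (!anyDuplicated(ids)) {
    return(mat)
  }
  grp <- factor(ids, levels = unique(ids))
  out <- rowsum(mat, grp) / as.vector(table(grp))
  rownames(out) <- levels(grp)
  out
}

#' Read a probe-to-gene map
#'
#' Two-column delimited file (`probe_id`, `gene_id`); a probe occurring on
#' several rows maps to several genes and will be discarded by
#' [collapse_probes()].
#'
#' @param path Path to a two-column TSV/CSV.
#' @param delimiter Field delimiter.
#' @return A tibble with columns `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop_data(sprintf("probe map file not found: %s", path))
  }
  df <- readr::read_delim(path, delim = delimiter, col_types = "cc",
                          show_col_types = FALSE, progress = FALSE)
  names(df)[1:2] <- c("probe_id", "gene_id")
  tibble::as_tibble(df[, 1:2])
}

#' Collapse a probe-level matrix to gene level
#'
#' Applies the standard microarray collapsing rule: probes mapping to no gene
#' or to multiple genes are discarded; for each gene, the expression values of
#' its remaining probes are averaged per sample to give a single measurement.
#'
#' @param matrix Probe-by-sample numeric matrix (rownames are probe ids).
#' @param probe_map Tibble or data frame with columns `probe_id`, `gene_id`.
#' @return Gene-by-sample numeric matrix.
#' @export
collapse_probes <- function(matrix, probe_map) {
  matrix <- as_expression_matrix(matrix)
  pm <- tibble::as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(pm))) {
    stop_data("probe_map must have columns probe_id and gene_id")
  }
  pm <- dplyr::distinct(pm, .data$probe_id, .data$gene_id)
  multi <- pm$probe_id[duplicated(pm$probe_id)]
  pm <- dplyr::filter(pm, !.data$probe_id %in% multi,
                      .data$probe_id %in% rownames(matrix))
  if (nrow(pm) == 0) {
    stop_data("no probe maps uniquely to a gene: collapsed matrix would be empty")
  }
  sub <- matrix[pm$probe_id, , drop = FALSE]
  grp <- factor(pm$gene_id, levels = unique(pm$gene_id))
  out <- rowsum(sub, grp) / as.vector(table(grp))
  rownames(out) <- levels(grp)
  out[order(rownames(out)), , drop = FALSE]
}

#' Read MSI/MSS sample labels
#'
#' Two-column delimited file (`sample_id`, `status`), header optional. Status
#' tokens are matched case-insensitively: `MSI` and `MSI-H` normalise to
#' `MSI`; `MSS` and `MSI-L` normalise to `MSS` (MSI-low tumors are managed
#' clinically like MSS and are grouped with them). Any other token is an
#' error.
#'
#' @param path Path to the label file.
#' @param delimiter Field delimiter.
#' @return A tibble with columns `sample_id` (character) and `status`
#'   (factor with levels `MSI`, `MSS`).
#' @export
read_labels <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop_data(sprintf("label file not found: %s", path))
  }
  df <- readr::read_delim(path, delim = delimiter, col_types = "cc",
                          col_names = FALSE, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) {
    stop_data(sprintf("label file %s must have two columns (sample_id, status)", path))
  }
  names(df)[1:2] <- c("sample_id", "status")
  # tolerate an optional header line
  if (nrow(df) > 0 && is.na(normalize_status(df$status[1], strict = FALSE))) {
    first <- tolower(df$status[1])
    if (first %in% c("status", "label", "msi_status", "class")) {
      df <- df[-1, , drop = FALSE]
    }
  }
  make_label_table(df$sample_id, df$status)
}

#' Build a normalised label table
#'
#' @param sample_id Character vector of sample identifiers.
#' @param status Character vector of MSI-status tokens (`MSI`, `MSI-H`,
#'   `MSS`, `MSI-L`; case-insensitive).
#' @return A tibble with columns `sample_id`, `status` (factor MSI/MSS).
#' @export
make_label_table <- function(sample_id, status) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop_data(sprintf("duplicate sample id(s) in labels: %s",
                      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")))
  }
  norm <- normalize_status(status, strict = TRUE)
  tibble(sample_id = sample_id,
         status = factor(norm, levels = c("MSI", "MSS")))
}

normalize_status <- function(status, strict = TRUE) {
  s <- toupper(trimws(as.character(status)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("MSI", "MSI-H", "MSI_H", "MSIH")] <- "MSI"
  out[s %in% c("MSS", "MSI-L", "MSI_L", "MSIL")] <- "MSS"
  if (strict && anyNA(out)) {
    bad <- unique(status[is.na(out)])
    stop_data(sprintf("unknown MSI status token(s): %s",
                      paste(bad, collapse = ", ")))
  }
  out
}

# align a label table against a matrix; returns labels restricted/ordered to
# the matrix columns, erroring on labeled samples missing from the matrix
align_labels <- function(matrix, labels) {
  labels <- tibble::as_tibble(labels)
  if (!all(c("sample_id", "status") %in% names(labels))) {
    stop_data("labels must have columns sample_id and status")
  }
  missing <- setdiff(labels$sample_id, colnames(matrix))
  if (length(missing) > 0) {
    stop_data(sprintf("labeled sample(s) absent from expression matrix: %s",
                      paste(head(missing, 5), collapse = ", ")))
  }
  labels$status <- factor(normalize_status(labels$status), levels = c("MSI", "MSS"))
  labels
}
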