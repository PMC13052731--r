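# Differential-expression table filtering and recovery summaries.
#
# The pipeline consumes gene-level DE result tables produced upstream
# (e.g. DESeq2 output): gene_id, log2 fold change, adjusted p-value.

#' Read a DE result table from TSV
#'
#' Expects columns `gene_id`, `log2fc`, `padj`; a column mapping supports
#' DESeq2-style headers (e.g. `log2FoldChange`).
#'
#' @param path TSV file with a header row.
#' @param col_map named character vector mapping required names to the
#'   file's column names, e.g.
#'   `c(log2fc = "log2FoldChange", gene_id = "gene")`.
#' @return validated data.frame with `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(tab)) {
        stop("mapped column '", col_map[[nm]], "' not found")
      }
      names(tab)[names(tab) == col_map[[nm]]] <- nm
    }
  }
  validate_de_table(tab)
}

validate_de_table <- function(tab) {
  req <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(req, names(tab))
  if (length(missing) > 0) {
    stop("DE table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab <- tab[, req]
  drop <- is.na(tab$padj)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing padj dropped")
    tab <- tab[!drop, ]
  }
  if (anyDuplicated(tab$gene_id)) stop("gene_id values must be unique")
  if (any(tab$padj < 0 | tab$padj > 1)) stop("padj must lie in [0, 1]")
  tab
}

#' Apply the DE significance filter
#'
#' A gene is differentially expressed when its adjusted p-value is below
#' `padj_cut` AND its absolute linear fold change exceeds `fc_cut`
#' (both strict): up if `log2fc > log2(fc_cut)`, down if
#' `log2fc < -log2(fc_cut)`.
#'
#' @param table data.frame with `gene_id`, `log2fc`, `padj`.
#' @param padj_cut adjusted p-value cutoff (default 0.05).
#' @param fc_cut linear fold-change cutoff (default 2).
#' @return list with character vectors `up`, `down`, and `de` (union),
#'   plus the cutoffs used.
#' @export
filter_de <- function(table, padj_cut = 0.05, fc_cut = 2) {
  table <- validate_de_table(table)
  lcut <- log2(fc_cut)
  sig <- table$padj < padj_cut
  up <- table$gene_id[sig & table$log2fc > lcut]
  down <- table$gene_id[sig & table$log2fc < -lcut]
  list(up = up, down = down, de = c(up, down),
       padj_cut = padj_cut, fc_cut = fc_cut)
}

#' Overlap structure of named gene sets
#'
#' Computes, for two or more named sets, the per-set sizes, all pairwise
#' intersection counts, the unique count per set, and the count of every
#' membership pattern (the Venn regions).
#'
#' @param sets named list (>= 2) of character vectors.
#' @return object of class `de_overlap`: list with `sizes`, `pairwise`
#'   (matrix of intersection counts), `unique_counts`, and `patterns`
#'   (data.frame: one row per nonempty membership pattern with its count).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  k <- length(sets)
  all_genes <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  sizes <- vapply(sets, length, integer(1))
  pairwise <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pairwise[i, j] <- sum(memb[, i] & memb[, j])
  }
  pattern_key <- apply(memb, 1, function(r) paste(as.integer(r),
                                                  collapse = ""))
  pat <- table(pattern_key)
  patterns <- data.frame(pattern = names(pat),
                         count = as.integer(pat),
                         stringsAsFactors = FALSE)
  only <- vapply(seq_len(k), function(i) {
    sum(memb[, i] & rowSums(memb) == 1)
  }, integer(1))
  names(only) <- names(sets)
  structure(list(sizes = sizes, pairwise = pairwise,
                 unique_counts = only, patterns = patterns,
                 set_names = names(sets)),
            class = "de_overlap")
}

#' Fold-change correlation between two DE tables
#'
#' Matches genes by id (optionally restricted to a gene filter, e.g. the
#' union of the two DE sets), then reports the Pearson correlation and the
#' ordinary least-squares fit of the second table's log2 fold changes on
#' the first's.
#'
#' @param table_a,table_b DE tables with `gene_id`, `log2fc`, `padj`.
#' @param gene_filter optional character vector; only matched genes in
#'   this set are used.
#' @return list with `pearson_r`, `slope`, `intercept`, `n_matched`.
#' @export
fc_correlation <- function(table_a, table_b, gene_filter = NULL) {
  table_a <- validate_de_table(table_a)
  table_b <- validate_de_table(table_b)
  m <- merge(table_a, table_b, by = "gene_id", suffixes = c("_a", "_b"))
  if (!is.null(gene_filter)) m <- m[m$gene_id %in% gene_filter, ]
  if (nrow(m) < 3) stop("fewer than 3 matched genes")
  fit <- stats::lm(log2fc_b ~ log2fc_a, data = m)
  co <- stats::coef(fit)
  list(pearson_r = stats::cor(m$log2fc_a, m$log2fc_b),
       slope = unname(co[2]), intercept = unname(co[1]),
       n_matched = nrow(m))
}

#' Write a DE table as TSV
#'
#' @param table data.frame with `gene_id`, `log2fc`, `padj`.
#' @param path output file.
#' @export
write_de_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
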