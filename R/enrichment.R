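# Enrichment of mark-combination categories and generic gene sets.
#
# Combination enrichment uses the one-sided hypergeometric tail (exact
# subset-vs-background test, significance at p < 0.01); gene-set (GO
# style) enrichment uses Pearson's chi-squared on the 2x2 table without
# continuity correction, BH-corrected with an FDR cutoff of 0.05.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment. Missing p-values propagate as `NA` and
#' are excluded from the number of tests m.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.enrich_row <- function(term, k, n, K, N) {
  data.frame(term = term, k = k, n = n, K = K, N = N,
             fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Enrichment of mark combinations in a gene subset
#'
#' For each combination category, tests whether the subset contains more
#' category genes than expected from the universe, with the one-sided
#' hypergeometric tail p = P(X >= k). Fold is (k/n) / (K/N), the
#' subset frequency over the genome-wide average.
#'
#' @param profile Factor from [classify_combinations()] (names = genes).
#' @param subset Character vector of genes (must be non-empty and a
#'   subset of the universe).
#' @param universe Gene universe (default: all genes in `profile`).
#' @param alpha Significance level on the unadjusted p (default 0.01).
#' @return data.frame per category: `term`, `k`, `n`, `K`, `N`, `fold`,
#'   `p_value`, `significant`.
#' @export
combination_enrichment <- function(profile, subset,
                                   universe = names(profile),
                                   alpha = 0.01) {
  if (length(subset) == 0) stop("empty subset")
  subset <- unique(subset)
  if (!all(subset %in% universe)) stop("subset must lie within the universe")
  lab <- profile[match(universe, names(profile))]
  sub_lab <- profile[match(subset, names(profile))]
  N <- length(universe)
  n <- length(subset)
  rows <- lapply(combination_levels, function(cat) {
    K <- sum(lab == cat, na.rm = TRUE)
    k <- sum(sub_lab == cat, na.rm = TRUE)
    out <- .enrich_row(cat, k, n, K, N)
    out$p_value <- if (K > 0) stats::phyper(k - 1, K, N - K, n,
                                            lower.tail = FALSE) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Gene-set enrichment by Pearson's chi-squared
#'
#' For each term, forms the 2x2 table (in/out of subset x in/out of
#' term) over the universe, computes the Pearson chi-squared statistic
#' (1 df, no continuity correction) and its two-sided p, adjusts across
#' terms by BH, and flags terms with fdr < `fdr_cutoff`. Terms with a
#' zero margin get `NA` p-values (excluded from m).
#'
#' @param gene_sets Named list of character vectors (term -> genes), or a
#'   two-column data.frame (`term`, `gene_id`).
#' @param subset Character vector of genes, subset of `universe`.
#' @param universe Gene universe; gene sets are intersected with it.
#' @param fdr_cutoff Significance threshold on the adjusted p.
#' @return data.frame per term: `term`, `k`, `n`, `K`, `N`, `fold`,
#'   `statistic`, `p_value`, `fdr`, `significant`.
#' @export
gene_set_enrichment <- function(gene_sets, subset, universe,
                                fdr_cutoff = 0.05) {
  if (is.data.frame(gene_sets)) {
    stopifnot(ncol(gene_sets) >= 2)
    gene_sets <- split(as.character(gene_sets[[2]]),
                       as.character(gene_sets[[1]]))
  }
  subset <- unique(subset)
  if (!all(subset %in% universe)) stop("subset must lie within the universe")
  N <- length(universe)
  n <- length(subset)
  rows <- lapply(names(gene_sets), function(tm) {
    gs <- intersect(gene_sets[[tm]], universe)
    K <- length(gs)
    k <- length(intersect(gs, subset))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2)
    out <- .enrich_row(tm, k, n, K, N)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      out$statistic <- NA_real_
      out$p_value <- NA_real_
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      out$statistic <- unname(ct$statistic)
      out$p_value <- unname(ct$p.value)
    }
    out
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_cutoff
  out
}

#' Read gene sets from a two-column TSV
#'
#' Expects columns `term` and `gene_id` (header optional when the first
#' row parses as data).
#'
#' @param path TSV file: term, gene_id.
#' @return Named list term -> character vector of genes.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("term", "gene_id"))
  if (nrow(df) && identical(tolower(df$term[1]), "term")) df <- df[-1, ]
  split(df$gene_id, df$term)
}
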