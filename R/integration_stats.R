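# Integration of marks with expression: the acylation-proportion
# statistic, its between-condition changes, expression summaries per
# combination category and proportion band, total acylation, and
# mark-change vs expression-change correlation.

#' Per-gene acylation proportions
#'
#' p_m(g) = TPM_m(g) / (TPM_H3K9ac(g) + TPM_Kbu(g) + TPM_Kcr(g)), on
#' replicate-averaged gene-body TPM. Genes with zero total acylation are
#' jointly missing (`NA` proportions).
#'
#' @param tpm_k9ac,tpm_kbu,tpm_kcr Named per-gene body TPM vectors
#'   (replicate-averaged), same gene universe.
#' @return data.frame: `gene_id`, `p_H3K9ac`, `p_Kbu`, `p_Kcr`,
#'   `total_acylation`.
#' @export
acylation_proportions <- function(tpm_k9ac, tpm_kbu, tpm_kcr) {
  g <- names(tpm_k9ac)
  if (is.null(g) || !identical(g, names(tpm_kbu)) ||
      !identical(g, names(tpm_kcr))) {
    stop("TPM vectors must share one named gene universe")
  }
  if (any(c(tpm_k9ac, tpm_kbu, tpm_kcr) < 0, na.rm = TRUE)) {
    stop("negative TPM")
  }
  total <- tpm_k9ac + tpm_kbu + tpm_kcr
  ok <- !is.na(total) & total > 0
  p <- function(x) ifelse(ok, x / total, NA_real_)
  data.frame(gene_id = g, p_H3K9ac = p(tpm_k9ac), p_Kbu = p(tpm_kbu),
             p_Kcr = p(tpm_kcr), total_acylation = total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion changes in differentially expressed genes
#'
#' Delta p_m = p_m(treated) - p_m(control) per gene, with median (and
#' mean) summaries within the up- and down-regulated DEG sets. Genes with
#' missing proportions in either condition are excluded and counted.
#'
#' @param props_control,props_treated Outputs of
#'   [acylation_proportions()] over the same universe.
#' @param deg data.frame with `gene_id` and `call` from
#'   [diff_expression()].
#' @return List: `delta` (per-gene data.frame with `dp_<mark>` columns),
#'   `summary` (per direction x mark: n, median, mean), `n_excluded`.
#' @export
proportion_change <- function(props_control, props_treated, deg) {
  stopifnot(identical(props_control$gene_id, props_treated$gene_id))
  marks <- paste0("p_", acyl_marks)
  ok <- stats::complete.cases(props_control[marks]) &
    stats::complete.cases(props_treated[marks])
  delta <- data.frame(gene_id = props_control$gene_id,
                      stringsAsFactors = FALSE)
  for (m in acyl_marks) {
    delta[[paste0("dp_", m)]] <-
      ifelse(ok, props_treated[[paste0("p_", m)]] -
               props_control[[paste0("p_", m)]], NA_real_)
  }
  call <- deg$call[match(delta$gene_id, deg$gene_id)]
  rows <- list()
  for (direction in c("up", "down")) {
    in_set <- !is.na(call) & call == direction & ok
    for (m in acyl_marks) {
      d <- delta[[paste0("dp_", m)]][in_set]
      rows[[length(rows) + 1L]] <- data.frame(
        direction = direction, mark = m, n = sum(in_set),
        median_dp = if (length(d)) stats::median(d) else NA_real_,
        mean_dp = if (length(d)) mean(d) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(delta = delta, summary = do.call(rbind, rows),
       n_excluded = sum(!ok))
}

# log10(FPKM + 0.001), the transform used for expression summaries
.log_expr <- function(fpkm) log10(fpkm + 0.001)

.summarize_groups <- function(value, group) {
  lv <- levels(group)
  out <- lapply(lv, function(g) {
    v <- value[!is.na(group) & group == g]
    data.frame(group = g, n = length(v),
               q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expression by combination category
#'
#' Median and quartiles of log10(FPKM + 0.001) within each of the eight
#' mark-combination categories.
#'
#' @param fpkm Named per-gene FPKM vector (e.g. replicate-averaged
#'   control FPKM).
#' @param profile Factor from [classify_combinations()] over the same
#'   genes.
#' @return data.frame per category: `group`, `n`, `q25`, `median`, `q75`.
#' @export
expression_by_category <- function(fpkm, profile) {
  stopifnot(identical(names(fpkm), names(profile)))
  if (any(fpkm < 0, na.rm = TRUE)) stop("negative FPKM")
  out <- .summarize_groups(.log_expr(fpkm), profile)
  names(out)[1] <- "category"
  out
}

#' Expression by acylation-proportion band
#'
#' Bins genes by quantiles of one mark's proportion and summarizes
#' log10(FPKM + 0.001) per band, for each mark in turn.
#'
#' @param fpkm Named per-gene FPKM vector.
#' @param props Output of [acylation_proportions()] over the same genes.
#' @param n_bands Number of quantile bands (>= 2).
#' @return data.frame: `mark`, `band` (1 = lowest proportion), `n`,
#'   `q25`, `median`, `q75`.
#' @export
expression_by_proportion_band <- function(fpkm, props, n_bands = 4) {
  stopifnot(n_bands >= 2, identical(names(fpkm), props$gene_id))
  if (any(fpkm < 0, na.rm = TRUE)) stop("negative FPKM")
  value <- .log_expr(fpkm)
  rows <- list()
  for (m in acyl_marks) {
    p <- props[[paste0("p_", m)]]
    ok <- !is.na(p)
    if (sum(ok) < n_bands) {
      stop("fewer non-missing genes (", sum(ok), ") than bands (", n_bands, ")")
    }
    brk <- unique(stats::quantile(p[ok], probs = seq(0, 1, length.out = n_bands + 1)))
    if (length(brk) < 3) {
      stop("proportions of ", m, " too degenerate to form ", n_bands, " bands")
    }
    band <- cut(p, breaks = brk, include.lowest = TRUE, labels = FALSE)
    s <- .summarize_groups(value[ok], factor(band[ok], seq_len(length(brk) - 1)))
    s <- data.frame(mark = m, band = as.integer(s$group),
                    s[c("n", "q25", "median", "q75")],
                    stringsAsFactors = FALSE)
    rows[[m]] <- s
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Total acylation by combination category
#'
#' Sum of the three body TPMs per gene, summarized (median, quartiles)
#' per combination category.
#'
#' @param tpm_k9ac,tpm_kbu,tpm_kcr Named per-gene body TPM vectors.
#' @param profile Factor from [classify_combinations()].
#' @return data.frame per category: `category`, `n`, `q25`, `median`,
#'   `q75`.
#' @export
total_acylation_by_category <- function(tpm_k9ac, tpm_kbu, tpm_kcr,
                                        profile) {
  total <- tpm_k9ac + tpm_kbu + tpm_kcr
  stopifnot(identical(names(total), names(profile)))
  out <- .summarize_groups(total, profile)
  names(out)[1] <- "category"
  out
}

#' Correlation of mark changes with expression changes
#'
#' Pearson r between the log2 expression fold change and the log2
#' modification fold change over the DEG set (or all genes).
#'
#' @param diffexpr Output of [diff_expression()].
#' @param diffmod Output of [diff_modification()] (one mark), same gene
#'   universe.
#' @param degs_only Restrict to genes called `up` or `down` in
#'   `diffexpr` (default) rather than all genes.
#' @return List: `r` (Pearson, `NA` if fewer than 3 genes or zero
#'   variance), `n` (genes used).
#' @export
change_correlation <- function(diffexpr, diffmod, degs_only = TRUE) {
  idx <- match(diffexpr$gene_id, diffmod$gene_id)
  keep <- !is.na(idx)
  if (degs_only) keep <- keep & diffexpr$call != "unchanged"
  x <- diffexpr$log2fc[keep]
  y <- diffmod$log2fc[idx[keep]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = length(x)))
  }
  list(r = stats::cor(x, y), n = length(x))
}
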