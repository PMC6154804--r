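# Differential calls.
#
# Three rules, each with the thresholds fixed by the study design:
#  - differential modification: TPM fold change > 1.5 in BOTH replicates;
#  - differential expression: adjusted p < 0.05 AND fold change > 4;
#  - diurnal rhythm: FDR < 0.05 and fold change > 2 in more than two of
#    the six pairwise comparisons among four time points.

#' Differential modification (replicate-consistent fold change)
#'
#' Per replicate r, FC_r = (TPM_treated_r + epsilon) / (TPM_control_r +
#' epsilon). A gene is `up` iff FC_r > `fc_threshold` in both replicates,
#' `down` iff FC_r < 1/`fc_threshold` in both, else `unchanged`.
#' Replicates are paired by index. The reported log2 fold change is the
#' mean of the per-replicate log2 FCs.
#'
#' @param tpm_control,tpm_treated Gene x 2 matrices of TPM (same genes,
#'   two replicate columns), e.g. from [tpm_matrix()].
#' @param epsilon Pseudocount in TPM units (> 0); bounds fold changes on
#'   empty genes.
#' @param fc_threshold Fold-change threshold (> 1).
#' @return data.frame: `gene_id`, `fc_rep1`, `fc_rep2`, `log2fc`, `call`
#'   (`up`/`down`/`unchanged`).
#' @export
diff_modification <- function(tpm_control, tpm_treated, epsilon = 1,
                              fc_threshold = 1.5) {
  tpm_control <- as.matrix(tpm_control)
  tpm_treated <- as.matrix(tpm_treated)
  if (ncol(tpm_control) != 2L || ncol(tpm_treated) != 2L) {
    stop("diff_modification expects exactly two replicates per condition")
  }
  if (epsilon <= 0) stop("epsilon must be > 0")
  stopifnot(nrow(tpm_control) == nrow(tpm_treated), fc_threshold > 1)
  fc <- (tpm_treated + epsilon) / (tpm_control + epsilon)
  call <- rep("unchanged", nrow(fc))
  call[fc[, 1] > fc_threshold & fc[, 2] > fc_threshold] <- "up"
  call[fc[, 1] < 1 / fc_threshold & fc[, 2] < 1 / fc_threshold] <- "down"
  gene_id <- rownames(tpm_control)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(fc)))
  data.frame(gene_id = gene_id, fc_rep1 = fc[, 1], fc_rep2 = fc[, 2],
             log2fc = rowMeans(log2(fc)),
             call = factor(call, c("up", "down", "unchanged")),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Row-wise Welch t-test on a log2 matrix, two groups.
.welch_rows <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, g2, drop = FALSE], 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & m1 == m2] <- 1
  p
}

#' Differential expression (FDR + fold-change thresholds)
#'
#' Tests each gene between two count matrices on the log2(count + 1)
#' scale, adjusts p-values by Benjamini-Hochberg across genes, and calls
#' `up` iff adjusted p < `fdr_threshold` AND fold change >
#' `fc_threshold` (`down` symmetric). The fold change is
#' 2^(difference of group means of log2(count + 1)).
#'
#' The default test is a limma moderated t (linear model on
#' log2(count + 1), empirical-Bayes variance moderation with a
#' mean-variance trend), which retains power at the small replicate
#' numbers of the study design; `method = "welch"` gives a plain Welch
#' t-test, and precomputed per-gene p-values can be supplied instead to
#' slot in an external DE engine.
#'
#' @param counts_control,counts_treated Gene x replicate count (or FPKM)
#'   matrices, >= 2 replicates each, same genes.
#' @param fc_threshold Fold-change threshold (default 4).
#' @param fdr_threshold BH-adjusted p threshold (default 0.05).
#' @param method `"moderated"` (limma, default) or `"welch"`.
#' @param p_values Optional precomputed per-gene p-values (unadjusted);
#'   overrides `method`.
#' @return data.frame: `gene_id`, `log2fc`, `p_value`, `fdr`, `call`.
#' @export
diff_expression <- function(counts_control, counts_treated,
                            fc_threshold = 4, fdr_threshold = 0.05,
                            method = c("moderated", "welch"),
                            p_values = NULL) {
  method <- match.arg(method)
  counts_control <- as.matrix(counts_control)
  counts_treated <- as.matrix(counts_treated)
  if (ncol(counts_control) < 2L || ncol(counts_treated) < 2L) {
    stop("diff_expression needs >= 2 replicates per condition")
  }
  stopifnot(nrow(counts_control) == nrow(counts_treated), fc_threshold > 1)
  x <- log2(cbind(counts_control, counts_treated) + 1)
  g1 <- seq_len(ncol(counts_control))
  g2 <- ncol(counts_control) + seq_len(ncol(counts_treated))
  log2fc <- rowMeans(x[, g2, drop = FALSE]) - rowMeans(x[, g1, drop = FALSE])
  if (!is.null(p_values)) {
    stopifnot(length(p_values) == nrow(x))
    p <- p_values
  } else if (method == "moderated") {
    design <- cbind(intercept = 1,
                    treated = c(rep(0, length(g1)), rep(1, length(g2))))
    fit <- limma::lmFit(x, design)
    # zero-variance rows (all-zero counts) are routine in these matrices;
    # limma offsets them and warns, which is expected here
    fit <- withCallingHandlers(
      limma::eBayes(fit, trend = TRUE, robust = FALSE),
      warning = function(w) {
        if (grepl("Zero sample variances", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    p <- fit$p.value[, "treated"]
  } else {
    p <- .welch_rows(x, g1, g2)
  }
  fdr <- bh_fdr(p)
  call <- rep("unchanged", nrow(x))
  up <- !is.na(fdr) & fdr < fdr_threshold & 2^log2fc > fc_threshold
  dn <- !is.na(fdr) & fdr < fdr_threshold & 2^log2fc < 1 / fc_threshold
  call[up] <- "up"
  call[dn] <- "down"
  gene_id <- rownames(counts_control)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(x)))
  data.frame(gene_id = gene_id, log2fc = log2fc, p_value = as.numeric(p),
             fdr = as.numeric(fdr),
             call = factor(call, c("up", "down", "unchanged")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Diurnal rhythm classification over four time points
#'
#' Runs the [diff_expression()] logic (fold-change threshold 2 by
#' default, BH adjustment within each comparison) for each of the six
#' unordered pairs of the four time points and counts, per gene, the
#' comparisons with a significant change. Genes significant in more than
#' two comparisons (>= `min_comparisons`) are flagged diurnal.
#'
#' @param counts Gene x sample count matrix.
#' @param timepoint Factor/character vector over columns of `counts` with
#'   exactly 4 levels, >= 2 replicates each.
#' @param fc_threshold,fdr_threshold Per-comparison thresholds.
#' @param min_comparisons Minimum significant comparisons for the diurnal
#'   flag ("more than two of six" read strictly: default 3).
#' @param method Test passed to [diff_expression()].
#' @return data.frame: `gene_id`, `n_significant` (0-6), `diurnal`.
#' @export
diurnal_classification <- function(counts, timepoint, fc_threshold = 2,
                                   fdr_threshold = 0.05,
                                   min_comparisons = 3,
                                   method = "moderated") {
  counts <- as.matrix(counts)
  timepoint <- as.factor(timepoint)
  stopifnot(length(timepoint) == ncol(counts))
  if (nlevels(timepoint) != 4L) {
    stop("diurnal_classification requires exactly 4 time points, got ",
         nlevels(timepoint))
  }
  if (any(table(timepoint) < 2)) stop("each time point needs >= 2 replicates")
  lv <- levels(timepoint)
  n_sig <- integer(nrow(counts))
  for (i in 1:3) for (j in (i + 1):4) {
    de <- diff_expression(counts[, timepoint == lv[i], drop = FALSE],
                          counts[, timepoint == lv[j], drop = FALSE],
                          fc_threshold = fc_threshold,
                          fdr_threshold = fdr_threshold, method = method)
    n_sig <- n_sig + (de$call != "unchanged")
  }
  gene_id <- rownames(counts)
  if (is.null(gene_id)) gene_id <- as.character(seq_len(nrow(counts)))
  data.frame(gene_id = gene_id, n_significant = n_sig,
             diurnal = n_sig >= min_comparisons,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of changed-gene sets across marks
#'
#' Pairwise and triple intersections of the up- (and down-) regulated
#' gene sets of several differential results, with percentages relative
#' to each set.
#'
#' @param results Named list of data.frames with `gene_id` and `call`
#'   (e.g. from [diff_modification()]), over the same gene universe.
#' @return data.frame: `direction`, `sets` (e.g. `"H3K9ac&Kbu"`),
#'   `n_intersection`, and `pct_of_<name>` columns.
#' @export
changed_set_overlap <- function(results) {
  stopifnot(length(results) >= 2, !is.null(names(results)))
  nm <- names(results)
  rows <- list()
  for (direction in c("up", "down")) {
    sets <- lapply(results, function(r) r$gene_id[r$call == direction])
    combos <- c(utils::combn(nm, 2, simplify = FALSE),
                if (length(nm) >= 3) utils::combn(nm, 3, simplify = FALSE))
    for (cmb in combos) {
      inter <- Reduce(intersect, sets[cmb])
      row <- data.frame(direction = direction,
                        sets = paste(cmb, collapse = "&"),
                        n_intersection = length(inter),
                        stringsAsFactors = FALSE)
      for (s in cmb) {
        row[[paste0("pct_of_", s)]] <-
          if (length(sets[[s]])) 100 * length(inter) / length(sets[[s]])
          else NA_real_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- data.table::rbindlist(rows, fill = TRUE)
  as.data.frame(out)
}
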