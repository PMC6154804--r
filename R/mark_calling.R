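# Marked-gene calling and combination classification.
#
# A gene is "marked" by a modification when a peak overlaps its body or
# 2-kb strand-aware upstream window in BOTH replicates (AND rule). The
# three marks' boolean calls partition genes into eight combination
# categories.

#' Call marked genes from two replicate peak sets
#'
#' A gene is marked iff at least one peak overlaps its body or its
#' strand-aware upstream window in replicate 1 AND in replicate 2.
#'
#' @param peaks_rep1,peaks_rep2 `GRanges` peak sets from [read_peaks()] or
#'   [generate_chip()]; must carry the same `metadata()$mark`.
#' @param annotation `GRanges` annotation.
#' @param upstream Upstream window width in bases.
#' @return Named logical vector (gene_id -> marked) with attribute `mark`.
#' @export
call_marked_genes <- function(peaks_rep1, peaks_rep2, annotation,
                              upstream = 2000) {
  m1 <- S4Vectors::metadata(peaks_rep1)$mark
  m2 <- S4Vectors::metadata(peaks_rep2)$mark
  if (!is.null(m1) && !is.null(m2) && !identical(m1, m2)) {
    stop("replicate peak sets carry different marks: ", m1, " vs ", m2)
  }
  region <- gene_with_upstream(annotation, upstream)
  hit1 <- IRanges::overlapsAny(region, peaks_rep1, ignore.strand = TRUE)
  hit2 <- IRanges::overlapsAny(region, peaks_rep2, ignore.strand = TRUE)
  status <- hit1 & hit2
  names(status) <- annotation$gene_id
  attr(status, "mark") <- if (!is.null(m1)) m1 else m2
  status
}

#' Classify the eight mark combinations
#'
#' Turns the three boolean mark-status vectors into the per-gene
#' combination label, a partition of the gene universe over
#' [combination_levels].
#'
#' @param status_k9ac,status_kbu,status_kcr Named logical vectors over the
#'   same gene universe (from [call_marked_genes()]).
#' @return Named factor (gene_id -> label) with levels
#'   [combination_levels].
#' @export
classify_combinations <- function(status_k9ac, status_kbu, status_kcr) {
  g <- names(status_k9ac)
  if (is.null(g) || !identical(g, names(status_kbu)) ||
      !identical(g, names(status_kcr))) {
    stop("mark status vectors must share one named gene universe")
  }
  parts <- cbind(H3K9ac = status_k9ac, Kbu = status_kbu, Kcr = status_kcr)
  label <- apply(parts, 1L, function(b) {
    if (!any(b)) "none" else paste(acyl_marks[b], collapse = "+")
  })
  factor(stats::setNames(label, g), levels = combination_levels)
}

#' Marginal totals, pairwise overlaps, and co-marking percentages
#'
#' From an eight-category profile (or its category counts), computes the
#' per-mark marked-gene totals, all pairwise and the triple overlap, the
#' percentage of each mark's genes co-marked by both other marks, and the
#' number of genes carrying Kbu or Kcr but not H3K9ac.
#'
#' @param profile A factor from [classify_combinations()], or a named
#'   numeric vector of category counts over [combination_levels].
#' @return List: `category_counts`, `totals` (per mark), `pairwise`
#'   (named `A&B` counts), `triple`, `pct_comarked` (per mark, 100 x
#'   triple / total), and `acyl_only` (Kbu or Kcr without H3K9ac).
#' @examples
#' marginal_counts(rice_category_counts())
#' @export
marginal_counts <- function(profile) {
  if (is.factor(profile) || is.character(profile)) {
    counts <- table(factor(profile, levels = combination_levels))
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    stopifnot(all(combination_levels %in% names(profile)))
    counts <- profile[combination_levels]
  }
  has <- function(m) grepl(m, combination_levels, fixed = TRUE)
  totals <- vapply(acyl_marks,
                   function(m) sum(counts[has(m)]), numeric(1))
  pair_names <- c("H3K9ac&Kbu", "H3K9ac&Kcr", "Kbu&Kcr")
  pairwise <- vapply(list(c("H3K9ac", "Kbu"), c("H3K9ac", "Kcr"),
                          c("Kbu", "Kcr")),
                     function(p) sum(counts[has(p[1]) & has(p[2])]),
                     numeric(1))
  names(pairwise) <- pair_names
  triple <- as.numeric(counts[["H3K9ac+Kbu+Kcr"]])
  pct <- vapply(acyl_marks, function(m) {
    if (totals[[m]] > 0) 100 * triple / totals[[m]] else NA_real_
  }, numeric(1))
  acyl_only <- sum(counts[c("Kbu", "Kcr", "Kbu+Kcr")])
  list(category_counts = counts, totals = totals, pairwise = pairwise,
       triple = triple, pct_comarked = pct, acyl_only = acyl_only)
}

#' Genomic context of peaks
#'
#' Assigns each peak to one context with priority genic > promoter
#' (strand-aware upstream window) > intergenic, crossed with the feature
#' class of the assigned gene (coding before TE-related when a peak
#' touches both).
#'
#' @param peaks `GRanges` peak set.
#' @param annotation `GRanges` annotation.
#' @param upstream Promoter window width in bases.
#' @return data.frame with `context`, `feature_class` (`NA` for
#'   intergenic), `n`, and `proportion` (sums to 1 when peaks exist).
#' @export
peak_context_distribution <- function(peaks, annotation, upstream = 2000) {
  n <- length(peaks)
  context <- rep("intergenic", n)
  klass <- rep(NA_character_, n)
  if (n && length(annotation)) {
    coding_first <- order(annotation$feature_class != "coding")
    body <- annotation[coding_first]
    prom <- upstream_region(body, upstream)
    hit_body <- GenomicRanges::findOverlaps(peaks, body,
                                            ignore.strand = TRUE,
                                            select = "first")
    hit_prom <- GenomicRanges::findOverlaps(peaks, prom,
                                            ignore.strand = TRUE,
                                            select = "first")
    genic <- !is.na(hit_body)
    promo <- !genic & !is.na(hit_prom)
    context[genic] <- "genic"
    context[promo] <- "promoter"
    klass[genic] <- body$feature_class[hit_body[genic]]
    klass[promo] <- body$feature_class[hit_prom[promo]]
  }
  tab <- as.data.frame(table(context = factor(context,
                                              c("genic", "promoter",
                                                "intergenic")),
                             feature_class = factor(klass,
                                                    c("coding", "te_related")),
                             useNA = "ifany"),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0 | (tab$context != "intergenic" &
                            !is.na(tab$feature_class)) |
               (tab$context == "intergenic" & is.na(tab$feature_class)), ]
  tab$proportion <- if (n > 0) tab$n / n else 0
  rownames(tab) <- NULL
  tab
}
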