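# Tag-density quantification: per-gene TPM, genome-bin TPM vectors and
# their correlation, and metagene TSS profiles.
#
# TPM here is the ChIP sense: tags per kilobase of region length per
# million mapped tags, TPM = C * 1e9 / (L * N), with C apportioned to the
# region by overlap length (fractional tags allowed).

# GRanges of the non-zero bins of a track (1-based, closed).
.track_bins_gr <- function(track) {
  v <- track$values
  bw <- track$bin_width
  GenomicRanges::GRanges(v$chrom,
                         IRanges::IRanges(start = v$bin * bw + 1,
                                          width = bw),
                         count = v$count)
}

# Tags overlapping each region, apportioned by overlap length.
.region_counts <- function(track, regions) {
  out <- numeric(length(regions))
  if (nrow(track$values) == 0L || length(regions) == 0L) return(out)
  bins <- .track_bins_gr(track)
  hits <- GenomicRanges::findOverlaps(regions, bins, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(regions)[q], GenomicRanges::ranges(bins)[s]))
  contrib <- bins$count[s] * ov / track$bin_width
  agg <- tapply(contrib, q, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Per-gene TPM from a coverage track
#'
#' TPM(g) = C(g) * 1e9 / (L(g) * N): C is the tag count overlapping the
#' quantified region (gene body, or body plus the 2-kb strand-aware
#' upstream window), apportioned by overlap length; L the region length in
#' bases; N the track's total mapped tags.
#'
#' @param track A [coverage_track()].
#' @param annotation `GRanges` annotation.
#' @param region_mode `"body"` or `"body_plus_upstream2kb"`.
#' @param upstream Upstream width used by the `body_plus_upstream2kb` mode.
#' @return Named numeric vector (gene_id -> TPM) with attributes `mark`,
#'   `sample_id`, `replicate`, and `region_mode`. `NA` for zero-length
#'   regions.
#' @export
compute_tpm <- function(track, annotation,
                        region_mode = c("body", "body_plus_upstream2kb"),
                        upstream = 2000) {
  region_mode <- match.arg(region_mode)
  stopifnot(inherits(track, "coverage_track"), track$total_mapped_tags > 0)
  regions <- if (region_mode == "body") annotation
             else gene_with_upstream(annotation, upstream)
  L <- GenomicRanges::width(regions)
  C <- .region_counts(track, regions)
  tpm <- ifelse(L > 0, C * 1e9 / (L * track$total_mapped_tags), NA_real_)
  names(tpm) <- annotation$gene_id
  attr(tpm, "mark") <- track$mark
  attr(tpm, "sample_id") <- track$sample_id
  attr(tpm, "replicate") <- track$replicate
  attr(tpm, "region_mode") <- region_mode
  tpm
}

#' Gene x replicate TPM matrix for one mark
#'
#' Applies [compute_tpm()] to a list of replicate tracks of the same mark.
#'
#' @param tracks List of [coverage_track()]s (same mark).
#' @param annotation,region_mode,upstream As in [compute_tpm()].
#' @return Matrix gene x replicate with attributes `mark`, `region_mode`.
#' @export
tpm_matrix <- function(tracks, annotation, region_mode = "body",
                       upstream = 2000) {
  marks <- unique(vapply(tracks, function(t) t$mark, character(1)))
  if (length(marks) != 1L) stop("tpm_matrix: tracks mix marks: ",
                                paste(marks, collapse = ", "))
  cols <- lapply(tracks, compute_tpm, annotation = annotation,
                 region_mode = region_mode, upstream = upstream)
  mat <- do.call(cbind, cols)
  colnames(mat) <- vapply(tracks, function(t) t$sample_id, character(1))
  attr(mat, "mark") <- marks
  attr(mat, "region_mode") <- region_mode
  mat
}

#' Genome-wide binned TPM vector
#'
#' Re-bins a track into `bin_width` bins across the whole genome
#' (including untouched bins, as zero) and converts counts to TPM:
#' count * 1e9 / (bin_width * N).
#'
#' @param track A [coverage_track()]. `bin_width` must be a multiple of
#'   the track's bin width.
#' @param chrom_sizes Named vector of chromosome lengths (e.g.
#'   `seqlengths(annotation)`).
#' @param bin_width Output bin width in bases (default 1 kb).
#' @return Named numeric vector over all genome bins (`chrom:bin`).
#' @export
bin_genome_tpm <- function(track, chrom_sizes, bin_width = 1000) {
  stopifnot(inherits(track, "coverage_track"), bin_width > 0)
  if (bin_width %% track$bin_width != 0) {
    stop("bin_width must be a multiple of the track bin width (",
         track$bin_width, ")")
  }
  n_bins <- ceiling(chrom_sizes / bin_width)
  keys <- unlist(lapply(names(chrom_sizes), function(ch) {
    paste0(ch, ":", seq_len(n_bins[[ch]]) - 1L)
  }), use.names = FALSE)
  out <- stats::setNames(numeric(length(keys)), keys)
  v <- track$values
  if (nrow(v)) {
    fold <- bin_width / track$bin_width
    agg <- v[, list(count = sum(count)),
             by = list(chrom = chrom, bin = as.integer(floor(bin / fold)))]
    k <- paste0(agg$chrom, ":", agg$bin)
    known <- k %in% keys
    out[k[known]] <- agg$count[known] * 1e9 /
      (bin_width * track$total_mapped_tags)
  }
  out
}

#' Correlation matrix of binned tracks
#'
#' Pearson (or Spearman) correlations between equal-length per-bin TPM
#' vectors, e.g. from [bin_genome_tpm()]. Zero-variance vectors yield
#' `NA` correlations; the diagonal is 1.
#'
#' @param vectors Named list of equal-length numeric vectors, or a matrix
#'   with one column per track.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix.
#' @export
correlate_tracks <- function(vectors, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(vectors)) {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L) stop("vectors differ in length")
    vectors <- do.call(cbind, vectors)
  }
  stopifnot(ncol(vectors) >= 2, nrow(vectors) >= 3)
  cm <- suppressWarnings(stats::cor(vectors, method = method))
  diag(cm) <- 1
  cm
}

#' Metagene TSS profile
#'
#' Mean TPM-scaled coverage over aligned gene coordinates: `flank /
#' flank_bin` fixed-width bins upstream of the TSS, `n_body_bins`
#' length-normalized bins over the gene body, and the same number of
#' fixed-width bins downstream of the TES, all oriented 5'->3' (minus
#' strand genes reversed). Each bin value is tags per kb per million
#' mapped tags in that bin, averaged across qualifying genes (body length
#' >= `n_body_bins` bases).
#'
#' @param track A [coverage_track()].
#' @param annotation `GRanges` annotation.
#' @param flank Flank width in bases.
#' @param flank_bin Flank bin width in bases.
#' @param n_body_bins Number of equal-width body bins.
#' @return data.frame with `zone` (`upstream`/`body`/`downstream`),
#'   `index` (within zone), `position` (bin centre for flanks, relative
#'   body fraction for body), and `mean_tpm`; attribute `n_genes`.
#' @export
metagene_profile <- function(track, annotation, flank = 2000,
                             flank_bin = 50, n_body_bins = 40) {
  stopifnot(inherits(track, "coverage_track"), flank %% flank_bin == 0)
  keep <- GenomicRanges::width(annotation) >= n_body_bins
  genes <- annotation[keep]
  if (length(genes) == 0L) stop("no genes with body length >= ", n_body_bins)
  n_flank <- flank %/% flank_bin
  plus <- as.character(GenomicRanges::strand(genes)) == "+"
  gs <- GenomicRanges::start(genes)
  ge <- GenomicRanges::end(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  sl <- GenomeInfoDb::seqlengths(annotation)

  bin_edges <- function(i) {
    # 0-based half-open [lo, hi) genomic coordinates of profile bin i
    # (i in 1..(2*n_flank + n_body_bins)), per gene, strand-oriented
    if (i <= n_flank) {               # upstream, 5'-most first
      d_hi <- flank - (i - 1L) * flank_bin
      lo <- ifelse(plus, gs - 1 - d_hi, ge + d_hi - flank_bin)
      hi <- lo + flank_bin
    } else if (i <= n_flank + n_body_bins) {
      j <- i - n_flank
      w <- (ge - gs + 1) / n_body_bins
      lo <- ifelse(plus, (gs - 1) + (j - 1) * w, ge - j * w)
      hi <- lo + w
    } else {
      j <- i - n_flank - n_body_bins
      lo <- ifelse(plus, ge + (j - 1) * flank_bin,
                   gs - 1 - j * flank_bin)
      hi <- lo + flank_bin
    }
    list(lo = lo, hi = hi)
  }

  n_bins_total <- 2L * n_flank + n_body_bins
  mean_tpm <- numeric(n_bins_total)
  N <- track$total_mapped_tags
  bins <- .track_bins_gr(track)
  for (i in seq_len(n_bins_total)) {
    e <- bin_edges(i)
    lo <- pmax(e$lo, 0)
    hi <- pmin(e$hi, as.numeric(sl[chrom]))
    ok <- hi > lo
    cnt <- numeric(length(genes))
    if (any(ok)) {
      reg <- GenomicRanges::GRanges(chrom[ok],
                                    IRanges::IRanges(start = floor(lo[ok]) + 1,
                                                     end = ceiling(hi[ok])))
      # fractional edges: apportion by exact overlap with the real window
      hits <- GenomicRanges::findOverlaps(reg, bins, ignore.strand = TRUE)
      if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        s <- S4Vectors::subjectHits(hits)
        b_lo <- GenomicRanges::start(bins)[s] - 1
        b_hi <- GenomicRanges::end(bins)[s]
        ov <- pmin(b_hi, hi[ok][q]) - pmax(b_lo, lo[ok][q])
        ov <- pmax(ov, 0)
        contrib <- bins$count[s] * ov / track$bin_width
        agg <- tapply(contrib, q, sum)
        cnt_ok <- numeric(sum(ok))
        cnt_ok[as.integer(names(agg))] <- as.numeric(agg)
        cnt[ok] <- cnt_ok
      }
    }
    width_i <- pmax(e$hi - e$lo, .Machine$double.eps)
    tpm_i <- ifelse(ok, cnt * 1e9 / (width_i * N), NA_real_)
    mean_tpm[i] <- mean(tpm_i, na.rm = TRUE)
  }
  zone <- rep(c("upstream", "body", "downstream"),
              times = c(n_flank, n_body_bins, n_flank))
  index <- c(seq_len(n_flank), seq_len(n_body_bins), seq_len(n_flank))
  position <- c(-flank + (seq_len(n_flank) - 0.5) * flank_bin,
                (seq_len(n_body_bins) - 0.5) / n_body_bins,
                (seq_len(n_flank) - 0.5) * flank_bin)
  out <- data.frame(zone = zone, index = index, position = position,
                    mean_tpm = mean_tpm)
  attr(out, "n_genes") <- length(genes)
  attr(out, "mark") <- track$mark
  out
}
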