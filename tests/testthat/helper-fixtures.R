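# Shared fixtures and independent oracles.

# A small deterministic annotation on two chromosomes.
toy_annotation <- function() {
  gr <- GenomicRanges::GRanges(
    seqnames = c("chr1", "chr1", "chr1", "chr2"),
    ranges = IRanges::IRanges(start = c(2001, 9001, 16001, 3001),
                              end = c(5000, 11000, 18000, 7000)),
    strand = c("+", "-", "+", "-"),
    gene_id = c("gA", "gB", "gC", "gD"),
    feature_class = c("coding", "coding", "te_related", "coding"))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 25000, chr2 = 10000)
  names(gr) <- gr$gene_id
  gr
}

# Peak set helper: 0-based half-open triplets -> GRanges with metadata.
toy_peaks <- function(chrom, start0, end0, mark = "Kbu", replicate = 1L) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0))
  S4Vectors::metadata(gr) <- list(sample_id = "toy", mark = mark,
                                  replicate = replicate)
  gr
}

# Coverage track from explicit bins.
toy_track <- function(chrom, bin, count, bin_width = 1000, N = 1e6,
                      mark = "Kbu") {
  coverage_track(data.frame(chrom = chrom, bin = as.integer(bin),
                            count = count),
                 bin_width = bin_width, total_mapped_tags = N, mark = mark)
}

# Named mark-status triple -> combination profile input.
status_vec <- function(x, genes) {
  stats::setNames(as.logical(x), genes)
}

# Independent oracle: hypergeometric tail P(X >= k) by exhaustive
# enumeration of all subsets of size n from a universe of size N with K
# successes (N <= 12).
enum_hyper_tail <- function(k, K, N, n) {
  stopifnot(N <= 12)
  universe <- seq_len(N)
  hits <- seq_len(K)
  subs <- utils::combn(universe, n)
  count <- sum(apply(subs, 2, function(s) sum(s %in% hits) >= k))
  count / ncol(subs)
}

# Independent oracle: textbook Pearson correlation.
pearson_textbook <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Independent oracle: BH step-up computed by the definition.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small default-free simulation config for unit tests.
small_sim <- function(n_genes = 600, seed = 101, ...) {
  sim_config(n_genes = n_genes, n_chroms = 3, n_deg = 40, n_diurnal = 60,
             seed = seed, ...)
}
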