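# TPM arithmetic, genome-bin vectors, correlations, metagene profiles.

test_that("per-gene TPM follows C * 1e9 / (L * N)", {
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                strand = "+", gene_id = "g1",
                                feature_class = "coding")
  GenomeInfoDb::seqlengths(ann) <- c(chr1 = 10000)
  names(ann) <- "g1"
  # 10 tags in the gene body, L = 1000, N = 1e6 -> TPM 10
  tr <- toy_track("chr1", 0, 10, bin_width = 1000, N = 1e6)
  expect_equal(unname(compute_tpm(tr, ann, "body")[["g1"]]), 10)
  # zero coverage -> 0
  tr0 <- toy_track("chr1", 5, 7, bin_width = 1000, N = 1e6)
  expect_equal(unname(compute_tpm(tr0, ann, "body")[["g1"]]), 0)
  # C = 50, L = 2500, N = 2e7 -> TPM 1
  ann2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2500),
                                 strand = "+", gene_id = "g1",
                                 feature_class = "coding")
  GenomeInfoDb::seqlengths(ann2) <- c(chr1 = 10000)
  names(ann2) <- "g1"
  tr2 <- toy_track("chr1", c(0, 1, 2), c(20, 20, 20), bin_width = 1000,
                   N = 2e7)
  # third bin [2000,3000) overlaps the gene by half -> contributes 10
  expect_equal(unname(compute_tpm(tr2, ann2, "body")[["g1"]]), 1.0)
})

test_that("TPM is linear in counts and invariant to joint scaling", {
  ann <- toy_annotation()
  tr <- toy_track("chr1", c(2, 3, 9, 16), c(7, 3, 11, 5), bin_width = 1000,
                  N = 1e6)
  base <- compute_tpm(tr, ann, "body")
  doubled <- toy_track("chr1", c(2, 3, 9, 16), 2 * c(7, 3, 11, 5),
                       bin_width = 1000, N = 1e6)
  expect_equal(unname(compute_tpm(doubled, ann, "body")), unname(2 * base))
  both <- toy_track("chr1", c(2, 3, 9, 16), 2 * c(7, 3, 11, 5),
                    bin_width = 1000, N = 2e6)
  expect_equal(unname(compute_tpm(both, ann, "body")), unname(base))
})

test_that("body_plus_upstream2kb mode extends the quantified region", {
  ann <- toy_annotation()
  # place tags only in gA's upstream window [1,2000]
  tr <- toy_track("chr1", c(0, 1), c(5, 5), bin_width = 1000, N = 1e6)
  body <- compute_tpm(tr, ann, "body")
  ext <- compute_tpm(tr, ann, "body_plus_upstream2kb")
  expect_equal(unname(body[["gA"]]), 0)
  expect_equal(unname(ext[["gA"]]), 10 * 1e9 / (5000 * 1e6))
})

test_that("genome-bin TPM conserves the total tag count", {
  set.seed(99)
  bins <- sort(sample(0:199, 60))
  counts <- rpois(60, 8) + runif(60)
  tr <- toy_track("chr1", bins, counts, bin_width = 500, N = 3e6)
  v <- bin_genome_tpm(tr, c(chr1 = 100000), bin_width = 1000)
  expect_length(v, 100)
  # conservation: sum(TPM) * bin_width * N / 1e9 = total binned tags
  expect_equal(sum(v) * 1000 * 3e6 / 1e9, sum(counts))
  # uniform track -> all covered bins equal
  tru <- toy_track("chr1", 0:99, rep(4, 100), bin_width = 1000, N = 1e6)
  vu <- bin_genome_tpm(tru, c(chr1 = 100000), bin_width = 1000)
  expect_true(all(abs(vu - vu[1]) < 1e-12))
})

test_that("track correlations match the textbook formula and edge cases", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  cm <- correlate_tracks(list(a = x, b = y, c = -x + 10))
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_equal(cm["a", "b"], pearson_textbook(x, y))
  expect_equal(cm, t(cm))
  # zero-variance vector -> missing correlations, diagonal kept at 1
  cz <- correlate_tracks(list(a = x, z = rep(2, 10)))
  expect_true(is.na(cz["a", "z"]))
  expect_equal(cz["z", "z"], 1)
  # independent negative-binomial bins decorrelate
  set.seed(7)
  u <- rnbinom(10000, mu = 5, size = 2)
  w <- rnbinom(10000, mu = 5, size = 2)
  expect_lt(abs(correlate_tracks(list(u = u, w = w))["u", "w"]), 0.05)
})

test_that("metagene profiles are flat under uniform coverage", {
  ann <- toy_annotation()
  # uniform 1 tag per 50-bp bin everywhere on both chromosomes
  tr <- coverage_track(
    rbind(data.frame(chrom = "chr1", bin = 0:499, count = 1),
          data.frame(chrom = "chr2", bin = 0:199, count = 1)),
    bin_width = 50, total_mapped_tags = 1e6)
  prof <- metagene_profile(tr, ann)
  expect_equal(nrow(prof), 40 + 40 + 40)
  expect_equal(table(prof$zone)[["upstream"]], 40)
  expect_lt(diff(range(prof$mean_tpm)) / mean(prof$mean_tpm), 1e-6)
})

test_that("metagene profiles localize a TSS-proximal delta", {
  ann <- toy_annotation()
  tss_bins <- floor((ifelse(as.character(GenomicRanges::strand(ann)) == "+",
                            GenomicRanges::start(ann),
                            GenomicRanges::end(ann)) - 1) / 50)
  tr <- coverage_track(
    data.frame(chrom = as.character(GenomicRanges::seqnames(ann)),
               bin = tss_bins, count = 100),
    bin_width = 50, total_mapped_tags = 1e6)
  prof <- metagene_profile(tr, ann)
  peak_zone <- prof$zone[which.max(prof$mean_tpm)]
  peak_idx <- prof$index[which.max(prof$mean_tpm)]
  expect_true(peak_zone == "body" && peak_idx == 1 ||
                peak_zone == "upstream" && peak_idx == 40)
  # distal flanks empty
  expect_equal(prof$mean_tpm[prof$zone == "downstream" & prof$index > 5],
               rep(0, 35))
})

test_that("metagene profile of the synthetic generator peaks near the TSS", {
  cfg <- small_sim(n_genes = 400)
  st <- simulate_study(cfg, conditions = "control")
  prof <- metagene_profile(st$chip$control$tracks$Kbu[[1]], st$annotation)
  top <- prof[which.max(prof$mean_tpm), ]
  # kernel support is [TSS-500, TSS+1500]: maximum in late upstream or body
  expect_true((top$zone == "upstream" && top$index > 30) ||
                top$zone == "body")
  # strand symmetry: mirroring the genome leaves the profile unchanged
  sl <- GenomeInfoDb::seqlengths(st$annotation)
  ann_m <- st$annotation
  new_start <- sl[as.character(GenomicRanges::seqnames(ann_m))] -
    GenomicRanges::end(ann_m) + 1
  new_end <- sl[as.character(GenomicRanges::seqnames(ann_m))] -
    GenomicRanges::start(ann_m) + 1
  mirrored <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ann_m),
    IRanges::IRanges(new_start, new_end),
    strand = ifelse(as.character(GenomicRanges::strand(ann_m)) == "+",
                    "-", "+"),
    gene_id = ann_m$gene_id, feature_class = ann_m$feature_class)
  GenomeInfoDb::seqlengths(mirrored) <- sl
  names(mirrored) <- mirrored$gene_id
  tr <- st$chip$control$tracks$Kbu[[1]]
  v <- tr$values
  bw <- tr$bin_width
  n_bins <- ceiling(sl[v$chrom] / bw)
  v_m <- data.frame(chrom = v$chrom,
                    bin = as.integer(n_bins - 1 - v$bin),
                    count = v$count)
  tr_m <- coverage_track(v_m, bw, tr$total_mapped_tags, mark = tr$mark)
  prof_m <- metagene_profile(tr_m, mirrored)
  expect_equal(prof_m$mean_tpm, prof$mean_tpm, tolerance = 1e-6)
})
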