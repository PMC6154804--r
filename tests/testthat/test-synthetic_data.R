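# The synthetic study generator: determinism, marginal laws, truth
# consistency.

test_that("annotation generation is deterministic and honors the length law", {
  cfg <- sim_config(n_genes = 1000, n_chroms = 4, seed = 11)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(GenomicRanges::start(a1), GenomicRanges::start(a2))
  expect_identical(as.character(GenomicRanges::strand(a1)),
                   as.character(GenomicRanges::strand(a2)))
  expect_length(a1, 1000)
  # sample median within 10% of the configured 2-kb median
  expect_lt(abs(median(GenomicRanges::width(a1)) - 2000) / 2000, 0.10)
  # non-overlapping with >= 4 kb spacing, within chromosome bounds
  by_chr <- split(a1, GenomicRanges::seqnames(a1))
  for (chr in names(by_chr)) {
    g <- by_chr[[chr]][order(GenomicRanges::start(by_chr[[chr]]))]
    if (length(g) > 1) {
      gaps <- GenomicRanges::start(g)[-1] -
        GenomicRanges::end(g)[-length(g)]
      expect_true(all(gaps >= 4000))
    }
  }
  expect_true(all(GenomicRanges::end(a1) <=
                    GenomeInfoDb::seqlengths(a1)[
                      as.character(GenomicRanges::seqnames(a1))]))
  expect_length(generate_annotation(sim_config(n_genes = 0, seed = 1)), 0)
})

test_that("truth labels follow the configured category frequencies", {
  cfg <- sim_config(n_genes = 20000, seed = 5)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  obs <- table(factor(tr$label, combination_levels)) / nrow(tr)
  exp_freq <- cfg$category_freqs[combination_levels]
  # multinomial tolerance: 4 SDs per category
  tol <- 4 * sqrt(exp_freq * (1 - exp_freq) / nrow(tr))
  expect_true(all(abs(as.numeric(obs) - exp_freq) <= tol + 1e-12))
  # marked flags consistent with the label string
  expect_equal(tr$marked_Kbu, grepl("Kbu", tr$label, fixed = TRUE))
  expect_equal(tr$marked_H3K9ac, grepl("H3K9ac", tr$label, fixed = TRUE))
})

test_that("chip generation respects the truth and the detection law", {
  cfg <- small_sim(peak_detect_prob = 1, false_peak_rate = 0)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  ch <- generate_chip(cfg, ann, tr, "control")
  # with certain detection and no false peaks, peak calls sit exactly at
  # truly marked genes' loci
  for (m in acyl_marks) {
    for (r in 1:2) {
      marked_now <- call_marked_genes(ch$peaks[[m]][[r]],
                                      ch$peaks[[m]][[r]], ann)
      expect_equal(as.vector(marked_now), tr[[paste0("marked_", m)]])
    }
  }
  # depth = 0 means coverage is pure background
  cfg0 <- small_sim(depth = 0)
  ann0 <- generate_annotation(cfg0)
  tr0 <- generate_truth(cfg0, ann0)
  ch0 <- generate_chip(cfg0, ann0, tr0, "control")
  gene_bins <- sum(GenomicRanges::width(ann0)) / cfg0$coverage_bin_width
  expect_lt(sum(ch0$tracks$Kbu[[1]]$values$count),
            3 * cfg0$background_rate *
              sum(as.numeric(GenomeInfoDb::seqlengths(ann0))) / 1000)
})

test_that("mean tag count over truly marked genes matches the configured depth", {
  cfg <- sim_config(n_genes = 10000, seed = 23)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  ch <- generate_chip(cfg, ann, tr, "control")
  # count tags landing near each truly Kbu-marked gene via the track
  tr_kbu <- ch$tracks$Kbu[[1]]
  total_sig <- sum(tr_kbu$values$count) -
    0  # includes background; subtract its expectation instead
  bg_expect <- cfg$background_rate *
    sum(as.numeric(GenomeInfoDb::seqlengths(ann))) / 1000
  n_marked <- sum(tr$marked_Kbu)
  mean_tags <- (total_sig - bg_expect) / n_marked
  expect_lt(abs(mean_tags - cfg$depth) / cfg$depth, 0.05)
})

test_that("peak sets are identical with and without coverage generation", {
  cfg <- small_sim()
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  with_cov <- generate_chip(cfg, ann, tr, "control", coverage = TRUE)
  no_cov <- generate_chip(cfg, ann, tr, "control", coverage = FALSE)
  for (m in acyl_marks) for (r in 1:2) {
    expect_identical(GenomicRanges::start(with_cov$peaks[[m]][[r]]),
                     GenomicRanges::start(no_cov$peaks[[m]][[r]]))
  }
})

test_that("false peaks at unmarked genes occur at the configured rate", {
  cfg <- sim_config(n_genes = 10000, seed = 31)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  ch <- generate_chip(cfg, ann, tr, "control", coverage = FALSE)
  # single-replicate marking at unmarked genes estimates false_peak_rate
  s1 <- call_marked_genes(ch$peaks$Kcr[[1]], ch$peaks$Kcr[[1]], ann)
  unmarked <- !tr$marked_Kcr
  rate <- mean(s1[unmarked])
  p <- cfg$false_peak_rate
  tol <- 4 * sqrt(p * (1 - p) / sum(unmarked))
  expect_lt(abs(rate - p), tol)
})

test_that("expression carries planted effects and decouples when asked", {
  cfg <- small_sim(n_genes = 2000, seed = 17)
  ann <- generate_annotation(cfg)
  tr <- generate_truth(cfg, ann)
  ex <- generate_expression(cfg, ann, tr)
  grp <- ex$samples$group
  # planted 8-fold effect: treated/control mean ratio near 2^3 for up-DEGs
  up <- tr$deg_starvation == 1
  ratio <- rowMeans(ex$counts[up, grp == "starvation"]) /
    pmax(rowMeans(ex$counts[up, grp == "control"]), 1e-9)
  expect_lt(abs(median(log2(ratio)) - cfg$deg_log2fc), 0.35)
  # planted diurnal genes: max/min across time-point means near 2^amplitude
  tp <- c("T00", "T06", "T12", "T18")
  mns <- sapply(tp, function(t) rowMeans(ex$counts[tr$diurnal, grp == t]))
  ratio_d <- apply(mns, 1, max) / pmax(apply(mns, 1, min), 1e-9)
  expect_gt(median(ratio_d), 2)   # phase-dependent, bounded below
  expect_lt(median(ratio_d), 2^(cfg$diurnal_amplitude + 1))

  # with coupling off and no planted effects, expression is independent
  # of mark status
  cfg0 <- sim_config(n_genes = 10000, seed = 19, n_deg = 0, n_diurnal = 0,
                     mark_effects = c(H3K9ac = 0, Kbu = 0, Kcr = 0),
                     k9ac_prop_slope = 0)
  ann0 <- generate_annotation(cfg0)
  tr0 <- generate_truth(cfg0, ann0)
  ex0 <- generate_expression(cfg0, ann0, tr0)
  lf <- log2(rowMeans(ex0$counts[, ex0$samples$group == "control"]) + 1)
  r <- cor(lf, as.numeric(tr0$marked_H3K9ac))
  expect_lt(abs(r), 0.05)
})

test_that("the full study is deterministic given the seed", {
  cfg <- small_sim(n_genes = 300)
  s1 <- simulate_study(cfg, conditions = "control")
  s2 <- simulate_study(cfg, conditions = "control")
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expression$counts, s2$expression$counts)
  expect_identical(s1$chip$control$tracks$Kcr[[2]]$values,
                   s2$chip$control$tracks$Kcr[[2]]$values)
  expect_identical(GenomicRanges::start(s1$chip$control$peaks$Kbu[[1]]),
                   GenomicRanges::start(s2$chip$control$peaks$Kbu[[1]]))
})
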