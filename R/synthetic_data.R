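# Synthetic multi-mark study generator.
#
# Emulates the statistical structure the analysis assumes: genes on a few
# chromosomes, mark combinations at fixed category frequencies,
# TSS-peaked tag placement, negative-binomial replicate noise, expression
# coupled to marks and to the H3K9ac proportion, planted DEGs (with
# H3K9ac co-shift) and planted diurnal genes. Every product is
# deterministic given the seed, and a truth table records what was planted.

# Evaluate code under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Triangular deviates on [a, b] with mode m, by inverse CDF.
.rtriangle <- function(n, a, b, m) {
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic study. Defaults
#' describe the emulated study conditions: 20,000 genes, mark-combination
#' frequencies equal to the published rice category proportions
#' ([rice_category_counts()] scaled by 56,384), 50 expected tags per marked
#' gene, 0.5 background tags/kb, per-replicate peak detection probability
#' 0.95 with a 0.01 false-peak rate, and expression coupled to mark
#' presence and to the true H3K9ac proportion. Two ChIP replicates per
#' mark and condition; two RNA replicates per condition and time point.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of synthetic chromosomes.
#' @param gene_length_median,gene_length_sigma Log-normal gene-length law
#'   (median in bases; sigma on the log scale).
#' @param min_gap,max_gap Intergenic spacing range in bases (>= 4 kb
#'   ensures upstream windows do not collide).
#' @param te_fraction Fraction of genes labelled TE-related.
#' @param category_freqs Named probabilities over [combination_levels]
#'   (must sum to 1).
#' @param depth Expected tags per truly marked gene, per replicate.
#' @param mark_intensity_sigma Named per-mark log2 SD of the latent
#'   per-gene mark intensity (H3K9ac wider by default, so its proportion
#'   varies over a wider range).
#' @param replicate_dispersion Negative-binomial dispersion of tag counts
#'   across replicates (var = mu + dispersion * mu^2).
#' @param background_rate Background tags per kb, genome-wide.
#' @param peak_detect_prob Per-replicate probability that a truly marked
#'   gene yields a peak call.
#' @param false_peak_rate Per-replicate probability of a spurious peak at
#'   an unmarked gene's locus.
#' @param coverage_bin_width Coverage track bin width in bases.
#' @param kernel_span Tag-placement kernel support around the TSS,
#'   strand-oriented, in bases (default -500..+1500).
#' @param kernel_mode Mode of the triangular kernel, bases from the TSS.
#' @param expr_intercept_log2 Baseline log2 expected count for an unmarked
#'   gene of median length.
#' @param mark_effects Named per-mark additive effect on log2 expression.
#' @param k9ac_prop_slope Slope of log2 expression on the true H3K9ac
#'   proportion.
#' @param gene_noise_sd SD of the per-gene baseline log2 expression.
#' @param expr_dispersion Negative-binomial dispersion of expression counts.
#' @param n_deg Planted DEGs per stress condition (half up, half down),
#'   drawn among marked genes.
#' @param deg_log2fc Planted expression effect size (log2).
#' @param deg_mod_shift_log2 Named per-mark log2 shift of mark intensity in
#'   DEGs, same sign as the expression change (H3K9ac-coupled by default;
#'   Kbu/Kcr coupling off).
#' @param n_diurnal Planted diurnal genes, drawn among H3K9ac-marked genes.
#' @param diurnal_amplitude Log2 peak-to-trough amplitude of the planted
#'   sinusoid over the four time points.
#' @param seed Integer seed; mandatory, all outputs are deterministic in it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 20000,
                       n_chroms = 12,
                       gene_length_median = 2000,
                       gene_length_sigma = 0.6,
                       min_gap = 4000,
                       max_gap = 8000,
                       te_fraction = 0.15,
                       category_freqs = rice_category_counts() / sum(rice_category_counts()),
                       depth = 50,
                       mark_intensity_sigma = c(H3K9ac = 0.8, Kbu = 0.4, Kcr = 0.4),
                       replicate_dispersion = 0.1,
                       background_rate = 0.5,
                       peak_detect_prob = 0.95,
                       false_peak_rate = 0.01,
                       coverage_bin_width = 50,
                       kernel_span = c(-500, 1500),
                       kernel_mode = 250,
                       expr_intercept_log2 = 5,
                       mark_effects = c(H3K9ac = 1, Kbu = 0.5, Kcr = 0.5),
                       k9ac_prop_slope = 2,
                       gene_noise_sd = 0.7,
                       expr_dispersion = 0.05,
                       n_deg = 400,
                       deg_log2fc = 3,
                       deg_mod_shift_log2 = c(H3K9ac = 1.5, Kbu = 0, Kcr = 0),
                       n_diurnal = 2000,
                       diurnal_amplitude = 2,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- list(n_genes = n_genes, n_chroms = n_chroms,
              gene_length_median = gene_length_median,
              gene_length_sigma = gene_length_sigma,
              min_gap = min_gap, max_gap = max_gap,
              te_fraction = te_fraction,
              category_freqs = category_freqs, depth = depth,
              mark_intensity_sigma = mark_intensity_sigma,
              replicate_dispersion = replicate_dispersion,
              background_rate = background_rate,
              peak_detect_prob = peak_detect_prob,
              false_peak_rate = false_peak_rate,
              coverage_bin_width = coverage_bin_width,
              kernel_span = kernel_span, kernel_mode = kernel_mode,
              expr_intercept_log2 = expr_intercept_log2,
              mark_effects = mark_effects,
              k9ac_prop_slope = k9ac_prop_slope,
              gene_noise_sd = gene_noise_sd,
              expr_dispersion = expr_dispersion,
              n_deg = n_deg, deg_log2fc = deg_log2fc,
              deg_mod_shift_log2 = deg_mod_shift_log2,
              n_diurnal = n_diurnal, diurnal_amplitude = diurnal_amplitude,
              seed = as.integer(seed))
  stopifnot(n_genes >= 0, n_chroms >= 1, depth >= 0,
            min_gap >= 0, max_gap >= min_gap,
            te_fraction >= 0, te_fraction <= 1,
            peak_detect_prob >= 0, peak_detect_prob <= 1,
            false_peak_rate >= 0, false_peak_rate <= 1,
            background_rate >= 0, replicate_dispersion >= 0,
            expr_dispersion >= 0, diurnal_amplitude >= 0,
            all(combination_levels %in% names(category_freqs)),
            all(category_freqs >= 0),
            abs(sum(category_freqs) - 1) < 1e-8,
            all(acyl_marks %in% names(mark_intensity_sigma)),
            all(acyl_marks %in% names(mark_effects)),
            all(acyl_marks %in% names(deg_mod_shift_log2)),
            kernel_span[1] < kernel_mode, kernel_mode < kernel_span[2])
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` non-overlapping genes with at least `min_gap` spacing
#' on `n_chroms` chromosomes (round-robin), lengths drawn log-normally,
#' strands random, `te_fraction` labelled TE-related.
#'
#' @param config A [sim_config()].
#' @return `GRanges` annotation with `gene_id`, `feature_class`, and
#'   chromosome lengths in `seqlengths()`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    S4Vectors::mcols(gr)$feature_class <- character(0)
    return(gr)
  }
  .with_seed(config$seed + 1L, {
    len <- pmax(200L, as.integer(round(stats::rlnorm(
      n, meanlog = log(config$gene_length_median),
      sdlog = config$gene_length_sigma))))
    gap <- as.integer(round(stats::runif(n, config$min_gap, config$max_gap)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    te <- stats::runif(n) < config$te_fraction
    chrom_idx <- rep_len(seq_len(config$n_chroms), n)
    ord <- order(chrom_idx)
    start <- integer(n)
    chrom_len <- stats::setNames(integer(config$n_chroms),
                                 sprintf("chr%02d", seq_len(config$n_chroms)))
    # lay genes left to right per chromosome, leading gap first so the
    # first gene keeps a full upstream window
    pos <- rep(1L, config$n_chroms)
    for (i in ord) {
      ci <- chrom_idx[i]
      start[i] <- pos[ci] + gap[i]
      pos[ci] <- start[i] + len[i]
    }
    for (ci in seq_len(config$n_chroms)) {
      # round up to a whole number of kb so coverage bins tile exactly
      chrom_len[ci] <- as.integer(ceiling((pos[ci] + config$max_gap) / 1000) * 1000)
    }
    gr <- GenomicRanges::GRanges(
      seqnames = sprintf("chr%02d", chrom_idx),
      ranges = IRanges::IRanges(start = start, width = len),
      strand = strand,
      gene_id = sprintf("g%05d", seq_len(n)),
      feature_class = ifelse(te, "te_related", "coding"))
    GenomeInfoDb::seqlevels(gr) <- names(chrom_len)
    GenomeInfoDb::seqlengths(gr) <- chrom_len
    names(gr) <- gr$gene_id
    gr
  })
}

#' Generate the truth table
#'
#' Draws each gene's mark-combination label from `category_freqs`, latent
#' per-mark intensities (log-normal around `depth`, mean-corrected so the
#' expected tag count equals `depth`), planted DEG assignments per stress
#' condition (among marked genes, half up / half down), and planted
#' diurnal genes (among H3K9ac-marked genes) with random phases.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @return data.frame, one row per gene: `gene_id`, `label`,
#'   `marked_<mark>`, `intensity_<mark>`, `p_true_k9ac`,
#'   `deg_starvation`/`deg_submergence` (-1/0/+1), `diurnal`,
#'   `diurnal_phase`.
#' @export
generate_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(annotation)
  .with_seed(config$seed + 2L, {
    label <- sample(combination_levels, n, replace = TRUE,
                    prob = config$category_freqs[combination_levels])
    marked <- sapply(acyl_marks, function(m) {
      grepl(m, label, fixed = TRUE)
    })
    if (n == 1L) marked <- matrix(marked, nrow = 1,
                                  dimnames = list(NULL, acyl_marks))
    intensity <- sapply(acyl_marks, function(m) {
      s <- config$mark_intensity_sigma[[m]]
      # mean-correct the log-normal so E[intensity] = depth
      config$depth * 2^stats::rnorm(n, 0, s) / exp((s * log(2))^2 / 2)
    })
    if (n == 1L) intensity <- matrix(intensity, nrow = 1,
                                     dimnames = list(NULL, acyl_marks))
    eff <- marked * intensity
    tot <- rowSums(eff)
    p_k9 <- ifelse(tot > 0, eff[, "H3K9ac"] / tot, 0)
    deg <- matrix(0L, n, 2, dimnames = list(NULL, c("starvation", "submergence")))
    any_marked <- rowSums(marked) > 0
    for (cond in c("starvation", "submergence")) {
      k <- min(config$n_deg, sum(any_marked))
      if (k > 0) {
        pick <- sample(which(any_marked), k)
        dir <- rep_len(c(1L, -1L), k)
        deg[pick, cond] <- dir
      }
    }
    diurnal <- rep(FALSE, n)
    k9 <- which(marked[, "H3K9ac"])
    k <- min(config$n_diurnal, length(k9))
    if (k > 0) diurnal[sample(k9, k)] <- TRUE
    data.frame(gene_id = annotation$gene_id, label = label,
               marked_H3K9ac = marked[, "H3K9ac"],
               marked_Kbu = marked[, "Kbu"],
               marked_Kcr = marked[, "Kcr"],
               intensity_H3K9ac = intensity[, "H3K9ac"],
               intensity_Kbu = intensity[, "Kbu"],
               intensity_Kcr = intensity[, "Kcr"],
               p_true_k9ac = p_k9,
               deg_starvation = deg[, "starvation"],
               deg_submergence = deg[, "submergence"],
               diurnal = diurnal,
               diurnal_phase = ifelse(diurnal, stats::runif(n, 0, 2 * pi), 0),
               stringsAsFactors = FALSE)
  })
}

# 1-based TSS per gene
.tss <- function(annotation) {
  ifelse(as.character(GenomicRanges::strand(annotation)) == "+",
         GenomicRanges::start(annotation), GenomicRanges::end(annotation))
}

#' Generate ChIP coverage tracks and peak sets
#'
#' For one condition, draws per-gene tag counts NB(`depth`-scaled latent
#' intensity, `replicate_dispersion`) for truly marked genes, places tags
#' with a strand-oriented triangular kernel over `kernel_span` around the
#' TSS, adds Poisson background genome-wide, bins the tags into a
#' [coverage_track()], and emits peak calls: the kernel window with
#' probability `peak_detect_prob` at marked genes and `false_peak_rate`
#' at unmarked genes. In stress conditions, DEG-coupled marks shift their
#' intensity by `deg_mod_shift_log2` in the direction of the planted
#' expression change.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [generate_truth()].
#' @param condition `"control"`, `"starvation"`, or `"submergence"`.
#' @param coverage If `FALSE`, skip coverage tracks (peaks only; cheaper
#'   when only marked-gene calling is exercised).
#' @return List with elements `tracks` and `peaks`, each a list indexed
#'   `[[mark]][[replicate]]`.
#' @export
generate_chip <- function(config, annotation, truth,
                          condition = c("control", "starvation", "submergence"),
                          coverage = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  cond_idx <- match(condition, c("control", "starvation", "submergence"))
  n <- length(annotation)
  stopifnot(nrow(truth) == n)
  sl <- GenomeInfoDb::seqlengths(annotation)
  chroms <- names(sl)
  genome_bp <- sum(as.numeric(sl))
  tss <- .tss(annotation)
  plus <- as.character(GenomicRanges::strand(annotation)) == "+"
  chrom_of <- as.character(GenomicRanges::seqnames(annotation))
  deg_dir <- if (condition == "control") rep(0L, n)
             else truth[[paste0("deg_", condition)]]
  # independent sub-seeds per (condition, mark, replicate, component) so
  # peak sets are identical whether or not coverage is generated
  sub_seed <- function(mi, r, comp) {
    (config$seed %% 100000L) * 10000L + cond_idx * 1000L + mi * 100L +
      r * 10L + comp
  }
  tracks <- list()
  peaks <- list()
  size <- if (config$replicate_dispersion > 0)
    1 / config$replicate_dispersion else Inf
  for (mi in seq_along(acyl_marks)) {
    m <- acyl_marks[mi]
    shift <- 2^(deg_dir * config$deg_mod_shift_log2[[m]])
    mu <- truth[[paste0("intensity_", m)]] * shift
    marked <- truth[[paste0("marked_", m)]]
    tracks[[m]] <- list()
    peaks[[m]] <- list()
    for (r in 1:2) {
      sid <- sprintf("%s_%s_rep%d", m, condition, r)
      if (coverage) {
        tracks[[m]][[r]] <- .with_seed(sub_seed(mi, r, 1L), {
          idx <- which(marked)
          tags <- if (length(idx))
            stats::rnbinom(length(idx), mu = mu[idx], size = size)
          else integer(0)
          gi <- rep.int(idx, tags)
          total_sig <- sum(tags)
          n_bg <- stats::rpois(1, config$background_rate * genome_bp / 1000)
          off <- .rtriangle(total_sig, config$kernel_span[1],
                            config$kernel_span[2], config$kernel_mode)
          pos0 <- ifelse(plus[gi], tss[gi] - 1 + off, tss[gi] - 1 - off)
          sig_chrom <- chrom_of[gi]
          bg_chrom <- sample(chroms, n_bg, replace = TRUE,
                             prob = as.numeric(sl) / genome_bp)
          bg_pos0 <- floor(stats::runif(n_bg, 0, sl[bg_chrom]))
          ch <- c(sig_chrom, bg_chrom)
          p0 <- pmin(pmax(c(pos0, bg_pos0), 0), sl[ch] - 1)
          dt <- data.table::data.table(
            chrom = ch,
            bin = as.integer(floor(p0 / config$coverage_bin_width)))
          dt <- dt[, list(count = as.numeric(.N)), by = c("chrom", "bin")]
          coverage_track(dt, config$coverage_bin_width,
                         total_mapped_tags = max(total_sig + n_bg, 1),
                         sample_id = sid, mark = m, replicate = r)
        })
      }
      peaks[[m]][[r]] <- .with_seed(sub_seed(mi, r, 2L), {
        detect <- (marked & stats::runif(n) < config$peak_detect_prob) |
          (!marked & stats::runif(n) < config$false_peak_rate)
        widx <- which(detect)
        w_start <- ifelse(plus[widx], tss[widx] + config$kernel_span[1],
                          tss[widx] - config$kernel_span[2])
        w_end <- ifelse(plus[widx], tss[widx] + config$kernel_span[2],
                        tss[widx] - config$kernel_span[1])
        w_start <- pmax(w_start, 1)
        w_end <- pmin(w_end, sl[chrom_of[widx]])
        pk <- GenomicRanges::GRanges(chrom_of[widx],
                                     IRanges::IRanges(w_start, w_end))
        pk <- GenomicRanges::reduce(GenomicRanges::sort(pk))
        S4Vectors::metadata(pk) <- list(sample_id = sid, mark = m,
                                        replicate = r)
        pk
      })
    }
  }
  list(tracks = tracks, peaks = peaks)
}

#' Generate coupled expression matrices
#'
#' Log2 expected expression is `expr_intercept_log2` plus the per-mark
#' additive effects, plus `k9ac_prop_slope` times the true H3K9ac
#' proportion, plus per-gene N(0, `gene_noise_sd`) noise; counts scale
#' with gene length and are drawn NB with `expr_dispersion`. Planted DEGs
#' receive +/- `deg_log2fc` in their stress condition; planted diurnal
#' genes receive a sinusoid of log2 peak-to-trough `diurnal_amplitude`
#' across the four time points. FPKM is derived from counts, gene length,
#' and per-sample totals.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()].
#' @param truth Output of [generate_truth()].
#' @return List: `counts` and `fpkm` (gene x sample matrices) and
#'   `samples` (data.frame with `sample`, `group`, `replicate`). Groups
#'   are `control`, `starvation`, `submergence`, and time points `T00`,
#'   `T06`, `T12`, `T18`; two replicates each.
#' @export
generate_expression <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(annotation)
  len <- GenomicRanges::width(annotation)
  groups <- c("control", "starvation", "submergence",
              "T00", "T06", "T12", "T18")
  samples <- data.frame(
    sample = as.vector(t(outer(groups, 1:2, function(g, r)
      sprintf("%s_rep%d", g, r)))),
    group = rep(groups, each = 2),
    replicate = rep(1:2, times = length(groups)),
    stringsAsFactors = FALSE)
  .with_seed(config$seed + 20L, {
    base <- config$expr_intercept_log2 +
      truth$marked_H3K9ac * config$mark_effects[["H3K9ac"]] +
      truth$marked_Kbu * config$mark_effects[["Kbu"]] +
      truth$marked_Kcr * config$mark_effects[["Kcr"]] +
      config$k9ac_prop_slope * truth$p_true_k9ac +
      stats::rnorm(n, 0, config$gene_noise_sd)
    tp_hours <- c(T00 = 0, T06 = 6, T12 = 12, T18 = 18)
    counts <- matrix(0, nrow = n, ncol = nrow(samples),
                     dimnames = list(truth$gene_id, samples$sample))
    size <- if (config$expr_dispersion > 0) 1 / config$expr_dispersion else Inf
    for (j in seq_len(nrow(samples))) {
      g <- samples$group[j]
      offset <- numeric(n)
      if (g %in% c("starvation", "submergence")) {
        offset <- truth[[paste0("deg_", g)]] * config$deg_log2fc
      } else if (g %in% names(tp_hours)) {
        phase_t <- 2 * pi * tp_hours[[g]] / 24
        offset <- ifelse(truth$diurnal,
                         (config$diurnal_amplitude / 2) *
                           sin(phase_t + truth$diurnal_phase), 0)
      }
      mu <- 2^(base + offset) * len / config$gene_length_median
      counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
    }
    totals <- pmax(colSums(counts), 1)
    fpkm <- sweep(counts * 1e9 / len, 2, totals, "/")
    list(counts = counts, fpkm = fpkm, samples = samples)
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper: annotation, truth, ChIP for the requested
#' conditions, and expression, optionally written to disk in the formats
#' the readers consume (GFF3, BED, bedGraph, TSV, plus `truth.tsv`).
#'
#' @param config A [sim_config()].
#' @param conditions ChIP conditions to generate.
#' @param coverage Generate coverage tracks (see [generate_chip()]).
#' @param dir If non-`NULL`, write all products under this directory.
#' @return List: `config`, `annotation`, `truth`, `chip` (per condition),
#'   `expression`.
#' @export
simulate_study <- function(config,
                           conditions = c("control", "starvation", "submergence"),
                           coverage = TRUE, dir = NULL) {
  annotation <- generate_annotation(config)
  truth <- generate_truth(config, annotation)
  chip <- lapply(stats::setNames(conditions, conditions), function(cond) {
    generate_chip(config, annotation, truth, cond, coverage = coverage)
  })
  expression <- generate_expression(config, annotation, truth)
  res <- list(config = config, annotation = annotation, truth = truth,
              chip = chip, expression = expression)
  if (!is.null(dir)) .write_study(res, dir)
  res
}

.write_study <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_models(res$annotation, file.path(dir, "genes.gff3"))
  utils::write.table(res$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cond in names(res$chip)) {
    for (m in acyl_marks) {
      for (r in 1:2) {
        pk <- res$chip[[cond]]$peaks[[m]][[r]]
        write_peaks(pk, file.path(dir, sprintf("peaks.%s.%s.rep%d.bed",
                                               m, cond, r)))
        tr <- res$chip[[cond]]$tracks[[m]][[r]]
        if (!is.null(tr)) {
          write_coverage(tr, file.path(dir, sprintf(
            "coverage.%s.%s.rep%d.bedgraph", m, cond, r)))
        }
      }
    }
  }
  for (what in c("counts", "fpkm")) {
    mat <- res$expression[[what]]
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0("expression.", what, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
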