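# End-to-end orchestration: simulate (or read) -> quantify -> call ->
# classify -> differential -> proportions -> enrichment -> report.

#' Assemble a run configuration
#'
#' Bundles the analysis thresholds (all at the study's fixed defaults),
#' the simulation settings, and output options, and validates them.
#'
#' @param sim A [sim_config()]; the synthetic study to analyse. Mutually
#'   exclusive with `input_dir`.
#' @param input_dir Directory of input files in the layout written by
#'   [simulate_study()] (`genes.gff3`, `peaks.<mark>.<condition>.rep<r>.bed`,
#'   `coverage.<mark>.<condition>.rep<r>.bedgraph`,
#'   `expression.counts.tsv`, `expression.fpkm.tsv`).
#' @param out_dir Where to write stage outputs and `report.json`; `NULL`
#'   keeps everything in memory.
#' @param mod_fc Differential-modification fold-change threshold.
#' @param mod_epsilon Pseudocount (TPM) for modification fold changes.
#' @param de_fc,de_fdr Differential-expression thresholds.
#' @param diurnal_fc,diurnal_fdr,diurnal_min_comparisons Diurnal-rhythm
#'   thresholds.
#' @param enrich_alpha Combination-enrichment significance level.
#' @param go_fdr Gene-set enrichment FDR cutoff.
#' @param de_method Test used by [diff_expression()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim = NULL, input_dir = NULL, out_dir = NULL,
                       mod_fc = 1.5, mod_epsilon = 1, de_fc = 4,
                       de_fdr = 0.05, diurnal_fc = 2, diurnal_fdr = 0.05,
                       diurnal_min_comparisons = 3, enrich_alpha = 0.01,
                       go_fdr = 0.05, de_method = "moderated") {
  if (is.null(sim) == is.null(input_dir)) {
    stop("provide exactly one of sim= (a sim_config) or input_dir=")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  stopifnot(mod_fc > 1, mod_epsilon > 0, de_fc > 1, de_fdr > 0,
            diurnal_fc > 1, diurnal_fdr > 0, diurnal_min_comparisons >= 1,
            enrich_alpha > 0, go_fdr > 0)
  cfg <- list(sim = sim, input_dir = input_dir, out_dir = out_dir,
              mod_fc = mod_fc, mod_epsilon = mod_epsilon, de_fc = de_fc,
              de_fdr = de_fdr, diurnal_fc = diurnal_fc,
              diurnal_fdr = diurnal_fdr,
              diurnal_min_comparisons = diurnal_min_comparisons,
              enrich_alpha = enrich_alpha, go_fdr = go_fdr,
              de_method = de_method)
  class(cfg) <- "run_config"
  cfg
}

.read_study_dir <- function(dir) {
  gff <- file.path(dir, "genes.gff3")
  if (!file.exists(gff)) stop("missing input file: ", gff)
  annotation <- read_gene_models(gff)
  counts_f <- file.path(dir, "expression.counts.tsv")
  fpkm_f <- file.path(dir, "expression.fpkm.tsv")
  for (f in c(counts_f, fpkm_f)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  read_mat <- function(f) {
    df <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  counts <- read_mat(counts_f)
  groups <- sub("_rep[0-9]+$", "", colnames(counts))
  samples <- data.frame(sample = colnames(counts), group = groups,
                        replicate = as.integer(sub(".*_rep", "",
                                                   colnames(counts))),
                        stringsAsFactors = FALSE)
  conditions <- intersect(c("control", "starvation", "submergence"),
                          unique(groups))
  # a condition is present only if its peak files were written
  conditions <- Filter(function(cond) {
    file.exists(file.path(dir, sprintf("peaks.%s.%s.rep1.bed",
                                       acyl_marks[1], cond)))
  }, conditions)
  if (!"control" %in% conditions) stop("missing control peak files in ", dir)
  chip <- lapply(stats::setNames(conditions, conditions), function(cond) {
    peaks <- list(); tracks <- list()
    for (m in acyl_marks) {
      peaks[[m]] <- list(); tracks[[m]] <- list()
      for (r in 1:2) {
        bed <- file.path(dir, sprintf("peaks.%s.%s.rep%d.bed", m, cond, r))
        if (!file.exists(bed)) stop("missing input file: ", bed)
        peaks[[m]][[r]] <- read_peaks(bed, sprintf("%s_%s_rep%d", m, cond, r),
                                      m, r)
        bg <- file.path(dir, sprintf("coverage.%s.%s.rep%d.bedgraph",
                                     m, cond, r))
        if (file.exists(bg)) {
          v <- utils::read.table(bg, sep = "\t", header = FALSE)
          tracks[[m]][[r]] <- read_coverage(
            bg, bin_width = min(v[[3]] - v[[2]]),
            total_mapped_tags = sum(v[[4]]),
            sample_id = sprintf("%s_%s_rep%d", m, cond, r),
            mark = m, replicate = r)
        }
      }
    }
    list(peaks = peaks, tracks = tracks)
  })
  list(annotation = annotation,
       truth = NULL,
       chip = chip,
       expression = list(counts = counts, fpkm = read_mat(fpkm_f),
                         samples = samples))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order on a synthetic study (or a
#' directory of inputs) and returns all stage outputs plus a
#' machine-readable report. With `out_dir` set, stage tables are written
#' as TSV and the report as `report.json`. Given identical configuration
#' the run is deterministic, and the report records the configuration
#' hash and seed.
#'
#' @param config A [run_config()].
#' @return List: `study`, `tpm` (per condition x mark: gene x rep
#'   matrices), `status`, `profile`, `marginals`, `diffmod`, `diffexpr`,
#'   `diurnal`, `proportions`, `prop_change`, `change_cor`, `enrichment`,
#'   `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- if (!is.null(config$sim)) simulate_study(config$sim)
           else .read_study_dir(config$input_dir)
  ann <- study$annotation
  expr <- study$expression
  conditions <- names(study$chip)
  treated <- setdiff(conditions, "control")

  # --- quantification: body TPM per condition x mark x replicate
  tpm <- lapply(study$chip, function(ch) {
    lapply(ch$tracks, function(reps) {
      if (length(reps) == 0 || is.null(reps[[1]])) return(NULL)
      tpm_matrix(reps, ann, region_mode = "body")
    })
  })

  # --- marked genes and combinations (control condition)
  pk <- study$chip[["control"]]$peaks
  status <- lapply(acyl_marks, function(m) {
    call_marked_genes(pk[[m]][[1]], pk[[m]][[2]], ann)
  })
  names(status) <- acyl_marks
  profile <- classify_combinations(status$H3K9ac, status$Kbu, status$Kcr)
  marginals <- marginal_counts(profile)

  # --- differential modification per treated condition x mark
  diffmod <- lapply(stats::setNames(treated, treated), function(cond) {
    lapply(stats::setNames(acyl_marks, acyl_marks), function(m) {
      if (is.null(tpm[["control"]][[m]]) || is.null(tpm[[cond]][[m]])) {
        return(NULL)
      }
      diff_modification(tpm[["control"]][[m]], tpm[[cond]][[m]],
                        epsilon = config$mod_epsilon,
                        fc_threshold = config$mod_fc)
    })
  })

  # --- differential expression and diurnal rhythm
  grp <- expr$samples$group
  diffexpr <- lapply(stats::setNames(treated, treated), function(cond) {
    diff_expression(expr$counts[, grp == "control", drop = FALSE],
                    expr$counts[, grp == cond, drop = FALSE],
                    fc_threshold = config$de_fc,
                    fdr_threshold = config$de_fdr,
                    method = config$de_method)
  })
  tp <- grep("^T[0-9]", unique(grp), value = TRUE)
  diurnal <- if (length(tp) == 4) {
    keep <- grp %in% tp
    diurnal_classification(expr$counts[, keep, drop = FALSE],
                           grp[keep], fc_threshold = config$diurnal_fc,
                           fdr_threshold = config$diurnal_fdr,
                           min_comparisons = config$diurnal_min_comparisons,
                           method = config$de_method)
  } else NULL

  # --- proportions and their changes in DEGs
  rep_mean <- function(cond, m) {
    x <- tpm[[cond]][[m]]
    if (is.null(x)) NULL else rowMeans(x)
  }
  proportions <- lapply(stats::setNames(conditions, conditions), function(cond) {
    k9 <- rep_mean(cond, "H3K9ac")
    if (is.null(k9)) return(NULL)
    acylation_proportions(k9, rep_mean(cond, "Kbu"), rep_mean(cond, "Kcr"))
  })
  prop_change <- lapply(stats::setNames(treated, treated), function(cond) {
    if (is.null(proportions[["control"]]) || is.null(proportions[[cond]])) {
      return(NULL)
    }
    proportion_change(proportions[["control"]], proportions[[cond]],
                      diffexpr[[cond]])
  })

  # --- mark-change vs expression-change correlation over DEGs
  change_cor <- lapply(stats::setNames(treated, treated), function(cond) {
    lapply(stats::setNames(acyl_marks, acyl_marks), function(m) {
      dm <- diffmod[[cond]][[m]]
      if (is.null(dm)) return(NULL)
      change_correlation(diffexpr[[cond]], dm)
    })
  })

  # --- enrichment of combinations in up-DEGs and diurnal genes
  enrichment <- list()
  for (cond in treated) {
    up <- diffexpr[[cond]]$gene_id[diffexpr[[cond]]$call == "up"]
    enrichment[[paste0("up_", cond)]] <-
      if (length(up)) combination_enrichment(profile, up,
                                             alpha = config$enrich_alpha)
      else NULL
  }
  if (!is.null(diurnal) && any(diurnal$diurnal)) {
    enrichment[["diurnal"]] <- combination_enrichment(
      profile, diurnal$gene_id[diurnal$diurnal],
      alpha = config$enrich_alpha)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("acylscape")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    config_hash = rlang::hash(config),
    n_genes = length(ann),
    category_counts = as.list(marginals$category_counts),
    mark_totals = as.list(marginals$totals),
    n_deg = lapply(diffexpr, function(d) as.list(table(d$call))),
    n_diffmod = lapply(diffmod, function(byc) {
      lapply(byc, function(d) if (is.null(d)) NULL else as.list(table(d$call)))
    }),
    n_diurnal = if (is.null(diurnal)) NA else sum(diurnal$diurnal),
    thresholds = config[c("mod_fc", "mod_epsilon", "de_fc", "de_fdr",
                          "diurnal_fc", "diurnal_fdr",
                          "diurnal_min_comparisons", "enrich_alpha",
                          "go_fdr")]
  )

  res <- list(study = study, tpm = tpm, status = status, profile = profile,
              marginals = marginals, diffmod = diffmod,
              diffexpr = diffexpr, diurnal = diurnal,
              proportions = proportions, prop_change = prop_change,
              change_cor = change_cor, enrichment = enrichment,
              report = report)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config)
  res
}

.write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  status_df <- data.frame(gene_id = names(res$status[[1]]),
                          H3K9ac = unname(res$status$H3K9ac),
                          Kbu = unname(res$status$Kbu),
                          Kcr = unname(res$status$Kcr))
  wtsv(status_df, "mark_status.tsv")
  wtsv(data.frame(gene_id = names(res$profile),
                  category = as.character(res$profile)),
       "combinations.tsv")
  for (cond in names(res$diffexpr)) {
    wtsv(res$diffexpr[[cond]], sprintf("diffexpr.%s.tsv", cond))
    for (m in acyl_marks) {
      dm <- res$diffmod[[cond]][[m]]
      if (!is.null(dm)) wtsv(dm, sprintf("diffmod.%s.%s.tsv", m, cond))
    }
    pc <- res$prop_change[[cond]]
    if (!is.null(pc)) {
      wtsv(pc$delta, sprintf("proportion_change.%s.tsv", cond))
      wtsv(pc$summary, sprintf("proportion_change_summary.%s.tsv", cond))
    }
  }
  if (!is.null(res$diurnal)) wtsv(res$diurnal, "diurnal.tsv")
  for (cond in names(res$proportions)) {
    pr <- res$proportions[[cond]]
    if (!is.null(pr)) wtsv(pr, sprintf("proportions.%s.tsv", cond))
  }
  for (nm in names(res$enrichment)) {
    if (!is.null(res$enrichment[[nm]]))
      wtsv(res$enrichment[[nm]], sprintf("enrichment.%s.tsv", nm))
  }
  jsonlite::write_json(res$report,
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
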