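# Interval substrate and format I/O.
#
# Internal convention: every interval lives in a GRanges (1-based, closed),
# the standard Bioconductor representation. BED and bedGraph (0-based,
# half-open) and GFF3 (1-based, closed) are converted at the file boundary,
# so downstream code never mixes conventions.

#' Read gene models from GFF3
#'
#' Parses `gene`-type records of a GFF3 file into an annotation object:
#' a `GRanges` with metadata columns `gene_id` and `feature_class`, and
#' chromosome lengths in `seqlengths()` (taken from `##sequence-region`
#' pragmas when present, otherwise the right-most gene end per chromosome).
#'
#' @param path GFF3 file. Records with type `gene` are used; others ignored.
#' @param te_keywords Character vector; a gene whose attribute string
#'   contains any keyword (case-insensitive, fixed match) is classed
#'   `te_related`, otherwise `coding`.
#' @param feature_type GFF3 `type` value(s) treated as genes.
#' @return `GRanges` annotation; zero-length for an empty file.
#' @seealso [write_gene_models()], [upstream_region()]
#' @export
read_gene_models <- function(path, te_keywords = c("transposon", "retrotransposon"),
                             feature_type = "gene") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  pragma <- grep("^##sequence-region", lines, value = TRUE)
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    S4Vectors::mcols(gr)$feature_class <- character(0)
    return(gr)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- body_idx[which(nf != 9L)[1L]]
    stop("malformed GFF3 record at line ", bad, ": expected 9 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3L] %in% feature_type
  m <- m[keep, , drop = FALSE]
  kept_lines <- body_idx[keep]
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- kept_lines[which(is.na(start) | is.na(end))[1L]]
    stop("non-numeric coordinate in GFF3 at line ", bad)
  }
  if (any(start > end) || any(start < 1L)) {
    bad <- kept_lines[which(start > end | start < 1L)[1L]]
    stop("invalid coordinates in GFF3 at line ", bad)
  }
  attrs <- m[, 9L]
  gene_id <- sub(".*ID=([^;]+).*", "\\1", attrs)
  no_id <- !grepl("(^|;)\\s*ID=", attrs)
  if (any(no_id)) {
    stop("GFF3 gene record without ID attribute at line ", kept_lines[which(no_id)[1L]])
  }
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in GFF3: ", gene_id[which(duplicated(gene_id))[1L]])
  }
  strand <- m[, 7L]
  if (any(!strand %in% c("+", "-"))) {
    stop("gene with undefined strand at line ",
         kept_lines[which(!strand %in% c("+", "-"))[1L]])
  }
  te <- rep(FALSE, nrow(m))
  for (kw in te_keywords) {
    te <- te | grepl(kw, attrs, ignore.case = TRUE, fixed = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    gene_id = gene_id,
    feature_class = ifelse(te, "te_related", "coding")
  )
  sizes <- .pragma_sizes(pragma)
  gr <- .apply_chrom_sizes(gr, sizes)
  names(gr) <- gr$gene_id
  gr
}

.pragma_sizes <- function(pragma) {
  if (length(pragma) == 0L) return(NULL)
  parts <- strsplit(trimws(pragma), "\\s+")
  stats::setNames(
    vapply(parts, function(p) as.numeric(p[4L]), numeric(1)),
    vapply(parts, function(p) p[2L], character(1))
  )
}

.apply_chrom_sizes <- function(gr, sizes = NULL) {
  lev <- unique(c(as.character(GenomeInfoDb::seqlevels(gr)), names(sizes)))
  if (length(lev) == 0L) return(gr)
  observed <- vapply(lev, function(ch) {
    w <- as.character(GenomicRanges::seqnames(gr)) == ch
    if (any(w)) max(GenomicRanges::end(gr)[w]) else 0
  }, numeric(1))
  len <- observed
  if (!is.null(sizes)) len[names(sizes)] <- pmax(sizes, observed[names(sizes)])
  GenomeInfoDb::seqlevels(gr) <- lev
  GenomeInfoDb::seqlengths(gr) <- len
  if (any(GenomicRanges::end(gr) > GenomeInfoDb::seqlengths(gr)[
        as.character(GenomicRanges::seqnames(gr))])) {
    stop("gene interval extends beyond declared chromosome length")
  }
  gr
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]; emits `##sequence-region` pragmas from
#' `seqlengths()` and one `gene` record per range. Round-trips coordinates
#' exactly.
#' @param annotation `GRanges` from [read_gene_models()] or
#'   [generate_annotation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  sl <- GenomeInfoDb::seqlengths(annotation)
  for (ch in names(sl)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch, sl[[ch]]), con)
  }
  if (length(annotation)) {
    note <- ifelse(annotation$feature_class == "te_related",
                   ";Note=transposon", "")
    writeLines(sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       as.character(GenomicRanges::seqnames(annotation)),
                       GenomicRanges::start(annotation),
                       GenomicRanges::end(annotation),
                       as.character(GenomicRanges::strand(annotation)),
                       annotation$gene_id, note), con)
  }
  invisible(path)
}

#' Read a peak set from BED
#'
#' Reads BED3+ (0-based, half-open), converts to `GRanges`, merges
#' overlapping and bookended intervals, and sorts. The sample identity is
#' stored in `metadata()`.
#'
#' @param path BED file (3 or more columns; extra columns ignored).
#' @param sample_id,mark,replicate Sample identity; `mark` must be one of
#'   [acyl_marks], `replicate` an integer >= 1.
#' @return `GRanges` peak set (strand `*`) with
#'   `metadata()$sample_id/mark/replicate`.
#' @export
read_peaks <- function(path, sample_id, mark, replicate) {
  mark <- match.arg(mark, acyl_marks)
  stopifnot(file.exists(path), replicate >= 1)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & !startsWith(lines, "track") &
                  nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    if (any(lengths(fields) < 3L)) {
      stop("BED record with fewer than 3 fields at line ",
           keep[which(lengths(fields) < 3L)[1L]])
    }
    chrom <- vapply(fields, `[`, character(1), 1L)
    s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    if (anyNA(s0) || anyNA(e0)) {
      stop("non-numeric coordinate in BED at line ",
           keep[which(is.na(s0) | is.na(e0))[1L]])
    }
    if (any(s0 >= e0) || any(s0 < 0)) {
      stop("invalid BED interval (start >= end or start < 0) at line ",
           keep[which(s0 >= e0 | s0 < 0)[1L]])
    }
    # BED 0-based half-open [s0, e0) -> GRanges 1-based closed [s0+1, e0]
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0))
    gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  }
  S4Vectors::metadata(gr) <- list(sample_id = sample_id, mark = mark,
                                  replicate = as.integer(replicate))
  gr
}

#' Write a peak set to BED3
#'
#' @param peaks `GRanges` peak set.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read binned coverage from bedGraph
#'
#' Reads a bedGraph (0-based half-open records carrying a tag-count value)
#' and apportions each record's value into fixed-width bins proportionally
#' to overlap length, producing a [coverage_track()]. Bin counts may be
#' fractional; bins never touched by a record are absent (zero downstream).
#'
#' @param path bedGraph file.
#' @param bin_width Bin width in bases.
#' @param total_mapped_tags Library size N for TPM scaling (> 0).
#' @param sample_id,mark,replicate Sample identity.
#' @return A `coverage_track` object.
#' @export
read_coverage <- function(path, bin_width, total_mapped_tags,
                          sample_id = basename(path), mark = "H3K9ac",
                          replicate = 1L) {
  stopifnot(file.exists(path), bin_width > 0)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & !startsWith(lines, "track") &
                  nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(coverage_track(data.table::data.table(chrom = character(0),
                                                 bin = integer(0),
                                                 count = numeric(0)),
                          bin_width, total_mapped_tags, sample_id, mark,
                          replicate))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) {
    stop("bedGraph record with fewer than 4 fields at line ",
         keep[which(lengths(fields) < 4L)[1L]])
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  if (anyNA(s0) || anyNA(e0) || anyNA(val)) {
    stop("non-numeric field in bedGraph at line ",
         keep[which(is.na(s0) | is.na(e0) | is.na(val))[1L]])
  }
  if (any(val < 0)) {
    stop("negative value in bedGraph at line ", keep[which(val < 0)[1L]])
  }
  if (any(s0 >= e0) || any(s0 < 0)) {
    stop("invalid bedGraph interval at line ", keep[which(s0 >= e0 | s0 < 0)[1L]])
  }
  pieces <- .apportion_to_bins(chrom, s0, e0, val, bin_width)
  coverage_track(pieces, bin_width, total_mapped_tags, sample_id, mark,
                 replicate)
}

# Split records on 0-based coordinates into fixed bins; value spread
# uniformly per base. Returns data.table(chrom, bin, count).
.apportion_to_bins <- function(chrom, s0, e0, val, bin_width) {
  first_bin <- floor(s0 / bin_width)
  last_bin <- ceiling(e0 / bin_width) - 1
  n_bins <- last_bin - first_bin + 1
  idx <- rep.int(seq_along(chrom), n_bins)
  bin <- unlist(lapply(seq_along(chrom),
                       function(i) seq.int(first_bin[i], last_bin[i])),
                use.names = FALSE)
  bs <- bin * bin_width
  be <- bs + bin_width
  ov <- pmin(be, e0[idx]) - pmax(bs, s0[idx])
  dens <- val[idx] / (e0[idx] - s0[idx])
  dt <- data.table::data.table(chrom = chrom[idx], bin = as.integer(bin),
                               count = dens * ov)
  dt <- dt[, list(count = sum(count)), by = c("chrom", "bin")]
  data.table::setkey(dt, chrom, bin)
  dt[]
}

#' Construct a coverage track
#'
#' A coverage track holds fixed-width-binned tag counts for one
#' mark/replicate sample plus the library size used for TPM scaling.
#' Bins are indexed from 0 in 0-based genomic coordinates: bin `i` covers
#' bases `[i * bin_width, (i + 1) * bin_width)`.
#'
#' @param values `data.table`/data.frame with columns `chrom`, `bin`
#'   (integer, 0-based index), `count` (>= 0; fractional allowed).
#' @param bin_width Bin width in bases.
#' @param total_mapped_tags Library size N (> 0).
#' @param sample_id,mark,replicate Sample identity.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_width, total_mapped_tags,
                           sample_id = "sample", mark = "H3K9ac",
                           replicate = 1L) {
  values <- data.table::as.data.table(values)
  stopifnot(all(c("chrom", "bin", "count") %in% names(values)),
            bin_width > 0, total_mapped_tags > 0,
            all(values$count >= 0))
  mark <- match.arg(mark, acyl_marks)
  data.table::setkey(values, chrom, bin)
  structure(list(values = values, bin_width = bin_width,
                 total_mapped_tags = total_mapped_tags,
                 sample_id = sample_id, mark = mark,
                 replicate = as.integer(replicate)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s (%s, rep %d)\n  %d non-zero %d-bp bins, %.0f mapped tags\n",
              x$sample_id, x$mark, x$replicate, nrow(x$values), x$bin_width,
              x$total_mapped_tags))
  invisible(x)
}

#' Write a coverage track to bedGraph
#'
#' One record per non-zero bin (0-based half-open coordinates).
#' @param track `coverage_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  v <- track$values
  df <- data.frame(chrom = v$chrom, start = v$bin * track$bin_width,
                   end = (v$bin + 1) * track$bin_width, value = v$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware upstream region of a gene
#'
#' The `width`-base window 5' of the TSS: upstream of `start` for `+`
#' genes, downstream of `end` for `-` genes, clipped to the chromosome.
#' May be empty at a chromosome edge.
#'
#' @param genes `GRanges` with defined strand and `seqlengths`.
#' @param width Window width in bases (> 0).
#' @return `GRanges` parallel to `genes` (zero-width ranges where fully
#'   clipped).
#' @export
upstream_region <- function(genes, width = 2000) {
  stopifnot(width > 0)
  # flank may step over the chromosome edge; trim immediately
  up <- suppressWarnings(GenomicRanges::flank(genes, width = width,
                                              start = TRUE))
  GenomicRanges::trim(up)
}

#' Gene body plus strand-aware upstream window
#'
#' The union of the gene body and its 2-kb (by default) upstream region --
#' the region in which a modification peak makes a gene "marked".
#' @param genes `GRanges` annotation.
#' @param upstream Window width in bases.
#' @return `GRanges` parallel to `genes`.
#' @export
gene_with_upstream <- function(genes, upstream = 2000) {
  ext <- suppressWarnings(GenomicRanges::resize(
    genes, width = GenomicRanges::width(genes) + upstream, fix = "end"))
  GenomicRanges::trim(ext)
}

#' Interval overlap (half-open semantics)
#'
#' Two intervals overlap iff they share a chromosome and at least one base.
#' Bookended intervals (one ends where the other starts, in 0-based
#' half-open terms) do not overlap.
#' @param a,b `GRanges`.
#' @return Logical vector, recycled elementwise.
#' @export
interval_overlaps <- function(a, b) {
  # disjoint chromosome sets are a legitimate "no overlap", not a problem
  suppressWarnings(IRanges::overlapsAny(a, b, minoverlap = 1L))
}
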