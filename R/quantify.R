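#' Exon-level read counts for one sample
#'
#' @param sample_id sample identifier.
#' @param counts non-negative integer vector, one entry per exon ordinal.
#' @param total_mapped_reads library size (primary mapped reads); used only
#'   for RPKM. Defaults to `sum(counts)`.
#' @return an object of class `exon_counts`.
#' @export
exon_counts <- function(sample_id, counts, total_mapped_reads = sum(counts)) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be raw integer reads, not normalized values")
  if (total_mapped_reads < 0) stop("total_mapped_reads must be >= 0")
  structure(list(sample_id = sample_id, counts = counts,
                 total_mapped_reads = as.numeric(total_mapped_reads)),
            class = "exon_counts")
}

#' @export
print.exon_counts <- function(x, ...) {
  cat("exon_counts:", x$sample_id, "-", length(x$counts), "exons,",
      sum(x$counts), "reads in gene,", x$total_mapped_reads, "in library\n")
  invisible(x)
}

#' Count reads per exon from a SAM/BAM alignment file
#'
#' Counts primary mapped alignments only (secondary, supplementary and
#' unmapped records are ignored). A read overlapping a single exon
#' increments that exon; a read overlapping several exons increments the
#' exon of maximal overlap, ties resolved to the lower ordinal. Reads with
#' no exon overlap are ignored. `total_mapped_reads` is the number of
#' primary mapped reads in the whole file.
#'
#' @param alignment_path path to a SAM or BAM file (SAM is converted on the
#'   fly).
#' @param model a [gene_model()].
#' @param sample_id identifier for the returned counts; defaults to the file
#'   basename.
#' @return an [exon_counts()] object.
#' @export
count_exon_reads <- function(alignment_path, model,
                             sample_id = sub("\\.(sam|bam)$", "",
                                             basename(alignment_path),
                                             ignore.case = TRUE)) {
  if (!file.exists(alignment_path))
    stop("alignment file not found: ", alignment_path)
  bam <- alignment_path
  if (grepl("\\.sam$", alignment_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment_path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = TRUE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  reads <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  total <- length(reads)
  seqs <- GenomeInfoDb::seqlevels(reads)
  if (!model$chrom %in% seqs)
    stop("chromosome mismatch: model is on '", model$chrom,
         "' but alignment header has {", paste(seqs, collapse = ", "), "}")
  ex <- model$exons
  exon_gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1, end = ex$end))
  read_gr <- GenomicRanges::granges(reads)
  hits <- GenomicRanges::findOverlaps(read_gr, exon_gr)
  n <- nrow(ex)
  counts <- numeric(n)
  if (length(hits) > 0) {
    ov <- IRanges::pintersect(read_gr[S4Vectors::queryHits(hits)],
                              exon_gr[S4Vectors::subjectHits(hits)])
    w <- BiocGenerics::width(ov)
    h <- data.frame(read = S4Vectors::queryHits(hits),
                    exon = S4Vectors::subjectHits(hits), w = w)
    # maximal overlap per read; ties to the lower exon ordinal
    h <- h[order(h$read, -h$w, h$exon), ]
    h <- h[!duplicated(h$read), ]
    tab <- table(factor(h$exon, levels = seq_len(n)))
    counts <- as.numeric(tab)
  }
  exon_counts(sample_id = sample_id, counts = counts,
              total_mapped_reads = total)
}

#' Closed-form two-isoform deconvolution of exon counts
#'
#' Estimates the abundance ratio `R` of an alternate-start variant
#' transcript (sharing exons `k..n`) to the full-length transcript, under
#' the assumption that per-nucleotide read coverage is uniform along each
#' isoform and that these are the only two isoforms present.
#'
#' With `r0` the summed raw counts over the exclusive 5' exons `1..k-1` and
#' `r1` the summed counts over the shared exons `k..n`:
#' \deqn{F_0 = r_0 L_0 / (L_0 - L_1)}
#' \deqn{F_1 = r_1 - F_0 L_1 / L_0}
#' \deqn{R = (F_1/L_1) / (F_0/L_0)}
#' where `F0` and `F1` are the read counts assignable to the full-length
#' and variant transcripts.
#'
#' Edge policies: a negative raw `F1` (sampling noise) is clipped to 0 for
#' `R` and flagged `F1_CLIPPED_NEGATIVE` (the raw value is retained);
#' `r0 = 0` with `r1 > 0` (pure variant signal) yields `R = Inf` with flag
#' `R_UNDEFINED_ZERO_F0`; fewer than `low_count_threshold` total reads sets
#' `LOW_COUNTS` (all-zero counts give `R = 0`). `log2R = log2(R + epsilon)`.
#'
#' @param counts an [exon_counts()] object.
#' @param model a [gene_model()].
#' @param epsilon pseudocount added to `R` before log2 (default `1e-6`).
#' @param low_count_threshold minimum gene-level read total below which the
#'   estimate is flagged `LOW_COUNTS` (default 10).
#' @return an object of class `ratio_estimate`: list with `sample_id`,
#'   `r0`, `r1`, `F0`, `F1_raw`, `F1`, `R`, `log2R`, `flags` (character
#'   vector, possibly empty).
#' @examples
#' m <- gene_model("g", "c", starts = (0:14) * 100, ends = (1:15) * 100,
#'                 strand = "+", variant_start_exon = 10)
#' cnt <- exon_counts("s", c(rep(100, 9), rep(300, 6)))
#' estimate_isoform_ratio(cnt, m)$R  # 2
#' @export
estimate_isoform_ratio <- function(counts, model, epsilon = 1e-6,
                                   low_count_threshold = 10) {
  stopifnot(inherits(counts, "exon_counts"), inherits(model, "gene_model"))
  n <- nrow(model$exons)
  if (length(counts$counts) != n)
    stop("counts has ", length(counts$counts), " exons but model has ", n)
  if (epsilon <= 0) stop("epsilon must be positive")
  k <- model$variant_start_exon
  L0 <- model$L0; L1 <- model$L1
  r0 <- sum(counts$counts[seq_len(k - 1)])
  r1 <- sum(counts$counts[k:n])
  flags <- character(0)
  if (r0 + r1 < low_count_threshold) flags <- c(flags, "LOW_COUNTS")
  if (r0 == 0 && r1 == 0) {
    F0 <- 0; F1_raw <- 0; F1 <- 0; R <- 0
  } else if (r0 == 0) {
    # no exclusive 5' signal: full-length abundance estimate is zero and
    # the ratio is unbounded above
    F0 <- 0; F1_raw <- r1; F1 <- r1; R <- Inf
    flags <- c(flags, "R_UNDEFINED_ZERO_F0")
  } else {
    F0 <- r0 * L0 / (L0 - L1)
    F1_raw <- r1 - F0 * L1 / L0
    F1 <- F1_raw
    if (F1_raw < 0) {
      F1 <- 0
      flags <- c(flags, "F1_CLIPPED_NEGATIVE")
    }
    R <- (F1 / L1) / (F0 / L0)
  }
  structure(list(sample_id = counts$sample_id, r0 = r0, r1 = r1,
                 F0 = F0, F1_raw = F1_raw, F1 = F1, R = R,
                 log2R = log2(R + epsilon), flags = flags),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("ratio_estimate: %s  R = %.4g (log2R = %.3f)\n",
              x$sample_id, x$R, x$log2R))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Estimate isoform ratios for every sample of a long count table
#'
#' @param count_table data.frame with columns `sample_id`, `exon_index`,
#'   `count` and optionally `total_mapped_reads` (constant per sample),
#'   e.g. from [read_exon_counts()] or [simulate_cohort()].
#' @inheritParams estimate_isoform_ratio
#' @return data.frame with one row per sample: `sample_id`, `r0`, `r1`,
#'   `F0`, `F1_raw`, `F1`, `R`, `log2R`, `flags` (semicolon-joined).
#' @export
estimate_isoform_ratios <- function(count_table, model, epsilon = 1e-6,
                                    low_count_threshold = 10) {
  req <- c("sample_id", "exon_index", "count")
  if (!all(req %in% names(count_table)))
    stop("count table must have columns: ", paste(req, collapse = ", "))
  out <- lapply(split(count_table, count_table$sample_id), function(d) {
    d <- d[order(d$exon_index), ]
    tot <- if ("total_mapped_reads" %in% names(d))
      d$total_mapped_reads[1] else sum(d$count)
    est <- estimate_isoform_ratio(
      exon_counts(d$sample_id[1], d$count, tot), model,
      epsilon = epsilon, low_count_threshold = low_count_threshold)
    data.frame(sample_id = est$sample_id, r0 = est$r0, r1 = est$r1,
               F0 = est$F0, F1_raw = est$F1_raw, F1 = est$F1,
               R = est$R, log2R = est$log2R,
               flags = paste(est$flags, collapse = ";"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-exon RPKM and log2 RPKM profile
#'
#' `rpkm_i = count_i * 1e9 / (length_i * total_mapped_reads)`;
#' `log2_rpkm_i = log2(rpkm_i + 1)`.
#'
#' @inheritParams estimate_isoform_ratio
#' @return an object of class `exon_expression`: list with `sample_id`,
#'   `rpkm`, `log2_rpkm` (vectors per exon).
#' @export
compute_exon_rpkm <- function(counts, model) {
  stopifnot(inherits(counts, "exon_counts"), inherits(model, "gene_model"))
  if (length(counts$counts) != nrow(model$exons))
    stop("counts length does not match model")
  if (counts$total_mapped_reads <= 0)
    stop("total_mapped_reads must be positive for RPKM")
  rpkm <- counts$counts * 1e9 /
    (exon_lengths(model) * counts$total_mapped_reads)
  structure(list(sample_id = counts$sample_id, rpkm = rpkm,
                 log2_rpkm = log2(rpkm + 1)),
            class = "exon_expression")
}

#' Call variant positivity from a ratio estimate
#'
#' A sequencing surrogate for the study's PCR-band positivity call: a
#' sample is positive when `R >= threshold`. A pure-variant sample
#' (flagged `R_UNDEFINED_ZERO_F0`, sentinel-infinite `R`) is positive.
#'
#' @param estimate a `ratio_estimate` (or a numeric `R` value).
#' @param threshold non-negative ratio threshold (default 0.1).
#' @return `"positive"` or `"negative"`.
#' @export
call_positivity <- function(estimate, threshold = 0.1) {
  if (threshold < 0) stop("threshold must be non-negative")
  R <- if (inherits(estimate, "ratio_estimate")) estimate$R else
    as.numeric(estimate)
  ifelse(is.infinite(R) | R >= threshold, "positive", "negative")
}

#' Read / write a long exon-count table as TSV
#'
#' Columns `sample_id`, `exon_index`, `count` (header required); an
#' optional `total_mapped_reads` column carries the library size.
#'
#' @param path TSV path.
#' @return `read_exon_counts()` returns the data.frame;
#'   `write_exon_counts()` returns `path` invisibly.
#' @export
read_exon_counts <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "exon_index", "count")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("count table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(d$count) | d$count < 0 | d$count != round(d$count))
  if (length(bad))  # +1 for the header row: report the file line
    stop("count table ", path,
         ": non-integer or negative count at line ", bad[1] + 1)
  d
}

#' @param counts_df data.frame as returned by [read_exon_counts()].
#' @rdname read_exon_counts
#' @export
write_exon_counts <- function(counts_df, path) {
  utils::write.table(counts_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ratio-estimate table as TSV
#'
#' Columns: `sample_id`, `F0`, `F1_raw`, `F1`, `R`, `log2R`, `flags`
#' (semicolon list).
#'
#' @param estimates data.frame from [estimate_isoform_ratios()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(estimates, path) {
  cols <- c("sample_id", "F0", "F1_raw", "F1", "R", "log2R", "flags")
  utils::write.table(estimates[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
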