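#' Construct a gene model from exon intervals
#'
#' A gene model holds the ordered exon structure of one gene together with
#' the ordinal `k` of the first exon shared with the alternate-start variant
#' transcript, and the two length constants the deconvolution estimator
#' needs: `L0`, the summed length of all exons, and `L1`, the summed length
#' of exons `k..n` (the exons shared by both isoforms).
#'
#' Coordinates are 0-based half-open internally; exon ordinals follow
#' transcription order, so on the minus strand exon 1 is the genomically
#' last exon.
#'
#' @param gene_id gene identifier.
#' @param chrom sequence (chromosome) name; all exons must share it.
#' @param starts,ends integer vectors of 0-based half-open exon coordinates,
#'   given in transcription order (element `i` is exon `i`).
#' @param strand `"+"` or `"-"`.
#' @param variant_start_exon integer `k`, the exon ordinal at which the
#'   variant transcript begins; must satisfy `1 < k <= n`.
#' @param intronic_extension optional length (bp) of the variant's intronic
#'   5' extension, recorded for documentation only; it is never added to
#'   `L1`, which counts shared exon sequence only.
#' @return an object of class `gene_model`: a list with `gene_id`, `chrom`,
#'   `strand`, `exons` (data.frame with `index`, `start`, `end`, `length`),
#'   `variant_start_exon`, `L0`, `L1`, `intronic_extension`.
#' @examples
#' m <- gene_model("g", "chr1", starts = c(0, 200), ends = c(100, 250),
#'                 strand = "+", variant_start_exon = 2)
#' m$L0  # 150
#' m$L1  # 50
#' @export
gene_model <- function(gene_id, chrom, starts, ends, strand = "+",
                       variant_start_exon, intronic_extension = NA_real_) {
  n <- length(starts)
  stopifnot(length(ends) == n)
  if (n < 2L)
    stop("gene model needs at least 2 exons, got ", n)
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  if (length(unique(chrom)) != 1L)
    stop("all exons must be on one chromosome")
  starts <- as.numeric(starts); ends <- as.numeric(ends)
  if (any(ends <= starts))
    stop("every exon must satisfy end > start (0-based half-open)")
  k <- as.integer(variant_start_exon)
  if (is.na(k) || k <= 1L || k > n)
    stop("variant_start_exon must satisfy 1 < k <= n (n = ", n, "), got ",
         variant_start_exon)
  exons <- data.frame(index = seq_len(n), start = starts, end = ends,
                      length = ends - starts)
  # overlap check in genomic order, independent of transcription order
  g <- exons[order(exons$start), ]
  if (any(g$start[-1] < g$end[-nrow(g)]))
    stop("exons overlap after sorting; not a valid single-transcript model")
  # transcription order must be monotone along the strand
  mono <- if (strand == "+") all(diff(exons$start) > 0) else
    all(diff(exons$start) < 0)
  if (!mono)
    stop("exon ordinals are not in transcription order for strand ", strand)
  L0 <- sum(exons$length)
  L1 <- sum(exons$length[exons$index >= k])
  model <- structure(list(gene_id = gene_id, chrom = chrom[1], strand = strand,
                          exons = exons, variant_start_exon = k,
                          L0 = L0, L1 = L1,
                          intronic_extension = intronic_extension),
                     class = "gene_model")
  validate_gene_model(model)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$gene_id, sprintf("(%s, %s strand)\n", x$chrom, x$strand))
  cat(sprintf("  %d exons, variant starts at exon %d\n",
              nrow(x$exons), x$variant_start_exon))
  cat(sprintf("  L0 = %g bp, L1 = %g bp\n", x$L0, x$L1))
  invisible(x)
}

validate_gene_model <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  stopifnot(inherits(model, "gene_model"))
  if (!identical(ex$index, seq_len(n)))
    stop("exon indices must be consecutive 1..n without duplicates")
  if (any(ex$length <= 0)) stop("exon lengths must be positive")
  if (!isTRUE(all.equal(model$L0, sum(ex$length))))
    stop("L0 must equal the summed exon lengths")
  if (model$L1 >= model$L0)
    stop("L1 must be strictly smaller than L0 (k > 1 guarantees this)")
  if (model$L1 <= 0) stop("L1 must be positive")
  model
}

#' Exon lengths of a gene model
#'
#' @param model a [gene_model()].
#' @return numeric vector of exon lengths (bp) in transcription order;
#'   sums to `model$L0`.
#' @export
exon_lengths <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  model$exons$length
}

#' Load a gene model from a GTF or BED annotation file
#'
#' Reads the exon structure of one gene from a GTF file (Ensembl dialect:
#' `exon` features carrying `gene_id` and, if available, `exon_number`
#' attributes; 1-based inclusive coordinates) or a BED6 file whose `name`
#' column is the exon ordinal (0-based half-open coordinates). GTF starts
#' are shifted by -1 on read so that one half-open convention holds
#' internally.
#'
#' Exon ordinals follow transcription order: when the annotation supplies
#' no `exon_number`, exons are ranked by genomic start on the plus strand
#' and by decreasing start on the minus strand.
#'
#' @param annotation_path path to a `.gtf`/`.gff` or `.bed` file.
#' @param gene_id gene identifier to extract.
#' @param variant_start_exon ordinal of the variant's first shared exon.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @param intronic_extension see [gene_model()].
#' @return a [gene_model()].
#' @export
load_gene_model <- function(annotation_path, gene_id, variant_start_exon,
                            format = c("auto", "gtf", "bed"),
                            intronic_extension = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(annotation_path))
    format <- switch(ext, gtf = "gtf", gff = "gtf", gff3 = "gtf",
                     bed = "bed",
                     stop("cannot infer annotation format from extension '",
                          ext, "'; pass format="))
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(annotation_path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    gr <- gr[!is.na(gr$gene_id) & gr$gene_id == gene_id]
    if (length(gr) == 0L) stop("gene not found: ", gene_id)
    strand <- as.character(BiocGenerics::strand(gr))[1]
    if (strand == "*") strand <- "+"
    ord <- if (!is.null(gr$exon_number) && !anyNA(gr$exon_number)) {
      order(as.integer(as.character(gr$exon_number)))
    } else if (strand == "+") {
      order(BiocGenerics::start(gr))
    } else {
      order(BiocGenerics::start(gr), decreasing = TRUE)
    }
    gr <- gr[ord]
    starts <- BiocGenerics::start(gr) - 1L  # GTF 1-based -> half-open
    ends <- BiocGenerics::end(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
  } else {
    gr <- rtracklayer::import(annotation_path, format = "bed")
    if (is.null(gr$name) || anyNA(suppressWarnings(as.integer(gr$name))))
      stop("BED reader expects exon ordinals in the name column")
    gr <- gr[order(as.integer(gr$name))]
    strand <- as.character(BiocGenerics::strand(gr))[1]
    if (strand == "*") strand <- "+"
    starts <- BiocGenerics::start(gr) - 1L  # rtracklayer re-bases BED to 1
    ends <- BiocGenerics::end(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
  }
  gene_model(gene_id = gene_id, chrom = chrom, starts = starts, ends = ends,
             strand = strand, variant_start_exon = variant_start_exon,
             intronic_extension = intronic_extension)
}

#' Write a gene model's exons as BED6
#'
#' The `name` column carries the exon ordinal, so the file round-trips
#' through [load_gene_model()].
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_bed <- function(model, path) {
  ex <- model$exons
  bed <- data.frame(chrom = model$chrom,
                    start = format(ex$start, scientific = FALSE, trim = TRUE),
                    end = format(ex$end, scientific = FALSE, trim = TRUE),
                    name = ex$index, score = 0L, strand = model$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene model's exons as GTF
#'
#' Emits Ensembl-dialect `exon` records (1-based inclusive) with `gene_id`
#' and `exon_number` attributes.
#'
#' @inheritParams write_gene_model_bed
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(model, path) {
  ex <- model$exons
  attrs <- sprintf('gene_id "%s"; exon_number "%d";', model$gene_id, ex$index)
  lines <- paste(model$chrom, "isoratio", "exon",
                 format(ex$start + 1, scientific = FALSE, trim = TRUE),
                 format(ex$end, scientific = FALSE, trim = TRUE),
                 ".", model$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a gene model as JSON
#'
#' @inheritParams write_gene_model_bed
#' @return `write_gene_model()` returns `path` invisibly;
#'   `read_gene_model()` returns the restored [gene_model()].
#' @export
write_gene_model <- function(model, path) {
  payload <- list(gene_id = model$gene_id, chrom = model$chrom,
                  strand = model$strand,
                  start = model$exons$start, end = model$exons$end,
                  variant_start_exon = model$variant_start_exon,
                  intronic_extension = model$intronic_extension)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_model(gene_id = p$gene_id, chrom = p$chrom,
             starts = p$start, ends = p$end, strand = p$strand,
             variant_start_exon = p$variant_start_exon,
             intronic_extension = if (is.null(p$intronic_extension))
               NA_real_ else suppressWarnings(
                 as.numeric(p$intronic_extension)))
}
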