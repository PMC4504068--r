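#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the pipeline targets: a 15-exon gene
#' whose variant transcript comprises the last 6 exons (variant start at
#' exon 10), uniform per-nucleotide coverage per isoform with Poisson count
#' noise, 87 tumor/normal pairs, a variant ratio that is near zero in
#' normal tissue and elevated in tumors (most strongly in ER+ tumors, then
#' ER-/Her2+, then ER-/Her2-), and exponential relapse-free survival whose
#' hazard depends on variant positivity.
#'
#' @param n_exons number of exons (default 15).
#' @param variant_start_exon ordinal of the variant's first shared exon
#'   (default 10).
#' @param exon_length exon length(s) in bp; a scalar is recycled
#'   (default 100).
#' @param noise `"poisson"`, `"none"` (rounded expectations), or `"nb"`.
#' @param nb_size negative-binomial size parameter for `noise = "nb"`.
#' @param seed integer; fully determines all generator output.
#' @param n_pairs number of tumor/normal pairs (default 87).
#' @param coverage_meanlog,coverage_sdlog lognormal parameters of the
#'   full-length per-nucleotide coverage `a` (reads/bp; default meanlog
#'   log 50).
#' @param normal_rho_meanlog,normal_rho_sdlog lognormal parameters of the
#'   true variant/full-length ratio in normal tissue (default meanlog
#'   log 0.01: the variant is essentially absent from normal breast).
#' @param tumor_rho_meanlog named vector of lognormal meanlogs of the
#'   tumor ratio per receptor subgroup (`er_pos`, `er_neg_her2_pos`,
#'   `er_neg_her2_neg`).
#' @param tumor_rho_sdlog lognormal sdlog of the tumor ratio.
#' @param er_pos_prev,her2_pos_prev marginal prevalences of ER+ and Her2+.
#' @param pr_pos_given_er_pos,pr_pos_given_er_neg conditional PR+
#'   prevalences.
#' @param grade_probs probabilities of grades 1/2/3 (sum to 1).
#' @param tp53_mut_given_er_pos,tp53_mut_given_er_neg conditional TP53
#'   mutation prevalences.
#' @param positivity_threshold true-ratio threshold defining a truly
#'   variant-positive tumor (the generator's stand-in for a PCR call).
#' @param baseline_hazard relapse hazard per month for variant-negative
#'   tumors (default log(2)/120: 120-month median).
#' @param hazard_ratio relapse hazard ratio, positive vs negative
#'   (default 0.5: positivity is protective).
#' @param censor_hazard independent censoring hazard per month.
#' @param followup_cap administrative censoring time (months).
#' @param lib_size total mapped reads per library (for RPKM only).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 15, variant_start_exon = 10,
                       exon_length = 100,
                       noise = c("poisson", "none", "nb"), nb_size = 10,
                       seed = 1,
                       n_pairs = 87,
                       coverage_meanlog = log(50), coverage_sdlog = 0.3,
                       normal_rho_meanlog = log(0.005),
                       normal_rho_sdlog = 0.5,
                       tumor_rho_meanlog = c(er_pos = log(0.25),
                                             er_neg_her2_pos = log(0.12),
                                             er_neg_her2_neg = log(0.05)),
                       tumor_rho_sdlog = 1.0,
                       er_pos_prev = 0.6, her2_pos_prev = 0.15,
                       pr_pos_given_er_pos = 0.8,
                       pr_pos_given_er_neg = 0.2,
                       grade_probs = c(0.15, 0.45, 0.40),
                       tp53_mut_given_er_pos = 0.2,
                       tp53_mut_given_er_neg = 0.5,
                       positivity_threshold = 0.1,
                       baseline_hazard = log(2) / 120, hazard_ratio = 0.5,
                       censor_hazard = log(2) / 180, followup_cap = 240,
                       lib_size = 2e7) {
  noise <- match.arg(noise)
  exon_length <- rep_len(exon_length, n_exons)
  stopifnot(n_exons >= 2, variant_start_exon > 1,
            variant_start_exon <= n_exons, all(exon_length > 0),
            n_pairs >= 1, lib_size > 0)
  probs <- c(er_pos_prev, her2_pos_prev, pr_pos_given_er_pos,
             pr_pos_given_er_neg, tp53_mut_given_er_pos,
             tp53_mut_given_er_neg)
  if (any(probs < 0 | probs > 1))
    stop("prevalences must lie in [0, 1]")
  if (abs(sum(grade_probs) - 1) > 1e-8 || any(grade_probs < 0))
    stop("grade_probs must be non-negative and sum to 1")
  if (any(c(baseline_hazard, censor_hazard) <= 0) || hazard_ratio <= 0)
    stop("hazards and hazard ratio must be positive")
  req <- c("er_pos", "er_neg_her2_pos", "er_neg_her2_neg")
  if (!all(req %in% names(tumor_rho_meanlog)))
    stop("tumor_rho_meanlog needs entries: ", paste(req, collapse = ", "))
  structure(as.list(environment()), class = "sim_config")
}

#' Build the synthetic gene model of a configuration
#'
#' Equal-length exons separated by 500 bp introns on a synthetic
#' chromosome, plus strand.
#'
#' @param config a [sim_config()].
#' @return a [gene_model()].
#' @export
simulate_gene_model <- function(config = sim_config()) {
  len <- config$exon_length
  gap <- 500
  starts <- cumsum(c(1000, utils::head(len, -1) + gap))
  gene_model(gene_id = "GENE1", chrom = "chrS",
             starts = starts, ends = starts + len, strand = "+",
             variant_start_exon = config$variant_start_exon,
             intronic_extension = 150)
}

#' Simulate exon counts from true isoform coverages
#'
#' Inverse of the uniform-coverage model the estimator assumes: the
#' expected count of exon `i` is `a * length_i` on exclusive 5' exons and
#' `(a + b) * length_i` on shared exons, where `a` and `b` are the
#' full-length and variant per-nucleotide coverages.
#'
#' @param a,b per-nucleotide coverages (reads/bp), `a + b > 0`.
#' @param model a [gene_model()].
#' @param noise `"none"` (counts = rounded expectations), `"poisson"`, or
#'   `"nb"` (negative binomial with dispersion `nb_size`, for robustness
#'   checks against overdispersed counts).
#' @param seed optional integer seed (set when given).
#' @param sample_id identifier for the returned counts.
#' @param lib_size library size recorded as `total_mapped_reads`.
#' @param nb_size negative-binomial size (inverse-dispersion) parameter;
#'   variance is `mu + mu^2/nb_size`.
#' @return an [exon_counts()] object.
#' @export
simulate_counts <- function(a, b, model, noise = c("none", "poisson", "nb"),
                            seed = NULL, sample_id = "sim",
                            lib_size = 2e7, nb_size = 10) {
  noise <- match.arg(noise)
  stopifnot(a >= 0, b >= 0, a + b > 0)
  if (!is.null(seed)) set.seed(seed)
  len <- exon_lengths(model)
  shared <- model$exons$index >= model$variant_start_exon
  mu <- ifelse(shared, (a + b) * len, a * len)
  cnt <- switch(noise,
    none = round(mu),
    poisson = stats::rpois(length(mu), mu),
    nb = stats::rnbinom(length(mu), mu = mu, size = nb_size))
  exon_counts(sample_id = sample_id, counts = cnt,
              total_mapped_reads = lib_size)
}

#' Simulate a paired tumor/normal cohort
#'
#' Generates, under one seed, a gene model, a long exon-count table for
#' every tumor and normal sample, a clinical sample sheet, and the
#' ground-truth coverages. Patient covariates (ER, Her2, PR, grade, TP53)
#' are drawn once per pair and shared by both tissues; the true variant
#' ratio is drawn from the tumor subgroup distribution for tumors and the
#' near-zero normal distribution for normals. Relapse-free survival is
#' exponential with a hazard ratio between truly variant-positive and
#' -negative tumors, with independent exponential censoring capped at the
#' follow-up horizon.
#'
#' @param config a [sim_config()].
#' @return list with `model` ([gene_model()]), `counts` (long data.frame:
#'   `sample_id`, `exon_index`, `count`, `total_mapped_reads`), `sheet`
#'   (sample sheet data.frame), `truth` (data.frame: `sample_id`,
#'   `pair_id`, `tissue`, `a`, `b`, `rho`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- simulate_gene_model(config)
  n <- config$n_pairs
  pair_id <- sprintf("P%03d", seq_len(n))

  er <- ifelse(stats::runif(n) < config$er_pos_prev, "pos", "neg")
  her2 <- ifelse(stats::runif(n) < config$her2_pos_prev, "pos", "neg")
  pr <- ifelse(stats::runif(n) < ifelse(er == "pos",
                                        config$pr_pos_given_er_pos,
                                        config$pr_pos_given_er_neg),
               "pos", "neg")
  grade <- sample(c("1", "2", "3"), n, replace = TRUE,
                  prob = config$grade_probs)
  tp53 <- ifelse(stats::runif(n) < ifelse(er == "pos",
                                          config$tp53_mut_given_er_pos,
                                          config$tp53_mut_given_er_neg),
                 "Mut", "WT")

  subgroup <- ifelse(er == "pos", "er_pos",
                     ifelse(her2 == "pos", "er_neg_her2_pos",
                            "er_neg_her2_neg"))
  rho_t <- stats::rlnorm(n, config$tumor_rho_meanlog[subgroup],
                         config$tumor_rho_sdlog)
  rho_n <- stats::rlnorm(n, config$normal_rho_meanlog,
                         config$normal_rho_sdlog)
  a_t <- stats::rlnorm(n, config$coverage_meanlog, config$coverage_sdlog)
  a_n <- stats::rlnorm(n, config$coverage_meanlog, config$coverage_sdlog)

  true_pos <- rho_t >= config$positivity_threshold
  hazard <- config$baseline_hazard *
    ifelse(true_pos, config$hazard_ratio, 1)
  t_event <- stats::rexp(n, hazard)
  t_cens <- pmin(stats::rexp(n, config$censor_hazard), config$followup_cap)
  rfs_time <- round(pmin(t_event, t_cens), 2)
  event <- ifelse(t_event <= t_cens, "relapse", "censored")

  make_rows <- function(tissue, a, b) {
    sid <- paste0(pair_id, "_", ifelse(tissue == "tumor", "T", "N"))
    counts <- lapply(seq_len(n), function(i)
      simulate_counts(a[i], b[i], model, noise = config$noise,
                      sample_id = sid[i], lib_size = config$lib_size,
                      nb_size = config$nb_size))
    long <- do.call(rbind, lapply(counts, function(cc)
      data.frame(sample_id = cc$sample_id,
                 exon_index = seq_along(cc$counts), count = cc$counts,
                 total_mapped_reads = cc$total_mapped_reads)))
    list(sid = sid, long = long)
  }
  tum <- make_rows("tumor", a_t, rho_t * a_t)
  nor <- make_rows("normal", a_n, rho_n * a_n)

  sheet <- rbind(
    data.frame(sample_id = tum$sid, pair_id = pair_id, tissue = "tumor",
               er = er, her2 = her2, pr = pr, grade = grade, tp53 = tp53,
               rfs_time = rfs_time, event = event,
               positivity = ifelse(true_pos, "positive", "negative")),
    data.frame(sample_id = nor$sid, pair_id = pair_id, tissue = "normal",
               er = er, her2 = her2, pr = pr, grade = grade, tp53 = tp53,
               rfs_time = NA_real_, event = NA_character_,
               positivity = "unknown"))
  truth <- rbind(
    data.frame(sample_id = tum$sid, pair_id = pair_id, tissue = "tumor",
               a = a_t, b = rho_t * a_t, rho = rho_t),
    data.frame(sample_id = nor$sid, pair_id = pair_id, tissue = "normal",
               a = a_n, b = rho_n * a_n, rho = rho_n))
  list(model = model, counts = rbind(tum$long, nor$long), sheet = sheet,
       truth = truth)
}

#' Write a simulated cohort to a directory as TSV
#'
#' Emits the same dialects the pipeline reads: `counts.tsv`, `sheet.tsv`,
#' `truth.tsv`, plus the gene model as `model.json` and `model.gtf`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_exon_counts(cohort$counts, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$sheet, file.path(dir, "sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_model(cohort$model, file.path(dir, "model.json"))
  write_gene_model_gtf(cohort$model, file.path(dir, "model.gtf"))
  invisible(dir)
}

#' Emit synthetic single-end reads as SAM
#'
#' Read-level counterpart of [simulate_counts()] for end-to-end tests of
#' [count_exon_reads()]: per-exon read numbers are drawn exactly as there,
#' then each read is placed uniformly at random fully inside its exon
#' (every exon must be at least one read length long), so counting the
#' emitted alignments reproduces the simulated counts exactly.
#'
#' @inheritParams simulate_counts
#' @param path output SAM path.
#' @param read_length read length in bp (default 29).
#' @return the [exon_counts()] realized in the file, invisibly.
#' @export
simulate_reads_sam <- function(a, b, model, path,
                               noise = c("none", "poisson"),
                               seed = NULL, read_length = 29,
                               sample_id = "sim", lib_size = 2e7) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  len <- exon_lengths(model)
  if (any(len < read_length))
    stop("every exon must be at least read_length (", read_length, ") bp")
  cnt <- simulate_counts(a, b, model, noise = noise, seed = NULL,
                         sample_id = sample_id, lib_size = lib_size)
  ex <- model$exons
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", model$chrom,
                      as.integer(max(ex$end) + 1000)))
  lines <- header
  rid <- 0L
  for (i in seq_len(nrow(ex))) {
    ni <- cnt$counts[i]
    if (ni == 0) next
    # 1-based leftmost positions keeping the read fully inside the exon
    pos <- ex$start[i] + 1 +
      floor(stats::runif(ni) * (len[i] - read_length + 1))
    rid_i <- rid + seq_len(ni)
    lines <- c(lines, sprintf(
      "read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
      rid_i, model$chrom, as.integer(pos), read_length,
      strrep("A", read_length), strrep("I", read_length)))
    rid <- rid + ni
  }
  writeLines(lines, path)
  invisible(cnt)
}
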