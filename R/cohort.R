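#' Read a clinical sample sheet TSV
#'
#' Required columns: `sample_id`, `pair_id`, `tissue` (tumor/normal), `er`,
#' `her2`, `pr` (pos/neg/unknown), `grade` (1/2/3/unknown), `tp53`
#' (WT/Mut/unknown), `rfs_time` (months), `event` (relapse/censored/
#' unknown). An optional `positivity` column (positive/negative/unknown)
#' carries an assay-based variant call; when absent it is filled with
#' "unknown". Empty `pair_id` marks unpaired samples.
#'
#' @param path TSV path with header.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  req <- c("sample_id", "pair_id", "tissue", "er", "her2", "pr", "grade",
           "tp53", "rfs_time", "event")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("sample sheet ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"positivity" %in% names(d)) d$positivity <- "unknown"
  chk <- function(col, allowed) {
    v <- d[[col]]
    bad <- !is.na(v) & !v %in% allowed
    if (any(bad))
      stop("sample sheet column '", col, "' has invalid value '",
           v[bad][1], "' (allowed: ", paste(allowed, collapse = "/"), ")")
  }
  chk("tissue", c("tumor", "normal"))
  for (col in c("er", "her2", "pr")) chk(col, c("pos", "neg", "unknown"))
  chk("grade", c("1", "2", "3", "unknown"))
  chk("tp53", c("WT", "Mut", "unknown"))
  chk("event", c("relapse", "censored", "unknown"))
  chk("positivity", c("positive", "negative", "unknown"))
  d$rfs_time <- as.numeric(d$rfs_time)
  if (any(!is.na(d$rfs_time) & d$rfs_time < 0))
    stop("rfs_time must be non-negative")
  has_t <- !is.na(d$rfs_time)
  has_e <- !is.na(d$event) & d$event != "unknown"
  if (any(has_t != has_e))
    stop("rfs_time must be present exactly when event is present")
  dup <- duplicated(d$sample_id)
  if (any(dup)) stop("duplicate sample_id: ", d$sample_id[dup][1])
  d
}

#' Paired tumor/normal differences in log2 R
#'
#' For every pair with exactly one tumor and one normal sample whose ratio
#' estimates are finite, computes `delta = log2R(tumor) - log2R(normal)`
#' (both on the pseudocount convention of [estimate_isoform_ratio()]).
#' Pairs with a missing or sentinel-infinite member are excluded and the
#' reason recorded.
#'
#' @param estimates data.frame from [estimate_isoform_ratios()].
#' @param sheet sample sheet data.frame (see [read_sample_sheet()]).
#' @return list with `differences` (data.frame: `pair_id`, `log2R_tumor`,
#'   `log2R_normal`, `delta`), `n_pairs`, `n_excluded`, `exclusions`
#'   (data.frame: `pair_id`, `reason`).
#' @export
paired_log2_difference <- function(estimates, sheet) {
  s <- sheet[!is.na(sheet$pair_id) & sheet$pair_id != "", ]
  merged <- merge(s[, c("sample_id", "pair_id", "tissue")],
                  estimates[, c("sample_id", "log2R", "flags")],
                  by = "sample_id", all.x = TRUE)
  res <- list(); excl <- list()
  for (pid in unique(merged$pair_id)) {
    p <- merged[merged$pair_id == pid, ]
    if (anyDuplicated(p$tissue))
      stop("pair '", pid, "' has duplicate tissue '",
           p$tissue[duplicated(p$tissue)][1], "'")
    tum <- p[p$tissue == "tumor", ]; nor <- p[p$tissue == "normal", ]
    if (nrow(tum) != 1L || nrow(nor) != 1L) {
      excl[[pid]] <- "incomplete pair"; next
    }
    if (is.na(tum$log2R) || is.na(nor$log2R)) {
      excl[[pid]] <- "missing estimate"; next
    }
    if (!is.finite(tum$log2R) || !is.finite(nor$log2R)) {
      excl[[pid]] <- "undefined ratio (zero full-length signal)"; next
    }
    res[[pid]] <- data.frame(pair_id = pid, log2R_tumor = tum$log2R,
                             log2R_normal = nor$log2R,
                             delta = tum$log2R - nor$log2R)
  }
  differences <- if (length(res)) do.call(rbind, res) else
    data.frame(pair_id = character(0), log2R_tumor = numeric(0),
               log2R_normal = numeric(0), delta = numeric(0))
  rownames(differences) <- NULL
  exclusions <- if (length(excl))
    data.frame(pair_id = names(excl), reason = unlist(excl)) else
    data.frame(pair_id = character(0), reason = character(0))
  rownames(exclusions) <- NULL
  list(differences = differences, n_pairs = nrow(differences),
       n_excluded = nrow(exclusions), exclusions = exclusions)
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided throughout. In `auto` mode the exact null distribution is
#' used when `n_a + n_b <= 12` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param labels length-2 character vector naming the groups.
#' @return list of class `group_comparison`: `group_labels`, `n_per_group`,
#'   `statistic` (rank-sum W of group a, Mann-Whitney form), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b,
                              mode = c("auto", "exact", "normal_approx"),
                              labels = c("a", "b")) {
  mode <- match.arg(mode)
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(structure(list(group_labels = labels,
                          n_per_group = c(length(values_a), length(values_b)),
                          statistic = length(values_a) * length(values_b) / 2,
                          p_value = 1, method = "degenerate"),
                     class = "group_comparison"))
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = (length(values_a) + length(values_b) <= 12) && !ties)
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  structure(list(group_labels = labels,
                 n_per_group = c(length(values_a), length(values_b)),
                 statistic = unname(wt$statistic),
                 p_value = min(wt$p.value, 1),
                 method = if (use_exact && !ties) "exact" else
                   "normal approximation (tie/continuity corrected)"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: %s (n=%d) vs %s (n=%d)  W = %g, p = %.4g [%s]\n",
              x$group_labels[1], x$n_per_group[1], x$group_labels[2],
              x$n_per_group[2], x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Fisher exact test on a 2 x k contingency table
#'
#' Two-sided exact p by enumeration of tables with fixed margins whose
#' probability does not exceed the observed table's (k = 2 or 3). A table
#' with a zero row or column margin carries no evidence and returns p = 1
#' with a warning.
#'
#' @param tab 2 x k matrix of non-negative integer counts.
#' @return list with `p_value` and `odds_ratio` (conditional MLE, 2 x 2
#'   only; `NA` otherwise).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2 || !ncol(tab) %in% c(2, 3))
    stop("expected a 2x2 or 2x3 table, got ", nrow(tab), "x", ncol(tab))
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in contingency table; p = 1")
    return(list(p_value = 1, odds_ratio = NA_real_))
  }
  ft <- stats::fisher.test(tab)
  list(p_value = min(ft$p.value, 1),
       odds_ratio = if (all(dim(tab) == 2)) unname(ft$estimate) else NA_real_)
}

#' Kaplan-Meier curves and log-rank test stratified by a factor
#'
#' Product-limit estimate per stratum, `S(t) = prod(1 - d_i/n_i)` over
#' event times `t_i <= t` (events precede censorings at tied times, the
#' standard convention), and the two-group log-rank chi-square (1 df).
#'
#' @param records data.frame with columns `rfs_time`, `event`
#'   (relapse/censored, or 1/0) and the stratum column.
#' @param strata_col name of the stratum column (default "positivity").
#'   Rows with `unknown`/`NA` stratum or missing survival data are dropped
#'   (count reported).
#' @return list of class `survival_result`: `curves` (data.frame: `group`,
#'   `time`, `n_risk`, `n_event`, `survival`), `n_per_group`,
#'   `events_per_group`, `logrank_statistic`, `df`, `p_value`,
#'   `n_excluded`, `no_events` flag.
#' @export
km_logrank <- function(records, strata_col = "positivity") {
  if (!strata_col %in% names(records))
    stop("column '", strata_col, "' not found in records")
  ev <- records$event
  status <- if (is.numeric(ev)) as.integer(ev != 0) else
    ifelse(ev == "relapse", 1L, ifelse(ev == "censored", 0L, NA_integer_))
  grp <- records[[strata_col]]
  grp[grp %in% "unknown"] <- NA
  keep <- !is.na(records$rfs_time) & !is.na(status) & !is.na(grp)
  n_excluded <- sum(!keep)
  d <- data.frame(time = records$rfs_time[keep], status = status[keep],
                  group = as.character(grp[keep]))
  groups <- sort(unique(d$group))
  if (length(groups) == 0 || any(table(factor(d$group, groups)) == 0))
    stop("every stratum must have at least one subject")
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = d)
  strata_names <- if (is.null(fit$strata)) groups else
    sub("^group=", "", names(fit$strata))
  lens <- if (is.null(fit$strata)) length(fit$time) else fit$strata
  curves <- data.frame(group = rep(strata_names, lens),
                       time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, survival = fit$surv)
  no_events <- sum(d$status) == 0
  if (no_events || length(groups) < 2) {
    chisq <- NA_real_; p <- NA_real_; df <- length(groups) - 1L
    if (no_events)
      warning("no events in any stratum; log-rank undefined, curves are 1")
  } else {
    sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = d)
    chisq <- sd$chisq
    df <- length(groups) - 1L
    p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  }
  structure(list(curves = curves,
                 n_per_group = table(factor(d$group, groups)),
                 events_per_group = tapply(d$status,
                                           factor(d$group, groups), sum),
                 logrank_statistic = chisq, df = df, p_value = p,
                 n_excluded = n_excluded, no_events = no_events),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("Kaplan-Meier by stratum: n =",
      paste(sprintf("%s:%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "), "\n")
  if (is.na(x$logrank_statistic)) cat("  log-rank: undefined\n") else
    cat(sprintf("  log-rank chi-square = %.3f (df=%d), p = %.4g\n",
                x$logrank_statistic, x$df, x$p_value))
  invisible(x)
}

#' Run the full cohort analysis
#'
#' Orchestrates the cohort-level analyses over a table of per-sample ratio
#' estimates and a clinical sheet: paired tumor/normal log2-ratio
#' differences (with the count of pairs exceeding a threshold, default 1),
#' Wilcoxon comparisons of tumor R between receptor-defined subgroups
#' (ER+/Her2- vs ER-/Her2-, and ER-/Her2+ vs ER-/Her2-), Fisher exact
#' association of positivity with grade/ER/PR/TP53, and Kaplan-Meier /
#' log-rank relapse-free survival by positivity overall and within the
#' ER+ and ER- subsets.
#'
#' @param estimates data.frame from [estimate_isoform_ratios()].
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param config list of options: `positivity_threshold` (default 0.1),
#'   `positivity_source` ("estimate" to threshold R, "sheet" to use the
#'   sheet's assay call; default "estimate"), `delta_threshold` (default
#'   1), `adjust_fisher` (Benjamini-Hochberg across the Fisher battery;
#'   default FALSE).
#' @return list of class `cohort_report` with elements `paired`,
#'   `wilcoxon`, `fisher`, `survival`, `positivity`, `log`.
#' @export
run_cohort_analysis <- function(estimates, sheet, config = list()) {
  cfg <- utils::modifyList(list(positivity_threshold = 0.1,
                                positivity_source = "estimate",
                                delta_threshold = 1,
                                adjust_fisher = FALSE), config)
  log <- character(0)

  paired <- paired_log2_difference(estimates, sheet)
  n_gt <- sum(paired$differences$delta > cfg$delta_threshold)
  paired$delta_threshold <- cfg$delta_threshold
  paired$n_delta_above <- n_gt
  log <- c(log, sprintf(
    "paired: %d pairs analysed, %d excluded, %d with delta > %g",
    paired$n_pairs, paired$n_excluded, n_gt, cfg$delta_threshold))

  tum <- merge(sheet[sheet$tissue == "tumor", ], estimates, by = "sample_id")
  tum$positivity_used <- if (cfg$positivity_source == "sheet") {
    tum$positivity
  } else {
    call_positivity(tum$R, threshold = cfg$positivity_threshold)
  }

  grp_R <- function(er, her2) tum$R[tum$er == er & tum$her2 == her2 &
                                      tum$er != "unknown" &
                                      tum$her2 != "unknown"]
  ref <- grp_R("neg", "neg")
  wilcoxon <- list()
  for (ct in list(c("pos", "neg", "ER+/Her2- vs ER-/Her2-"),
                  c("neg", "pos", "ER-/Her2+ vs ER-/Her2-"))) {
    x <- grp_R(ct[1], ct[2])
    key <- ct[3]
    if (length(x) == 0 || length(ref) == 0) {
      wilcoxon[[key]] <- NULL
      log <- c(log, sprintf("wilcoxon '%s': skipped (empty group)", key))
    } else {
      wilcoxon[[key]] <- wilcoxon_rank_sum(
        x, ref, labels = c(strsplit(key, " vs ")[[1]]))
      log <- c(log, sprintf("wilcoxon '%s': n = %d vs %d, p = %.4g", key,
                            length(x), length(ref),
                            wilcoxon[[key]]$p_value))
    }
  }

  fisher <- list()
  fisher_factors <- list(grade = c("1", "2", "3"), er = c("pos", "neg"),
                         pr = c("pos", "neg"), tp53 = c("WT", "Mut"))
  for (fac in names(fisher_factors)) {
    lev <- fisher_factors[[fac]]
    keep <- tum[[fac]] %in% lev & tum$positivity_used %in%
      c("positive", "negative")
    tab <- table(factor(tum$positivity_used[keep],
                        c("positive", "negative")),
                 factor(tum[[fac]][keep], lev))
    fisher[[fac]] <- c(list(table = unclass(tab), n = sum(tab)),
                       fisher_exact(tab))
    log <- c(log, sprintf("fisher positivity x %s: n = %d, p = %.4g",
                          fac, sum(tab), fisher[[fac]]$p_value))
  }
  if (isTRUE(cfg$adjust_fisher)) {
    padj <- stats::p.adjust(vapply(fisher, `[[`, 0, "p_value"), "BH")
    for (i in seq_along(fisher)) fisher[[i]]$p_adjusted <- padj[[i]]
  }

  surv_input <- tum[!is.na(tum$rfs_time) & tum$event %in%
                      c("relapse", "censored"), ]
  run_km <- function(d, label) {
    pos_lvls <- unique(d$positivity_used[d$positivity_used != "unknown"])
    if (nrow(d) == 0 || length(pos_lvls) < 2) {
      log <<- c(log, sprintf("survival '%s': skipped (needs both strata)",
                             label))
      return(NULL)
    }
    res <- suppressWarnings(km_logrank(
      data.frame(rfs_time = d$rfs_time, event = d$event,
                 positivity = d$positivity_used)))
    log <<- c(log, sprintf("survival '%s': n = %s, log-rank p = %.4g",
                           label,
                           paste(res$n_per_group, collapse = "/"),
                           res$p_value))
    res
  }
  survival <- list(
    overall = run_km(surv_input, "overall"),
    er_positive = run_km(surv_input[surv_input$er == "pos", ], "ER+"),
    er_negative = run_km(surv_input[surv_input$er == "neg", ], "ER-"))

  structure(list(paired = paired, wilcoxon = wilcoxon, fisher = fisher,
                 survival = survival,
                 positivity = table(tum$positivity_used),
                 config = cfg, log = log),
            class = "cohort_report")
}

#' Write a cohort report bundle to a directory
#'
#' Emits the paired-difference table, the ratio-by-sample table inputs it
#' was given, per-stratum survival curves, and a plain-text summary.
#'
#' @param report a `cohort_report` from [run_cohort_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$paired$differences,
                     file.path(dir, "paired_differences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$survival)) {
    res <- report$survival[[nm]]
    if (!is.null(res))
      utils::write.table(res$curves,
                         file.path(dir, paste0("km_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summ <- c("Cohort analysis summary", "=======================", "",
            report$log, "",
            sprintf("Fisher exact p-values:%s", ""),
            vapply(names(report$fisher), function(f)
              sprintf("  positivity x %-5s p = %.4g", f,
                      report$fisher[[f]]$p_value), ""))
  writeLines(summ, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  writeLines(x$log)
  invisible(x)
}
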