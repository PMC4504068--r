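est_row <- function(sample_id, R, eps = 1e-6, flags = "")
  data.frame(sample_id = sample_id, r0 = 1, r1 = 1, F0 = 1, F1_raw = 1,
             F1 = 1, R = R, log2R = log2(R + eps), flags = flags)

sheet_row <- function(sample_id, pair_id, tissue, er = "pos", her2 = "neg",
                      pr = "pos", grade = "2", tp53 = "WT",
                      rfs_time = NA_real_, event = NA_character_,
                      positivity = "unknown")
  data.frame(sample_id = sample_id, pair_id = pair_id, tissue = tissue,
             er = er, her2 = her2, pr = pr, grade = grade, tp53 = tp53,
             rfs_time = rfs_time, event = event, positivity = positivity)

# paired differences ---------------------------------------------------------

test_that("paired log2 differences follow the ratio algebra", {
  est <- rbind(est_row("t1", 2), est_row("n1", 0.5),
               est_row("t2", 1), est_row("n2", 1))
  sheet <- rbind(sheet_row("t1", "p1", "tumor"),
                 sheet_row("n1", "p1", "normal"),
                 sheet_row("t2", "p2", "tumor"),
                 sheet_row("n2", "p2", "normal"))
  pd <- paired_log2_difference(est, sheet)
  expect_equal(pd$n_pairs, 2)
  expect_equal(pd$differences$delta[pd$differences$pair_id == "p1"], 2,
               tolerance = 1e-5)
  expect_equal(pd$differences$delta[pd$differences$pair_id == "p2"], 0)
})

test_that("pairs with undefined or missing members are excluded with reasons", {
  est <- rbind(est_row("t1", 2),
               est_row("n1", Inf, flags = "R_UNDEFINED_ZERO_F0"),
               est_row("t2", 2))
  sheet <- rbind(sheet_row("t1", "p1", "tumor"),
                 sheet_row("n1", "p1", "normal"),
                 sheet_row("t2", "p2", "tumor"),
                 sheet_row("n2", "p2", "normal"))
  pd <- paired_log2_difference(est, sheet)
  expect_equal(pd$n_pairs, 0)
  expect_equal(pd$n_excluded, 2)
  expect_match(pd$exclusions$reason[pd$exclusions$pair_id == "p1"],
               "undefined")
  expect_match(pd$exclusions$reason[pd$exclusions$pair_id == "p2"],
               "missing")
})

test_that("duplicate tissue within a pair is an error", {
  est <- rbind(est_row("t1", 2), est_row("t2", 1))
  sheet <- rbind(sheet_row("t1", "p1", "tumor"),
                 sheet_row("t2", "p1", "tumor"))
  expect_error(paired_log2_difference(est, sheet), "duplicate tissue")
})

# Wilcoxon -------------------------------------------------------------------

test_that("exact Wilcoxon p-values match hand enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3)
  expect_equal(w$method, "exact")
  w2 <- wilcoxon_rank_sum(1:5, 6:10)
  expect_equal(w2$p_value, 2 / 252)
  expect_warning(w3 <- wilcoxon_rank_sum(c(2, 2), c(2, 2)), "identical")
  expect_equal(w3$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact mode matches the enumeration oracle on random splits", {
  set.seed(8)
  for (na in 1:4) for (nb in na:5) {
    x <- sample(100, na + nb)  # no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b, mode = "exact")$p_value,
                 enumerate_wilcoxon_p(a, b),
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("same-multiset groups give p = 1 by symmetry", {
  w <- wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9))
  expect_equal(w$p_value, 1)
})

# Fisher ---------------------------------------------------------------------

test_that("Fisher exact p-values match hypergeometric enumeration", {
  f <- fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(f$p_value, 34 / 70)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(4, 0, 0, 4), 2))$p_value, 2 / 70)
  expect_warning(fz <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(fz$p_value, 1)
  expect_error(fisher_exact(matrix(1, 2, 4)), "2x2 or 2x3")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("2x3 tables are handled and the odds ratio is 2x2-only", {
  f <- fisher_exact(matrix(c(8, 3, 1, 2, 5, 6), nrow = 2, byrow = TRUE))
  expect_true(f$p_value > 0 && f$p_value <= 1)
  expect_true(is.na(f$odds_ratio))
  f2 <- fisher_exact(matrix(c(8, 2, 2, 8), 2))
  expect_false(is.na(f2$odds_ratio))
})

# Kaplan-Meier / log-rank -----------------------------------------------------

test_that("the product-limit estimate matches hand computation", {
  d <- data.frame(rfs_time = c(1, 2, 3), event = rep("relapse", 3),
                  positivity = "positive")
  km <- km_logrank(d)
  expect_equal(km$curves$survival, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(km$curves$survival) <= 0))

  # censoring between events, against the independent oracle
  d2 <- data.frame(rfs_time = c(2, 3, 3, 5, 8, 9, 11),
                   event = c("relapse", "relapse", "censored", "relapse",
                             "censored", "relapse", "censored"),
                   positivity = "positive")
  km2 <- km_logrank(d2)
  oracle <- product_limit_oracle(d2$rfs_time,
                                 as.integer(d2$event == "relapse"))
  got <- km2$curves[km2$curves$n_event > 0, c("time", "survival")]
  rownames(got) <- NULL
  expect_equal(got, oracle)
})

test_that("identical strata give a null log-rank and all-censored flat curves", {
  d <- data.frame(rfs_time = rep(c(1, 3, 7, 9), 2),
                  event = rep(c("relapse", "censored", "relapse", "relapse"), 2),
                  positivity = rep(c("positive", "negative"), each = 4))
  km <- km_logrank(d)
  expect_equal(km$logrank_statistic, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1)

  dc <- data.frame(rfs_time = c(1, 2, 3, 4), event = "censored",
                   positivity = rep(c("positive", "negative"), 2))
  expect_warning(kmc <- km_logrank(dc), "no events")
  expect_true(all(kmc$curves$survival == 1))
  expect_true(kmc$no_events)
  expect_true(is.na(kmc$logrank_statistic))

  expect_error(km_logrank(data.frame(rfs_time = 1, event = "relapse",
                                     positivity = NA_character_)),
               "at least one subject")
})

# sample sheet ---------------------------------------------------------------

test_that("sample sheet validation catches structural problems", {
  co <- simulate_cohort(sim_config(n_pairs = 5, seed = 2))
  p <- tempfile(fileext = ".tsv")
  write.table(co$sheet, p, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- read_sample_sheet(p)
  expect_equal(nrow(s), 10)

  write.table(co$sheet[, setdiff(names(co$sheet), "er")], p, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(p), "er")

  bad <- co$sheet; bad$tissue[1] <- "plasma"
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(p), "tissue")

  bad2 <- co$sheet; bad2$rfs_time[bad2$tissue == "normal"][1] <- 12
  write.table(bad2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_sheet(p), "rfs_time")
})

# orchestration ---------------------------------------------------------------

test_that("identical tumor/normal ratios give all-zero deltas", {
  est <- rbind(est_row(c("t1", "t2", "t3"), c(1, 2, 3)),
               est_row(c("n1", "n2", "n3"), c(1, 2, 3)))
  sheet <- rbind(sheet_row(c("t1", "t2", "t3"), c("p1", "p2", "p3"), "tumor",
                           er = c("pos", "neg", "pos")),
                 sheet_row(c("n1", "n2", "n3"), c("p1", "p2", "p3"), "normal",
                           er = c("pos", "neg", "pos")))
  # degenerate positivity margins in this 3-pair fixture warn by design
  rep <- suppressWarnings(run_cohort_analysis(est, sheet))
  expect_equal(rep$paired$n_delta_above, 0)
  expect_true(all(rep$paired$differences$delta == 0))
})

test_that("the default synthetic cohort produces a complete report bundle", {
  co <- simulate_cohort(sim_config(n_pairs = 40, seed = 12))
  est <- estimate_isoform_ratios(co$counts, co$model)
  rep <- run_cohort_analysis(est, co$sheet)
  expect_s3_class(rep, "cohort_report")
  expect_equal(rep$paired$n_pairs + rep$paired$n_excluded, 40)
  expect_length(rep$wilcoxon, 2)
  expect_named(rep$fisher, c("grade", "er", "pr", "tp53"))
  for (f in rep$fisher) expect_true(f$p_value > 0 && f$p_value <= 1)
  expect_false(is.null(rep$survival$overall))
  expect_true(length(rep$log) >= 8)

  dir <- tempfile()
  write_cohort_report(rep, dir)
  expect_true(file.exists(file.path(dir, "paired_differences.tsv")))
  expect_true(file.exists(file.path(dir, "summary.txt")))
  expect_true(file.exists(file.path(dir, "km_overall.tsv")))
})

test_that("the BH switch adds adjusted p-values across the Fisher battery", {
  co <- simulate_cohort(sim_config(n_pairs = 30, seed = 3))
  est <- estimate_isoform_ratios(co$counts, co$model)
  rep <- run_cohort_analysis(est, co$sheet, config = list(adjust_fisher = TRUE))
  raw <- vapply(rep$fisher, `[[`, 0, "p_value")
  adj <- vapply(rep$fisher, `[[`, 0, "p_adjusted")
  expect_equal(unname(adj), unname(p.adjust(raw, "BH")))
})
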