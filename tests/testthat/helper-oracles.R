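# Independent oracles, deliberately brute-force and separate from the
# implementation paths they check.

# Two-sided exact Wilcoxon rank-sum p by enumeration of every assignment
# of the pooled ranks to group a (no ties assumed).
enumerate_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  ranks <- seq_len(n)
  u_all <- apply(sets, 2, function(ix) sum(ranks[ix]) - na * (na + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric mass
# summation over all tables with the observed margins.
hypergeom_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- max(0, k - n):min(k, m)
  mass <- stats::dhyper(x, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# Hand product-limit estimator: survival at each distinct event time,
# events before censorings at ties.
product_limit_oracle <- function(time, status) {
  ev_times <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = ev_times, survival = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Small helpers used across test files.
make_uniform_model <- function(n_exons = 15, k = 10, len = 100) {
  gene_model("g", "chrT", starts = (seq_len(n_exons) - 1) * (len + 50),
             ends = (seq_len(n_exons) - 1) * (len + 50) + len,
             strand = "+", variant_start_exon = k)
}

# Random valid gene model (variable exon count, lengths, k).
random_model <- function() {
  n <- sample(4:20, 1)
  len <- sample(50:300, n, replace = TRUE)
  starts <- cumsum(c(100, len[-n] + sample(50:500, n - 1, replace = TRUE)))
  gene_model("g", "chrT", starts = starts, ends = starts + len,
             strand = "+", variant_start_exon = sample(2:n, 1))
}

# Counts implied by exact integer coverages (noise-free, no rounding).
exact_counts <- function(a, b, model) {
  len <- exon_lengths(model)
  shared <- model$exons$index >= model$variant_start_exon
  exon_counts("exact", ifelse(shared, (a + b) * len, a * len))
}
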