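#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the design the downstream analyses assume: one 15-exon gene
# whose variant transcript comprises exons 10-15, and 87 tumor/normal
# pairs with receptor-dependent variant expression, Poisson count noise,
# and positivity-dependent relapse-free survival. Everything is
# reproducible from the seed (first command-line argument, default 1).

suppressMessages(library(isoratio))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
out <- file.path("results", "simdata")
write_cohort(cohort, out)

cat(sprintf("simulated %d tumor/normal pairs (seed %d)\n",
            cfg$n_pairs, seed))
cat(sprintf("gene: %d exons, variant starts at exon %d, L0 = %g, L1 = %g\n",
            nrow(cohort$model$exons), cohort$model$variant_start_exon,
            cohort$model$L0, cohort$model$L1))
cat(sprintf("true positivity (rho >= %g) among tumors: %d of %d\n",
            cfg$positivity_threshold,
            sum(cohort$sheet$positivity == "positive"), cfg$n_pairs))
cat("wrote", out, "\n")
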