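#!/usr/bin/env Rscript

# Statistical comparison stage on the simulated cohort produced by
# 02_decode_cohort.R: does feedback condition (the three post-baseline
# runs) change MI accuracy? One-way repeated-measures ANOVA with
# Mauchly's sphericity check and GG/HF/LB-corrected p-values, for both
# the max- and mean-accuracy summaries; plus the healthy-vs-stroke
# baseline comparison with a normality gate (Shapiro-Wilk choosing
# between pooled t and Mann-Whitney U).
#
# In this cohort all five runs share the same generator settings within
# subject, so the protocol's expected outcome is a null: no condition
# effect.

library(mibci)

tab <- read.delim("results/cohort_accuracy.tsv", check.names = FALSE)
cells_of <- function(mode) {
  sub <- tab[tab$mode == mode, ]
  runs <- c("T2-S1", "T1-S2", "T2-S2")
  m <- sapply(runs, function(r) tapply(sub[[r]], sub$subject, mean))
  matrix(m, ncol = 3, dimnames = list(NULL, runs))
}

out <- list()
for (mode in c("max", "mean")) {
  r <- rm_anova(cells_of(mode))
  cat(sprintf("\n== %s accuracy: condition comparison ==\n", mode))
  print(r)
  out[[paste0("rm_anova_", mode)]] <- unclass(r)
}

# group baseline comparison at T1-S1 (the reference run)
base <- tab[tab$mode == "max", ]
b <- tapply(base[["T1-S1"]], base$subject, mean)
groups <- tapply(base$group, base$subject, `[`, 1)
h <- b[groups == "healthy"]; s <- b[groups == "stroke"]
sw_h <- shapiro_wilk(h); sw_s <- shapiro_wilk(s)
cat(sprintf("\nBaseline (T1-S1 max): healthy %.1f%%, stroke %.1f%%\n",
            mean(h), mean(s)))
cat(sprintf("Shapiro-Wilk p: healthy %.3f, stroke %.3f\n", sw_h$p, sw_s$p))
if (min(sw_h$p, sw_s$p) > 0.05) {
  r <- t_test_ind(h, s)
  cat(sprintf("pooled t test: t = %.3f, p = %.3f\n", r$t, r$p))
  out$baseline <- c(list(test = "t"), r)
} else {
  r <- mann_whitney_u(h, s)
  cat(sprintf("Mann-Whitney U: U = %g, p = %.3f\n", r$U, r$p))
  out$baseline <- c(list(test = "mann-whitney"), r)
}

jsonlite::write_json(out, "results/condition_stats.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nwrote results/condition_stats.json\n")
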