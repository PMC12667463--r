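#!/usr/bin/env Rscript
# Instructive vs permissive interface scenarios: 25 subpopulations sampled
# from the non-transmigrated distribution (normal, mean 2, sd 0.1); the
# instructive interface shifts every constant by +0.2, the permissive
# interface admits only subpopulations with R >= 2.15. 24 replicate plates
# per scenario; Mann-Whitney comparisons of the CV profiles.

library(transmig)

seed <- 20260928
dir.create("results", showWarnings = FALSE)

set.seed(seed)
sets <- scenario_sets(n = 25, mean = 2, sd = 0.1, shift = 0.2,
                      threshold = 2.15)
for (s in sets) {
  cat(sprintf("%-14s mean R = %.3f, sd = %.3f\n",
              s$label, mean(s$constants), sd(s$constants)))
}

cvs <- do.call(rbind, lapply(sets, function(s)
  simulate_scenario_cv(s, replicates = 24)))
write_results_table(cbind(cvs, seed = seed), "results/scenario_cv.csv")

cat("\nInstructive model (uniform shift 2.0 -> 2.2):\n")
instructive <- compare_trends(
  rbind(cvs[cvs$label == "instructive_nt", ], cvs[cvs$label == "instructive_t", ]),
  "label")
cat(sprintf("  pooled CV profiles, Mann-Whitney p = %.3f -> %s\n",
            instructive$p_value,
            if (instructive$p_value > 0.05) "indistinguishable" else "different"))

cat("Permissive model (selection R >= 2.15):\n")
rows <- lapply(c(1000, 100, 10), function(block) {
  sub <- rbind(cvs[cvs$label == "permissive_t" & cvs$seed_count == block, ],
               cvs[cvs$label == "permissive_nt" & cvs$seed_count == block, ])
  res <- compare_trends(sub, "label", alternative = "less")
  cat(sprintf("  block %4d cells: one-sided Mann-Whitney p = %.2g (CV lower after selection)\n",
              block, res$p_value))
  data.frame(block = block, p_one_sided = res$p_value)
})
write_results_table(
  cbind(rbind(data.frame(block = NA, p_one_sided = instructive$p_value),
              do.call(rbind, rows)),
        comparison = c("instructive_pooled", rep("permissive_by_block", 3)),
        seed = seed),
  "results/scenario_tests.csv")

cat("\nA uniformly instructing interface preserves the CV-vs-cell-number\n")
cat("profile; a permissive (selecting) interface lowers CV at every block.\n")
cat("Matching experimental profiles before/after transmigration therefore\n")
cat("argue for an instructive interface.\n")
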