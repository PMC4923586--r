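#!/usr/bin/env Rscript
# Monte-Carlo behaviour of the group-vs-rest emotion test at a reduced
# replicate count for a quick look (the validation suite runs the full
# 1000-replicate null and 200-replicate power settings).

library(demotext)

dir.create("results", showWarnings = FALSE)

nul <- simulate_null_rejection_rate(n_replicates = 200L, posts_per_group = 500L,
                                    seed = 10L)
pw <- simulate_power(n_replicates = 50L, posts_per_group = 1000L,
                     p_target = 0.40, p_other = 0.25, seed = 20L)

out <- list(null_rejection_rate = nul$rejection_rate,
            null_comparisons = nul$n_comparisons,
            power = pw$power, power_replicates = pw$n_replicates)
jsonlite::write_json(out, "results/calibration.json", auto_unbox = TRUE)

cat(sprintf("Null rejection rate at alpha = .05: %.3f over %d comparisons\n",
            nul$rejection_rate, nul$n_comparisons))
cat(sprintf("Power at injection 0.40 vs 0.25 (n = 1000/group): %.2f\n", pw$power))
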