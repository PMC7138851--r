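#!/usr/bin/env Rscript
# Simulates A340 progress curves of the coupled NADPH/glutathione-reductase
# assay for wild-type ScGrx7 over the canonical GSSCys levels and checks
# that the extracted initial rates reproduce the Dalziel rate law.

library(grxfun)
dir.create("results", showWarnings = FALSE)

set <- load_variant("WT")
gssr_levels <- c(25, 50, 100, 150) * 1e-6

rows <- lapply(gssr_levels, function(cg) {
  cond <- assay_conditions(enzyme0 = 10e-9, gssr0 = cg, gsh0 = 1e-3)
  curve <- simulate_assay(set$kinetic, cond, t_end = 120, dt = 0.5)
  v0 <- initial_rate(curve, window = 10)
  v_pred <- dalziel_rate(set$kinetic, cond$enzyme0, cg, cond$gsh0)
  data.frame(gssr_M = cg, gsh_M = cond$gsh0,
             v0_extracted_M_per_s = v0, v0_ratelaw_M_per_s = v_pred,
             relative_error = abs(v0 - v_pred) / v_pred,
             a340_drop_AU = max(curve$a340) - min(curve$a340))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/progress_curve_rates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Initial rates extracted from simulated progress curves:\n")
print(tab, digits = 4)
cat(sprintf("\nMax relative error vs the rate law: %.2e (slope window 10 s)\n",
            max(tab$relative_error)))
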