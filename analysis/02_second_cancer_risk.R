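#!/usr/bin/env Rscript
# Neutron second-cancer risk: combined bladder + rectum lifetime attributable
# risk for the standard-of-care (brass aperture) and MLC-only plans, from the
# bundled Monte Carlo organ neutron-dose tables, plus the per-organ dose
# differences between the plans.

library(hypofrac)
dir.create("results", showWarnings = FALSE)

soc <- neutron_dose_fixture("soc")
mlc <- neutron_dose_fixture("mlc_only")

risk_soc <- combined_risk(soc)
risk_mlc <- combined_risk(mlc)
cmp <- compare_plan_doses(soc, mlc)

report <- data.frame(
  plan = c("soc", "mlc_only"),
  bladder_risk_pct = c(attr(risk_soc, "per_organ")["bladder"],
                       attr(risk_mlc, "per_organ")["bladder"]),
  rectum_risk_pct = c(attr(risk_soc, "per_organ")["rectum"],
                      attr(risk_mlc, "per_organ")["rectum"]),
  combined_risk_pct = c(as.numeric(risk_soc), as.numeric(risk_mlc))
)
write.csv(report, "results/neutron_risk.csv", row.names = FALSE, quote = FALSE)
write.csv(cmp$per_organ, "results/neutron_dose_deltas.csv",
          row.names = FALSE, quote = FALSE)

cat("Lifetime attributable risk of second cancer from stray neutrons\n")
cat("(bladder 0.66 %/Sv, rectum 0.19 %/Sv after the 0.2 colon mass fraction):\n\n")
print(report, row.names = FALSE)
cat(sprintf("\nBoth plans round to %.2f%%: replacing the custom aperture with an\n",
            as.numeric(risk_soc)))
cat("MLC shifts neutron dose from external (treatment head) to internal\n")
cat("(in-patient) production but leaves the total nearly unchanged -- the\n")
cat(sprintf("largest per-organ total difference is %d mSv (prostate).\n",
            round(cmp$max_abs_total_delta_mSv)))
cat("\nWrote results/neutron_risk.csv, results/neutron_dose_deltas.csv\n")
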