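#!/usr/bin/env Rscript
# Unreimbursed patient cost savings from hypofractionation: 25 fractions
# instead of the 44-fraction standard of care, under a Monday-start weekday
# treatment calendar with weekends counted inside the delivery span.

library(hypofrac)
library(jsonlite)
dir.create("results", showWarnings = FALSE)

std <- treatment_calendar_days(44)
hyp <- treatment_calendar_days(25)
cat(sprintf("44 fx: %d delivery days (+5 planning = %d total)\n",
            std$delivery_span_days, std$total_days))
cat(sprintf("25 fx: %d delivery days (+5 planning = %d total)\n",
            hyp$delivery_span_days, hyp$total_days))

s <- savings(n_standard = 44, n_hypo = 25)
print(s)
cat(sprintf("\nThe $%.0f wage figure uses $%.0f/day, a $52,100 median household\n",
            s$wages_usd, annual_wage_to_daily(52100, "workday")))
cat("income over the ~260 working days of a year.\n")

write_json(list(days_saved = s$days_saved,
                meals_usd = as.list(setNames(s$meals_usd, c("low", "high"))),
                lodging_usd = as.list(setNames(s$lodging_usd, c("low", "high"))),
                wages_usd = s$wages_usd),
           "results/cost_savings.json", auto_unbox = TRUE, digits = NA)
cat("\nWrote results/cost_savings.json\n")
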