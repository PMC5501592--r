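#!/usr/bin/env Rscript
# The climate-fertility link: behaviour of the packaged logistic model and a
# parameter-recovery exercise on synthetic reproductive-status records.

library(batpva)

dir.create("results", showWarnings = FALSE)

b <- logistic_coefficients()
cat("Packaged coefficients: beta0", b[1], " betaT", b[2], " betaP", b[3], "\n")
cat(sprintf("Reference climate (10.85 C, 541 mm): Pr(reproductive) = %.4f\n",
            predict_fertility(b, 10.85, 541)))
cat(sprintf("+4 C at equal precipitation: %.4f (hotter years depress it)\n",
            predict_fertility(b, 14.85, 541)))
cat(sprintf("+100 mm at equal temperature: %.4f (wetter years raise it)\n\n",
            predict_fertility(b, 10.85, 641)))

# Recovery at the scale of the reference capture series (~190 records) and at
# a comfortable asymptotic scale (~5,000 records).
recover <- function(records_per_year, seed) {
  spec <- synthetic_spec(seed = seed, records_per_year = records_per_year,
                         T_jitter = 1.2, P_jitter = 90)
  fit <- fit_fertility_model(gen_repro_records(spec))
  data.frame(n = fit$n,
             beta0 = fit$coefficients[["beta0"]], se0 = fit$se[["beta0"]],
             betaT = fit$coefficients[["betaT"]], seT = fit$se[["betaT"]],
             betaP = fit$coefficients[["betaP"]], seP = fit$se[["betaP"]])
}
tab <- rbind(recover(15L, 1), recover(385L, 1))
cat("Parameter recovery from synthetic Bernoulli records (truth = packaged):\n")
print(tab, digits = 3, row.names = FALSE)
cat("\nAt ~190 records the climate slopes are weakly identified (wide SEs),\n")
cat("matching the caution warranted for a 13-year capture series; at ~5,000\n")
cat("records every coefficient sits within a standard error or two of truth.\n")

write_table_csv(tab, "results/fit_recovery.csv")
cat("\nWrote results/fit_recovery.csv\n")
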