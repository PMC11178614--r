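#!/usr/bin/env Rscript
# Prognostic analysis on a simulated cohort: Kaplan-Meier and inverse-KM
# follow-up, log-rank on median-dichotomized MTV/TLG, univariable and
# multivariable Cox models, and ROC with Youden cut points for the 2-year
# outcome.

suppressPackageStartupMessages(library(marrowquant))

seed <- 20260903L
cc <- cohort_config(n_subjects = 200, seed = seed)
cohort <- generate_cohort(cc)
cohort$iss <- iss_stage(cohort$b2m_mg_l, cohort$albumin_g_dl)
cohort$r_iss <- r_iss_stage(cohort$iss, cohort$cyto_highrisk == 1,
                            cohort$ldh_high == 1)
write_table(cohort, "results/simulated_cohort.csv", seed = seed, config = cc)

study <- run_survival_study(cohort, markers = c("mtv_ml", "tlg_g"),
                            horizon_months = 24, roc_mode = "binary")

cat(sprintf("n = %d subjects, %d events; KM median %.1f months; median\n",
            nrow(cohort), sum(cohort$event), study$km$median_months))
cat(sprintf("follow-up (inverse KM) %.1f months.\n\n",
            study$median_followup_months))
cat("Log-rank on median-dichotomized markers:\n")
print(study$logrank, digits = 3, row.names = FALSE)
cat("\nUnivariable Cox (HR per mL / per g):\n")
print(study$cox_univariable[, c("marker", "hr", "hr_lower", "hr_upper", "p")],
      digits = 6, row.names = FALSE)
cat("\nMultivariable Cox (adjusted for infiltration rate and cytogenetics):\n")
print(study$cox_multivariable[, c("marker", "covariate", "hr", "p")],
      digits = 6, row.names = FALSE)
cat("\n2-year outcome ROC with Youden-optimal cuts:\n")
print(study$roc, digits = 3, row.names = FALSE)

write_table(study$logrank, "results/logrank.csv", seed = seed)
write_table(study$cox_univariable, "results/cox_univariable.csv", seed = seed)
write_table(study$cox_multivariable, "results/cox_multivariable.csv",
            seed = seed)
write_table(study$roc, "results/roc_2yr.csv", seed = seed)
cat("\nTables written under results/.\n")
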