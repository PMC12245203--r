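#!/usr/bin/env Rscript
# Compare motor and blood outcomes across the three ager classes with the
# two-way GLM ANOVA (MAA status x sex, type-III SS) and Bonferroni-adjusted
# pairwise contrasts; report percent differences of accelerated vs
# decelerated agers and the correlation matrix of the acceleration measures.

suppressMessages(library(muscleclock))

cohort <- read_cohort("results/cohort.csv")
scores <- read.csv("results/scores.csv")
co <- cohort[match(scores$id, cohort$id), ]
cls <- factor(scores$class, c("decelerated", "normal", "accelerated"))

outcomes <- c("handgrip", "tug", "six_mwt", "smm", "asmm", "gait_speed",
              "wbc", "mcv", "rdw_pct", "ishii_probability")
rows <- lapply(outcomes, function(v) {
  y <- if (v %in% names(co)) co[[v]] else scores[[v]]
  an <- two_way_anova(y, cls, scores$sex)
  ov <- an$means[an$means$stratum == "overall", ]
  eff <- an$effects
  data.frame(outcome = v,
             mean_decelerated = ov$mean[ov$group == "decelerated"],
             sem_decelerated = ov$sem[ov$group == "decelerated"],
             mean_normal = ov$mean[ov$group == "normal"],
             mean_accelerated = ov$mean[ov$group == "accelerated"],
             sem_accelerated = ov$sem[ov$group == "accelerated"],
             pct_accel_vs_decel = round(percent_difference(
               ov$mean[ov$group == "decelerated"],
               ov$mean[ov$group == "accelerated"])),
             F_status = eff$F[eff$term == "status"],
             p_status = eff$p[eff$term == "status"],
             F_sex = eff$F[eff$term == "sex"],
             p_sex = eff$p[eff$term == "sex"],
             F_interaction = eff$F[eff$term == "status:sex"],
             p_interaction = eff$p[eff$term == "status:sex"],
             p_adj_decel_vs_accel = an$pairwise$adj_p[
               an$pairwise$stratum == "overall" &
                 an$pairwise$contrast == "decelerated vs accelerated"])
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/group_comparison.csv", row.names = FALSE)

cat("Outcomes differing across ager classes (status p < 0.05):\n")
sig <- tab[tab$p_status < 0.05, c("outcome", "pct_accel_vs_decel",
                                  "F_status", "p_status")]
print(sig, row.names = FALSE, digits = 3)

wbc_men <- two_way_anova(co$wbc[scores$sex == "M"],
                         cls[scores$sex == "M"],
                         rep("M", sum(scores$sex == "M")))
m <- wbc_men$means
cat(sprintf("\nWBC in men, decelerated vs accelerated: %.2f vs %.2f (%+d%%)\n",
            m$mean[m$group == "decelerated"],
            m$mean[m$group == "accelerated"],
            round(percent_difference(m$mean[m$group == "decelerated"],
                                     m$mean[m$group == "accelerated"]))))

corrs <- pearson_correlations(
  data.frame(maa = scores$maa, phenoaa = scores$phenoaa,
             ishii_probability = scores$ishii_probability,
             mortality_risk_10y = scores$mortality_risk_10y),
  stratify_by = scores$sex)
cat("\nCorrelation matrix of the acceleration measures (overall):\n")
print(round(corrs$overall$r, 3))
jsonlite::write_json(
  lapply(corrs, function(z) list(r = as.data.frame(z$r),
                                 p = as.data.frame(z$p),
                                 n = as.data.frame(z$n))),
  "results/correlations.json", auto_unbox = TRUE, digits = NA)
cat("\nWrote results/group_comparison.csv and results/correlations.json\n")
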