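#!/usr/bin/env Rscript
# Published risk scores on the simulated cohort: the Ishii sarcopenia chart
# score with its probability (high risk above 105 points for men, 120 for
# women) and the Levine PhenoAge with its residual acceleration (PhenoAA).

suppressMessages(library(muscleclock))

cohort <- read_cohort("results/cohort.csv")
maa <- read.csv("results/maa.csv")
co <- cohort[match(maa$id, cohort$id), ]

ish <- ishii_score(co$age, co$handgrip, co$calf_circumference, co$sex)
ph <- phenoage(co, co$age)

scores <- data.frame(maa[, c("id", "sex", "age", "predicted", "maa", "class")],
                     ishii_score = ish$score,
                     ishii_probability = ish$probability,
                     ishii_high_risk = ish$high_risk,
                     phenoage = ph$phenoage,
                     mortality_risk_10y = ph$mortality_risk_10y,
                     phenoaa = pheno_age_acceleration(ph$phenoage, co$age))
write.csv(scores, "results/scores.csv", row.names = FALSE)

cls <- factor(scores$class, c("decelerated", "normal", "accelerated"))
cat("Mean Ishii sarcopenia probability by ager class:\n")
print(round(tapply(scores$ishii_probability, cls, mean), 3))
cat(sprintf("High-risk flags: %d of %d participants\n",
            sum(scores$ishii_high_risk), nrow(scores)))
cat(sprintf("PhenoAge vs chronological age: r = %.2f\n",
            cor(scores$phenoage, scores$age)))
cat(sprintf("MAA vs PhenoAA: r = %.2f (independent residual clocks)\n",
            cor(scores$maa, scores$phenoaa)))
cat("Wrote results/scores.csv\n")
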