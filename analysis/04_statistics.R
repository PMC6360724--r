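#!/usr/bin/env Rscript
# Step 4 — inferential statistics.
#
# Repeated-measures ANOVA with Greenhouse-Geisser correction and Bonferroni
# pairwise comparisons per kinematic variable (navicular drop over the three
# first-position conditions), stepwise regression of foot abduction on the
# candidate pronation strategies per condition, and Pearson correlations of
# hindfoot eversion with the seated external tibiofemoral rotation
# measurements.

suppressMessages(library(turnoutfoot))

values <- read.delim("results/measured_values.tsv")
knee <- read.delim("results/measured_knee_er.tsv")
rep <- run_cohort(values, knee)

anova_tab <- do.call(rbind, lapply(names(rep$anova), function(v) {
  a <- rep$anova[[v]]
  data.frame(variable = v, F = a$F, df_num = a$df_num, df_den = a$df_den,
             epsilon_gg = a$epsilon_gg, p_gg = a$p_gg)
}))
pairwise_tab <- do.call(rbind, lapply(names(rep$anova), function(v)
  cbind(variable = v, rep$anova[[v]]$pairwise)))
reg_tab <- do.call(rbind, lapply(names(rep$regression), function(cn) {
  r <- rep$regression[[cn]]
  data.frame(condition = cn,
             selected = paste(r$selected, collapse = "+"),
             r_squared = r$r_squared, adj_r_squared = r$adj_r_squared,
             F = r$F, df_num = r$df_num, df_den = r$df_den,
             p = r$p_overall)
}))
write.table(anova_tab, "results/rm_anova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pairwise_tab, "results/pairwise_bonferroni.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(reg_tab, "results/stepwise_regression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rep$correlations, "results/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(rep)
cat("\nCorrelations of hindfoot eversion with seated knee external rotation:\n")
print(rep$correlations, row.names = FALSE)
d <- rep$deltas
hf <- d$delta[d$variable == "hindfoot_eversion" &
                d$contrast == "functional_minus_natural"]
cat(sprintf("\nRecovered functional-natural hindfoot eversion: %.1f deg\n", hf))
cat("Wrote results/rm_anova.tsv, pairwise_bonferroni.tsv, stepwise_regression.tsv, correlations.tsv\n")
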