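#!/usr/bin/env Rscript
# Step 3 — condition summaries and clinical classifications.
#
# Builds the per-condition summary (mean, SE, 95% CI over subjects) from the
# recovered kinematics, the pairwise condition deltas, and the two clinical
# classifications: hallux-valgus severity from the first-MTPJ transverse
# angle and arch-height stability from navicular drop.

suppressMessages(library(turnoutfoot))

values <- read.delim("results/measured_values.tsv")
summary <- summarise_conditions(values)
deltas <- table2_deltas(summary)
write.table(summary, "results/condition_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(deltas, "results/condition_deltas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cls <- values[values$variable %in% c("mtpj_abduction", "navicular_drop_mm"), ]
cls$class <- NA_character_
i <- cls$variable == "mtpj_abduction"
cls$class[i] <- as.character(classify_hallux_valgus(cls$value[i]))
cls$class[!i] <- as.character(classify_navicular(cls$value[!i]))
write.table(cls, "results/classifications.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Condition summary (mean (SE)):\n")
for (v in unique(as.character(summary$variable))) {
  row <- summary[summary$variable == v, ]
  cat(sprintf("  %-20s %s\n", v,
              paste(sprintf("%s %.1f (%.1f)", row$condition, row$mean,
                            row$se), collapse = " | ")))
}
hv <- table(cls$class[i & cls$condition == "forced"])
cat("Hallux-valgus classes in forced turnout:",
    paste(names(hv), hv, collapse = ", "), "\n")
ns <- table(cls$class[!i & cls$condition == "saute"])
cat("Arch stability classes during sautes:",
    paste(names(ns), ns, collapse = ", "), "\n")
cat("Wrote results/condition_summary.tsv, condition_deltas.tsv, classifications.tsv\n")
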