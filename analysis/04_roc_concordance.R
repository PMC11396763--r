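#!/usr/bin/env Rscript
# Tabulate the classification characteristics of the cross-validated
# patterns — AUC, Youden threshold, sensitivity, specificity, PPV, NPV —
# and the two-modality concordance combination.

library(jsonlite)

report <- fromJSON("results/study_report.json", simplifyVector = FALSE)

rows <- lapply(report$modalities, function(b) {
  if (is.null(b$roc)) {
    return(data.frame(modality = b$modality, auc = NA, threshold = NA,
                      sensitivity = NA, specificity = NA, ppv = NA,
                      npv = NA))
  }
  data.frame(modality = b$modality, auc = round(b$roc$auc, 2),
             threshold = signif(b$roc$threshold, 3),
             sensitivity = b$roc$sensitivity,
             specificity = b$roc$specificity,
             ppv = b$roc$ppv, npv = b$roc$npv)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/roc_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("ROC table -> results/roc_table.tsv\n\n")
print(tab, row.names = FALSE)

cc <- report$concordance
if (!is.null(cc)) {
  m <- cc$metrics_within_concordant
  conc <- data.frame(
    pair = paste(unlist(cc$pair), collapse = "+"),
    concordance_percent = cc$concordance_percent,
    n_concordant = length(cc$concordant_ids),
    sensitivity = m$sensitivity, specificity = m$specificity,
    ppv = m$ppv, npv = m$npv)
  write.table(conc, "results/concordance_table.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("\nconcordance table -> results/concordance_table.tsv\n")
  print(conc, row.names = FALSE)
  cat("\nSubjects on whom both modalities agree can be phenotyped with",
      "higher confidence; discordant subjects receive no call.\n")
} else {
  cat("\nno concordance pair available (fewer than two modalities with",
      "classifiable patterns)\n")
}
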