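#!/usr/bin/env Rscript
# Per-genus contribution to the arginine/ornithine/citrulline pathways,
# stratified by week-12 PTSD and depression diagnosis groups
# (PTSD raw score > 31; depression t-score >= 60).
#
# Reads results/ from 01_simulate.R; writes pathway_contributions.csv.

library(gutapns)

pathways <- read_pathway_table("results/synthetic_pw_pathways.tsv")
cohort <- read.csv("results/synthetic_cohort.csv", stringsAsFactors = FALSE)
panel <- read.csv("results/synthetic_outcomes.csv", stringsAsFactors = FALSE)

wk12 <- panel[panel$week == 12, ]
sample_of <- cohort$sample_id[match(wk12$subject_id, cohort$subject_id)]
group_sets <- list(
  ptsd = setNames(ifelse(diagnose_ptsd(wk12$pcl5_raw),
                         "PTSD Raw Score > 31", "PTSD Raw Score <= 31"),
                  sample_of),
  depression = setNames(ifelse(diagnose_depression(wk12$promis_t),
                               "Depression t-score >= 60",
                               "Depression t-score < 60"),
                        sample_of))

ids <- setdiff(unique(sub(":.*$", "", sub("\\|.*$", "", pathways$row_keys))),
               "UNMAPPED")
tabs <- list()
for (lbl in names(group_sets)) {
  for (id in ids) {
    fr <- taxon_fractions(pathways, id, rank = "genus")
    tabs[[paste(lbl, id)]] <- group_contribution(fr, group_sets[[lbl]])
  }
}
tab <- do.call(rbind, tabs)
rownames(tab) <- NULL
write.csv(tab, "results/pathway_contributions.csv", row.names = FALSE)

cat("Genus contributions (percent) for", length(ids),
    "pathways x", length(group_sets), "diagnosis stratifications\n")
print(utils::head(tab, 8), row.names = FALSE)
cat("Every (pathway, group) column sums to 100 within rounding:",
    all(abs(tapply(tab$percent, paste(tab$pathway_id, tab$group), sum) - 100)
        <= 0.1), "\n")
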