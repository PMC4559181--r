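#!/usr/bin/env Rscript
# Step 4 — protocol comparison at the expression level.
#
# Filters to expressed genes (max CPM > 1 across all eight samples),
# TMM-normalizes, and compares stranded vs non-stranded profiles:
# sample-sample correlations on log2(RPKM + 0.5), per-gene fold-change
# discordance (Welch t on log2(CPM + 0.5), BH-adjusted; discordant =
# |FC| > 1.5 and adjusted p < 0.05), a gene-type breakdown crossed with
# opposite-strand overlap, and the enrichment tests (two-proportion and
# 2x2 chi-square with continuity correction).

suppressMessages(library(strandlap))

res_dir <- "results/compare"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

if (!file.exists("results/counts/counts.tsv")) {
  stop("run analysis/03_count_fragments.R first", call. = FALSE)
}
ann <- parse_gtf("results/study/annotation.gtf")
tab <- read.delim("results/counts/counts.tsv", check.names = FALSE)
counts <- as.matrix(tab[, -1])
rownames(counts) <- tab$gene_id
grp <- ifelse(startsWith(colnames(counts), "NS"), "NS", "S")

keep <- expressed_filter(counts)
cat(sprintf("%d of %d genes expressed (max CPM > 1)\n", length(keep), nrow(counts)))

lens <- setNames(ann$genes$exonic_length, ann$genes$gene_id)
lrpkm <- rpkm(counts, lens, log = TRUE)[keep, , drop = FALSE]
cc <- correlation_matrix(lrpkm)
write.table(data.frame(sample = rownames(cc), round(cc, 4), check.names = FALSE),
            file.path(res_dir, "correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
within <- c(cc[grp == "S", grp == "S"][upper.tri(diag(sum(grp == "S")))],
            cc[grp == "NS", grp == "NS"][upper.tri(diag(sum(grp == "NS")))])
cross <- as.vector(cc[grp == "S", grp == "NS"])
cat(sprintf("correlation: within-protocol %.3f, cross-protocol %.3f\n",
            mean(within), mean(cross)))

expr_tab <- data.frame(gene_id = rownames(lrpkm), round(lrpkm, 4),
                       check.names = FALSE)
write.table(expr_tab, file.path(res_dir, "expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rep_tab <- discordance(counts[, grp == "S"], counts[, grp == "NS"])
write.table(data.frame(rep_tab[1], round(rep_tab[2:4], 6), rep_tab[5]),
            file.path(res_dir, "discordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("discordant genes: %d of %d expressed (fold change > 1.5, adj. p < 0.05)\n",
            sum(rep_tab$discordant), nrow(rep_tab)))

pairs_opp <- find_overlapping_pairs(ann, "opposite_strand")
bt <- breakdown_by_type(rep_tab, ann, pairs_opp)
write.table(bt, file.path(res_dir, "breakdown.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(bt, row.names = FALSE)

# enrichment of each category among discordant genes vs the global rate,
# and dependence of discordance on opposite-strand overlap; cells are small
# at desk scale, so the chi-square approximation advisories are expected
# and suppressed here
tot <- bt[bt$gene_type == "Total", ]
tests <- list()
for (gt in setdiff(bt$gene_type, "Total")) {
  row <- bt[bt$gene_type == gt, ]
  pt <- suppressWarnings(
    two_proportion_test(row$n_discordant, row$n_expressed,
                        tot$n_discordant - row$n_discordant,
                        tot$n_expressed - row$n_expressed))
  tests[[paste0("prop_", gt)]] <- list(statistic = pt$statistic,
                                       p_value = pt$p_value,
                                       p_display = pt$p_display)
  m <- matrix(c(row$de_overlap_no, row$de_overlap_yes,
                row$nonde_overlap_no, row$nonde_overlap_yes), 2, byrow = TRUE)
  if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
    cs <- suppressWarnings(chi_square_independence(m))
    tests[[paste0("chisq_overlap_", gt)]] <- list(statistic = cs$statistic,
                                                  p_value = cs$p_value,
                                                  p_display = cs$p_display)
  }
}
jsonlite::write_json(tests, file.path(res_dir, "tests.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("expression, discordance, breakdown and tests -> %s/\n", res_dir))
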