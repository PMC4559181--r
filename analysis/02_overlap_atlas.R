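#!/usr/bin/env Rscript
# Step 2 — strand-stratified overlap atlas.
#
# Quantifies gene overlap in an annotation at three levels: genes with at
# least one overlapping partner (per strand relation), shared exonic bases
# as a fraction of strand-specific transcribed bases, and the per-pair
# overlap ratio (shared bases / shorter gene's exonic length, 1 = full
# containment). Defaults to the simulated study annotation from step 1; an
# alternative GTF (e.g. a genome annotation) can be passed with --gtf.
#
# Usage: Rscript analysis/02_overlap_atlas.R [--gtf file.gtf[.gz]] [--bins 20]

suppressMessages(library(strandlap))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
gtf <- get_opt("--gtf", "results/study/annotation.gtf")
n_bins <- as.integer(get_opt("--bins", "20"))
out_dir <- "results/atlas"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

if (!file.exists(gtf)) {
  cat("study annotation not found; generating it first\n")
  ann <- generate_annotation(default_study_config(n_fragments = 0, seed = 1))
} else {
  ann <- parse_gtf(gtf)
}
cat(sprintf("annotation: %d genes (%s)\n", nrow(ann$genes), ann$meta$source))

os <- overlap_summary(ann, n_bins = n_bins)
print(os)

for (rel in c("same_strand", "opposite_strand")) {
  p <- os$pairs[os$pairs$relation == rel,
                c("gene_a", "gene_b", "overlap_bases",
                  "shorter_exonic_length", "overlap_ratio")]
  f <- file.path(out_dir, paste0("pairs_", sub("_strand", "", rel), ".tsv"))
  write.table(p, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rd <- if (rel == "same_strand") os$ratio_same else os$ratio_opposite
  if (!is.null(rd)) {
    write.table(rd$hist, file.path(out_dir, paste0("ratio_hist_", sub("_strand", "", rel), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
write.table(os$gene_level, file.path(out_dir, "gene_level.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(os$base_level, file.path(out_dir, "base_level.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

gw <- os$gene_level[os$gene_level$chrom == "genome", ]
bw <- os$base_level[os$base_level$chrom == "genome", ]
summary <- list(
  n_genes = nrow(ann$genes),
  n_pairs = as.list(os$n_pairs),
  containment = as.list(os$containment),
  pct_gene = list(same = gw$pct_gene_same, opposite = gw$pct_gene_opposite),
  pct_base = list(same = bw$pct_base_same, opposite = bw$pct_base_opposite),
  median_ratio = list(
    same = if (!is.null(os$ratio_same)) os$ratio_same$median,
    opposite = if (!is.null(os$ratio_opposite)) os$ratio_opposite$median))
jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA, null = "null")
cat(sprintf("pair tables, ratio histograms and summary.json -> %s/\n", out_dir))
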