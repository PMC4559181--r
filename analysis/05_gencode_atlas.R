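#!/usr/bin/env Rscript
# Step 5 (optional, genome scale) — overlap atlas of a human annotation.
#
# Runs the full strand-stratified overlap atlas on a genome annotation,
# e.g. the Gencode Release 19 GTF. The file is not bundled (it is ~40 MB
# compressed) and must be downloaded once, e.g.:
#
#   curl -o scratch/gencode.v19.annotation.gtf.gz \
#     https://ftp.ebi.ac.uk/pub/databases/gencode/Gencode_human/release_19/gencode.v19.annotation.gtf.gz
#
# Usage: Rscript analysis/05_gencode_atlas.R [path/to/annotation.gtf.gz]

suppressMessages(library(strandlap))

args <- commandArgs(trailingOnly = TRUE)
gtf <- if (length(args)) args[1] else "scratch/gencode.v19.annotation.gtf.gz"
if (!file.exists(gtf)) {
  stop(sprintf("annotation not found: %s (download it first; see the header of this script)", gtf),
       call. = FALSE)
}

cat(sprintf("parsing %s ...\n", gtf))
ann <- suppressWarnings(parse_gtf(gtf))
cat(sprintf("parsed %d genes\n", nrow(ann$genes)))

# restrict to the primary chromosomes before computing overlap statistics
main_chroms <- paste0("chr", c(1:22, "X", "Y", "M"))
keep <- ann$genes$gene_id[ann$genes$chrom %in% main_chroms]
ex <- as.data.frame(ann$exons)
ex <- data.frame(chrom = as.character(ex$seqnames), start = ex$start,
                 end = ex$end, strand = as.character(ex$strand),
                 gene_id = ex$gene_id,
                 gene_name = ann$genes$gene_name[match(ex$gene_id, ann$genes$gene_id)],
                 gene_type = ann$genes$gene_type[match(ex$gene_id, ann$genes$gene_id)])
ann <- annotation_set(ex[ex$gene_id %in% keep, ], source = basename(gtf))

out_dir <- "results/gencode_atlas"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
os <- overlap_summary(ann)
print(os)

for (rel in c("same_strand", "opposite_strand")) {
  p <- os$pairs[os$pairs$relation == rel,
                c("gene_a", "gene_b", "overlap_bases",
                  "shorter_exonic_length", "overlap_ratio")]
  write.table(p, file.path(out_dir, paste0("pairs_", sub("_strand", "", rel), ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(os$gene_level, file.path(out_dir, "gene_level.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(os$base_level, file.path(out_dir, "base_level.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(annotation_summary(ann), file.path(out_dir, "annotation_summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("atlas tables -> %s/\n", out_dir))
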