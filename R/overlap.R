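#' Overlapping gene pairs, stratified by strand relation
#'
#' Finds every unordered pair of distinct genes on the same chromosome whose
#' flattened exons share at least one genomic base, in the requested strand
#' relation. For each pair the number of shared exonic bases, the exonic
#' length of the shorter gene, and their ratio (1 = the shorter gene's
#' exonic bases are fully contained in the other's) are reported.
#' Unstranded ("*") genes participate in neither relation.
#'
#' @param annotation an [AnnotationSet].
#' @param relation `"same_strand"`, `"opposite_strand"`, or `"both"` to get
#'   the two relations in one table.
#' @return data.frame with columns `gene_a`, `gene_b` (lexicographic order),
#'   `relation`, `overlap_bases`, `exonic_length_a`, `exonic_length_b`,
#'   `shorter_exonic_length`, `overlap_ratio`.
#' @examples
#' ann <- annotation_set(data.frame(
#'   chrom = "chr1", start = c(1, 51), end = c(100, 150),
#'   strand = c("+", "+"), gene_id = c("A", "B")))
#' find_overlapping_pairs(ann, "same_strand")  # 50 shared bases, ratio 0.5
#' @export
find_overlapping_pairs <- function(annotation,
                                   relation = c("same_strand", "opposite_strand", "both")) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  relation <- match.arg(relation)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      relation = character(), overlap_bases = integer(),
                      exonic_length_a = integer(), exonic_length_b = integer(),
                      shorter_exonic_length = integer(), overlap_ratio = numeric(),
                      stringsAsFactors = FALSE)
  flat <- annotation$flat
  gid <- S4Vectors::mcols(flat)$gene_id
  gstrand <- as.character(GenomicRanges::strand(flat))
  keep <- gstrand != "*"
  flat <- flat[keep]; gid <- gid[keep]; gstrand <- gstrand[keep]
  if (length(flat) == 0L) return(empty)

  hits <- GenomicRanges::findOverlaps(flat, flat, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  sel <- gid[q] < gid[s]  # distinct genes, canonical (lexicographic) order once
  q <- q[sel]; s <- s[sel]
  if (length(q) == 0L) return(empty)

  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(flat[q]),
                                          IRanges::ranges(flat[s])))
  rel <- ifelse(gstrand[q] == gstrand[s], "same_strand", "opposite_strand")
  dt <- data.table::data.table(gene_a = gid[q], gene_b = gid[s], relation = rel, w = w)
  if (relation != "both") {
    keep_rel <- dt[["relation"]] == relation  # evaluate outside the dt frame
    dt <- dt[keep_rel]
  }
  if (nrow(dt) == 0L) return(empty)
  # flattened exons are disjoint within each gene, so the per-exon-pair
  # intersections partition the shared bases: summing is exact
  pairs <- dt[, .(overlap_bases = as.integer(sum(w))), by = .(gene_a, gene_b, relation)]

  len <- setNames(annotation$genes$exonic_length, annotation$genes$gene_id)
  pairs[, `:=`(exonic_length_a = as.integer(len[gene_a]),
               exonic_length_b = as.integer(len[gene_b]))]
  pairs[, shorter_exonic_length := pmin(exonic_length_a, exonic_length_b)]
  pairs[, overlap_ratio := overlap_bases / shorter_exonic_length]
  out <- as.data.frame(pairs[order(gene_a, gene_b)])
  rownames(out) <- NULL
  out
}

#' Gene-level overlap summary
#'
#' A gene counts as "overlapping" in a relation if it participates in at
#' least one overlapping pair of that relation. Percentages are over all
#' parsed genes (unstranded genes are in the denominator but can never be
#' pair members). Reported per chromosome plus a `genome` row.
#'
#' @param annotation an [AnnotationSet].
#' @param pairs optional precomputed table from
#'   [find_overlapping_pairs()] with `relation = "both"`.
#' @return data.frame with `chrom`, `n_genes`, `n_overlapping_same`,
#'   `n_overlapping_opposite`, `pct_gene_same`, `pct_gene_opposite`.
#' @export
gene_level_summary <- function(annotation, pairs = NULL) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  if (is.null(pairs)) pairs <- find_overlapping_pairs(annotation, "both")
  g <- annotation$genes
  same_ids <- unique(c(pairs$gene_a[pairs$relation == "same_strand"],
                       pairs$gene_b[pairs$relation == "same_strand"]))
  opp_ids <- unique(c(pairs$gene_a[pairs$relation == "opposite_strand"],
                      pairs$gene_b[pairs$relation == "opposite_strand"]))
  per_chrom <- function() {
    dt <- data.table::data.table(
      chrom = g$chrom,
      same = g$gene_id %in% same_ids,
      opp = g$gene_id %in% opp_ids)
    dt[, .(n_genes = .N, n_overlapping_same = sum(same),
           n_overlapping_opposite = sum(opp)), by = chrom]
  }
  by_chr <- per_chrom()
  genome <- data.table::data.table(chrom = "genome",
                                   n_genes = nrow(g),
                                   n_overlapping_same = length(same_ids),
                                   n_overlapping_opposite = length(opp_ids))
  out <- rbind(by_chr[order(chrom)], genome)
  out[, pct_gene_same := 100 * n_overlapping_same / pmax(n_genes, 1L)]
  out[, pct_gene_opposite := 100 * n_overlapping_opposite / pmax(n_genes, 1L)]
  as.data.frame(out)
}

#' Nucleotide-level overlap summary
#'
#' Works on strand-specific exonic bases: the denominator is the number of
#' bases in the union of flattened exons, counted separately per strand
#' (a base exonic on both strands contributes twice). The same-strand
#' numerator is the number of strand-specific bases covered by two or more
#' genes of that strand. The opposite-strand numerator is the number of
#' genomic bases exonic on both strands, counted once per strand (doubled)
#' by default, so it reads as the fraction of transcribed strand-bases that
#' face an antisense partner; `count_once = TRUE` counts each such genomic
#' base once instead.
#'
#' @param annotation an [AnnotationSet].
#' @param count_once logical; see above.
#' @return data.frame with `chrom` (plus a `genome` row),
#'   `strand_bases` (denominator), `multi_same_bases`, `opposite_bases`
#'   (numerators), `pct_base_same`, `pct_base_opposite`.
#' @export
base_level_summary <- function(annotation, count_once = FALSE) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  flat <- annotation$flat
  st <- as.character(GenomicRanges::strand(flat))
  chroms <- sort(unique(as.character(GenomicRanges::seqnames(flat))))
  rows <- lapply(chroms, function(ch) {
    on_ch <- as.character(GenomicRanges::seqnames(flat)) == ch
    res <- c(strand_bases = 0, multi_same_bases = 0, opposite_bases = 0)
    union_by_strand <- list()
    for (s in c("+", "-")) {
      ex <- IRanges::ranges(flat[on_ch & st == s])
      u <- IRanges::reduce(ex)
      union_by_strand[[s]] <- u
      res["strand_bases"] <- res["strand_bases"] + sum(IRanges::width(u))
      if (length(ex)) {
        cov <- IRanges::coverage(ex)  # per-gene exons disjoint => depth = #genes
        res["multi_same_bases"] <- res["multi_same_bases"] +
          sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 2L])
      }
    }
    both <- IRanges::intersect(union_by_strand[["+"]], union_by_strand[["-"]])
    res["opposite_bases"] <- sum(IRanges::width(both)) * if (count_once) 1 else 2
    data.frame(chrom = ch, t(res), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), strand_bases = numeric(),
                      multi_same_bases = numeric(), opposite_bases = numeric())
  }
  genome <- data.frame(chrom = "genome", strand_bases = sum(out$strand_bases),
                       multi_same_bases = sum(out$multi_same_bases),
                       opposite_bases = sum(out$opposite_bases))
  out <- rbind(out, genome)
  denom <- pmax(out$strand_bases, 1)
  out$pct_base_same <- 100 * out$multi_same_bases / denom
  out$pct_base_opposite <- 100 * out$opposite_bases / denom
  rownames(out) <- NULL
  out
}

#' Count fully contained genes
#'
#' Counts, per strand relation, the distinct genes that are the shorter
#' member of at least one pair with overlap ratio exactly 1 (all of the
#' gene's exonic bases lie inside the partner's). A gene contained in
#' several hosts counts once; when both members of a ratio-1 pair have equal
#' exonic lengths (identical base sets) both count as contained.
#'
#' @param pairs pair table from [find_overlapping_pairs()] (any relation mix).
#' @return named integer vector `c(n_contained_same, n_contained_opposite)`.
#' @export
containment_counts <- function(pairs) {
  count_rel <- function(rel) {
    p <- pairs[pairs$relation == rel & pairs$overlap_bases == pairs$shorter_exonic_length, ,
               drop = FALSE]
    if (nrow(p) == 0L) return(0L)
    contained <- c(p$gene_a[p$exonic_length_a == p$shorter_exonic_length],
                   p$gene_b[p$exonic_length_b == p$shorter_exonic_length])
    length(unique(contained))
  }
  c(n_contained_same = count_rel("same_strand"),
    n_contained_opposite = count_rel("opposite_strand"))
}

#' Distribution of pair overlap ratios
#'
#' Histogram over \[0, 1\] with `n_bins` equal-width right-closed bins, the
#' empirical CDF evaluated at the bin edges, and the median (50th
#' percentile, linear interpolation).
#'
#' @param ratios numeric vector of overlap ratios in \[0, 1\], or a pair
#'   table from [find_overlapping_pairs()] (its `overlap_ratio` column is
#'   used).
#' @param n_bins number of bins (default 20).
#' @return list with `hist` (data.frame `bin_lo`, `bin_hi`, `count`),
#'   `cdf` (data.frame `edge`, `cdf`), `median`, `n`.
#' @export
ratio_distribution <- function(ratios, n_bins = 20L) {
  if (is.data.frame(ratios)) ratios <- ratios$overlap_ratio
  if (length(ratios) == 0L) stop2("no pairs")
  stopifnot(is_count1(n_bins), all(ratios >= 0 & ratios <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- graphics::hist(ratios, breaks = edges, plot = FALSE,
                           right = TRUE, include.lowest = TRUE)$counts
  list(
    hist = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                      count = counts),
    cdf = data.frame(edge = edges, cdf = ecdf(ratios)(edges)),
    median = unname(quantile(ratios, 0.5, type = 7)),
    n = length(ratios))
}

#' Full strand-stratified overlap atlas
#'
#' Composes [find_overlapping_pairs()], [gene_level_summary()],
#' [base_level_summary()], [containment_counts()] and
#' [ratio_distribution()] into one summary object.
#'
#' @param annotation an [AnnotationSet].
#' @param n_bins histogram bins for the ratio distributions.
#' @param count_once passed to [base_level_summary()].
#' @return an `OverlapSummary` list: `pairs` (both relations),
#'   `gene_level`, `base_level`, `containment`, `ratio_same`,
#'   `ratio_opposite` (NULL when a relation has no pairs), and `n_pairs`.
#' @export
overlap_summary <- function(annotation, n_bins = 20L, count_once = FALSE) {
  pairs <- find_overlapping_pairs(annotation, "both")
  rs <- pairs$overlap_ratio[pairs$relation == "same_strand"]
  ro <- pairs$overlap_ratio[pairs$relation == "opposite_strand"]
  out <- list(
    pairs = pairs,
    gene_level = gene_level_summary(annotation, pairs),
    base_level = base_level_summary(annotation, count_once = count_once),
    containment = containment_counts(pairs),
    n_pairs = c(same_strand = length(rs), opposite_strand = length(ro)),
    ratio_same = if (length(rs)) ratio_distribution(rs, n_bins),
    ratio_opposite = if (length(ro)) ratio_distribution(ro, n_bins))
  class(out) <- "OverlapSummary"
  out
}

#' @export
print.OverlapSummary <- function(x, ...) {
  gw <- x$gene_level[x$gene_level$chrom == "genome", ]
  bw <- x$base_level[x$base_level$chrom == "genome", ]
  cat(sprintf("OverlapSummary: %d genes\n", gw$n_genes))
  cat(sprintf("  pairs: %d same-strand, %d opposite-strand\n",
              x$n_pairs[["same_strand"]], x$n_pairs[["opposite_strand"]]))
  cat(sprintf("  gene-level overlap: %.1f%% same, %.1f%% opposite\n",
              gw$pct_gene_same, gw$pct_gene_opposite))
  cat(sprintf("  base-level overlap: %.2f%% same, %.2f%% opposite\n",
              bw$pct_base_same, bw$pct_base_opposite))
  cat(sprintf("  contained genes: %d same, %d opposite\n",
              x$containment[["n_contained_same"]], x$containment[["n_contained_opposite"]]))
  if (!is.null(x$ratio_same))
    cat(sprintf("  median ratio same: %.3f\n", x$ratio_same$median))
  if (!is.null(x$ratio_opposite))
    cat(sprintf("  median ratio opposite: %.3f\n", x$ratio_opposite$median))
  invisible(x)
}
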