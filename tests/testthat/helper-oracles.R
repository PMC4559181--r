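# Brute-force oracles, deliberately written without GenomicRanges or
# data.table so they share no code path with the implementation.

# random annotation: n_genes genes on one chromosome, 1..3 exons each,
# random strands; coordinates < max_coord
rand_annotation <- function(n_genes, max_coord = 5000L, chrom = "chrT",
                            strands = c("+", "-")) {
  rows <- list()
  for (i in seq_len(n_genes)) {
    k <- sample(1:3, 1)
    st <- sort(sample.int(max_coord - 400L, k))
    w <- sample(30:300, k, replace = TRUE)
    rows[[i]] <- data.frame(chrom = chrom, start = st, end = pmin(st + w - 1L, max_coord),
                            strand = sample(strands, 1),
                            gene_id = sprintf("R%03d", i), stringsAsFactors = FALSE)
  }
  annotation_set(do.call(rbind, rows))
}

# boolean-array base coverage of a set of 1-based closed intervals
base_mask <- function(starts, ends, max_coord) {
  m <- logical(max_coord)
  for (j in seq_along(starts)) m[starts[j]:ends[j]] <- TRUE
  m
}

# per-gene exonic base masks for an AnnotationSet (single chromosome)
gene_masks <- function(ann, max_coord) {
  ex <- as.data.frame(ann$exons)
  out <- list()
  for (id in ann$genes$gene_id) {
    e <- ex[ex$gene_id == id, ]
    out[[id]] <- base_mask(e$start, e$end, max_coord)
  }
  out
}

# all-against-all pair finding on base masks
oracle_pairs <- function(ann, max_coord) {
  masks <- gene_masks(ann, max_coord)
  g <- ann$genes
  rows <- list()
  ids <- g$gene_id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (!(ids[i] < ids[j])) next
    if (g$chrom[i] != g$chrom[j]) next
    if (g$strand[i] == "*" || g$strand[j] == "*") next
    ov <- sum(masks[[ids[i]]] & masks[[ids[j]]])
    if (ov == 0) next
    la <- sum(masks[[ids[i]]]); lb <- sum(masks[[ids[j]]])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids[i], gene_b = ids[j],
      relation = if (g$strand[i] == g$strand[j]) "same_strand" else "opposite_strand",
      overlap_bases = ov, shorter = min(la, lb),
      ratio = ov / min(la, lb), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(gene_a = character(), gene_b = character(),
                                       relation = character(), overlap_bases = integer(),
                                       shorter = integer(), ratio = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$gene_a, out$gene_b), ]
}

# strand-specific base-level percentages on coverage arrays
oracle_base_level <- function(ann, max_coord, count_once = FALSE) {
  masks <- gene_masks(ann, max_coord)
  g <- ann$genes
  denom <- 0; multi <- 0
  union_s <- list()
  for (s in c("+", "-")) {
    ids <- g$gene_id[g$strand == s]
    cov <- integer(max_coord)
    for (id in ids) cov <- cov + masks[[id]]
    union_s[[s]] <- cov > 0
    denom <- denom + sum(cov > 0)
    multi <- multi + sum(cov >= 2)
  }
  both <- sum(union_s[["+"]] & union_s[["-"]])
  opp <- both * if (count_once) 1 else 2
  c(pct_same = 100 * multi / max(denom, 1), pct_opposite = 100 * opp / max(denom, 1))
}

# containment by explicit subset test on masks
oracle_containment <- function(ann, max_coord) {
  masks <- gene_masks(ann, max_coord)
  g <- ann$genes
  res <- c(same = 0L, opposite = 0L)
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "*") next
    for (rel in c("same", "opposite")) {
      found <- FALSE
      for (j in seq_len(nrow(g))) {
        if (i == j || g$chrom[i] != g$chrom[j] || g$strand[j] == "*") next
        same_rel <- g$strand[i] == g$strand[j]
        if ((rel == "same") != same_rel) next
        mi <- masks[[g$gene_id[i]]]; mj <- masks[[g$gene_id[j]]]
        if (sum(mi) > sum(mj)) next  # must be the shorter member
        if (!any(mi & !mj) && any(mi & mj)) { found <- TRUE; break }
      }
      if (found) res[rel] <- res[rel] + 1L
    }
  }
  res
}

# per-fragment exhaustive classification with plain arithmetic
oracle_classify <- function(frags, ann, cfg) {
  f <- frags$frags; bl <- frags$blocks
  ex <- as.data.frame(ann$flat)
  g <- ann$genes
  out <- character(nrow(f)); genes_hit <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    if (!f$unique[i] || (cfg$require_both_ends && !f$both_ends[i]) ||
        (cfg$discard_chimeric && f$chimeric[i])) {
      out[i] <- "filtered"; next
    }
    cand <- character()
    for (gi in seq_len(nrow(g))) {
      per_mate <- c(0, 0)
      for (m in 1:2) {
        b <- bl[bl$frag == i & bl$mate == m, ]
        e <- ex[ex$gene_id == g$gene_id[gi] &
                  ex$seqnames == (b$chrom[1] %||% ""), ]
        if (!nrow(b) || !nrow(e)) next
        for (r in seq_len(nrow(b))) for (q in seq_len(nrow(e))) {
          per_mate[m] <- per_mate[m] +
            max(0, min(b$end[r], e$end[q]) - max(b$start[r], e$start[q]) + 1)
        }
      }
      ov <- if (cfg$mate_overlap == "sum") sum(per_mate) else max(per_mate)
      if (ov < cfg$min_overlap_bases) next
      if (cfg$strand_mode == "reverse_stranded") {
        if (is.na(f$m1_strand[i]) || g$strand[gi] == "*" ||
            f$m1_strand[i] == g$strand[gi]) next
      }
      cand <- c(cand, g$gene_id[gi])
    }
    genes_hit[[i]] <- sort(cand)
    out[i] <- if (length(cand) == 0) "no_feature" else
      if (length(cand) == 1) "assigned" else "ambiguous"
  }
  list(category = out, candidates = genes_hit)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# textbook two-proportion chi-square with optional Yates correction
oracle_prop <- function(x1, n1, x2, n2, correct = TRUE) {
  p <- (x1 + x2) / (n1 + n2)
  e <- c(n1 * p, n1 * (1 - p), n2 * p, n2 * (1 - p))
  o <- c(x1, n1 - x1, x2, n2 - x2)
  cc <- if (correct) min(0.5, abs(x1 / n1 - x2 / n2) * n1 * n2 / (n1 + n2)) else 0
  stat <- sum((abs(o - e) - cc)^2 / e)
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Pearson chi-square on a 2x2 with Yates correction, direct formula
oracle_chisq <- function(tb, correct = TRUE) {
  e <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  d <- abs(tb - e)
  if (correct) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / e)
  c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# small GTF writer for fixtures (independent of write_gtf)
toy_gtf <- function(df, path) {
  lines <- sprintf('%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s";',
                   df$chrom, df$feature %||% "exon", df$start, df$end, df$strand,
                   df$gene_id, df$gene_type %||% "protein_coding")
  writeLines(lines, path)
  path
}
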