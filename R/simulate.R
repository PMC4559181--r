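#' Describe one simulated locus
#'
#' A locus template places one gene (`disjoint`) or an overlapping gene
#' pair with an exactly controlled strand relation and overlap fraction.
#' Pair templates put the first ("host") gene on the "+" strand; the
#' partner is the shorter gene and carries the declared relation:
#' `partial_*` overlaps the host's tail by `round(overlap_fraction *
#' partner_length)` exonic bases, `nested_*` sits fully inside the host
#' (overlap ratio 1 by construction). Multi-exon genes (exons separated by
#' fixed 200-base introns) are supported for `disjoint` loci, where they
#' exercise exon flattening and junction-split mates without disturbing the
#' exact overlap geometry of the pair templates.
#'
#' @param type one of `disjoint`, `partial_same_strand`,
#'   `partial_opposite_strand`, `nested_same_strand`,
#'   `nested_opposite_strand`.
#' @param n number of copies of this locus (default 1).
#' @param gene_length exonic length of the (host) gene in bases.
#' @param partner_length exonic length of the partner gene (pair templates).
#' @param overlap_fraction overlap ratio realized by `partial_*` templates
#'   (fraction of the partner's exonic length; in (0, 1]).
#' @param n_exons exons per gene (disjoint loci only).
#' @param gene_type biotype label of the (host) gene.
#' @param partner_type biotype label of the partner; defaults to
#'   `"antisense"` for opposite-strand templates and the host's type
#'   otherwise.
#' @return a `locus` list.
#' @export
locus <- function(type = c("disjoint", "partial_same_strand", "partial_opposite_strand",
                           "nested_same_strand", "nested_opposite_strand"),
                  n = 1L, gene_length = 2000L, partner_length = 1000L,
                  overlap_fraction = 0.5, n_exons = 1L,
                  gene_type = "protein_coding", partner_type = NULL) {
  type <- match.arg(type)
  stopifnot(is_count1(n), is_count1(gene_length), is_count1(n_exons))
  if (type != "disjoint") {
    stopifnot(is_count1(partner_length))
    if (n_exons > 1L) stop2("multi-exon genes are only supported for disjoint loci")
    if (partner_length > gene_length)
      stop2("impossible geometry: partner_length must not exceed gene_length")
    if (startsWith(type, "partial")) {
      if (overlap_fraction <= 0 || overlap_fraction > 1)
        stop2("overlap_fraction must be in (0, 1]")
      if (round(overlap_fraction * partner_length) < 1)
        stop2("impossible geometry: overlap_fraction * partner_length rounds to 0 bases")
    }
  }
  if (is.null(partner_type)) {
    partner_type <- if (grepl("opposite", type)) "antisense" else gene_type
  }
  structure(list(type = type, n = as.integer(n),
                 gene_length = as.integer(gene_length),
                 partner_length = as.integer(partner_length),
                 overlap_fraction = overlap_fraction,
                 n_exons = as.integer(n_exons),
                 gene_type = gene_type, partner_type = partner_type),
            class = "locus")
}

#' Simulation configuration
#'
#' Bundles the locus templates with the sequencing-model parameters: a
#' 2 x `read_length` paired-end layout and a truncated-normal fragment-size
#' distribution (minimum = read length). The defaults emulate a 2 x 100
#' base run of a dUTP stranded library with mean fragment size 170 and SD
#' 40, which puts about 4% of fragments below the read length before
#' truncation; non-stranded libraries run roughly 30 bases longer, which is
#' representable by raising `fragment_mean`.
#'
#' @param loci list of [locus()] templates.
#' @param n_fragments number of fragments to simulate.
#' @param protocol `"stranded_dutp"` (read 1 antisense to the source
#'   transcript) or `"non_stranded"` (read 1 orientation Bernoulli(0.5)).
#' @param read_length read length in bases (default 100).
#' @param fragment_mean,fragment_sd fragment-size distribution before
#'   truncation at `read_length`.
#' @param expression_weights named per-gene relative abundance weights;
#'   genes not named default to 1. Sampling probability is proportional to
#'   weight x exonic length.
#' @param seed RNG seed used by [simulate_fragments()].
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(loci, n_fragments = 10000L,
                              protocol = c("stranded_dutp", "non_stranded"),
                              read_length = 100L, fragment_mean = 170,
                              fragment_sd = 40, expression_weights = NULL,
                              seed = 1L) {
  protocol <- match.arg(protocol)
  if (inherits(loci, "locus")) loci <- list(loci)
  stopifnot(is.list(loci), all(vapply(loci, inherits, logical(1), "locus")),
            is.numeric(n_fragments), n_fragments >= 0,
            is_count1(read_length), fragment_sd >= 0)
  if (fragment_mean < read_length)
    stop2("fragment_mean must be at least read_length")
  structure(list(loci = loci, n_fragments = as.integer(n_fragments),
                 protocol = protocol, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 expression_weights = expression_weights, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate a synthetic annotation with controlled overlap structure
#'
#' Realizes every locus template exactly: loci are laid out left to right
#' on a single synthetic chromosome (`chrS1`) with 10 kb spacers, so no
#' overlap exists beyond the declared ones. Deterministic: the geometry is
#' a pure function of the configuration.
#'
#' @param cfg a [simulation_config()].
#' @param chrom chromosome name used for all loci.
#' @return an [AnnotationSet]; write it out with [write_gtf()] if needed.
#' @export
generate_annotation <- function(cfg, chrom = "chrS1") {
  stopifnot(inherits(cfg, "SimulationConfig"))
  gap <- 10000L
  intron <- 200L
  pos <- 1L
  gidx <- 0L
  rows <- list()
  add_gene <- function(start, exonic_len, n_exons, strand, gtype) {
    gidx <<- gidx + 1L
    id <- sprintf("SYNG%04d", gidx)
    base <- floor(exonic_len / n_exons)
    w <- rep(base, n_exons)
    w[n_exons] <- exonic_len - base * (n_exons - 1L)
    st <- start + cumsum(c(0L, head(w, -1L) + intron))
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(st), end = as.integer(st + w - 1L),
      strand = strand, gene_id = id, gene_name = id, gene_type = gtype,
      stringsAsFactors = FALSE)
    max(st + w - 1L)
  }
  for (lc in cfg$loci) {
    for (k in seq_len(lc$n)) {
      if (lc$type == "disjoint") {
        last <- add_gene(pos, lc$gene_length, lc$n_exons, "+", lc$gene_type)
      } else {
        La <- lc$gene_length; Lb <- lc$partner_length
        pstrand <- if (grepl("opposite", lc$type)) "-" else "+"
        if (startsWith(lc$type, "nested")) {
          b_start <- pos + as.integer(floor((La - Lb) / 2))
        } else {
          ob <- as.integer(round(lc$overlap_fraction * Lb))
          b_start <- pos + La - ob
        }
        last <- add_gene(pos, La, 1L, "+", lc$gene_type)
        last <- max(last, add_gene(b_start, Lb, 1L, pstrand, lc$partner_type))
      }
      pos <- as.integer(last + gap)
    }
  }
  ex <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), gene_id = character())
  annotation_set(ex, source = "synthetic")
}

# truncated-normal draw by rejection: X ~ N(mean, sd) conditioned on X >= lo
rtnorm_min <- function(n, mean, sd, lo) {
  if (sd == 0) return(rep(max(mean, lo), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out) + 16L, mean, sd)
    out <- c(out, x[x >= lo])
  }
  out[seq_len(n)]
}

# map a spliced-coordinate window [a, b] (1-based along the gene's
# flattened exons in genomic order) to genomic blocks
spliced_to_genomic <- function(ex_start, ex_width, cum, a, b) {
  i <- findInterval(a - 1L, cum) + 1L
  j <- findInterval(b - 1L, cum) + 1L
  ks <- i:j
  gs <- ex_start[ks]
  ge <- gs + ex_width[ks] - 1L
  gs[1L] <- ex_start[i] + (a - 1L - if (i > 1L) cum[i - 1L] else 0L)
  ge[length(ks)] <- ex_start[j] + (b - 1L - if (j > 1L) cum[j - 1L] else 0L)
  list(start = as.integer(gs), end = as.integer(ge))
}

#' Simulate aligned paired-end fragments with ground truth
#'
#' Draws each fragment's source gene with probability proportional to
#' expression weight times exonic length, places the fragment uniformly on
#' the gene's flattened exonic (spliced) coordinate space, and emits the
#' two mates as their genomic footprints (split per exon when a mate spans
#' a junction). Under `stranded_dutp`, read 1 aligns antisense to the
#' source gene; under `non_stranded`, read 1 orientation is a fair coin.
#' All fragments are uniquely mapped, both-ends-mapped and non-chimeric.
#' Fragments longer than their source gene are truncated to the gene's
#' exonic length with a warning.
#'
#' @param annotation an [AnnotationSet] (typically from
#'   [generate_annotation()]).
#' @param cfg a [simulation_config()]; `cfg$seed` makes the draw
#'   reproducible.
#' @return list with `fragments` (a [fragment_set()]) and `truth` (list:
#'   `source` data.frame of fragment_id/gene_id, `per_gene` named counts
#'   over all genes, `n_truncated`).
#' @export
simulate_fragments <- function(annotation, cfg) {
  stopifnot(inherits(annotation, "AnnotationSet"), inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  g <- annotation$genes
  w <- setNames(rep(1, nrow(g)), g$gene_id)
  if (!is.null(cfg$expression_weights)) {
    ew <- cfg$expression_weights
    if (is.null(names(ew))) stop2("expression_weights must be named by gene_id")
    if (any(ew < 0)) stop2("expression_weights must be non-negative")
    unknown <- setdiff(names(ew), g$gene_id)
    if (length(unknown)) stop2("expression_weights for unknown gene(s): %s",
                               paste(unknown, collapse = ", "))
    w[names(ew)] <- ew
  }
  prob <- w * g$exonic_length
  if (sum(prob) <= 0) stop2("all sampling probabilities are zero")
  n <- cfg$n_fragments
  rl <- cfg$read_length

  # per-gene exon lookup in genomic order
  flat <- annotation$flat
  fid <- S4Vectors::mcols(flat)$gene_id
  ord <- order(fid, GenomicRanges::start(flat))
  exo <- split(data.frame(start = GenomicRanges::start(flat)[ord],
                          width = IRanges::width(flat)[ord]),
               fid[ord])
  exo <- lapply(exo, function(e) list(start = e$start, width = e$width,
                                      cum = cumsum(e$width)))

  src_i <- sample.int(nrow(g), n, replace = TRUE, prob = prob)
  src <- g$gene_id[src_i]
  L <- g$exonic_length[src_i]
  flen <- round(rtnorm_min(n, cfg$fragment_mean, cfg$fragment_sd, rl))
  trunc <- flen > L
  if (any(trunc)) {
    warning(sprintf("%d fragment(s) truncated to their gene's exonic length", sum(trunc)),
            call. = FALSE)
    flen[trunc] <- L[trunc]
  }
  s <- 1L + floor(stats::runif(n) * (L - flen + 1))
  ml <- pmin(rl, flen)
  gs <- g$strand[src_i]
  m1 <- if (cfg$protocol == "stranded_dutp") flip_strand(gs) else
    ifelse(stats::runif(n) < 0.5, "+", "-")
  m2 <- flip_strand(m1)

  frags <- data.frame(
    fragment_id = sprintf("frag%06d", seq_len(n)),
    chrom = g$chrom[src_i],
    m1_strand = m1, m2_strand = m2,
    unique = TRUE, both_ends = TRUE, chimeric = FALSE,
    stringsAsFactors = FALSE)

  # left window holds the "+" mate, right window the "-" mate
  # (reads point inward; in genomic coordinates the reverse-strand read
  # sits at the downstream end of the fragment)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    e <- exo[[src[i]]]
    lw <- c(s[i], s[i] + ml[i] - 1L)
    rw <- c(s[i] + flen[i] - ml[i], s[i] + flen[i] - 1L)
    lmate <- if (m1[i] == "+") 1L else 2L
    bl <- spliced_to_genomic(e$start, e$width, e$cum, lw[1], lw[2])
    br <- spliced_to_genomic(e$start, e$width, e$cum, rw[1], rw[2])
    blocks[[i]] <- data.frame(
      frag = i,
      mate = c(rep(lmate, length(bl$start)), rep(3L - lmate, length(br$start))),
      chrom = g$chrom[src_i[i]],
      start = c(bl$start, br$start), end = c(bl$end, br$end),
      stringsAsFactors = FALSE)
  }
  blocks <- if (n) do.call(rbind, blocks) else
    data.frame(frag = integer(), mate = integer(), chrom = character(),
               start = integer(), end = integer())
  blocks <- blocks[order(blocks$frag, blocks$mate, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL

  per_gene <- setNames(integer(nrow(g)), g$gene_id)
  tb <- table(src)
  per_gene[names(tb)] <- as.integer(tb)
  list(fragments = fragment_set(frags, blocks),
       truth = list(source = data.frame(fragment_id = frags$fragment_id,
                                        gene_id = src, stringsAsFactors = FALSE),
                    per_gene = per_gene, n_truncated = sum(trunc)))
}

#' Analytic assignment-category expectations
#'
#' Computes, by exact integration over the discrete (fragment length,
#' start position) space, the probability that a random fragment from each
#' gene is assigned, ambiguous, or no-feature under both counting modes,
#' given the configured protocol's read-1 orientation rule. Fragment
#' lengths are integrated over the integer-discretized truncated normal;
#' lengths beyond a gene's exonic length collapse onto it (mirroring the
#' simulator's truncation). Each gene's exonic space is treated as one
#' contiguous interval at its span start — exact for single-exon genes,
#' an approximation otherwise.
#'
#' @param annotation an [AnnotationSet].
#' @param cfg a [simulation_config()].
#' @param min_overlap_bases counting threshold (default 60, matching
#'   [protocol_config()]).
#' @param length_step integration step over fragment lengths (default 1;
#'   larger values trade accuracy for speed).
#' @return list with `per_gene` (data.frame: gene_id, mode, p_assigned,
#'   p_ambiguous, p_no_feature) and `aggregate` (data.frame: mode,
#'   assigned, ambiguous, no_feature), aggregated over genes by their
#'   sampling probability.
#' @export
expected_summary <- function(annotation, cfg, min_overlap_bases = 60L,
                             length_step = 1L) {
  stopifnot(inherits(annotation, "AnnotationSet"), inherits(cfg, "SimulationConfig"))
  g <- annotation$genes
  w <- setNames(rep(1, nrow(g)), g$gene_id)
  if (!is.null(cfg$expression_weights)) w[names(cfg$expression_weights)] <- cfg$expression_weights
  prob_g <- w * g$exonic_length
  prob_g <- prob_g / sum(prob_g)
  rl <- cfg$read_length
  Fmax <- as.integer(ceiling(cfg$fragment_mean + 4 * cfg$fragment_sd))
  Fgrid <- seq.int(rl, max(rl, Fmax), by = as.integer(length_step))
  pF <- if (cfg$fragment_sd == 0) {
    ifelse(Fgrid == round(cfg$fragment_mean), 1, 0)
  } else {
    dnorm(Fgrid, cfg$fragment_mean, cfg$fragment_sd)
  }
  pF <- pF / sum(pF)

  flat <- annotation$flat
  fid <- S4Vectors::mcols(flat)$gene_id
  exon_start <- GenomicRanges::start(flat)
  exon_end <- GenomicRanges::end(flat)

  modes <- c("unstranded", "reverse_stranded")
  res <- list()
  for (gi in seq_len(nrow(g))) {
    if (prob_g[gi] == 0) next
    L <- g$exonic_length[gi]
    pos0 <- g$span_start[gi]
    neigh <- query_overlapping_genes(annotation, g$chrom[gi],
                                     max(1L, g$span_start[gi] - Fmax),
                                     g$span_end[gi] + Fmax, strand_mode = "both")
    hstrand <- g$strand[match(neigh, g$gene_id)]
    hexons <- lapply(neigh, function(id) {
      sel <- fid == id
      list(start = exon_start[sel], end = exon_end[sel])
    })
    # fragment-length weights with the truncation-at-L mass collapsed
    Feff <- pmin(Fgrid, L)
    acc <- matrix(0, nrow = 2L, ncol = 3L,
                  dimnames = list(modes, c("assigned", "ambiguous", "no_feature")))
    scen <- if (cfg$protocol == "stranded_dutp") {
      list(list(m1 = flip_strand(g$strand[gi]), w = 1))
    } else {
      list(list(m1 = "+", w = 0.5), list(m1 = "-", w = 0.5))
    }
    for (Fu in unique(Feff)) {
      pFu <- sum(pF[Feff == Fu])
      if (pFu == 0) next
      ml <- min(rl, Fu)
      s <- seq_len(L - Fu + 1L)
      leftS <- pos0 + s - 1L; leftE <- leftS + ml - 1L
      rightE <- pos0 + s + Fu - 2L; rightS <- rightE - ml + 1L
      ov <- vapply(hexons, function(e) {
        o <- numeric(length(s))
        for (k in seq_along(e$start)) {
          o <- o + pmax(0L, pmin(leftE, e$end[k]) - pmax(leftS, e$start[k]) + 1L) +
            pmax(0L, pmin(rightE, e$end[k]) - pmax(rightS, e$start[k]) + 1L)
        }
        o
      }, numeric(length(s)))
      ov <- matrix(ov, nrow = length(s))
      cand_un <- ov >= min_overlap_bases
      n_un <- rowSums(cand_un)
      acc["unstranded", ] <- acc["unstranded", ] + pFu * c(
        mean(n_un == 1L), mean(n_un >= 2L), mean(n_un == 0L))
      for (sc in scen) {
        pass <- hstrand != "*" & hstrand != sc$m1
        n_rev <- rowSums(cand_un[, pass, drop = FALSE])
        acc["reverse_stranded", ] <- acc["reverse_stranded", ] + pFu * sc$w * c(
          mean(n_rev == 1L), mean(n_rev >= 2L), mean(n_rev == 0L))
      }
    }
    for (mo in modes) {
      res[[length(res) + 1L]] <- data.frame(
        gene_id = g$gene_id[gi], mode = mo,
        p_assigned = acc[mo, "assigned"],
        p_ambiguous = acc[mo, "ambiguous"],
        p_no_feature = acc[mo, "no_feature"],
        prob = prob_g[gi], stringsAsFactors = FALSE)
    }
  }
  per_gene <- do.call(rbind, res)
  agg <- do.call(rbind, lapply(modes, function(mo) {
    pg <- per_gene[per_gene$mode == mo, ]
    data.frame(mode = mo,
               assigned = sum(pg$p_assigned * pg$prob) / sum(pg$prob),
               ambiguous = sum(pg$p_ambiguous * pg$prob) / sum(pg$prob),
               no_feature = sum(pg$p_no_feature * pg$prob) / sum(pg$prob))
  }))
  per_gene$prob <- NULL
  list(per_gene = per_gene, aggregate = agg)
}

#' Default simulated study configuration
#'
#' The package's standing desk-scale emulation of a genome-like overlap
#' mix: 172 loci / 200 genes, of which 9% of genes overlap a same-strand
#' partner and 19% an opposite-strand partner (the genome-wide proportions
#' a human annotation shows), with partial-overlap fractions matching the
#' observed median overlap ratios (0.47 same strand, 0.19 opposite) and a
#' minority of fully nested loci. Disjoint loci carry a spread of biotypes
#' (protein_coding, lincRNA, processed_pseudogene, processed_transcript,
#' sense_intronic) so gene-type breakdowns are exercised.
#'
#' @param n_fragments fragments per sample (default 20000).
#' @param protocol passed to [simulation_config()].
#' @param seed RNG seed.
#' @return a [simulation_config()].
#' @export
default_study_config <- function(n_fragments = 20000L,
                                 protocol = c("stranded_dutp", "non_stranded"),
                                 seed = 1L) {
  protocol <- match.arg(protocol)
  loci <- list(
    locus("disjoint", n = 118, gene_length = 2000),
    locus("disjoint", n = 10, gene_length = 1500, gene_type = "lincRNA"),
    locus("disjoint", n = 8, gene_length = 800, gene_type = "processed_pseudogene"),
    locus("disjoint", n = 4, gene_length = 1200, gene_type = "processed_transcript"),
    locus("disjoint", n = 2, gene_length = 1000, gene_type = "sense_intronic"),
    locus("disjoint", n = 2, gene_length = 2500, n_exons = 4),
    locus("partial_same_strand", n = 7, gene_length = 2000,
          partner_length = 1000, overlap_fraction = 0.47),
    locus("nested_same_strand", n = 2, gene_length = 2000, partner_length = 800),
    locus("partial_opposite_strand", n = 14, gene_length = 2000,
          partner_length = 1000, overlap_fraction = 0.19),
    locus("nested_opposite_strand", n = 5, gene_length = 2000, partner_length = 800))
  simulation_config(loci, n_fragments = n_fragments, protocol = protocol,
                    seed = seed)
}
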