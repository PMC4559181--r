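#' Aligned paired-end fragments
#'
#' A `FragmentSet` holds aligned fragments at the level the counting rules
#' need: per-fragment mate strands and mapping flags, plus the genomic
#' blocks each mate covers (a mate spanning an exon junction contributes
#' one block per exon, so intronic bases never count toward overlap).
#'
#' @param frags data.frame, one row per fragment: `fragment_id`, `chrom`,
#'   `m1_strand`, `m2_strand` (NA if the second mate is absent), `unique`
#'   (uniquely mapped), `both_ends` (both mates mapped), `chimeric` (mates
#'   on different chromosomes).
#' @param blocks data.frame, one row per aligned block: `frag` (row index
#'   into `frags`), `mate` (1 or 2), `chrom`, `start`, `end` (1-based
#'   closed). Blocks of one mate must be disjoint.
#' @return a `FragmentSet`.
#' @export
fragment_set <- function(frags, blocks) {
  stopifnot(is.data.frame(frags), is.data.frame(blocks))
  need_f <- c("fragment_id", "chrom", "m1_strand", "m2_strand",
              "unique", "both_ends", "chimeric")
  need_b <- c("frag", "mate", "chrom", "start", "end")
  if (!all(need_f %in% names(frags))) stop2("frags must have columns: %s", paste(need_f, collapse = ", "))
  if (!all(need_b %in% names(blocks))) stop2("blocks must have columns: %s", paste(need_b, collapse = ", "))
  if (nrow(blocks) && (max(blocks$frag) > nrow(frags) || min(blocks$frag) < 1L))
    stop2("blocks$frag out of range")
  out <- list(frags = frags, blocks = blocks)
  class(out) <- "FragmentSet"
  out
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet: %d fragments, %d aligned blocks\n",
              nrow(x$frags), nrow(x$blocks)))
  invisible(x)
}

#' @export
length.FragmentSet <- function(x) nrow(x$frags)

#' Counting-rule configuration
#'
#' Mirrors exon-level fragment counting with a minimum-overlap requirement:
#' a gene is a candidate for a fragment when the fragment's summed exonic
#' overlap (over both mates; a genomic base covered by both mates counts
#' once per mate) reaches `min_overlap_bases`. Under `reverse_stranded`
#' (dUTP second-strand protocol) a candidate must additionally have read 1
#' aligned antisense to the gene. Fragments that are not uniquely mapped,
#' lack a mapped mate (when `require_both_ends`), or are chimeric (when
#' `discard_chimeric`) are filtered before assignment.
#'
#' @param strand_mode `"unstranded"` or `"reverse_stranded"`.
#' @param min_overlap_bases minimum summed exonic overlap (default 60).
#' @param require_both_ends drop fragments without both mates mapped
#'   (default TRUE).
#' @param discard_chimeric drop fragments with mates on different
#'   chromosomes (default TRUE).
#' @param mate_overlap `"sum"` (default; overlap summed over mates) or
#'   `"per_mate"` (a gene qualifies if any single mate reaches the
#'   threshold).
#' @return a `ProtocolConfig` list.
#' @export
protocol_config <- function(strand_mode = c("unstranded", "reverse_stranded"),
                            min_overlap_bases = 60L,
                            require_both_ends = TRUE,
                            discard_chimeric = TRUE,
                            mate_overlap = c("sum", "per_mate")) {
  strand_mode <- match.arg(strand_mode)
  mate_overlap <- match.arg(mate_overlap)
  stopifnot(is_count1(min_overlap_bases))
  structure(list(strand_mode = strand_mode,
                 min_overlap_bases = as.integer(min_overlap_bases),
                 require_both_ends = isTRUE(require_both_ends),
                 discard_chimeric = isTRUE(discard_chimeric),
                 mate_overlap = mate_overlap),
            class = "ProtocolConfig")
}

#' Classify fragments against an annotation
#'
#' Applies the counting rules of [protocol_config()] to every fragment:
#' `filtered` (failed mapping filters), `no_feature` (0 candidate genes),
#' `assigned` (exactly 1), or `ambiguous` (2 or more).
#'
#' @param frags a [fragment_set()].
#' @param annotation an [AnnotationSet].
#' @param cfg a [protocol_config()].
#' @return data.frame, one row per fragment, with `fragment_id`,
#'   `category`, `gene_id` (NA unless assigned), `n_candidates`, and a
#'   `candidates` list-column of candidate gene ids.
#' @export
classify_fragments <- function(frags, annotation, cfg = protocol_config()) {
  stopifnot(inherits(frags, "FragmentSet"), inherits(annotation, "AnnotationSet"),
            inherits(cfg, "ProtocolConfig"))
  n <- nrow(frags$frags)
  category <- rep("no_feature", n)
  gene_id <- rep(NA_character_, n)
  n_candidates <- integer(n)
  candidates <- vector("list", n)

  f <- frags$frags
  filtered <- !f$unique |
    (cfg$require_both_ends & !f$both_ends) |
    (cfg$discard_chimeric & f$chimeric)
  category[filtered] <- "filtered"

  live <- which(!filtered)
  bl <- frags$blocks[frags$blocks$frag %in% live, , drop = FALSE]
  if (nrow(bl) && length(annotation$flat)) {
    bgr <- GenomicRanges::GRanges(bl$chrom, IRanges::IRanges(bl$start, bl$end))
    # fragments on chromosomes absent from the annotation are a plain
    # no_feature case, not worth a seqlevel warning
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(bgr, annotation$flat, ignore.strand = TRUE))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(bgr[q]), IRanges::ranges(annotation$flat[s])))
      dt <- data.table::data.table(
        frag = bl$frag[q], mate = bl$mate[q],
        gene = S4Vectors::mcols(annotation$flat)$gene_id[s], w = w)
      # blocks disjoint within a mate, flattened exons disjoint within a
      # gene: summing per (frag, mate, gene) is the exact per-mate overlap
      per_mate <- dt[, .(w = sum(w)), by = .(frag, mate, gene)]
      per_gene <- if (cfg$mate_overlap == "sum") {
        per_mate[, .(ov = sum(w)), by = .(frag, gene)]
      } else {
        per_mate[, .(ov = max(w)), by = .(frag, gene)]
      }
      cand <- per_gene[ov >= cfg$min_overlap_bases]
      if (cfg$strand_mode == "reverse_stranded" && nrow(cand)) {
        gs <- annotation$genes$strand[match(cand$gene, annotation$genes$gene_id)]
        m1 <- f$m1_strand[cand$frag]
        # read 1 must align antisense to the gene; unstranded genes and
        # unknown read-1 strands never qualify
        cand <- cand[!is.na(m1) & gs != "*" & m1 != "*" & m1 != gs]
      }
      if (nrow(cand)) {
        sets <- split(cand$gene, cand$frag)
        idx <- as.integer(names(sets))
        k <- lengths(sets)
        n_candidates[idx] <- k
        candidates[idx] <- lapply(sets, sort)
        category[idx[k == 1L]] <- "assigned"
        category[idx[k >= 2L]] <- "ambiguous"
        gene_id[idx[k == 1L]] <- vapply(sets[k == 1L], identity, character(1))
      }
    }
  }
  out <- data.frame(fragment_id = f$fragment_id, category = category,
                    gene_id = gene_id, n_candidates = n_candidates,
                    stringsAsFactors = FALSE)
  out$candidates <- candidates
  out
}

#' Classify a single fragment
#'
#' Convenience wrapper around [classify_fragments()] for one fragment.
#'
#' @param frag a [fragment_set()] of length 1.
#' @inheritParams classify_fragments
#' @return one-row data.frame as in [classify_fragments()].
#' @export
classify_fragment <- function(frag, annotation, cfg = protocol_config()) {
  stopifnot(length(frag) == 1L)
  classify_fragments(frag, annotation, cfg)
}

#' Count fragments per gene for one sample
#'
#' @param frags a [fragment_set()] (all fragments of one sample).
#' @param annotation an [AnnotationSet].
#' @param cfg a [protocol_config()].
#' @param sample_id sample label.
#' @return list with `counts` (named integer vector over all annotation
#'   genes; assigned fragments only), `summary` (one-row data.frame:
#'   `sample`, `n_assigned`, `n_ambiguous`, `n_no_feature`, `n_filtered`,
#'   `n_total`), and `assignments` (the [classify_fragments()] table).
#' @export
count_fragments <- function(frags, annotation, cfg = protocol_config(),
                            sample_id = "sample") {
  if (anyDuplicated(frags$frags$fragment_id))
    warning("duplicate fragment_id values; all occurrences counted", call. = FALSE)
  cls <- classify_fragments(frags, annotation, cfg)
  counts <- setNames(integer(nrow(annotation$genes)), annotation$genes$gene_id)
  tab <- table(cls$gene_id[cls$category == "assigned"])
  counts[names(tab)] <- as.integer(tab)
  summary <- data.frame(
    sample = sample_id,
    n_assigned = sum(cls$category == "assigned"),
    n_ambiguous = sum(cls$category == "ambiguous"),
    n_no_feature = sum(cls$category == "no_feature"),
    n_filtered = sum(cls$category == "filtered"),
    n_total = nrow(cls),
    stringsAsFactors = FALSE)
  list(counts = counts, summary = summary, assignments = cls)
}

#' Assemble a genes-by-samples count table
#'
#' @param columns named list of [count_fragments()] results (names are
#'   sample ids; unnamed lists fall back to each column's `summary$sample`).
#' @return a `CountTable`: list with `counts` (integer matrix, genes x
#'   samples) and `summary` (per-sample assignment totals). The
#'   conservation identity `assigned + ambiguous + no_feature + filtered ==
#'   total` is checked per sample.
#' @export
count_table <- function(columns) {
  stopifnot(is.list(columns), length(columns) >= 1L)
  ids <- names(columns) %||% vapply(columns, function(x) x$summary$sample, character(1))
  if (is.null(names(columns))) names(columns) <- ids
  gene_ids <- names(columns[[1L]]$counts)
  mats <- vapply(columns, function(x) {
    if (!identical(names(x$counts), gene_ids)) stop2("count columns disagree on gene universe")
    x$counts
  }, integer(length(gene_ids)))
  counts <- matrix(mats, nrow = length(gene_ids),
                   dimnames = list(gene_ids, names(columns)))
  summary <- do.call(rbind, lapply(seq_along(columns), function(i) {
    s <- columns[[i]]$summary
    s$sample <- names(columns)[i]
    s
  }))
  with(summary, stopifnot(
    all(n_assigned + n_ambiguous + n_no_feature + n_filtered == n_total)))
  stopifnot(all(colSums(counts) == summary$n_assigned))
  structure(list(counts = counts, summary = summary), class = "CountTable")
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf("CountTable: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read aligned paired-end fragments from a SAM file
#'
#' Ingests a plain SAM (or BAM) file, pairs mates by query name, and
#' derives the counting flags: secondary (0x100) and supplementary (0x800)
#' alignments are excluded before pairing; `unique` means both mates'
#' mapping quality reaches `mapq_unique` (default 50, which treats STAR's
#' 255 unique-mapper convention as unique and its multi-mapper values as
#' not); an unpaired mate yields `both_ends = FALSE`; mates on different
#' chromosomes are flagged `chimeric`. Mate blocks are CIGAR-aware (N/D
#' gaps split a mate into its reference blocks).
#'
#' @param path SAM or BAM file path.
#' @param mapq_unique minimum MAPQ for a uniquely mapped fragment.
#' @return a [fragment_set()].
#' @export
read_sam <- function(path, mapq_unique = 50L) {
  if (!file.exists(path)) stop2("alignment file not found: %s", path)
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0L) {
    return(fragment_set(
      data.frame(fragment_id = character(), chrom = character(),
                 m1_strand = character(), m2_strand = character(),
                 unique = logical(), both_ends = logical(), chimeric = logical()),
      data.frame(frag = integer(), mate = integer(), chrom = character(),
                 start = integer(), end = integer())))
  }
  md <- S4Vectors::mcols(ga)
  flag <- md$flag
  mate <- ifelse(bitwAnd(flag, 0x40L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 0x80L) > 0L, 2L, 1L))
  rec <- data.table::data.table(
    qname = md$qname, mate = mate,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    mapq = as.integer(md$mapq), idx = seq_along(ga))
  dup <- duplicated(rec, by = c("qname", "mate"))
  if (any(dup)) {
    warning(sprintf("%d duplicate primary alignment(s) for the same mate dropped", sum(dup)),
            call. = FALSE)
    rec <- rec[!dup]
  }
  frag_tab <- data.table::dcast(rec, qname ~ mate,
                                value.var = c("chrom", "strand", "mapq", "idx"))
  for (col in c("chrom_1", "strand_1", "mapq_1", "idx_1",
                "chrom_2", "strand_2", "mapq_2", "idx_2")) {
    if (!col %in% names(frag_tab)) frag_tab[[col]] <- NA
  }
  frag_tab <- frag_tab[order(qname)]
  has1 <- !is.na(frag_tab$idx_1); has2 <- !is.na(frag_tab$idx_2)
  # a lone second mate stands in as mate 1 with its strand flipped
  # (proper-pair invariant: mate strands are opposite)
  m1_strand <- ifelse(has1, frag_tab$strand_1, flip_strand(frag_tab$strand_2))
  m2_strand <- ifelse(has2 & has1, frag_tab$strand_2, NA_character_)
  chimeric <- has1 & has2 & frag_tab$chrom_1 != frag_tab$chrom_2
  mapq_min <- pmin(ifelse(has1, frag_tab$mapq_1, Inf),
                   ifelse(has2, frag_tab$mapq_2, Inf))
  frags <- data.frame(
    fragment_id = frag_tab$qname,
    chrom = ifelse(has1, frag_tab$chrom_1, frag_tab$chrom_2),
    m1_strand = m1_strand, m2_strand = m2_strand,
    unique = mapq_min >= mapq_unique,
    both_ends = has1 & has2,
    chimeric = chimeric,
    stringsAsFactors = FALSE)

  blk <- GenomicAlignments::grglist(ga)  # CIGAR-aware reference blocks
  blk_fl <- unlist(blk, use.names = FALSE)
  blk_align <- rep(seq_along(ga), lengths(blk))
  keep <- blk_align %in% rec$idx
  blk_fl <- blk_fl[keep]; blk_align <- blk_align[keep]
  # map alignment index -> (fragment row, mate slot actually used);
  # a lone second mate occupies slot 1, matching m1_strand above
  frag_of <- integer(length(ga)); mate_of <- integer(length(ga))
  w1 <- which(has1); w2 <- which(has2)
  frag_of[frag_tab$idx_1[w1]] <- w1
  mate_of[frag_tab$idx_1[w1]] <- 1L
  frag_of[frag_tab$idx_2[w2]] <- w2
  mate_of[frag_tab$idx_2[w2]] <- ifelse(has1[w2], 2L, 1L)
  blocks <- data.frame(
    frag = frag_of[blk_align],
    mate = mate_of[blk_align],
    chrom = as.character(GenomicRanges::seqnames(blk_fl)),
    start = GenomicRanges::start(blk_fl),
    end = GenomicRanges::end(blk_fl),
    stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$frag, blocks$mate, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  fragment_set(frags, blocks)
}

#' Write fragments to the internal TSV format
#'
#' One row per fragment: `fragment_id`, `chrom`, `m1_start`, `m1_end`,
#' `m1_strand`, `m2_start`, `m2_end`, `m2_strand`, `mapq_unique`,
#' `both_ends`, `chimeric`. A mate split across exons stores its blocks as
#' ";"-joined lists in the start/end columns.
#'
#' @param frags a [fragment_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  stopifnot(inherits(frags, "FragmentSet"))
  join <- function(mate_no, what) {
    bl <- frags$blocks[frags$blocks$mate == mate_no, , drop = FALSE]
    out <- rep(NA_character_, nrow(frags$frags))
    if (nrow(bl)) {
      v <- split(bl[[what]], bl$frag)
      out[as.integer(names(v))] <- vapply(v, paste, character(1), collapse = ";")
    }
    out
  }
  df <- data.frame(
    fragment_id = frags$frags$fragment_id,
    chrom = frags$frags$chrom,
    m1_start = join(1L, "start"), m1_end = join(1L, "end"),
    m1_strand = frags$frags$m1_strand,
    m2_start = join(2L, "start"), m2_end = join(2L, "end"),
    m2_strand = frags$frags$m2_strand,
    mapq_unique = frags$frags$unique,
    both_ends = frags$frags$both_ends,
    chimeric = frags$frags$chimeric,
    stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read fragments from the internal TSV format
#'
#' @param path TSV written by [write_fragments()].
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path) {
  df <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          colClasses = list(character = c("m1_start", "m1_end",
                                                          "m2_start", "m2_end")))
  df <- as.data.frame(df)
  frags <- data.frame(
    fragment_id = as.character(df$fragment_id), chrom = df$chrom,
    m1_strand = as.character(df$m1_strand),
    m2_strand = as.character(df$m2_strand),
    unique = as.logical(df$mapq_unique),
    both_ends = as.logical(df$both_ends),
    chimeric = as.logical(df$chimeric),
    stringsAsFactors = FALSE)
  expand <- function(i, mate_no, s, e) {
    if (is.na(s)) return(NULL)
    st <- as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
    en <- as.integer(strsplit(e, ";", fixed = TRUE)[[1L]])
    data.frame(frag = i, mate = mate_no, chrom = df$chrom[i],
               start = st, end = en, stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, c(
    lapply(seq_len(nrow(df)), function(i) expand(i, 1L, df$m1_start[i], df$m1_end[i])),
    lapply(seq_len(nrow(df)), function(i) expand(i, 2L, df$m2_start[i], df$m2_end[i]))))
  if (is.null(blocks)) {
    blocks <- data.frame(frag = integer(), mate = integer(), chrom = character(),
                         start = integer(), end = integer())
  }
  blocks <- blocks[order(blocks$frag, blocks$mate, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  fragment_set(frags, blocks)
}
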