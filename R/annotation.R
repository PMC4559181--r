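#' Gene-model annotation sets
#'
#' An `AnnotationSet` holds one gene model per `gene_id`: the raw exons
#' (union over all transcripts), the flattened (merged, disjoint) exons that
#' all overlap arithmetic is based on, the exonic length, and the gene span.
#' Internally everything lives in [GenomicRanges::GRanges] objects with
#' 1-based closed coordinates; GTF input needs no coordinate conversion.
#'
#' Fields:
#' \describe{
#'   \item{genes}{data.frame with one row per gene: `gene_id`, `gene_name`,
#'     `gene_type`, `chrom`, `strand` ("+", "-", or "*" for unstranded),
#'     `n_exons` (raw exon records), `exonic_length` (distinct exonic bases),
#'     `span_start`, `span_end`.}
#'   \item{exons}{GRanges of raw exons with a `gene_id` metadata column.}
#'   \item{flat}{GRanges of flattened exons (sorted, disjoint, adjacent runs
#'     merged) with a `gene_id` metadata column; strand taken from the gene.}
#'   \item{meta}{list of parse/build statistics and warnings.}
#' }
#'
#' @name AnnotationSet
NULL

#' Build an AnnotationSet from an exon table
#'
#' Low-level constructor used by [parse_gtf()] and [generate_annotation()].
#' Genes whose exons span several chromosomes or mix strands are rejected
#' with a warning (recorded in `meta`).
#'
#' @param exons data.frame with columns `chrom`, `start`, `end` (1-based
#'   closed), `strand` ("+", "-", "*"), `gene_id`, and optionally
#'   `gene_name`, `gene_type`.
#' @param source character label recorded in `meta$source`.
#' @param meta optional list of extra metadata merged into the result.
#' @return an `AnnotationSet`.
#' @export
annotation_set <- function(exons, source = "in-memory", meta = list()) {
  stopifnot(is.data.frame(exons))
  need <- c("chrom", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(exons))) {
    stop2("exon table must have columns: %s", paste(need, collapse = ", "))
  }
  if (is.null(exons$gene_name)) exons$gene_name <- exons$gene_id
  if (is.null(exons$gene_type)) exons$gene_type <- rep("unknown", nrow(exons))
  exons$strand <- norm_strand(as.character(exons$strand))

  warnings <- character()
  n_multichrom <- 0L
  if (nrow(exons)) {
    dt <- data.table::as.data.table(exons)
    bad <- dt[, .(nchrom = data.table::uniqueN(chrom),
                  nstrand = data.table::uniqueN(strand)), by = gene_id]
    drop_ids <- bad[nchrom > 1L | nstrand > 1L, gene_id]
    n_multichrom <- length(drop_ids)
    if (n_multichrom) {
      warnings <- c(warnings, sprintf(
        "%d gene(s) with exons on multiple chromosomes/strands excluded", n_multichrom))
      warning(warnings[length(warnings)], call. = FALSE)
      exons <- exons[!(exons$gene_id %in% drop_ids), , drop = FALSE]
    }
  }

  if (nrow(exons) == 0L) {
    genes <- data.frame(gene_id = character(), gene_name = character(),
                        gene_type = character(), chrom = character(),
                        strand = character(), n_exons = integer(),
                        exonic_length = integer(), span_start = integer(),
                        span_end = integer(), stringsAsFactors = FALSE)
    gr0 <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr0)$gene_id <- character()
    ann <- list(genes = genes, exons = gr0, flat = gr0,
                meta = c(list(source = source, n_genes = 0L,
                              n_rejected_multichrom = n_multichrom,
                              warnings = warnings), meta))
    class(ann) <- "AnnotationSet"
    return(ann)
  }

  exons <- exons[order(exons$gene_id, exons$chrom, exons$start, exons$end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end),
    strand = exons$strand)
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id

  # flatten: merge overlapping AND adjacent exons per gene (base-coverage
  # semantics: [a,b] and [b+1,c] cover contiguous bases and are one block)
  by_gene <- GenomicRanges::split(gr, S4Vectors::mcols(gr)$gene_id)
  flat_l <- GenomicRanges::reduce(by_gene)  # default min.gapwidth = 1 merges adjacent
  flat <- unlist(flat_l, use.names = FALSE)
  S4Vectors::mcols(flat)$gene_id <- rep(names(flat_l), lengths(flat_l))

  first <- !duplicated(exons$gene_id)
  ginfo <- exons[first, c("gene_id", "gene_name", "gene_type", "chrom", "strand")]
  ginfo <- ginfo[order(ginfo$gene_id), , drop = FALSE]
  exo_len <- sum(IRanges::width(flat_l))
  spans <- unlist(range(flat_l))  # one range per gene, names = gene_id
  span_start <- setNames(GenomicRanges::start(spans), names(spans))
  span_end <- setNames(GenomicRanges::end(spans), names(spans))
  genes <- data.frame(
    gene_id = ginfo$gene_id,
    gene_name = ginfo$gene_name,
    gene_type = ginfo$gene_type,
    chrom = ginfo$chrom,
    strand = ginfo$strand,
    n_exons = as.integer(table(exons$gene_id)[ginfo$gene_id]),
    exonic_length = as.integer(exo_len[ginfo$gene_id]),
    span_start = as.integer(span_start[ginfo$gene_id]),
    span_end = as.integer(span_end[ginfo$gene_id]),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL

  ann <- list(genes = genes, exons = gr, flat = flat,
              meta = c(list(source = source, n_genes = nrow(genes),
                            n_rejected_multichrom = n_multichrom,
                            warnings = warnings), meta))
  class(ann) <- "AnnotationSet"
  ann
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes, %d raw exons (%s)\n",
              nrow(x$genes), length(x$exons), x$meta$source))
  tt <- sort(table(x$genes$gene_type), decreasing = TRUE)
  cat("  gene_type:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

GTF_ATTR_RX <- '%s "([^"]*)"'

gtf_attr <- function(attrs, key) {
  m <- regexec(sprintf(GTF_ATTR_RX, key), attrs)
  vapply(regmatches(attrs, m), function(h) if (length(h) == 2L) h[2L] else NA_character_,
         character(1))
}

#' Parse a GTF file into an AnnotationSet
#'
#' Reads a GTF 2.2 file (Gencode dialect; plain or gzip) and builds one gene
#' model per distinct `gene_id` that has at least one `exon` feature line.
#' Gene structure is the union of exons over all transcripts; `gene` /
#' `transcript` feature lines are ignored. Records with `end < start` or an
#' unknown strand symbol are rejected individually with a warning (counts
#' kept in `meta`); a line with the wrong number of tab-separated columns is
#' a parse error naming the line.
#'
#' @param path path to the GTF file (".gz" accepted).
#' @param feature_filter optional character vector of `gene_type` values to
#'   keep; `NULL` (default) keeps everything.
#' @param gene_type_fallback value used when the `gene_type` attribute is
#'   absent (default `"unknown"`).
#' @return an [AnnotationSet].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "demo", "exon", "101", "200", ".", "+", ".",
#'                  'gene_id "G1"; gene_type "protein_coding";',
#'                  sep = "\t"), gtf)
#' ann <- parse_gtf(gtf)
#' ann$genes$exonic_length  # 100
#' @export
parse_gtf <- function(path, feature_filter = NULL, gene_type_fallback = "unknown") {
  if (!file.exists(path)) stop2("GTF file not found: %s", path)
  con <- gzfile(path, open = "rt")  # transparently reads plain files too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]

  if (length(lines) == 0L) {
    return(annotation_set(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character()),
      source = basename(path),
      meta = list(n_exon_records = 0L, n_rejected_coord = 0L,
                  n_rejected_strand = 0L)))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop2("malformed GTF line %d: expected 9 tab-separated fields, got %d",
          lineno[bad], nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3L] == "exon"
  m <- m[is_exon, , drop = FALSE]
  ln <- lineno[is_exon]
  n_exon_records <- nrow(m)

  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop2("malformed GTF line %d: non-numeric coordinates", ln[bad])
  }
  strand <- m[, 7L]

  bad_coord <- end < start
  bad_strand <- !(strand %in% c("+", "-", "."))
  n_rejected_coord <- sum(bad_coord)
  n_rejected_strand <- sum(bad_strand & !bad_coord)
  if (n_rejected_coord)
    warning(sprintf("%d exon record(s) with end < start rejected", n_rejected_coord),
            call. = FALSE)
  if (n_rejected_strand)
    warning(sprintf("%d exon record(s) with unknown strand symbol rejected",
                    n_rejected_strand), call. = FALSE)
  ok <- !bad_coord & !bad_strand

  attrs <- m[ok, 9L]
  gene_id <- gtf_attr(attrs, "gene_id")
  if (anyNA(gene_id)) {
    bad <- which(is.na(gene_id))[1L]
    stop2("malformed GTF line %d: exon record without gene_id attribute", ln[ok][bad])
  }
  gene_name <- gtf_attr(attrs, "gene_name")
  gene_type <- gtf_attr(attrs, "gene_type")
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  gene_type[is.na(gene_type)] <- gene_type_fallback

  ex <- data.frame(chrom = m[ok, 1L], start = start[ok], end = end[ok],
                   strand = strand[ok], gene_id = gene_id,
                   gene_name = gene_name, gene_type = gene_type,
                   stringsAsFactors = FALSE)
  if (!is.null(feature_filter)) {
    ex <- ex[ex$gene_type %in% feature_filter, , drop = FALSE]
  }
  annotation_set(ex, source = basename(path),
                 meta = list(n_exon_records = n_exon_records,
                             n_rejected_coord = n_rejected_coord,
                             n_rejected_strand = n_rejected_strand))
}

#' Write an AnnotationSet back to GTF
#'
#' Emits one `exon` feature line per raw exon with `gene_id`, `gene_name`
#' and `gene_type` attributes, sorted by chromosome, start and gene id, so
#' identical annotations serialize byte-identically.
#'
#' @param annotation an [AnnotationSet].
#' @param path output file path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  gr <- annotation$exons
  gid <- S4Vectors::mcols(gr)$gene_id
  gi <- annotation$genes[match(gid, annotation$genes$gene_id), ]
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf(
    "%s\tstrandlap\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_name \"%s\"; gene_type \"%s\";",
    as.character(GenomicRanges::seqnames(gr)),
    GenomicRanges::start(gr), GenomicRanges::end(gr),
    strand, gid, gi$gene_name, gi$gene_type)
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr), gid)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines[ord], con)
  invisible(path)
}

#' Flatten a set of exon intervals
#'
#' Returns the minimal sorted disjoint interval set covering exactly the
#' same bases: overlapping and adjacent intervals are merged. All intervals
#' must be on one chromosome.
#'
#' @param exons a [GenomicRanges::GRanges], an [IRanges::IRanges], or a
#'   data.frame with `start` and `end` columns (1-based closed).
#' @return object of the same flavour (GRanges in, GRanges out; otherwise
#'   IRanges) holding the flattened intervals.
#' @examples
#' flatten_exons(data.frame(start = c(1, 6, 21), end = c(10, 15, 30)))
#' @export
flatten_exons <- function(exons) {
  if (is.data.frame(exons)) {
    exons <- IRanges::IRanges(start = exons$start, end = exons$end)
  }
  if (methods::is(exons, "GRanges")) {
    if (length(unique(as.character(GenomicRanges::seqnames(exons)))) > 1L) {
      stop2("flatten_exons: intervals on mixed chromosomes")
    }
    return(GenomicRanges::reduce(exons, ignore.strand = TRUE))
  }
  IRanges::reduce(exons)
}

#' Genes overlapping a genomic window
#'
#' Returns the `gene_id`s of all genes with at least one flattened-exon base
#' inside the window, subject to a strand predicate. An unknown chromosome
#' yields an empty set, not an error. Unstranded ("*") genes never satisfy
#' the `same` or `opposite` predicate.
#'
#' @param annotation an [AnnotationSet].
#' @param chrom chromosome name.
#' @param start,end window coordinates, 1-based closed.
#' @param strand window strand ("+", "-", "*"); ignored when
#'   `strand_mode = "both"`.
#' @param strand_mode `"both"` (ignore strand), `"same"` (gene strand equals
#'   window strand) or `"opposite"`.
#' @return character vector of gene ids (possibly empty).
#' @export
query_overlapping_genes <- function(annotation, chrom, start, end, strand = "*",
                                    strand_mode = c("both", "same", "opposite")) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  strand_mode <- match.arg(strand_mode)
  if (!(chrom %in% as.character(GenomicRanges::seqnames(annotation$flat)))) {
    return(character())
  }
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(win, annotation$flat, ignore.strand = TRUE)
  ids <- unique(S4Vectors::mcols(annotation$flat)$gene_id[S4Vectors::subjectHits(hits)])
  if (strand_mode == "both") return(ids)
  gs <- annotation$genes$strand[match(ids, annotation$genes$gene_id)]
  want <- if (strand_mode == "same") strand else flip_strand(strand)
  ids[gs == want & gs != "*" & want != "*"]
}

#' Summarize an AnnotationSet
#'
#' @param annotation an [AnnotationSet].
#' @return list (JSON-ready): total genes, counts by chromosome and by
#'   gene_type, number of unstranded genes, and parse warnings.
#' @export
annotation_summary <- function(annotation) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  g <- annotation$genes
  list(
    source = annotation$meta$source,
    n_genes = nrow(g),
    n_unstranded = sum(g$strand == "*"),
    genes_by_chrom = as.list(table(g$chrom)),
    genes_by_type = as.list(table(g$gene_type)),
    parse = annotation$meta[grep("^n_", names(annotation$meta))],
    warnings = annotation$meta$warnings %||% character())
}
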