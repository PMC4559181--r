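as_count_matrix <- function(counts) {
  if (inherits(counts, "CountTable")) counts <- counts$counts
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop2("counts must be non-negative")
  counts
}

#' Counts per million
#'
#' `CPM(g, s) = 1e6 * count(g, s) / (library_size(s) * norm_factor(s))`.
#' With unit normalization factors every column sums to one million.
#'
#' @param counts a `CountTable` or genes-by-samples matrix.
#' @param norm_factors optional per-sample normalization factors (e.g. from
#'   [tmm_factors()]); default 1.
#' @param log return `log2(CPM + prior)` instead.
#' @param prior pseudocount for the log transform (default 0.5).
#' @return numeric matrix, genes x samples.
#' @export
cpm <- function(counts, norm_factors = NULL, log = FALSE, prior = 0.5) {
  m <- as_count_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stop2("zero library size in sample(s): %s",
                           paste(colnames(m)[lib == 0], collapse = ", "))
  nf <- norm_factors %||% rep(1, ncol(m))
  out <- sweep(m, 2L, lib * nf, "/") * 1e6
  if (log) log2(out + prior) else out
}

#' Reads per kilobase per million
#'
#' `RPKM(g, s) = 1e9 * count(g, s) / (library_size(s) * exonic_length(g))`.
#'
#' @inheritParams cpm
#' @param lengths per-gene exonic lengths in bases (named or in row order).
#' @return numeric matrix, genes x samples.
#' @export
rpkm <- function(counts, lengths, norm_factors = NULL, log = FALSE, prior = 0.5) {
  m <- as_count_matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(m)]
  stopifnot(length(lengths) == nrow(m))
  if (any(is.na(lengths) | lengths <= 0)) stop2("gene lengths must be positive")
  out <- cpm(m, norm_factors = norm_factors) / lengths * 1e3
  if (log) log2(out + prior) else out
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors for count matrices. The reference sample
#' is the column whose 75th percentile of CPM is closest to the mean 75th
#' percentile. For each sample, genes with a zero count in either the
#' sample or the reference are dropped; the remaining genes are doubly
#' trimmed (by the log-ratio M, default 30% each tail, and by the average
#' log abundance A, default 5% each tail); the factor is 2 to the
#' precision-weighted mean of the surviving M-values (binomial delta-method
#' weights). Factors are rescaled so their geometric mean is 1.
#'
#' @param counts a `CountTable` or genes-by-samples matrix (>= 2 samples).
#' @param trim_M two-sided trim fraction on M-values (default 0.30).
#' @param trim_A two-sided trim fraction on A-values (default 0.05).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2L) stop2("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) stop2("sample(s) with all-zero counts: %s",
                           paste(colnames(m)[lib == 0], collapse = ", "))
  f75 <- apply(sweep(m, 2L, lib, "/"), 2L, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(i) {
    if (i == ref) return(1)
    obs <- m[, i]; refc <- m[, ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    if (length(obs) == 0L) return(1)
    p_o <- obs / lib[i]; p_r <- refc / lib[ref]
    M <- log2(p_o / p_r)
    A <- 0.5 * log2(p_o * p_r)
    if (max(abs(M)) < 1e-10) return(1)  # columns proportional: no shift
    w <- (lib[i] - obs) / (lib[i] * obs) + (lib[ref] - refc) / (lib[ref] * refc)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2) || sum(w[keep2]) == 0) return(1)
    2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }
  f <- vapply(seq_len(ncol(m)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Filter for expressed genes
#'
#' Keeps genes whose maximal CPM across all samples is strictly greater
#' than `min_cpm`.
#'
#' @param counts a `CountTable` or genes-by-samples matrix.
#' @param min_cpm CPM threshold (default 1; strict inequality).
#' @return character vector of surviving gene ids (row names), or integer
#'   indices if the matrix has no row names.
#' @export
expressed_filter <- function(counts, min_cpm = 1) {
  m <- as_count_matrix(counts)
  keep <- apply(cpm(m), 1L, max) > min_cpm
  if (is.null(rownames(m))) which(keep) else rownames(m)[keep]
}

#' Sample-sample Pearson correlation matrix
#'
#' @param expr expression matrix, genes x samples, typically
#'   `log2(RPKM + 0.5)` over the expressed gene subset.
#' @return symmetric samples-by-samples correlation matrix with unit
#'   diagonal; entries involving a zero-variance sample are NA (with a
#'   warning).
#' @export
correlation_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2L) stop2("need at least 2 genes for correlations")
  sds <- apply(expr, 2L, stats::sd)
  cc <- suppressWarnings(cor(expr, method = "pearson"))
  if (any(sds == 0)) {
    warning(sprintf("zero-variance sample(s): %s; correlations set to NA",
                    paste(colnames(expr)[sds == 0], collapse = ", ")), call. = FALSE)
    cc[sds == 0, ] <- NA; cc[, sds == 0] <- NA
  }
  diag(cc) <- 1
  cc
}

welch_t <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- apply(X, 1L, stats::var); vy <- apply(Y, 1L, stats::var)
  se2 <- vx / n1 + vy / n2
  t <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / n1)^2 / (n1 - 1) + (vy / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  # degenerate rows (no variance in either group): identical means -> 1
  zero <- se2 == 0
  p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
  list(t = t, df = df, p = p, diff = mx - my)
}

#' Protocol discordance analysis
#'
#' Compares per-gene expression between stranded and non-stranded samples
#' of the same material. Counts are filtered to expressed genes
#' ([expressed_filter()] over all samples), TMM-normalized, converted to
#' `log2(CPM + prior)`, and tested per gene with a Welch t-test
#' (stranded vs non-stranded) with Benjamini-Hochberg adjustment. The
#' moderated empirical-Bayes fit used for full-scale differential analyses
#' is deliberately not reproduced here; the Welch test is this package's
#' documented substitute. A gene is flagged discordant when
#' `|log2FC| > log2(fold_change_min)` and `adj_p < adj_p_max`. With fewer
#' than 2 replicates per protocol the report degrades to fold-change-only
#' mode (no p-values; flag by fold change alone, `fc_only` attribute set).
#'
#' @param counts_stranded,counts_nonstranded `CountTable`s or matrices over
#'   the same gene universe.
#' @param fold_change_min fold-change threshold (default 1.5, linear scale).
#' @param adj_p_max adjusted-p threshold (default 0.05).
#' @param prior pseudocount for the log transform (default 0.5).
#' @param min_cpm expression filter threshold (default 1).
#' @return data.frame (one row per expressed gene): `gene_id`, `log2FC`
#'   (stranded minus non-stranded group mean of log2(CPM + prior)),
#'   `p_value`, `adj_p`, `discordant`.
#' @export
discordance <- function(counts_stranded, counts_nonstranded,
                        fold_change_min = 1.5, adj_p_max = 0.05,
                        prior = 0.5, min_cpm = 1) {
  S <- as_count_matrix(counts_stranded)
  NS <- as_count_matrix(counts_nonstranded)
  if (!identical(rownames(S), rownames(NS)))
    stop2("stranded and non-stranded tables must share the same gene universe")
  all_counts <- cbind(S, NS)
  keep <- expressed_filter(all_counts, min_cpm = min_cpm)
  if (length(keep) == 0L) stop2("no gene passes the expression filter")
  nf <- tmm_factors(all_counts)
  lcpm <- cpm(all_counts, norm_factors = nf, log = TRUE, prior = prior)[keep, , drop = FALSE]
  Xs <- lcpm[, seq_len(ncol(S)), drop = FALSE]
  Xn <- lcpm[, ncol(S) + seq_len(ncol(NS)), drop = FALSE]
  fc_only <- ncol(Xs) < 2L || ncol(Xn) < 2L
  if (fc_only) {
    log2FC <- rowMeans(Xs) - rowMeans(Xn)
    out <- data.frame(gene_id = keep, log2FC = log2FC,
                      p_value = NA_real_, adj_p = NA_real_,
                      discordant = abs(log2FC) > log2(fold_change_min),
                      stringsAsFactors = FALSE)
  } else {
    wt <- welch_t(Xs, Xn)
    adj <- p.adjust(wt$p, method = "BH")
    out <- data.frame(gene_id = keep, log2FC = wt$diff,
                      p_value = wt$p, adj_p = adj,
                      discordant = abs(wt$diff) > log2(fold_change_min) & adj < adj_p_max,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "fc_only") <- fc_only
  attr(out, "thresholds") <- c(fold_change_min = fold_change_min, adj_p_max = adj_p_max)
  out
}

#' Collapse Gencode biotypes to breakdown categories
#'
#' Any biotype containing "pseudogene" collapses to `pseudogene`; the named
#' categories `protein_coding`, `antisense`, `lincRNA`,
#' `processed_transcript` and `sense_intronic` are kept; everything else
#' becomes `other`.
#'
#' @param gene_type character vector of biotype strings.
#' @return character vector of category labels.
#' @export
collapse_gene_type <- function(gene_type) {
  named <- c("protein_coding", "antisense", "lincRNA",
             "processed_transcript", "sense_intronic")
  out <- ifelse(grepl("pseudogene", gene_type), "pseudogene",
                ifelse(gene_type %in% named, gene_type, "other"))
  out
}

#' Gene-type breakdown of discordance and opposite-strand overlap
#'
#' Tallies, per gene-type category, the expressed genes, the discordant
#' genes, their ratio, and the 2x2 split of discordance against
#' participation in at least one opposite-strand overlapping pair. Within
#' each row the four split cells sum to the number of expressed genes.
#'
#' @param report a [discordance()] report (its genes define "expressed").
#' @param annotation an [AnnotationSet] supplying `gene_type`.
#' @param pairs_opposite opposite-strand pair table from
#'   [find_overlapping_pairs()].
#' @return data.frame with rows per category plus `Total`: `gene_type`,
#'   `n_expressed`, `n_discordant`, `ratio_pct`, `de_overlap_no`,
#'   `de_overlap_yes`, `nonde_overlap_no`, `nonde_overlap_yes`.
#' @export
breakdown_by_type <- function(report, annotation, pairs_opposite) {
  stopifnot(inherits(annotation, "AnnotationSet"))
  overlap_ids <- unique(c(pairs_opposite$gene_a, pairs_opposite$gene_b))
  gt <- annotation$genes$gene_type[match(report$gene_id, annotation$genes$gene_id)]
  cat_ <- collapse_gene_type(ifelse(is.na(gt), "unknown", gt))
  de <- report$discordant
  ov <- report$gene_id %in% overlap_ids
  lvl <- c("protein_coding", "antisense", "pseudogene", "lincRNA",
           "processed_transcript", "sense_intronic", "other")
  tally <- function(sel) {
    data.frame(
      n_expressed = sum(sel),
      n_discordant = sum(sel & de),
      ratio_pct = if (sum(sel)) 100 * sum(sel & de) / sum(sel) else 0,
      de_overlap_no = sum(sel & de & !ov),
      de_overlap_yes = sum(sel & de & ov),
      nonde_overlap_no = sum(sel & !de & !ov),
      nonde_overlap_yes = sum(sel & !de & ov))
  }
  rows <- lapply(lvl, function(l) cbind(gene_type = l, tally(cat_ == l)))
  rows <- rows[vapply(rows, function(r) r$n_expressed > 0, logical(1))]
  out <- do.call(rbind, c(rows, list(cbind(gene_type = "Total", tally(rep(TRUE, length(de)))))))
  rownames(out) <- NULL
  out
}

format_p <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", format(p, digits = 4))
}

#' Two-proportion test
#'
#' Chi-square-based test of equality of two binomial proportions with Yates
#' continuity correction (the `prop.test` default), two-sided. P-values
#' below 2.2e-16 are additionally reported with the conventional
#' "< 2.2e-16" floor string.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `statistic`, `p_value`, `p_display`, `estimate`
#'   (the two proportions).
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop2("trial counts must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop2("need 0 <= x <= n")
  ht <- stats::prop.test(c(x1, x2), c(n1, n2), correct = correct)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       p_display = format_p(ht$p.value), estimate = unname(ht$estimate))
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square with Yates continuity correction (the `chisq.test`
#' default for 2x2 tables), df = 1.
#'
#' @param table 2x2 matrix of non-negative counts with positive marginals.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `statistic`, `df`, `p_value`, `p_display`.
#' @export
chi_square_independence <- function(table, correct = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop2("all table marginals must be positive")
  ht <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, p_display = format_p(ht$p.value))
}
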