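simple_frag <- function(chrom, m1, m2, m1_strand = "-", id = "f1",
                        unique = TRUE, both_ends = TRUE, chimeric = FALSE) {
  fragment_set(
    data.frame(fragment_id = id, chrom = chrom, m1_strand = m1_strand,
               m2_strand = flip_strand(m1_strand), unique = unique,
               both_ends = both_ends, chimeric = chimeric,
               stringsAsFactors = FALSE),
    data.frame(frag = 1L, mate = c(1L, 2L), chrom = chrom,
               start = c(m1[1], m2[1]), end = c(m1[2], m2[2]),
               stringsAsFactors = FALSE))
}

plus_gene <- annotation_set(data.frame(chrom = "chr1", start = 1001, end = 3000,
                                       strand = "+", gene_id = "PG"))

test_that("reverse-stranded rule counts only read-1-antisense fragments", {
  # mate1 on "-" inside a "+" gene: assigned under reverse_stranded
  fr <- simple_frag("chr1", m1 = c(1501, 1600), m2 = c(1301, 1400), m1_strand = "-")
  r <- classify_fragment(fr, plus_gene, protocol_config("reverse_stranded"))
  expect_equal(r$category, "assigned")
  expect_equal(r$gene_id, "PG")
  # same fragment with mate1 on "+": sense to the gene, not counted
  fr2 <- simple_frag("chr1", m1 = c(1301, 1400), m2 = c(1501, 1600), m1_strand = "+")
  r2 <- classify_fragment(fr2, plus_gene, protocol_config("reverse_stranded"))
  expect_equal(r2$category, "no_feature")
  # unstranded mode takes both
  expect_equal(classify_fragment(fr2, plus_gene, protocol_config("unstranded"))$category,
               "assigned")
})

test_that("opposite-strand gene overlap is ambiguous unstranded, resolved reverse-stranded", {
  ann <- annotation_set(data.frame(chrom = "chr1", start = c(1, 1), end = c(2000, 2000),
                                   strand = c("+", "-"), gene_id = c("P", "M")))
  fr <- simple_frag("chr1", m1 = c(501, 600), m2 = c(701, 800), m1_strand = "-")
  ru <- classify_fragment(fr, ann, protocol_config("unstranded"))
  expect_equal(ru$category, "ambiguous")
  expect_equal(ru$candidates[[1]], c("M", "P"))
  rs <- classify_fragment(fr, ann, protocol_config("reverse_stranded"))
  expect_equal(rs$category, "assigned")
  expect_equal(rs$gene_id, "P")  # mate1 "-" is antisense to the "+" gene
})

test_that("min-overlap threshold is a strict boundary on summed mate overlap", {
  # gene starts at 1001; mates overlap it by 30 + 29 = 59 bases -> below 60
  fr59 <- simple_frag("chr1", m1 = c(931, 1030), m2 = c(930, 1029), m1_strand = "-")
  expect_equal(classify_fragment(fr59, plus_gene, protocol_config("unstranded"))$category,
               "no_feature")
  # one more base: 30 + 30 = 60 -> assigned (overlapping mates count once per mate)
  fr60 <- simple_frag("chr1", m1 = c(931, 1030), m2 = c(931, 1030), m1_strand = "-")
  expect_equal(classify_fragment(fr60, plus_gene, protocol_config("unstranded"))$category,
               "assigned")
  # per-mate mode: neither mate alone reaches 60
  expect_equal(classify_fragment(fr60, plus_gene,
                                 protocol_config("unstranded", mate_overlap = "per_mate"))$category,
               "no_feature")
})

test_that("mapping filters fire before assignment", {
  cfg <- protocol_config("unstranded")
  f_multi <- simple_frag("chr1", c(1501, 1600), c(1301, 1400), unique = FALSE)
  f_single <- simple_frag("chr1", c(1501, 1600), c(1301, 1400), both_ends = FALSE)
  f_chim <- simple_frag("chr1", c(1501, 1600), c(1301, 1400), chimeric = TRUE)
  expect_equal(classify_fragment(f_multi, plus_gene, cfg)$category, "filtered")
  expect_equal(classify_fragment(f_single, plus_gene, cfg)$category, "filtered")
  expect_equal(classify_fragment(f_chim, plus_gene, cfg)$category, "filtered")
  relaxed <- protocol_config("unstranded", require_both_ends = FALSE)
  expect_equal(classify_fragment(f_single, plus_gene, relaxed)$category, "assigned")
  # unknown chromosome: no_feature, not an error
  f_off <- simple_frag("chrZ", c(1501, 1600), c(1301, 1400))
  expect_equal(classify_fragment(f_off, plus_gene, cfg)$category, "no_feature")
})

test_that("counting satisfies conservation and permutation invariance", {
  cfg0 <- simulation_config(list(locus("partial_opposite_strand", n = 3),
                                 locus("disjoint", n = 3)),
                            n_fragments = 400, protocol = "non_stranded", seed = 21)
  ann <- generate_annotation(cfg0)
  sim <- simulate_fragments(ann, cfg0)
  for (mode in c("unstranded", "reverse_stranded")) {
    ct <- count_fragments(sim$fragments, ann, protocol_config(mode))
    s <- ct$summary
    expect_equal(s$n_assigned + s$n_ambiguous + s$n_no_feature + s$n_filtered, s$n_total)
    expect_equal(sum(ct$counts), s$n_assigned)
    # permute fragments: identical counts and summary
    perm <- sample(length(sim$fragments))
    fr <- sim$fragments
    remap <- match(seq_along(perm), perm)
    fr$frags <- fr$frags[perm, ]
    fr$blocks$frag <- remap[fr$blocks$frag]
    fr$blocks <- fr$blocks[order(fr$blocks$frag, fr$blocks$mate, fr$blocks$start), ]
    ct2 <- count_fragments(fr, ann, protocol_config(mode))
    expect_equal(ct2$counts, ct$counts)
    expect_equal(ct2$summary[, -1], ct$summary[, -1])
  }
})

test_that("classification matches the exhaustive per-fragment oracle", {
  set.seed(303)
  cfg0 <- simulation_config(list(locus("partial_opposite_strand", overlap_fraction = 0.3),
                                 locus("nested_same_strand"),
                                 locus("disjoint", n_exons = 3)),
                            n_fragments = 60, protocol = "non_stranded", seed = 17)
  ann <- generate_annotation(cfg0)
  sim <- simulate_fragments(ann, cfg0)
  fr <- sim$fragments
  # inject filterable fragments
  fr$frags$unique[1:3] <- FALSE
  fr$frags$chimeric[4:5] <- TRUE
  for (mode in c("unstranded", "reverse_stranded")) {
    cfg <- protocol_config(mode)
    got <- classify_fragments(fr, ann, cfg)
    want <- oracle_classify(fr, ann, cfg)
    expect_equal(got$category, want$category)
    amb <- got$category == "ambiguous"
    expect_equal(got$candidates[amb], want$candidates[amb])
  }
})

test_that("reverse-stranded ambiguity is a subset of unstranded ambiguity", {
  set.seed(404)
  for (rep in 1:10) {
    cfg0 <- simulation_config(list(
      locus("partial_opposite_strand", overlap_fraction = stats::runif(1, 0.1, 1)),
      locus("partial_same_strand", overlap_fraction = stats::runif(1, 0.1, 1)),
      locus("nested_opposite_strand"), locus("disjoint")),
      n_fragments = 200, protocol = sample(c("stranded_dutp", "non_stranded"), 1),
      seed = 1000 + rep)
    ann <- generate_annotation(cfg0)
    sim <- simulate_fragments(ann, cfg0)
    cu <- classify_fragments(sim$fragments, ann, protocol_config("unstranded"))
    cr <- classify_fragments(sim$fragments, ann, protocol_config("reverse_stranded"))
    amb_u <- cu$fragment_id[cu$category == "ambiguous"]
    amb_r <- cr$fragment_id[cr$category == "ambiguous"]
    expect_true(all(amb_r %in% amb_u))
  }
})

test_that("count_table assembles columns and validates the gene universe", {
  cfg0 <- simulation_config(locus("disjoint", n = 2), n_fragments = 100,
                            protocol = "stranded_dutp", seed = 3)
  ann <- generate_annotation(cfg0)
  sim <- simulate_fragments(ann, cfg0)
  c1 <- count_fragments(sim$fragments, ann, protocol_config("reverse_stranded"), "s1")
  c2 <- count_fragments(sim$fragments, ann, protocol_config("unstranded"), "s2")
  ct <- count_table(list(s1 = c1, s2 = c2))
  expect_equal(dim(ct$counts), c(2L, 2L))
  expect_equal(colSums(ct$counts), setNames(ct$summary$n_assigned, c("s1", "s2")))
  # empty input column
  empty <- fragment_set(
    data.frame(fragment_id = character(), chrom = character(),
               m1_strand = character(), m2_strand = character(),
               unique = logical(), both_ends = logical(), chimeric = logical()),
    data.frame(frag = integer(), mate = integer(), chrom = character(),
               start = integer(), end = integer()))
  c0 <- count_fragments(empty, ann, protocol_config("unstranded"), "s0")
  expect_equal(sum(c0$counts), 0L)
  expect_equal(c0$summary$n_total, 0L)
})

test_that("fragment TSV round-trips, including junction-split mates", {
  cfg0 <- simulation_config(locus("disjoint", n_exons = 4, gene_length = 1200),
                            n_fragments = 50, protocol = "stranded_dutp", seed = 9)
  ann <- generate_annotation(cfg0)
  sim <- simulate_fragments(ann, cfg0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(sim$fragments, tsv)
  back <- read_fragments(tsv)
  expect_equal(back$frags, sim$fragments$frags)
  expect_equal(back$blocks, sim$fragments$blocks)
})

sam_header <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:100000")
sam_line <- function(qname, flag, pos, cigar = "100M", mapq = 255, rnext = "=",
                     pnext = 1, chrom = "chr1") {
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, 0,
        strrep("A", 100), "*", sep = "\t")
}

test_that("SAM ingest pairs mates, derives flags and CIGAR-aware blocks", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    sam_header,
    # proper pair: read1 forward at 1001, read2 reverse at 1201
    sam_line("p1", 99, 1001), sam_line("p1", 147, 1201),
    # read1 reverse / read2 forward
    sam_line("p2", 83, 2201), sam_line("p2", 163, 2001),
    # secondary alignment must be ignored
    sam_line("p2", 339, 5001),
    # junction-spanning read1 (40M200N60M) + mate
    sam_line("p3", 99, 3001, cigar = "40M200N60M"), sam_line("p3", 147, 3301),
    # low-MAPQ pair (multi-mapper convention)
    sam_line("p4", 99, 4001, mapq = 3), sam_line("p4", 147, 4201, mapq = 3),
    # orphan read1
    sam_line("p5", 73, 6001)), sam)
  fr <- read_sam(sam)
  f <- fr$frags[order(fr$frags$fragment_id), ]
  expect_equal(f$fragment_id, c("p1", "p2", "p3", "p4", "p5"))
  expect_equal(f$m1_strand, c("+", "-", "+", "+", "+"))
  expect_equal(f$m2_strand, c("-", "+", "-", "-", NA))
  expect_equal(f$unique, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(f$both_ends, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(f$chimeric))
  # intervals: p1 mate1 1001..1100, mate2 1201..1300
  b1 <- fr$blocks[fr$blocks$frag == which(fr$frags$fragment_id == "p1"), ]
  expect_equal(b1$start[b1$mate == 1], 1001)
  expect_equal(b1$end[b1$mate == 1], 1100)
  expect_equal(b1$start[b1$mate == 2], 1201)
  expect_equal(b1$end[b1$mate == 2], 1300)
  # p3 mate1 splits into 3001..3040 and 3241..3300
  b3 <- fr$blocks[fr$blocks$frag == which(fr$frags$fragment_id == "p3"), ]
  expect_equal(b3$start[b3$mate == 1], c(3001, 3241))
  expect_equal(b3$end[b3$mate == 1], c(3040, 3300))
  # secondary alignment contributed no extra p2 blocks
  b2 <- fr$blocks[fr$blocks$frag == which(fr$frags$fragment_id == "p2"), ]
  expect_equal(nrow(b2), 2L)
  expect_false(any(b2$start == 5001))
})

test_that("SAM-ingested fragments count identically to their tabular form", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               sam_line("q1", 99, 1101), sam_line("q1", 147, 1401),
               sam_line("q2", 83, 1901), sam_line("q2", 163, 1701)), sam)
  fr <- read_sam(sam)
  ct <- count_fragments(fr, plus_gene, protocol_config("reverse_stranded"))
  # q2 has mate1 on "-": antisense to the "+" gene; q1 has mate1 on "+"
  expect_equal(unname(ct$counts["PG"]), 1L)
  expect_equal(ct$summary$n_no_feature, 1L)
})
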