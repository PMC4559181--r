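test_that("locus templates validate their geometry", {
  expect_error(locus("partial_same_strand", n_exons = 2), "disjoint")
  expect_error(locus("nested_opposite_strand", gene_length = 500,
                     partner_length = 800), "partner_length")
  expect_error(locus("partial_opposite_strand", overlap_fraction = 0), "overlap_fraction")
  expect_error(locus("partial_opposite_strand", partner_length = 100,
                     overlap_fraction = 0.001), "rounds to 0")
  # opposite-strand partners default to the antisense biotype
  expect_equal(locus("nested_opposite_strand")$partner_type, "antisense")
  expect_equal(locus("partial_same_strand")$partner_type, "protein_coding")
})

test_that("each locus template realizes its declared relation exactly", {
  # one nested opposite locus: exactly one opposite pair with ratio 1
  cfg <- simulation_config(locus("nested_opposite_strand", gene_length = 2000,
                                 partner_length = 800), seed = 2)
  os <- overlap_summary(generate_annotation(cfg))
  expect_equal(unname(os$n_pairs), c(0L, 1L))
  expect_equal(os$pairs$overlap_ratio, 1)
  expect_equal(unname(os$containment["n_contained_opposite"]), 1L)

  # 100 disjoint loci: no pairs in either relation
  cfg2 <- simulation_config(locus("disjoint", n = 100, gene_length = 500), seed = 2)
  os2 <- overlap_summary(generate_annotation(cfg2))
  expect_equal(unname(os2$n_pairs), c(0L, 0L))

  # k partial opposite loci at fraction f: median opposite ratio == f
  f <- 0.37
  cfg3 <- simulation_config(locus("partial_opposite_strand", n = 9,
                                  partner_length = 1000, overlap_fraction = f),
                            seed = 2)
  os3 <- overlap_summary(generate_annotation(cfg3))
  expect_equal(os3$ratio_opposite$median, f, tolerance = 1e-9)
  expect_equal(unname(os3$n_pairs), c(0L, 9L))
})

test_that("annotation generation and fragment simulation are byte-deterministic", {
  cfg <- simulation_config(list(locus("partial_opposite_strand"), locus("disjoint")),
                           n_fragments = 300, protocol = "non_stranded", seed = 77)
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  g1 <- withr::local_tempfile(fileext = ".gtf")
  g2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(a1, g1); write_gtf(a2, g2)
  expect_identical(readLines(g1), readLines(g2))
  s1 <- simulate_fragments(a1, cfg); s2 <- simulate_fragments(a2, cfg)
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(s1$fragments, t1); write_fragments(s2$fragments, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("sampling respects expression weights and exonic lengths", {
  cfg <- simulation_config(locus("disjoint", n = 3, gene_length = 1000),
                           n_fragments = 10000, protocol = "stranded_dutp",
                           expression_weights = c(SYNG0003 = 0), seed = 5)
  ann <- generate_annotation(cfg)
  sim <- simulate_fragments(ann, cfg)
  # weight 0: no fragments from that gene
  expect_equal(unname(sim$truth$per_gene["SYNG0003"]), 0L)
  # two equal-weight, equal-length genes: counts within binomial 3 SE of 5000
  expect_equal(sum(sim$truth$per_gene), 10000L)
  se <- sqrt(10000 * 0.5 * 0.5)
  expect_lt(abs(sim$truth$per_gene[["SYNG0001"]] - 5000), 3 * se)
  # truth totals match the per-fragment source table
  expect_equal(unname(sim$truth$per_gene),
               unname(as.integer(table(factor(sim$truth$source$gene_id,
                                              levels = ann$genes$gene_id)))))
})

test_that("fragments longer than their gene are truncated with a warning", {
  cfg <- simulation_config(locus("disjoint", gene_length = 120),
                           n_fragments = 50, protocol = "stranded_dutp",
                           fragment_mean = 200, fragment_sd = 10, seed = 6)
  ann <- generate_annotation(cfg)
  expect_warning(sim <- simulate_fragments(ann, cfg), "truncated")
  expect_gt(sim$truth$n_truncated, 0)
  bl <- sim$fragments$blocks
  expect_true(all(bl$start >= ann$genes$span_start & bl$end <= ann$genes$span_end))
})

test_that("dUTP protocol puts read 1 antisense to the source gene", {
  cfg <- simulation_config(list(locus("disjoint"),
                                locus("nested_opposite_strand")),
                           n_fragments = 500, protocol = "stranded_dutp", seed = 8)
  ann <- generate_annotation(cfg)
  sim <- simulate_fragments(ann, cfg)
  src_strand <- ann$genes$strand[match(sim$truth$source$gene_id, ann$genes$gene_id)]
  expect_true(all(sim$fragments$frags$m1_strand == flip_strand(src_strand)))
  # non-stranded: read 1 orientation is a fair coin
  cfg2 <- simulation_config(locus("disjoint"), n_fragments = 2000,
                            protocol = "non_stranded", seed = 8)
  sim2 <- simulate_fragments(generate_annotation(cfg2), cfg2)
  n_plus <- sum(sim2$fragments$frags$m1_strand == "+")
  expect_lt(abs(n_plus - 1000), 3 * sqrt(2000 * 0.25))
})

test_that("junction-spanning mates are emitted as per-exon blocks", {
  cfg <- simulation_config(locus("disjoint", n_exons = 4, gene_length = 1200),
                           n_fragments = 200, protocol = "stranded_dutp", seed = 9)
  ann <- generate_annotation(cfg)
  sim <- simulate_fragments(ann, cfg)
  bl <- sim$fragments$blocks
  # some mates must split (exons are 300 bases, reads 100)
  per_mate <- table(paste(bl$frag, bl$mate))
  expect_gt(max(per_mate), 1)
  # every block lies inside an exon, never in an intron
  ex <- as.data.frame(ann$flat)
  in_exon <- vapply(seq_len(nrow(bl)), function(i) {
    any(ex$start <= bl$start[i] & ex$end >= bl$end[i])
  }, logical(1))
  expect_true(all(in_exon))
  # per-fragment mate footprint in spliced bases equals min(read, fragment) length
  dt <- data.table::as.data.table(bl)
  mate_len <- dt[, .(len = sum(end - start + 1L)), by = .(frag, mate)]
  expect_true(all(mate_len$len <= cfg$read_length))
})

test_that("end-to-end conservation: overlap-free annotations count back the truth exactly", {
  cfg <- simulation_config(locus("disjoint", n = 6, gene_length = 900),
                           n_fragments = 1500, protocol = "stranded_dutp", seed = 10)
  ann <- generate_annotation(cfg)
  sim <- simulate_fragments(ann, cfg)
  for (mode in c("unstranded", "reverse_stranded")) {
    ct <- count_fragments(sim$fragments, ann, protocol_config(mode))
    expect_equal(ct$counts, sim$truth$per_gene)
    expect_equal(ct$summary$n_ambiguous, 0L)
    expect_equal(ct$summary$n_no_feature, 0L)
  }
})

test_that("nested antisense locus reproduces the contained-gene phenomenon", {
  # all expression on the inner antisense-overlapped gene
  cfg <- simulation_config(locus("nested_opposite_strand", gene_length = 2000,
                                 partner_length = 800),
                           n_fragments = 1000, protocol = "stranded_dutp",
                           expression_weights = c(SYNG0001 = 0), seed = 11)
  ann <- generate_annotation(cfg)
  sim <- simulate_fragments(ann, cfg)
  inner <- "SYNG0002"
  ctU <- count_fragments(sim$fragments, ann, protocol_config("unstranded"))
  ctS <- count_fragments(sim$fragments, ann, protocol_config("reverse_stranded"))
  # unstranded: every fragment ambiguous, inner gene invisible
  expect_equal(unname(ctU$counts[inner]), 0L)
  expect_equal(ctU$summary$n_ambiguous, 1000L)
  # reverse-stranded: ambiguity fully resolved to the inner gene
  expect_equal(unname(ctS$counts[inner]), 1000L)
  expect_equal(ctS$summary$n_ambiguous, 0L)
})

test_that("analytic expectations hit the degenerate limits", {
  # disjoint annotation: ambiguity 0 under both modes
  cfg <- simulation_config(locus("disjoint", n = 4), protocol = "stranded_dutp")
  es <- expected_summary(generate_annotation(cfg), cfg)
  expect_equal(es$aggregate$ambiguous, c(0, 0))
  # fully nested antisense locus, all expression inner:
  # unstranded ambiguous 1, reverse-stranded 0
  cfg2 <- simulation_config(locus("nested_opposite_strand", gene_length = 2000,
                                  partner_length = 800),
                            protocol = "stranded_dutp",
                            expression_weights = c(SYNG0001 = 0))
  es2 <- expected_summary(generate_annotation(cfg2), cfg2)
  agg <- es2$aggregate
  expect_equal(agg$ambiguous[agg$mode == "unstranded"], 1)
  expect_equal(agg$ambiguous[agg$mode == "reverse_stranded"], 0)
  expect_equal(agg$assigned[agg$mode == "reverse_stranded"], 1)
})

test_that("Monte-Carlo ambiguity agrees with the analytic value over seeds", {
  base <- simulation_config(locus("partial_opposite_strand", gene_length = 2000,
                                  partner_length = 1000, overlap_fraction = 0.5),
                            n_fragments = 2000, protocol = "stranded_dutp")
  ann <- generate_annotation(base)
  es <- expected_summary(ann, base)
  p_un <- es$aggregate$ambiguous[es$aggregate$mode == "unstranded"]
  p_rev <- es$aggregate$ambiguous[es$aggregate$mode == "reverse_stranded"]
  expect_equal(p_rev, 0)  # opposite-strand overlap is resolvable
  emp <- vapply(1:5, function(sd) {
    cfg <- simulation_config(base$loci, n_fragments = 2000,
                             protocol = "stranded_dutp", seed = 100 + sd)
    sim <- simulate_fragments(ann, cfg)
    ct <- count_fragments(sim$fragments, ann, protocol_config("unstranded"))
    ct$summary$n_ambiguous / ct$summary$n_total
  }, numeric(1))
  se <- sqrt(p_un * (1 - p_un) / (5 * 2000))
  expect_lt(abs(mean(emp) - p_un), 3 * se)
})

test_that("default study configuration realizes the declared genome-like mix", {
  cfg <- default_study_config(n_fragments = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 200L)
  gl <- gene_level_summary(ann)
  gw <- gl[gl$chrom == "genome", ]
  expect_equal(gw$pct_gene_same, 9)
  expect_equal(gw$pct_gene_opposite, 19)
})
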