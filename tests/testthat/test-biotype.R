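# reference: one 3-exon gene per strand plus an intron host
ref_fixture <- function() {
  make_ts(
    list(id = "rA.1", gene = "rA", starts = c(1000, 1550, 3450),
         ends = c(1300, 1950, 3750), strand = "+"),
    list(id = "rB.1", gene = "rB", starts = c(6000, 6550, 8450),
         ends = c(6300, 6950, 8750), strand = "-"))
}

test_that("positional biotypes follow the strand-aware overlap rules", {
  ref <- ref_fixture()
  # far from everything: lincRNA
  calls <- classify_transcripts(
    make_ts(list(id = "t", starts = 20000, ends = 20500, strand = "+")), ref)
  expect_equal(calls$labels, "lincRNA")
  # 1000-nt exonic transcript sharing exactly 100 nt with a + exon,
  # opposite strand: fraction exactly 0.1, inclusive -> NAT
  nat <- make_ts(list(id = "t", starts = 100, ends = 1100, strand = "-"))
  expect_equal(classify_transcripts(nat, ref)$labels, "NAT")
  # same geometry, same strand -> sense_exonic
  sx <- make_ts(list(id = "t", starts = 100, ends = 1100, strand = "+"))
  expect_equal(classify_transcripts(sx, ref)$labels, "sense_exonic")
  # 99 shared nt of 1000: below threshold; not inside an intron -> lincRNA
  sub <- make_ts(list(id = "t", starts = 99, ends = 1099, strand = "-"))
  expect_equal(classify_transcripts(sub, ref)$labels, "lincRNA")
  # wholly inside the long intron, touching no exon -> intronic (any strand)
  intr <- make_ts(list(id = "t", starts = 2100, ends = 2500, strand = "-"))
  expect_equal(classify_transcripts(intr, ref)$labels, "intronic")
  # unknown strand skips exonic labels and falls through
  unk <- make_ts(list(id = "t", starts = 1200, ends = 2200, strand = "*"))
  expect_equal(classify_transcripts(unk, ref)$labels, "lincRNA")
  unk_in <- make_ts(list(id = "t", starts = 2100, ends = 2500, strand = "*"))
  expect_equal(classify_transcripts(unk_in, ref)$labels, "intronic")
  # "both" policy assigns both exonic labels to unknown strands
  both <- classify_transcripts(unk, ref,
                               overlap_config(strand_policy = "both"))
  expect_equal(both$labels, "NAT,sense_exonic")
})

test_that("a transcript between opposing genes is both NAT and sense-exonic", {
  ref <- make_ts(
    list(id = "rA.1", gene = "rA", starts = 1000, ends = 1500, strand = "+"),
    list(id = "rB.1", gene = "rB", starts = 1800, ends = 2300, strand = "-"))
  dual <- make_ts(list(id = "t", starts = 1400, ends = 1900, strand = "+"))
  calls <- classify_transcripts(dual, ref)
  expect_equal(calls$labels, "NAT,sense_exonic")
  expect_true(calls$NAT && calls$sense_exonic && !calls$lincRNA)
})

test_that("empty reference labels everything lincRNA with a warning", {
  cand <- make_ts(list(id = "t", starts = 0, ends = 500))
  expect_warning(calls <- classify_transcripts(cand, NULL), "empty reference")
  expect_equal(calls$labels, "lincRNA")
})

test_that("gene-level aggregation unions isoform labels and counts duals once", {
  calls <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    gene_id = c("g1", "g1", "g2", "g3"),
    labels = c("lincRNA", "NAT", "NAT,sense_exonic", "intronic"),
    stringsAsFactors = FALSE)
  agg <- aggregate_gene_biotypes(calls)
  g1 <- agg$genes[agg$genes$gene_id == "g1", ]
  expect_equal(g1$labels, "NAT,lincRNA")
  expect_true(g1$ambiguous)
  expect_equal(agg$n_multi_label, 2L)
  expect_equal(agg$n_distinct_genes, 3L)
  # distinct genes = sum of per-label gene counts minus the label surplus
  surplus <- sum(agg$genes$n_labels - 1L)
  expect_equal(distinct_gene_count(agg$label_gene_counts, surplus),
               agg$n_distinct_genes)
  # all single-label: plain sum
  single <- aggregate_gene_biotypes(calls[c(2, 4), ])
  expect_equal(single$n_distinct_genes,
               sum(single$label_gene_counts))
})

test_that("annotation comparison requires identical spans on the same strand", {
  a <- make_ts(list(id = "a1", starts = c(100, 300), ends = c(200, 400),
                    strand = "+"),
               list(id = "a2", starts = 1000, ends = 1500, strand = "+"))
  b_same <- make_ts(list(id = "b1", starts = c(100, 320),
                         ends = c(180, 400), strand = "+"))
  cmp <- compare_annotations(a, b_same)   # same span, different exons: shared
  expect_equal(cmp$n_shared_a, 1L)
  expect_equal(cmp$shared_pairs$transcript_a, "a1")
  # 1 bp extension at the 3' end breaks reciprocal full overlap
  b_ext <- make_ts(list(id = "b1", starts = 100, ends = 401, strand = "+"))
  expect_equal(compare_annotations(a, b_ext)$n_shared_a, 0L)
  # opposite strand is never shared
  b_rev <- make_ts(list(id = "b1", starts = 100, ends = 400, strand = "-"))
  expect_equal(compare_annotations(a, b_rev)$n_shared_a, 0L)
  # shared counts are symmetric
  cmp_ab <- compare_annotations(a, b_same)
  cmp_ba <- compare_annotations(b_same, a)
  expect_equal(cmp_ab$n_shared_a, cmp_ba$n_shared_b)
  # disjoint chromosome names error
  b_chr <- make_ts(list(id = "b1", chrom = "chrX", starts = 100, ends = 400))
  expect_error(compare_annotations(a, b_chr), "chromosome")
})

test_that("classifier labels agree with the base-level brute force on random instances", {
  set.seed(99)
  for (rep in 1:12) {
    n_ref <- sample(2:5, 1)
    ref_rows <- lapply(seq_len(n_ref), function(i) {
      g <- (i - 1) * 4000 + sample(0:500, 1)
      list(id = sprintf("r%d.1", i), gene = sprintf("r%d", i),
           starts = g + c(0, 700), ends = g + c(300, 1200),
           strand = sample(c("+", "-"), 1))
    })
    ref <- do.call(make_ts, ref_rows)
    cand_rows <- lapply(1:8, function(j) {
      s <- sample(0:(n_ref * 4000), 1)
      list(id = sprintf("t%d", j), starts = s, ends = s + sample(150:900, 1),
           strand = sample(c("+", "-", "*"), 1, prob = c(.45, .45, .1)))
    })
    cand <- do.call(make_ts, cand_rows)
    got <- classify_transcripts(cand, ref)
    exp <- oracle_classify(cand, ref)
    for (tid in got$transcript_id) {
      expect_equal(got$labels[got$transcript_id == tid], exp[[tid]],
                   info = paste("rep", rep, tid))
    }
  }
})
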