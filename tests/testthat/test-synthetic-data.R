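test_that("the generator is deterministic given the seed", {
  cfg <- small_sim_config(seed = 7)
  a <- simulate_genome_and_annotation(cfg)
  b <- simulate_genome_and_annotation(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$candidates$exons, b$candidates$exons)
  expect_identical(a$candidates$sequences, b$candidates$sequences)
  expect_identical(a$transcripts, b$transcripts)
  ev_a <- simulate_evidence(a$transcripts, cfg)
  ev_b <- simulate_evidence(b$transcripts, cfg)
  expect_identical(ev_a, ev_b)
})

test_that("planted lincRNAs overlap no reference gene base", {
  geno <- simulate_genome_and_annotation(small_sim_config(seed = 2))
  man <- geno$transcripts
  linc_ids <- man$transcript_id[man$biotype == "lincRNA"]
  ref_sp <- transcript_spans(geno$reference)
  cand_sp <- transcript_spans(geno$candidates)
  for (tid in linc_ids) {
    t <- cand_sp[cand_sp$transcript_id == tid, ]
    same <- ref_sp[ref_sp$chrom == t$chrom, ]
    ov <- pmin(same$end, t$end) - pmax(same$start, t$start)
    expect_true(all(ov <= 0), info = tid)
  }
})

test_that("manifest biotypes equal the brute-force overlap oracle for every candidate", {
  geno <- simulate_genome_and_annotation(small_sim_config(seed = 3))
  man <- geno$transcripts
  got <- oracle_classify(geno$candidates, geno$reference)
  for (i in seq_len(nrow(man))) {
    expect_equal(got[[man$transcript_id[i]]], man$biotype[i],
                 info = man$transcript_id[i])
  }
})

test_that("clean lncRNAs carry no evidence; threshold witnesses are planted exactly", {
  cfg <- small_sim_config(seed = 4)
  geno <- simulate_genome_and_annotation(cfg)
  ev <- simulate_evidence(geno$transcripts, cfg)
  man <- geno$transcripts
  plain_clean <- man$transcript_id[man$class == "clean" & man$witness == "" &
                                     !man$rescuable]
  all_rows <- unlist(lapply(ev, function(df) df$qseqid))
  expect_length(intersect(plain_clean, all_rows), 0L)
  # exact boundary plantings
  expect_equal(ev$blastp_hits$evalue[ev$blastp_hits$qseqid ==
                                       "cont_evalue_boundary"], 1e-6)
  expect_equal(ev$signal_peptides$d_score[ev$signal_peptides$qseqid ==
                                            "cont_signalp"], 0.45)
  nr <- ev$nr_best_hits
  expect_equal(nr$pident[nr$qseqid == "cont_rescue_boundary"], 70)
  expect_match(nr$description[nr$qseqid == "cont_rescue_kw"],
               "hypothetical protein")
  # the rescuable boundary witness keeps a keyword description
  expect_match(nr$description[nr$qseqid == "cont_rescue_boundary"],
               "unknown")
})

test_that("length/ORF/intron witnesses sit exactly on their thresholds", {
  geno <- simulate_genome_and_annotation(small_sim_config(seed = 5))
  len <- exonic_lengths(geno$candidates)
  expect_equal(unname(len[["decoy_199nt"]]), 199)
  expect_equal(unname(len[["linc_200nt"]]), 200)
  intr <- derive_introns(geno$candidates)
  iw <- function(id) {
    r <- intr[intr$transcript_id == id, ]
    max(r$end - r$start)
  }
  expect_equal(iw("decoy_intron6001"), 6001)
  expect_equal(iw("linc_intron6000"), 6000)
  orf_aa <- function(id) {
    find_longest_orf(geno$candidates$sequences[[id]])$peptide_length_aa
  }
  expect_equal(orf_aa("cont_orf101"), 101L)
  expect_equal(orf_aa("linc_orf100"), 100L)
})

test_that("exactly the planted clean and rescuable transcripts survive the cascade", {
  cfg <- small_sim_config(seed = 6)
  geno <- simulate_genome_and_annotation(cfg)
  ev <- simulate_evidence(geno$transcripts, cfg)
  res <- apply_strict_method(geno$candidates, ev, filter_config())
  expected <- geno$transcripts$transcript_id[geno$transcripts$expected_survivor]
  expect_setequal(res$survivors, expected)
})

test_that("planted expression structure is recoverable", {
  cfg <- small_sim_config(seed = 8)
  coding <- sprintf("CG%04d", 1:80)
  lnc <- sprintf("L%02d", 1:14)
  expr <- simulate_expression(coding, lnc, character(0), cfg)
  truth <- expr$gene_truth
  rownames(truth) <- truth$gene_id
  # tissue-specific genes are exactly zero outside their tissue, Tau = 1
  spec <- truth$gene_id[!is.na(truth$specific_tissue)]
  expect_gt(length(spec), 0)
  grouping <- setNames(expr$metadata$tissue, expr$metadata$sample_id)
  tpm <- counts_to_tpm(expr$counts,
                       setNames(rep(500, nrow(expr$counts)),
                                rownames(expr$counts)))
  tau <- compute_tau(tpm, grouping)
  for (g in spec) {
    off <- expr$metadata$sample_id[expr$metadata$tissue !=
                                     truth[g, "specific_tissue"]]
    expect_true(all(expr$counts[g, off] == 0), info = g)
    expect_equal(tau$tau[tau$gene_id == g], 1, info = g)
  }
  # LC witnesses are all-zero
  lc <- truth$gene_id[truth$expected_confidence == "LC"]
  expect_true(all(expr$counts[lc, ] == 0))
  # sample ages cover the five stage bins
  staged <- assign_stage(expr$metadata)
  expect_setequal(unique(staged$stage), paste0("Stage", 1:5))
})

test_that("within-module correlation lands near its target across seeds", {
  cors_within <- numeric(0)
  cors_cross <- numeric(0)
  for (s in 1:20) {
    cfg <- simulation_config(seed = s, n_tissues = 6, samples_per_tissue = 10,
                             n_modules = 1, module_size = 50,
                             lnc_per_module = 0,
                             within_module_correlation = 0.8)
    coding <- sprintf("CG%04d", 1:120)
    lnc <- sprintf("L%02d", 1:10)
    expr <- simulate_expression(coding, lnc, character(0), cfg)
    truth <- expr$gene_truth
    # measure on the generative log2 scale: per-sample expected depth is
    # constant by construction, and library-size correction would absorb a
    # factor shared by such a large fraction of this small gene set
    norm <- log2(expr$counts + 1)
    mem <- truth$gene_id[truth$module_index == 1]
    bg <- truth$gene_id[truth$module_index == 0 &
                          is.na(truth$specific_tissue) &
                          truth$specificity_evaluable &
                          truth$expected_confidence == "HC"]
    cm <- cor(t(norm[mem, ]))
    cors_within[s] <- mean(cm[upper.tri(cm)])
    cx <- cor(t(norm[mem, ]), t(norm[utils::head(bg, 30), ]))
    cors_cross[s] <- mean(abs(cx))
  }
  expect_lt(abs(mean(cors_within) - 0.8), 0.1)
  expect_true(all(cors_cross < cors_within))
})
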