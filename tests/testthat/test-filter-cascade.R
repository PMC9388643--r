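# Tiny cascade fixture: intergenic transcripts with hand-planted evidence.
cascade_fixture <- function() {
  seqs <- c(
    ok500 = paste0(strrep("C", 250), strrep("A", 250)),
    short199 = strrep("C", 199),
    orf101 = NA, orf100 = NA,
    blastp_hit = paste0(strrep("C", 250), strrep("G", 250)),
    rescue_me = paste0(strrep("C", 200), strrep("A", 300)),
    trna_like = strrep("C", 300),
    long_intron = strrep("C", 400),
    ok_intron = strrep("C", 400))
  # designed ORFs: ATG + (aa-1) alanine codons + TGA inside a C pad
  orf_seq <- function(aa) {
    paste0(strrep("C", 30), "ATG", strrep("GCT", aa - 1), "TGA",
           strrep("C", 60))
  }
  seqs[["orf101"]] <- orf_seq(101)
  seqs[["orf100"]] <- orf_seq(100)
  pos <- 0
  rows <- lapply(names(seqs), function(id) {
    len <- nchar(seqs[[id]])
    if (id == "long_intron") {
      r <- list(id = id, starts = pos + c(0, 200 + 6001),
                ends = pos + c(200, 400 + 6001))
    } else if (id == "ok_intron") {
      r <- list(id = id, starts = pos + c(0, 200 + 6000),
                ends = pos + c(200, 400 + 6000))
    } else {
      r <- list(id = id, starts = pos, ends = pos + len)
    }
    pos <<- pos + len + 7000
    r
  })
  ts <- do.call(make_ts, rows)
  ts <- transcript_set(ts$exons, sequences = seqs)
  ev <- empty_evidence()
  brow <- function(q, pident, evalue, desc = NULL, sstrand = NULL) {
    r <- data.frame(qseqid = q, sseqid = "s", pident = pident, length = 50,
                    mismatch = 0, gapopen = 0, qstart = 1, qend = 50,
                    sstart = 1, send = 50, evalue = evalue, bitscore = 100,
                    stringsAsFactors = FALSE)
    if (!is.null(desc)) r$description <- desc
    if (!is.null(sstrand)) r$sstrand <- sstrand
    r
  }
  ev$blastp_hits <- rbind(brow("blastp_hit", 90, 1e-10),
                          brow("rescue_me", 85, 1e-9))
  ev$nr_best_hits <- rbind(
    brow("rescue_me", 85, 1e-12, desc = "hypothetical protein At1g99999"))
  ev$ncrna_family_hits <- data.frame(
    qseqid = "trna_like", family_id = "RF00005", family_class = "tRNA",
    evalue = 1e-9, stringsAsFactors = FALSE)
  list(ts = ts, ev = ev)
}

test_that("the longest ORF matches a naive enumeration oracle", {
  expect_equal(find_longest_orf("ATGAAATGA")$peptide, "MK")
  expect_equal(find_longest_orf("ATGAAATGA")$peptide_length_aa, 2L)
  expect_null(find_longest_orf("CCCCCC"))
  expect_null(find_longest_orf(""))
  # two ORFs: the longer one wins
  two <- paste0("ATG", strrep("GCT", 4), "TGA",
                "ATG", strrep("GCT", 6), "TGA")
  expect_equal(find_longest_orf(two)$peptide_length_aa, 7L)
  # N codons are neither start nor stop and translate to X
  orf <- find_longest_orf("ATGAANTGA")
  expect_equal(orf$peptide, "MX")
  expect_equal(orf$peptide_length_aa, 2L)
  set.seed(101)
  for (rep in 1:120) {
    s <- paste0(sample(c("A", "C", "G", "T"),
                       sample(20:120, 1), replace = TRUE), collapse = "")
    for (rs in c(TRUE, FALSE)) {
      got <- find_longest_orf(s, require_stop = rs)
      exp <- oracle_orf(s, require_stop = rs)
      if (is.null(exp)) {
        expect_null(got)
      } else {
        expect_equal(got$peptide_length_aa, exp$len, info = s)
        expect_equal(got$orf_start, exp$start - 1L, info = s)
      }
    }
  }
})

test_that("the nine filters remove each fixture transcript at its own step", {
  fx <- cascade_fixture()
  res <- apply_strict_method(fx$ts, fx$ev, filter_config())
  status <- res$status
  rownames(status) <- status$transcript_id
  expect_setequal(res$survivors,
                  c("ok500", "orf100", "rescue_me", "ok_intron"))
  expect_equal(status["short199", "first_fail_step"], 1L)
  expect_equal(status["blastp_hit", "first_fail_step"], 2L)
  expect_equal(status["orf101", "first_fail_step"], 6L)
  expect_equal(status["trna_like", "first_fail_step"], 8L)
  expect_equal(status["long_intron", "first_fail_step"], 9L)
  # rescue: fails blastp, keyword nr best hit flips it back to lncRNA
  expect_true(status["rescue_me", "rescued"])
  expect_equal(status["rescue_me", "final_status"], "lncRNA")
  trail <- res$trail
  expect_equal(trail$outcome[trail$transcript_id == "rescue_me" &
                               trail$step == 7], "rescued")
  # the full trail is recorded for every transcript at every step
  expect_equal(nrow(trail), 9L * length(transcript_ids(fx$ts)))
})

test_that("survival is per-transcript: input order does not matter", {
  fx <- cascade_fixture()
  base <- apply_strict_method(fx$ts, fx$ev, filter_config())
  set.seed(3)
  ids <- sample(transcript_ids(fx$ts))
  perm <- subset_transcripts(fx$ts, ids)
  res <- apply_strict_method(perm, fx$ev, filter_config())
  expect_setequal(res$survivors, base$survivors)
})

test_that("relaxing thresholds never shrinks the surviving set", {
  fx <- cascade_fixture()
  base <- apply_strict_method(fx$ts, fx$ev, filter_config())$survivors
  relaxed <- list(
    filter_config(min_length_nt = 100),
    filter_config(homology_evalue_max = 1e-12),
    filter_config(max_orf_aa = 150),
    filter_config(max_intron_bp = 10000),
    filter_config(signalp_d_cutoff = 0.9))
  for (cfg in relaxed) {
    surv <- apply_strict_method(fx$ts, fx$ev, cfg)$survivors
    expect_true(all(base %in% surv))
  }
})

test_that("missing sequences and stray evidence ids are handled", {
  ts <- make_ts(list(id = "t1", starts = 0, ends = 300))
  expect_error(apply_strict_method(ts, empty_evidence()), "sequence")
  ts <- transcript_set(ts$exons, sequences = c(t1 = strrep("C", 300)))
  ev <- empty_evidence()
  ev$blastp_hits <- data.frame(qseqid = "ghost", sseqid = "s", pident = 90,
                               length = 10, mismatch = 0, gapopen = 0,
                               qstart = 1, qend = 10, sstart = 1, send = 10,
                               evalue = 1e-10, bitscore = 40)
  expect_warning(apply_strict_method(ts, ev), "unknown transcript")
})

test_that("coding potential scores bin into the four categories", {
  sc <- data.frame(transcript_id = sprintf("t%d", 1:6),
                   coding_potential = c(0.10, 0.11, 0.50, 0.51, 0.89, 0.90))
  out <- categorize_coding_potential(sc)
  expect_equal(out$category,
               c("hc_noncoding", "noncoding", "noncoding", "coding",
                 "coding", "hc_coding"))
  expect_error(categorize_coding_potential(
    data.frame(transcript_id = "t", coding_potential = 1.2)), "\\[0, 1\\]")
})

test_that("evidence bundles survive a write/read round trip", {
  fx <- cascade_fixture()
  d <- tempfile()
  write_evidence(fx$ev, d)
  ev2 <- read_evidence(d)
  expect_equal(ev2$blastp_hits$evalue, fx$ev$blastp_hits$evalue)
  expect_equal(ev2$ncrna_family_hits$family_class, "tRNA")
  expect_equal(nrow(ev2$domain_hits), 0L)
})
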