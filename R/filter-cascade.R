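#' Filter cascade configuration
#'
#' Thresholds of the nine-step Strict Method cascade. All e-value comparisons
#' are inclusive (hit with e-value <= `homology_evalue_max` fails); the ORF
#' filter is strict (> `max_orf_aa` fails, exactly 100 aa passes); the intron
#' filter is strict (> `max_intron_bp` fails, exactly 6000 bp passes).
#'
#' @param min_length_nt minimum transcript length, nt
#' @param homology_evalue_max e-value ceiling for blastp/blastx/domain/nr/
#'   blastn evidence
#' @param signalp_d_cutoff signal-peptide D-score at or above which a signal
#'   peptide is called (standard signalP convention)
#' @param max_orf_aa longest tolerated ORF, amino acids
#' @param rescue_pident_min minimum percent identity for a best nr hit to
#'   take part in the keyword rescue step
#' @param max_intron_bp longest tolerated intron, bp
#' @param retention_keywords lower-cased substrings of nr hit descriptions
#'   marking uninformative protein annotations; a best nr hit matching one is
#'   rescued rather than removed
#' @param allowed_chroms chromosomes admitted at step 1 (`NULL` = all);
#'   use to restrict to autosomes
#' @param require_plus_strand_for_blastx only plus-strand blastx/blastn
#'   subject hits count as evidence
#' @return a list of class `filter_config`
#' @export
filter_config <- function(min_length_nt = 200,
                          homology_evalue_max = 1e-6,
                          signalp_d_cutoff = 0.45,
                          max_orf_aa = 100,
                          rescue_pident_min = 70,
                          max_intron_bp = 6000,
                          retention_keywords = c("hypothetical protein",
                                                 "similar to",
                                                 "putative protein",
                                                 "unknown",
                                                 "predicted protein",
                                                 "unnamed protein product"),
                          allowed_chroms = NULL,
                          require_plus_strand_for_blastx = TRUE) {
  stopifnot(min_length_nt > 0, homology_evalue_max > 0,
            signalp_d_cutoff > 0, max_orf_aa > 0,
            rescue_pident_min > 0, max_intron_bp > 0)
  structure(list(min_length_nt = min_length_nt,
                 homology_evalue_max = homology_evalue_max,
                 signalp_d_cutoff = signalp_d_cutoff,
                 max_orf_aa = max_orf_aa,
                 rescue_pident_min = rescue_pident_min,
                 max_intron_bp = max_intron_bp,
                 retention_keywords = tolower(retention_keywords),
                 allowed_chroms = allowed_chroms,
                 require_plus_strand_for_blastx = require_plus_strand_for_blastx),
            class = "filter_config")
}

GENETIC_CODE_STOPS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"    # codons containing N
  paste0(aa, collapse = "")
}

#' Find the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames for ORFs starting at ATG and ending at the
#' first in-frame stop codon. With `require_stop = FALSE` an ORF may run to
#' the end of the sequence. The longest ORF by peptide length wins; ties go
#' to the 5'-most start. Codons containing `N` are neither start nor stop and
#' translate to `X`.
#'
#' @param sequence nucleotide string over A/C/G/T/N
#' @param require_stop must the ORF end at a stop codon?
#' @return `NULL` if no ORF, else a list with `orf_start`, `orf_end`
#'   (0-based half-open transcript coordinates; the stop codon is included in
#'   the interval when present), `frame` (0/1/2), `peptide_length_aa` and
#'   `peptide` (no stop symbol).
#' @export
find_longest_orf <- function(sequence, require_stop = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3L) return(NULL)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(sequence, starts, starts + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% GENETIC_CODE_STOPS
    if (!any(is_start)) next
    stop_idx <- which(is_stop)
    for (si in which(is_start)) {
      nxt <- stop_idx[stop_idx > si]
      if (length(nxt) > 0L) {
        stop_at <- nxt[1L]
        pep_len <- stop_at - si
        orf_end0 <- frame + 3L * stop_at          # includes stop codon
        pep <- translate_codons(codons[si:(stop_at - 1L)])
      } else {
        if (require_stop) next
        pep_len <- ncod - si + 1L
        orf_end0 <- frame + 3L * ncod
        pep <- translate_codons(codons[si:ncod])
      }
      orf_start0 <- frame + 3L * (si - 1L)
      better <- is.null(best) ||
        pep_len > best$peptide_length_aa ||
        (pep_len == best$peptide_length_aa && orf_start0 < best$orf_start)
      if (better) {
        best <- list(orf_start = orf_start0, orf_end = orf_end0,
                     frame = frame, peptide_length_aa = pep_len,
                     peptide = pep)
      }
      # later starts in this frame share the same stop and are shorter,
      # but keep scanning: a start after this stop may begin a longer ORF
    }
  }
  best
}

#' An empty evidence bundle
#'
#' Evidence tables consumed by [apply_strict_method()], keyed by
#' `transcript_id` / `qseqid`; a transcript absent from a table simply has no
#' hits of that kind. Homology tables follow BLAST outfmt-6 column order
#' where applicable, extended with `sstrand` / `description` columns.
#'
#' @return a list of empty evidence data.frames with the expected columns
#'   (`blastp_hits`, `blastx_hits`, `domain_hits`, `signal_peptides`,
#'   `nr_best_hits`, `ncrna_family_hits`, `known_ncrna_blastn_hits`)
#' @export
empty_evidence <- function() {
  blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols), stringsAsFactors = FALSE)
    num <- intersect(cols, c("pident", "length", "mismatch", "gapopen",
                             "qstart", "qend", "sstart", "send", "evalue",
                             "bitscore", "d_score"))
    for (cc in num) df[[cc]] <- numeric(0)
    df
  }
  list(
    blastp_hits = empty(blast_cols),
    blastx_hits = empty(c(blast_cols, "sstrand")),
    domain_hits = empty(c("qseqid", "domain_id", "evalue")),
    signal_peptides = empty(c("qseqid", "d_score")),
    nr_best_hits = empty(c(blast_cols, "description")),
    ncrna_family_hits = empty(c("qseqid", "family_id", "family_class",
                                "evalue")),
    known_ncrna_blastn_hits = empty(c("qseqid", "sseqid", "evalue",
                                      "sstrand")))
}

STRICT_STEPS <- c("length_chrom", "blastp", "blastx", "domain",
                  "signal_peptide", "orf_length", "nr_rescue",
                  "ncrna_family", "intron_length")

#' Apply the Strict Method filter cascade
#'
#' Runs the nine sequential filters over every transcript and records a full
#' audit trail: every step is evaluated for every transcript even after a
#' fail, so the trail reproduces per-filter accounting. The steps are
#' (1) chromosome allowed and length >= `min_length_nt`; (2) any blastp hit at
#' e-value <= cutoff; (3) any plus-strand blastx hit at cutoff; (4) any
#' protein-domain hit at cutoff; (5) signal-peptide D-score >= cutoff;
#' (6) longest ORF > `max_orf_aa`; (7) nr best-hit keyword step: among
#' transcripts with nr evidence at cutoff whose best hit (lowest e-value,
#' ties by highest pident) has pident >= `rescue_pident_min`, a description
#' containing a retention keyword rescues the transcript, any other
#' description fails it; best hits below the pident floor leave the
#' transcript unaffected; (8) tRNA/rRNA family hits or plus-strand blastn
#' hits against known ncRNAs at cutoff; (9) any intron > `max_intron_bp`.
#'
#' A step-7 rescue overrides fails at the protein-evidence steps 2-6 (the
#' transcript is kept despite its homology evidence, mirroring the keyword
#' retention rule); fails at the structural steps 1, 8 and 9 are never
#' rescued.
#'
#' @param ts a `transcript_set`; every transcript must carry a sequence
#'   (see [add_sequences()])
#' @param evidence evidence bundle as produced by [empty_evidence()] /
#'   [read_evidence()]; missing tables are treated as empty
#' @param cfg a [filter_config()]
#' @return list with `survivors` (character vector of transcript ids with
#'   final status lncRNA), `trail` (long data.frame: transcript_id,
#'   step, step_name, outcome pass/fail/rescued, reason), and `status`
#'   (data.frame transcript_id, final_status lncRNA/removed, plus the id of
#'   the first failing step for removed transcripts)
#' @export
apply_strict_method <- function(ts, evidence = empty_evidence(),
                                cfg = filter_config()) {
  ids <- transcript_ids(ts)
  if (is.null(ts$sequences) || !all(ids %in% names(ts$sequences))) {
    stop("every transcript needs a sequence; call add_sequences() first")
  }
  base <- empty_evidence()
  for (nm in names(base)) {
    if (is.null(evidence[[nm]])) evidence[[nm]] <- base[[nm]]
  }
  known <- unlist(lapply(evidence, function(df) df$qseqid), use.names = FALSE)
  stray <- setdiff(known, ids)
  if (length(stray) > 0L) {
    warning("evidence rows for unknown transcript id(s) ignored: ",
            paste(utils::head(stray, 5L), collapse = ", "))
  }

  spans <- transcript_spans(ts)
  rownames(spans) <- spans$transcript_id
  lens <- exonic_lengths(ts)
  introns <- derive_introns(ts)
  emax <- cfg$homology_evalue_max

  ids_with <- function(df, cond) unique(df$qseqid[cond])

  fail1 <- ids[lens[ids] < cfg$min_length_nt]
  if (!is.null(cfg$allowed_chroms)) {
    fail1 <- union(fail1, ids[!spans[ids, "chrom"] %in% cfg$allowed_chroms])
  }
  bp <- evidence$blastp_hits
  fail2 <- ids_with(bp, bp$evalue <= emax)
  bx <- evidence$blastx_hits
  bx_ok <- bx$evalue <= emax
  if (cfg$require_plus_strand_for_blastx) {
    bx_ok <- bx_ok & bx$sstrand == "plus"
  }
  fail3 <- ids_with(bx, bx_ok)
  dm <- evidence$domain_hits
  fail4 <- ids_with(dm, dm$evalue <= emax)
  sp <- evidence$signal_peptides
  fail5 <- ids_with(sp, sp$d_score >= cfg$signalp_d_cutoff)
  orf_len <- vapply(ids, function(id) {
    orf <- find_longest_orf(ts$sequences[[id]])
    if (is.null(orf)) 0L else orf$peptide_length_aa
  }, integer(1L))
  fail6 <- ids[orf_len > cfg$max_orf_aa]

  # step 7: best nr hit at the e-value cutoff, keyword rescue
  nr <- evidence$nr_best_hits
  nr <- nr[nr$evalue <= emax & nr$qseqid %in% ids, , drop = FALSE]
  rescued7 <- character(0)
  fail7 <- character(0)
  reason7 <- character(0)
  if (nrow(nr) > 0L) {
    nr <- nr[order(nr$qseqid, nr$evalue, -nr$pident), , drop = FALSE]
    best <- nr[!duplicated(nr$qseqid), , drop = FALSE]
    eligible <- best[best$pident >= cfg$rescue_pident_min, , drop = FALSE]
    if (nrow(eligible) > 0L) {
      kw_hit <- vapply(tolower(eligible$description), function(d) {
        any(vapply(cfg$retention_keywords, grepl, logical(1L),
                   x = d, fixed = TRUE))
      }, logical(1L))
      rescued7 <- eligible$qseqid[kw_hit]
      fail7 <- eligible$qseqid[!kw_hit]
      reason7 <- stats::setNames(paste0("best nr hit '",
                                        eligible$description, "'"),
                                 eligible$qseqid)
    }
  }

  fam <- evidence$ncrna_family_hits
  fail8a <- ids_with(fam, fam$family_class %in% c("tRNA", "rRNA"))
  kb <- evidence$known_ncrna_blastn_hits
  fail8b <- ids_with(kb, kb$evalue <= emax & kb$sstrand == "plus")
  fail8 <- union(fail8a, fail8b)
  long_intron <- introns[introns$end - introns$start > cfg$max_intron_bp, ]
  fail9 <- unique(long_intron$transcript_id)

  fails <- list(fail1, fail2, fail3, fail4, fail5, fail6, fail7, fail8, fail9)
  reasons <- c("chromosome not allowed or length below minimum",
               "blastp protein homology", "blastx protein homology",
               "protein domain hit", "predicted signal peptide",
               sprintf("longest ORF > %d aa", cfg$max_orf_aa),
               "informative best nr hit",
               "tRNA/rRNA family or known-ncRNA hit",
               sprintf("intron > %d bp", cfg$max_intron_bp))

  trail <- do.call(rbind, lapply(seq_along(STRICT_STEPS), function(k) {
    outcome <- rep("pass", length(ids))
    outcome[ids %in% fails[[k]]] <- "fail"
    reason <- ifelse(outcome == "fail", reasons[k], "")
    if (k == 7L) {
      outcome[ids %in% rescued7] <- "rescued"
      idx <- ids %in% c(rescued7, fail7)
      reason[idx] <- unname(reason7[ids[idx]])
    }
    data.frame(transcript_id = ids, step = k, step_name = STRICT_STEPS[k],
               outcome = outcome, reason = reason, stringsAsFactors = FALSE)
  }))

  protein_fail <- Reduce(union, fails[2:6])
  structural_fail <- Reduce(union, fails[c(1L, 8L, 9L)])
  removed <- union(structural_fail, fail7)
  not_rescued_protein <- setdiff(protein_fail, rescued7)
  removed <- union(removed, not_rescued_protein)
  survivors <- setdiff(ids, removed)

  first_fail <- vapply(ids, function(id) {
    rows <- trail[trail$transcript_id == id & trail$outcome == "fail", ]
    if (nrow(rows) == 0L) NA_integer_ else min(rows$step)
  }, integer(1L))
  status <- data.frame(transcript_id = ids,
                       final_status = ifelse(ids %in% survivors,
                                             "lncRNA", "removed"),
                       first_fail_step = first_fail,
                       rescued = ids %in% rescued7,
                       stringsAsFactors = FALSE)
  rownames(status) <- NULL
  list(survivors = survivors, trail = trail, status = status)
}

#' Four-category coding-potential classification
#'
#' Bins a coding-potential score in \[0, 1\] into four mutually exclusive
#' categories: `hc_noncoding` (score <= 0.1), `noncoding` (0.1 < score <=
#' 0.5), `coding` (0.5 < score < 0.9) and `hc_coding` (score >= 0.9).
#'
#' @param scores data.frame with columns `transcript_id` and
#'   `coding_potential`
#' @return the input with a `category` column appended
#' @export
categorize_coding_potential <- function(scores) {
  s <- scores$coding_potential
  if (any(s < 0 | s > 1)) stop("coding potential scores must lie in [0, 1]")
  scores$category <- ifelse(s <= 0.1, "hc_noncoding",
                     ifelse(s <= 0.5, "noncoding",
                     ifelse(s < 0.9, "coding", "hc_coding")))
  scores
}

#' Read evidence tables from a directory
#'
#' Expects TSV files named `blastp_hits.tsv`, `blastx_hits.tsv`,
#' `domain_hits.tsv`, `signal_peptides.tsv`, `nr_best_hits.tsv`,
#' `ncrna_family_hits.tsv`, `known_ncrna_blastn_hits.tsv` (any subset;
#' missing files mean no evidence of that kind).
#'
#' @param dir directory containing the tables
#' @return an evidence bundle (list of data.frames)
#' @export
read_evidence <- function(dir) {
  ev <- empty_evidence()
  for (nm in names(ev)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(f)) {
      ev[[nm]] <- utils::read.delim(f, stringsAsFactors = FALSE)
    }
  }
  ev
}

#' Write evidence tables to a directory
#' @param evidence an evidence bundle
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_evidence <- function(evidence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(evidence)) {
    utils::write.table(evidence[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
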