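#' Simulation configuration
#'
#' The stated world of the synthetic dataset: a toy multi-chromosome genome
#' carrying multi-exon coding genes with embedded ORFs, planted lncRNAs of
#' every positional biotype, coding contaminants and tRNA/rRNA mimics with
#' planted evidence, boundary decoys witnessing every Strict Method
#' threshold (199/200 nt, 100/101 aa, 6000/6001 bp, e-value 1e-6, D-score
#' 0.45, pident 70), and an expression matrix over tissues/stages with
#' planted tissue-specific genes and planted co-expression modules driving
#' GO-coherent gene sets.
#'
#' @param seed RNG seed; every derived stream stays below 2^31
#' @param n_chroms number of chromosomes
#' @param chrom_length_bp length of each chromosome
#' @param n_coding_genes reference protein-coding genes (must accommodate
#'   the gene-attached lncRNAs: NAT + sense_exonic + intronic + 2 per dual)
#' @param n_lincRNA,n_NAT,n_sense_exonic,n_intronic,n_dual planted clean
#'   lncRNAs per biotype (dual = NAT + sense-exonic)
#' @param n_coding_contaminants coding contaminants (>= 8; the first eight
#'   are fixed threshold witnesses, extras are generic blastp-removable)
#' @param n_trna_rrna_mimics tRNA/rRNA mimics (>= 3; tRNA family, rRNA
#'   family and known-ncRNA blastn witnesses, extras generic tRNA)
#' @param n_tissues,samples_per_tissue expression design (tissue ages span
#'   the five developmental stage bins)
#' @param n_modules,module_size planted co-expression modules;
#'   `lnc_per_module` clean lncRNAs are planted inside each module
#' @param lnc_per_module lncRNA genes per planted module
#' @param within_module_correlation target expected pairwise correlation of
#'   module genes on the log scale
#' @param noise_sd per-sample log2 noise of non-module genes
#' @param fraction_tissue_specific fraction of non-module coding genes and of
#'   non-module clean lncRNA genes planted as strictly single-tissue
#' @param n_lc_lncrnas clean lncRNA genes planted with zero expression
#'   everywhere (Low Confidence witnesses)
#' @param prob_strand_unknown probability that a planted intronic lncRNA has
#'   unknown orientation (single-end assembly witnesses)
#' @param nb_dispersion negative-binomial size parameter of the count
#'   observation model
#' @param n_background_go_terms unstructured GO terms sprinkled over coding
#'   genes
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(seed = 1,
                              n_chroms = 5,
                              chrom_length_bp = 400000,
                              n_coding_genes = 400,
                              n_lincRNA = 10,
                              n_NAT = 8,
                              n_sense_exonic = 6,
                              n_intronic = 8,
                              n_dual = 3,
                              n_coding_contaminants = 8,
                              n_trna_rrna_mimics = 3,
                              n_tissues = 6,
                              samples_per_tissue = 10,
                              n_modules = 3,
                              module_size = 60,
                              lnc_per_module = 5,
                              within_module_correlation = 0.8,
                              noise_sd = 0.5,
                              fraction_tissue_specific = 0.2,
                              n_lc_lncrnas = 3,
                              prob_strand_unknown = 0.25,
                              nb_dispersion = 50,
                              n_background_go_terms = 25) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length_bp > 20000,
            cfg$within_module_correlation > 0,
            cfg$within_module_correlation < 1,
            cfg$n_coding_contaminants >= 8, cfg$n_trna_rrna_mimics >= 3,
            cfg$n_tissues >= 2, cfg$samples_per_tissue >= 2,
            cfg$fraction_tissue_specific >= 0,
            cfg$fraction_tissue_specific <= 1)
  need_genes <- cfg$n_NAT + cfg$n_sense_exonic + cfg$n_intronic +
    2L * cfg$n_dual
  if (cfg$n_coding_genes < need_genes) {
    stop("n_coding_genes must be at least ", need_genes,
         " to host the gene-attached lncRNAs")
  }
  n_module_coding <- cfg$n_modules * (cfg$module_size - cfg$lnc_per_module)
  if (n_module_coding > cfg$n_coding_genes) {
    stop("not enough coding genes for the requested modules")
  }
  class(cfg) <- "simulation_config"
  cfg
}

DNA_BASES <- c("A", "C", "G", "T")
NONSTOP_CODONS <- setdiff(
  apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L, paste0,
        collapse = ""),
  c("TAA", "TAG", "TGA"))

random_dna <- function(n) {
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# random sequence whose longest ORF stays at or below max_aa
random_noncoding_seq <- function(n, max_aa = 100, tries = 60) {
  for (i in seq_len(tries)) {
    s <- random_dna(n)
    orf <- find_longest_orf(s)
    if (is.null(orf) || orf$peptide_length_aa <= max_aa) return(s)
  }
  stop("could not generate a ", n, "-nt sequence without an ORF > ",
       max_aa, " aa")
}

# sequence of length n whose longest ORF has exactly orf_aa residues
designed_orf_seq <- function(n, orf_aa, tries = 60) {
  body_len <- 3L * (orf_aa + 1L)           # ATG + (aa-1) codons + stop
  pad5 <- 24L
  pad3 <- n - pad5 - body_len
  if (pad3 < 0L) stop("sequence too short for a ", orf_aa, "-aa ORF")
  for (i in seq_len(tries)) {
    body <- paste0("ATG",
                   paste0(sample(NONSTOP_CODONS, orf_aa - 1L, replace = TRUE),
                          collapse = ""),
                   "TGA")
    s <- paste0(random_dna(pad5), body, random_dna(pad3))
    orf <- find_longest_orf(s)
    if (!is.null(orf) && orf$peptide_length_aa == orf_aa) return(s)
  }
  stop("could not plant an ORF of exactly ", orf_aa, " aa")
}

# coding transcript sequence: UTRs around a >100-codon ORF
coding_transcript_seq <- function(n, orf_aa = 150) {
  designed_orf_seq(n, orf_aa)
}

# write a transcript sequence into per-chromosome character vectors
write_transcript_seq <- function(chrom_chars, exons, strand, seq) {
  if (strand == "-") seq <- revcomp_chr(seq)
  chars <- strsplit(seq, "")[[1L]]
  pos <- 1L
  exons <- exons[order(exons$start), , drop = FALSE]
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i]
    chrom_chars[(exons$start[i] + 1L):exons$end[i]] <-
      chars[pos:(pos + w - 1L)]
    pos <- pos + w
  }
  chrom_chars
}

# geometry of one coding gene at genomic offset g (0-based)
gene_exon_offsets <- function() {
  data.frame(start = c(0, 550, 2450), end = c(300, 950, 2750))
}
GENE_SPAN <- 2750
GENE_TX_LEN <- 1000

#' Simulate genome, reference annotation and candidate transcripts
#'
#' Lays out coding genes and planted candidates in non-overlapping cassettes
#' across the chromosomes, embeds designed ORFs in coding transcripts,
#' enforces that every clean lncRNA's longest ORF stays at or below 100 aa,
#' and returns the ground-truth transcript manifest. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [simulation_config()]
#' @return list with `genome` ([Biostrings::DNAStringSet]), `reference`
#'   (transcript_set of coding gene models), `candidates` (transcript_set
#'   with sequences), and `transcripts` (manifest data.frame: transcript_id,
#'   gene_id, class, biotype, rescuable, expected_survivor, witness)
#' @export
simulate_genome_and_annotation <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_chars <- lapply(chroms, function(x) {
    sample(DNA_BASES, cfg$chrom_length_bp, replace = TRUE)
  })
  names(chrom_chars) <- chroms

  # ---- task roster ----------------------------------------------------
  mk <- function(kind, n, prefix) {
    if (n <= 0L) return(character(0))
    sprintf("%s_%03d", prefix, seq_len(n))
  }
  tasks <- c(
    stats::setNames(rep("gene_nat", cfg$n_NAT), mk("nat", cfg$n_NAT, "nat")),
    stats::setNames(rep("gene_sx", cfg$n_sense_exonic),
                    mk("sx", cfg$n_sense_exonic, "sx")),
    stats::setNames(rep("gene_intronic", cfg$n_intronic),
                    mk("intr", cfg$n_intronic, "intr")),
    stats::setNames(rep("dual", cfg$n_dual), mk("dual", cfg$n_dual, "dual")),
    stats::setNames(rep("linc", cfg$n_lincRNA),
                    mk("linc", cfg$n_lincRNA, "linc")))
  n_plain <- cfg$n_coding_genes - cfg$n_NAT - cfg$n_sense_exonic -
    cfg$n_intronic - 2L * cfg$n_dual
  tasks <- c(tasks, stats::setNames(rep("plain_gene", n_plain),
                                    sprintf("plain_%03d", seq_len(n_plain))))
  witness_tasks <- c(
    linc_200nt = "witness_len200", decoy_199nt = "witness_len199",
    linc_orf100 = "witness_orf100", cont_orf101 = "witness_orf101",
    linc_intron6000 = "witness_intron6000",
    decoy_intron6001 = "witness_intron6001",
    cont_blastp = "cont_plain", cont_evalue_boundary = "cont_plain",
    cont_domain = "cont_plain", cont_signalp = "cont_plain",
    cont_rescue_kw = "cont_orf", cont_rescue_boundary = "cont_orf",
    cont_nr_informative = "cont_plain",
    w_blastp_weak = "linc", w_signalp_weak = "linc", w_nr_sub70 = "linc")
  extra_cont <- cfg$n_coding_contaminants - 8L
  if (extra_cont > 0L) {
    witness_tasks <- c(witness_tasks,
                       stats::setNames(rep("cont_orf", extra_cont),
                                       sprintf("cont_x%03d",
                                               seq_len(extra_cont))))
  }
  mimic_tasks <- c(mimic_trna = "mimic", mimic_rrna = "mimic",
                   mimic_blastn = "mimic")
  extra_mim <- cfg$n_trna_rrna_mimics - 3L
  if (extra_mim > 0L) {
    mimic_tasks <- c(mimic_tasks,
                     stats::setNames(rep("mimic", extra_mim),
                                     sprintf("mimic_x%03d",
                                             seq_len(extra_mim))))
  }
  tasks <- c(tasks, witness_tasks, mimic_tasks)
  tasks <- tasks[sample.int(length(tasks))]    # shuffle across the genome

  cursors <- stats::setNames(rep(2000, cfg$n_chroms), chroms)
  gap <- function() 800 + sample.int(400, 1L)

  ref_rows <- list()
  cand_rows <- list()
  manifest <- list()
  gene_counter <- 0L
  plain_gene_counter <- 0L

  new_gene_id <- function() {
    gene_counter <<- gene_counter + 1L
    sprintf("CG%04d", gene_counter)
  }
  add_ref_gene <- function(chrom, g, strand, two_isoforms = FALSE) {
    gid <- new_gene_id()
    off <- gene_exon_offsets()
    ref_rows[[length(ref_rows) + 1L]] <<- data.frame(
      transcript_id = paste0(gid, ".1"), gene_id = gid, chrom = chrom,
      start = g + off$start, end = g + off$end, strand = strand,
      stringsAsFactors = FALSE)
    if (two_isoforms) {
      ref_rows[[length(ref_rows) + 1L]] <<- data.frame(
        transcript_id = paste0(gid, ".2"), gene_id = gid, chrom = chrom,
        start = g + off$start[c(1L, 3L)], end = g + off$end[c(1L, 3L)],
        strand = strand, stringsAsFactors = FALSE)
    }
    # designed coding sequence for the main isoform
    exons <- data.frame(start = g + off$start, end = g + off$end)
    chrom_chars[[chrom]] <<- write_transcript_seq(
      chrom_chars[[chrom]], exons, strand,
      coding_transcript_seq(GENE_TX_LEN))
    gid
  }
  add_candidate <- function(tid, chrom, starts, ends, strand, class,
                            biotype, rescuable = FALSE, witness = "",
                            free_regions = NULL, designed_seq = NULL,
                            max_aa = 100) {
    rows <- data.frame(transcript_id = tid, gene_id = paste0("g.", tid),
                       chrom = chrom, start = starts, end = ends,
                       strand = strand, stringsAsFactors = FALSE)
    cand_rows[[length(cand_rows) + 1L]] <<- rows
    if (!is.null(designed_seq)) {
      chrom_chars[[chrom]] <<- write_transcript_seq(
        chrom_chars[[chrom]], rows, strand, designed_seq)
    } else if (!is.null(free_regions)) {
      # keep regenerating the free (non-gene) bases until no long ORF
      for (try in 1:60) {
        seq <- extract_one(chrom_chars[[chrom]], rows, strand)
        orf <- find_longest_orf(seq)
        if (is.null(orf) || orf$peptide_length_aa <= max_aa) break
        if (try == 60L) stop("could not de-ORF candidate ", tid)
        for (fr in free_regions) {
          chrom_chars[[chrom]][(fr[1L] + 1L):fr[2L]] <<-
            sample(DNA_BASES, fr[2L] - fr[1L], replace = TRUE)
        }
      }
    }
    manifest[[length(manifest) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = paste0("g.", tid), class = class,
      biotype = biotype, rescuable = rescuable,
      expected_survivor = (class == "clean") || rescuable,
      witness = witness, stringsAsFactors = FALSE)
  }
  extract_one <- function(chars, rows, strand) {
    rows <- rows[order(rows$start), , drop = FALSE]
    seq <- paste0(unlist(lapply(seq_len(nrow(rows)), function(i) {
      chars[(rows$start[i] + 1L):rows$end[i]]
    })), collapse = "")
    if (strand == "-") seq <- revcomp_chr(seq)
    seq
  }

  task_span <- function(kind) {
    switch(kind,
           plain_gene = GENE_SPAN,
           gene_nat = GENE_SPAN, gene_sx = GENE_SPAN,
           gene_intronic = GENE_SPAN,
           dual = 2L * GENE_SPAN + 150L,
           linc = 700L, witness_len200 = 200L, witness_len199 = 199L,
           witness_orf100 = 450L, witness_orf101 = 500L,
           witness_intron6000 = 6400L, witness_intron6001 = 6401L,
           cont_plain = 420L, cont_orf = 520L, mimic = 300L)
  }

  ci <- 0L
  for (ti in seq_along(tasks)) {
    kind <- tasks[[ti]]
    tid <- names(tasks)[ti]
    span <- task_span(kind)
    placed <- FALSE
    for (attempt in seq_len(cfg$n_chroms)) {
      ci <- (ci %% cfg$n_chroms) + 1L
      chrom <- chroms[ci]
      if (cursors[chrom] + span + 2000 <= cfg$chrom_length_bp) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("genome too small for the requested layout; ",
           "increase chrom_length_bp or n_chroms")
    }
    g <- cursors[[chrom]]
    flip <- function(s) if (s == "+") "-" else "+"
    gs <- sample(c("+", "-"), 1L)

    if (kind == "plain_gene") {
      plain_gene_counter <- plain_gene_counter + 1L
      add_ref_gene(chrom, g, gs,
                   two_isoforms = plain_gene_counter %% 8L == 0L)
    } else if (kind %in% c("gene_nat", "gene_sx")) {
      add_ref_gene(chrom, g, gs)
      lnc_strand <- if (kind == "gene_nat") flip(gs) else gs
      biotype <- if (kind == "gene_nat") "NAT" else "sense_exonic"
      add_candidate(tid, chrom, g + 800, g + 1300, lnc_strand, "clean",
                    biotype, free_regions = list(c(g + 950, g + 1300)))
    } else if (kind == "gene_intronic") {
      add_ref_gene(chrom, g, gs)
      lnc_strand <- if (stats::runif(1) < cfg$prob_strand_unknown) "*"
        else sample(c("+", "-"), 1L)
      add_candidate(tid, chrom, g + 1200, g + 1600, lnc_strand, "clean",
                    "intronic", free_regions = list(c(g + 1200, g + 1600)))
    } else if (kind == "dual") {
      sA <- gs
      add_ref_gene(chrom, g, sA)
      add_ref_gene(chrom, g + GENE_SPAN + 150L, flip(sA))
      add_candidate(tid, chrom, g + 2350, g + 3000, sA, "clean",
                    "NAT,sense_exonic",
                    free_regions = list(c(g + 2350, g + 2450),
                                        c(g + 2750, g + 2900)))
    } else if (kind == "linc") {
      witness <- if (startsWith(tid, "w_")) tid else ""
      add_candidate(tid, chrom, c(g, g + 450), c(g + 250, g + 650),
                    sample(c("+", "-"), 1L), "clean", "lincRNA",
                    witness = witness,
                    designed_seq = random_noncoding_seq(450))
    } else if (kind == "witness_len200") {
      add_candidate(tid, chrom, g, g + 200, "+", "clean", "lincRNA",
                    witness = "length_200",
                    designed_seq = random_noncoding_seq(200, max_aa = 60))
    } else if (kind == "witness_len199") {
      add_candidate(tid, chrom, g, g + 199, "+", "short_decoy", "lincRNA",
                    witness = "length_199",
                    designed_seq = random_noncoding_seq(199, max_aa = 60))
    } else if (kind == "witness_orf100") {
      add_candidate(tid, chrom, g, g + 450, "+", "clean", "lincRNA",
                    witness = "orf_100",
                    designed_seq = designed_orf_seq(450, 100))
    } else if (kind == "witness_orf101") {
      add_candidate(tid, chrom, g, g + 500, "+", "coding_contaminant",
                    "lincRNA", witness = "orf_101",
                    designed_seq = designed_orf_seq(500, 101))
    } else if (kind %in% c("witness_intron6000", "witness_intron6001")) {
      ilen <- if (kind == "witness_intron6000") 6000L else 6001L
      cls <- if (ilen == 6000L) "clean" else "long_intron_decoy"
      add_candidate(tid, chrom, c(g, g + 200L + ilen),
                    c(g + 200L, g + 400L + ilen),
                    "+", cls, "lincRNA", witness = paste0("intron_", ilen),
                    designed_seq = random_noncoding_seq(400))
    } else if (kind == "cont_plain") {
      add_candidate(tid, chrom, g, g + 420, sample(c("+", "-"), 1L),
                    "coding_contaminant", "lincRNA", witness = tid,
                    designed_seq = random_noncoding_seq(420))
    } else if (kind == "cont_orf") {
      rescuable <- tid %in% c("cont_rescue_kw", "cont_rescue_boundary")
      add_candidate(tid, chrom, g, g + 520, sample(c("+", "-"), 1L),
                    "coding_contaminant", "lincRNA",
                    rescuable = rescuable, witness = tid,
                    designed_seq = designed_orf_seq(520, 105 +
                                                      sample.int(30, 1L)))
    } else if (kind == "mimic") {
      add_candidate(tid, chrom, g, g + 300, "+", "trna_rrna_mimic",
                    "lincRNA", witness = tid,
                    designed_seq = random_noncoding_seq(300))
    }
    cursors[[chrom]] <- g + span + gap()
  }

  genome <- Biostrings::DNAStringSet(
    vapply(chrom_chars, paste0, character(1L), collapse = ""))
  names(genome) <- chroms

  reference <- transcript_set(do.call(rbind, ref_rows))
  candidates <- transcript_set(do.call(rbind, cand_rows))
  candidates <- add_sequences(candidates, genome)
  transcripts <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  list(genome = genome, reference = reference, candidates = candidates,
       transcripts = transcripts)
}

#' Simulate evidence tables for the planted candidates
#'
#' Coding contaminants receive blastp/blastx/domain/signal-peptide hits at
#' or beyond the Strict Method thresholds (including the exact-boundary
#' witnesses); rescuable transcripts receive nr best hits with
#' retention-keyword descriptions at pident >= 70; removable ones get
#' informative protein names; mimics receive tRNA/rRNA family or
#' known-ncRNA blastn hits; clean lncRNAs receive either nothing or —
#' for the dedicated weak-evidence witnesses — hits strictly below every
#' threshold.
#'
#' @param transcripts transcript manifest from
#'   [simulate_genome_and_annotation()]
#' @param cfg a [simulation_config()]
#' @return an evidence bundle (see [empty_evidence()])
#' @export
simulate_evidence <- function(transcripts, cfg = simulation_config()) {
  set.seed(cfg$seed + 1L)
  ev <- empty_evidence()
  blast_row <- function(qid, sid, pident, evalue, extra = NULL) {
    row <- data.frame(qseqid = qid, sseqid = sid, pident = pident,
                      length = 100, mismatch = 5, gapopen = 0,
                      qstart = 1, qend = 100, sstart = 1, send = 100,
                      evalue = evalue, bitscore = 200,
                      stringsAsFactors = FALSE)
    if (!is.null(extra)) row <- cbind(row, extra, stringsAsFactors = FALSE)
    row
  }
  add <- function(tab, row) rbind(ev[[tab]], row)

  for (i in seq_len(nrow(transcripts))) {
    tid <- transcripts$transcript_id[i]
    wit <- transcripts$witness[i]
    cls <- transcripts$class[i]
    if (wit == "cont_blastp" || grepl("^cont_x", wit)) {
      ev$blastp_hits <- add("blastp_hits",
        blast_row(tid, "sp|P99999|FAKE", 92, 10^-stats::runif(1, 8, 30)))
      ev$nr_best_hits <- add("nr_best_hits",
        blast_row(tid, "WP_000001.1", 88, 1e-12,
                  data.frame(description = "ATP synthase subunit beta")))
    } else if (wit == "cont_evalue_boundary") {
      ev$blastp_hits <- add("blastp_hits",
        blast_row(tid, "sp|P88888|EDGE", 80, 1e-6))
    } else if (wit == "cont_domain") {
      ev$domain_hits <- add("domain_hits",
        data.frame(qseqid = tid, domain_id = "PF00069", evalue = 1e-8,
                   stringsAsFactors = FALSE))
    } else if (wit == "cont_signalp") {
      ev$signal_peptides <- add("signal_peptides",
        data.frame(qseqid = tid, d_score = 0.45, stringsAsFactors = FALSE))
    } else if (wit == "cont_nr_informative") {
      ev$nr_best_hits <- add("nr_best_hits",
        blast_row(tid, "NP_000002.1", 90, 1e-9,
                  data.frame(description = "cytochrome P450 family protein")))
    } else if (wit == "cont_rescue_kw") {
      ev$blastp_hits <- add("blastp_hits",
        blast_row(tid, "sp|P77777|HYPO", 85, 1e-9))
      ev$nr_best_hits <- add("nr_best_hits",
        blast_row(tid, "XP_000003.1", 85, 1e-10,
                  data.frame(description = "hypothetical protein At1g99999")))
    } else if (wit == "cont_rescue_boundary") {
      ev$nr_best_hits <- add("nr_best_hits",
        blast_row(tid, "XP_000004.1", 70, 1e-8,
                  data.frame(description = "unknown protein")))
    } else if (wit == "mimic_trna" || grepl("^mimic_x", wit)) {
      ev$ncrna_family_hits <- add("ncrna_family_hits",
        data.frame(qseqid = tid, family_id = "RF00005",
                   family_class = "tRNA", evalue = 1e-10,
                   stringsAsFactors = FALSE))
    } else if (wit == "mimic_rrna") {
      ev$ncrna_family_hits <- add("ncrna_family_hits",
        data.frame(qseqid = tid, family_id = "RF00177",
                   family_class = "rRNA", evalue = 1e-15,
                   stringsAsFactors = FALSE))
    } else if (wit == "mimic_blastn") {
      ev$known_ncrna_blastn_hits <- add("known_ncrna_blastn_hits",
        data.frame(qseqid = tid, sseqid = "At-tRNA-Gly", evalue = 1e-8,
                   sstrand = "plus", stringsAsFactors = FALSE))
    } else if (wit == "w_blastp_weak") {
      ev$blastp_hits <- add("blastp_hits",
        blast_row(tid, "sp|Q11111|WEAK", 55, 1e-5))
    } else if (wit == "w_signalp_weak") {
      ev$signal_peptides <- add("signal_peptides",
        data.frame(qseqid = tid, d_score = 0.44, stringsAsFactors = FALSE))
    } else if (wit == "w_nr_sub70") {
      ev$nr_best_hits <- add("nr_best_hits",
        blast_row(tid, "NP_000005.1", 69.9, 1e-8,
                  data.frame(description = "kinase family protein")))
    } else if (wit == "orf_101") {
      # contaminant removed purely by its 101-aa ORF: no table rows
    } else if (cls == "coding_contaminant") {
      ev$blastp_hits <- add("blastp_hits",
        blast_row(tid, "sp|P66666|GEN", 90, 10^-stats::runif(1, 8, 20)))
    }
  }
  ev
}

#' Simulate the expression matrix with planted structure
#'
#' Counts follow a negative-binomial observation model over per-sample
#' expected expression on the log2 scale. Planted co-expression modules
#' share a tissue-driven latent profile whose gene-level noise is chosen so
#' the expected pairwise within-module correlation matches
#' `within_module_correlation`; planted tissue-specific genes have expected
#' expression exactly zero outside their tissue; planted Low Confidence
#' lncRNAs are zero everywhere. Tissue ages span the five developmental
#' stage bins.
#'
#' @param coding_gene_ids reference coding gene ids
#' @param lnc_gene_ids candidate gene ids of expected Strict Method
#'   survivors (clean plus rescuable)
#' @param other_gene_ids remaining candidate gene ids (flat background)
#' @param cfg a [simulation_config()]
#' @return list with `counts` (integer matrix genes x samples), `metadata`
#'   (sample table), `gene_truth` (data.frame gene_id, gene_type,
#'   module_index, specific_tissue, expected_confidence,
#'   specificity_evaluable)
#' @export
simulate_expression <- function(coding_gene_ids, lnc_gene_ids,
                                other_gene_ids = character(0),
                                cfg = simulation_config()) {
  set.seed(cfg$seed + 2L)
  tissue_pool <- c("embryo", "seedling", "leaf", "root", "flower",
                   "silique", "stem", "callus")
  age_pool <- c(4, 14, 27, 35, 42, 50, 30, 20)
  tissues <- tissue_pool[seq_len(cfg$n_tissues)]
  ages <- age_pool[seq_len(cfg$n_tissues)]
  n_samp <- cfg$n_tissues * cfg$samples_per_tissue
  tissue_of <- rep(tissues, each = cfg$samples_per_tissue)
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samp)),
    tissue = tissue_of,
    age_days = rep(ages, each = cfg$samples_per_tissue),
    condition = "baseline",
    library_layout = ifelse(tissue_of %in% tissues[1:2],
                            "single-end", "paired-end"),
    stringsAsFactors = FALSE)

  rho <- cfg$within_module_correlation
  n_mod_coding <- cfg$module_size - cfg$lnc_per_module

  coding_pool <- sample(coding_gene_ids)
  n_mod_coding_total <- cfg$n_modules * n_mod_coding
  module_coding <- split(coding_pool[seq_len(n_mod_coding_total)],
                         rep(seq_len(cfg$n_modules), each = n_mod_coding))
  nonmodule_coding <- if (n_mod_coding_total > 0L) {
    coding_pool[-seq_len(n_mod_coding_total)]
  } else coding_pool
  n_spec_coding <- round(cfg$fraction_tissue_specific *
                           length(nonmodule_coding))
  spec_coding <- nonmodule_coding[seq_len(n_spec_coding)]
  patterned_coding <- setdiff(nonmodule_coding, spec_coding)

  lnc_pool <- sample(lnc_gene_ids)
  need_mod_lnc <- cfg$n_modules * cfg$lnc_per_module
  if (length(lnc_pool) < need_mod_lnc + cfg$n_lc_lncrnas + 1L) {
    stop("not enough surviving lncRNA genes for the requested module and ",
         "LC planting")
  }
  module_lnc <- if (need_mod_lnc > 0L) {
    split(lnc_pool[seq_len(need_mod_lnc)],
          rep(seq_len(cfg$n_modules), each = cfg$lnc_per_module))
  } else {
    rep(list(character(0)), cfg$n_modules)
  }
  rest_lnc <- if (need_mod_lnc > 0L) lnc_pool[-seq_len(need_mod_lnc)]
    else lnc_pool
  lc_lnc <- rest_lnc[seq_len(cfg$n_lc_lncrnas)]
  rest_lnc <- setdiff(rest_lnc, lc_lnc)
  n_spec_lnc <- round(cfg$fraction_tissue_specific * length(rest_lnc))
  spec_lnc <- rest_lnc[seq_len(n_spec_lnc)]
  flat_lnc <- setdiff(rest_lnc, spec_lnc)

  all_genes <- c(coding_gene_ids, lnc_gene_ids, other_gene_ids)
  truth <- data.frame(gene_id = all_genes,
                      gene_type = c(rep("coding", length(coding_gene_ids)),
                                    rep("lncRNA", length(lnc_gene_ids)),
                                    rep("other", length(other_gene_ids))),
                      module_index = 0L,
                      specific_tissue = NA_character_,
                      expected_confidence = "HC",
                      specificity_evaluable = TRUE,
                      stringsAsFactors = FALSE)
  rownames(truth) <- truth$gene_id

  x <- matrix(0, nrow = length(all_genes), ncol = n_samp,
              dimnames = list(all_genes, meta$sample_id))
  base_of <- stats::setNames(stats::runif(length(all_genes), 6.5, 8.5),
                             all_genes)

  # planted modules: shared sample-level latent factor + calibrated noise,
  # so the expected pairwise within-module correlation hits rho; the factor
  # is deliberately tissue-free, keeping module co-expression orthogonal to
  # the tissue patterning that drives Tau
  for (m in seq_len(cfg$n_modules)) {
    members <- c(module_coding[[m]], module_lnc[[m]])
    truth[members, "module_index"] <- m
    profile <- stats::rnorm(n_samp, 0, 1)
    sigma_e <- sqrt(stats::var(profile) * (1 - rho) / rho)
    for (g in members) {
      x[g, ] <- base_of[g] + profile + stats::rnorm(n_samp, 0, sigma_e)
    }
  }
  # tissue-specific genes: expression strictly confined to one tissue
  for (g in c(spec_coding, spec_lnc)) {
    tis <- sample(tissues, 1L)
    truth[g, "specific_tissue"] <- tis
    x[g, ] <- ifelse(meta$tissue == tis,
                     8 + stats::rnorm(n_samp, 0, cfg$noise_sd), -Inf)
  }
  # patterned coding genes: expressed in a tissue subset; these carry the
  # bulk of the mRNA Tau distribution (their flag vs the recomputed median
  # cutoff is a coin toss by design, so they are not evaluable)
  for (g in patterned_coding) {
    k <- sample(2:4, 1L)
    on <- sample(tissues, k)
    truth[g, "specificity_evaluable"] <- FALSE
    x[g, ] <- ifelse(meta$tissue %in% on, 8, 0.5) +
      stats::rnorm(n_samp, 0, cfg$noise_sd)
  }
  # flat genes (lncRNA background, non-survivors)
  for (g in c(flat_lnc, other_gene_ids)) {
    x[g, ] <- base_of[g] + stats::rnorm(n_samp, 0, cfg$noise_sd)
  }
  # Low Confidence witnesses: never expressed
  for (g in lc_lnc) {
    x[g, ] <- -Inf
    truth[g, "expected_confidence"] <- "LC"
  }

  mu <- 2^x
  mu[x == -Inf] <- 0
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = cfg$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  rownames(truth) <- NULL
  list(counts = counts, metadata = meta, gene_truth = truth)
}

#' Simulate a GO annotation with module-coherent term blocks
#'
#' Each planted module receives a dedicated GO term carried by all its
#' coding members; background terms are sprinkled uniformly over coding
#' genes (every coding gene carries at least one term so the annotated
#' background equals the coding universe). lncRNAs carry no terms.
#'
#' @param gene_truth gene-level truth from [simulate_expression()]
#' @param cfg a [simulation_config()]
#' @return list with `annotation` (named list gene -> terms), `gene2go`
#'   (two-column data.frame) and `module_terms` (data.frame module_index,
#'   term_id)
#' @export
simulate_go_annotation <- function(gene_truth, cfg = simulation_config()) {
  set.seed(cfg$seed + 3L)
  coding <- gene_truth$gene_id[gene_truth$gene_type == "coding"]
  ann <- stats::setNames(vector("list", length(coding)), coding)
  module_terms <- data.frame(module_index = integer(0),
                             term_id = character(0),
                             stringsAsFactors = FALSE)
  for (m in sort(unique(gene_truth$module_index[gene_truth$module_index > 0]))) {
    term <- sprintf("GO:MOD%04d", m)
    members <- gene_truth$gene_id[gene_truth$module_index == m &
                                    gene_truth$gene_type == "coding"]
    for (g in members) ann[[g]] <- c(ann[[g]], term)
    module_terms <- rbind(module_terms,
                          data.frame(module_index = m, term_id = term,
                                     stringsAsFactors = FALSE))
  }
  bg_terms <- sprintf("GO:BG%04d", seq_len(cfg$n_background_go_terms))
  for (term in bg_terms) {
    carriers <- sample(coding, max(3L, round(0.04 * length(coding))))
    for (g in carriers) ann[[g]] <- c(ann[[g]], term)
  }
  # guarantee every coding gene is annotated (defines the background)
  bare <- coding[lengths(ann) == 0L]
  for (g in bare) ann[[g]] <- sample(bg_terms, 1L)
  ann <- lapply(ann, unique)
  gene2go <- data.frame(
    gene_id = rep(names(ann), lengths(ann)),
    term_id = unlist(ann, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(annotation = ann, gene2go = gene2go, module_terms = module_terms)
}

#' Simulate the full dataset with its ground-truth manifest
#'
#' Orchestrates [simulate_genome_and_annotation()], [simulate_evidence()],
#' [simulate_expression()] and [simulate_go_annotation()]; optionally writes
#' everything to disk as plain-text files (genome FASTA, reference and
#' candidate GTF, evidence TSVs, counts/metadata/lengths TSVs, gene-to-GO
#' TSV and a JSON manifest).
#'
#' @param cfg a [simulation_config()]
#' @param dir optional output directory
#' @return list with elements `genome`, `reference`, `candidates`,
#'   `evidence`, `counts`, `metadata`, `gene_lengths`, `go` and `manifest`
#'   (list of `transcripts`, `genes`, `modules` data.frames)
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = NULL) {
  geno <- simulate_genome_and_annotation(cfg)
  evidence <- simulate_evidence(geno$transcripts, cfg)

  surv <- geno$transcripts$expected_survivor
  lnc_genes <- geno$transcripts$gene_id[surv]
  other_genes <- geno$transcripts$gene_id[!surv]
  coding_genes <- sort(unique(geno$reference$exons$gene_id))
  expr <- simulate_expression(coding_genes, lnc_genes, other_genes, cfg)
  go <- simulate_go_annotation(expr$gene_truth, cfg)

  # gene effective lengths: mean isoform exonic length
  len_tab <- function(ts) {
    el <- exonic_lengths(ts)
    gmap <- ts$exons$gene_id[!duplicated(ts$exons$transcript_id)]
    names(gmap) <- ts$exons$transcript_id[!duplicated(ts$exons$transcript_id)]
    tapply(el[names(gmap)], gmap[names(gmap)], mean)
  }
  gl <- c(len_tab(geno$reference), len_tab(geno$candidates))
  gene_lengths <- stats::setNames(as.numeric(gl), names(gl))

  manifest <- list(transcripts = geno$transcripts,
                   genes = expr$gene_truth,
                   modules = go$module_terms,
                   config = unclass(cfg))
  out <- list(genome = geno$genome, reference = geno$reference,
              candidates = geno$candidates, evidence = evidence,
              counts = expr$counts, metadata = expr$metadata,
              gene_lengths = gene_lengths, go = go, manifest = manifest)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Write a simulated dataset to plain-text files
#' @param sim output of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$reference, file.path(dir, "reference.gtf"))
  write_annotation(sim$candidates, file.path(dir, "candidates.gtf"))
  write_evidence(sim$evidence, file.path(dir, "evidence"))
  utils::write.table(data.frame(gene_id = rownames(sim$counts),
                                sim$counts, check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(sim$gene_lengths),
                                length = sim$gene_lengths),
                     file.path(dir, "gene_lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$go$gene2go, file.path(dir, "gene2go.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
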