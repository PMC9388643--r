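#' Read a genome annotation (GTF/GFF3) into a transcript set
#'
#' Exon records are grouped by transcript and validated. GTF coordinates
#' (1-based closed) are converted to the internal 0-based half-open
#' convention. A strand of `"."` (or `"?"`) in the file maps to `"*"`
#' (unknown). Bookended exons are merged; overlapping exons within one
#' transcript are rejected.
#'
#' @param path GTF or GFF3 file. Records must carry `gene_id` and
#'   `transcript_id` attributes (GTF) or equivalents importable by
#'   rtracklayer.
#' @param format `"auto"` (from the extension), `"gtf"` or `"gff3"`.
#' @return a [transcript_set()]
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "gtf"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  meta <- S4Vectors::mcols(gr)
  if ("type" %in% names(meta)) {
    gr <- gr[as.character(meta$type) == "exon"]
    meta <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L) stop("no exon records in ", path)
  if (!all(c("gene_id", "transcript_id") %in% names(meta))) {
    stop("records in ", path, " lack gene_id/transcript_id attributes")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  exons <- data.frame(
    transcript_id = as.character(meta$transcript_id),
    gene_id = as.character(meta$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,   # 1-based closed -> 0-based half-open
    end = as.numeric(BiocGenerics::end(gr)),
    strand = ifelse(strand %in% c("+", "-"), strand, "*"),
    stringsAsFactors = FALSE)
  transcript_set(exons)
}

#' Write a transcript set as GTF
#'
#' Emits one `transcript` record plus its `exon` records per transcript,
#' converting internal 0-based half-open coordinates back to GTF's 1-based
#' closed convention; unknown strand is written as `"."`.
#'
#' @param ts a `transcript_set`
#' @param path output file
#' @param source value for the GTF source column
#' @return `path`, invisibly
#' @export
write_annotation <- function(ts, path, source = "lncstrict") {
  ex <- ts$exons
  sp <- transcript_spans(ts)
  fmt <- function(df, type) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            df$chrom, source, type, as.integer(df$start) + 1L,
            as.integer(df$end), ifelse(df$strand == "*", ".", df$strand),
            df$gene_id, df$transcript_id)
  }
  lines <- character(0)
  for (tid in unique(sp$transcript_id)) {
    lines <- c(lines,
               fmt(sp[sp$transcript_id == tid, , drop = FALSE], "transcript"),
               fmt(ex[ex$transcript_id == tid, , drop = FALSE], "exon"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a transcript set as BED6 or BED12
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' pass through unchanged. BED12 encodes the exon chain as blocks (one line
#' per transcript); BED6 writes the genomic span.
#'
#' @param ts a `transcript_set`
#' @param path output file
#' @param format `"bed12"` or `"bed6"`
#' @return `path`, invisibly
#' @export
write_bed <- function(ts, path, format = c("bed12", "bed6")) {
  format <- match.arg(format)
  sp <- transcript_spans(ts)
  strand <- ifelse(sp$strand == "*", ".", sp$strand)
  if (format == "bed6") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", sp$chrom,
                     as.integer(sp$start), as.integer(sp$end),
                     sp$transcript_id, strand)
  } else {
    ex <- split(ts$exons, ts$exons$transcript_id)
    lines <- vapply(seq_len(nrow(sp)), function(i) {
      df <- ex[[sp$transcript_id[i]]]
      sizes <- paste0(as.integer(df$end - df$start), collapse = ",")
      starts <- paste0(as.integer(df$start - sp$start[i]), collapse = ",")
      sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
              sp$chrom[i], as.integer(sp$start[i]), as.integer(sp$end[i]),
              sp$transcript_id[i], strand[i],
              as.integer(sp$start[i]), as.integer(sp$start[i]),
              nrow(df), sizes, starts)
    }, character(1L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]; sequence names are trimmed to the
#'   first whitespace-delimited token
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract transcript sequences from a genome
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements the result for minus-strand transcripts. Unknown
#' strand (`"*"`) is treated as plus.
#'
#' @param ts a `transcript_set`
#' @param genome a [Biostrings::DNAStringSet] (or named character vector)
#'   keyed by chromosome name
#' @param transcript_id optional subset of transcripts
#' @return named character vector of nucleotide sequences
#' @export
extract_sequence <- function(ts, genome, transcript_id = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  ex <- ts$exons
  if (!is.null(transcript_id)) {
    ex <- ex[ex$transcript_id %in% transcript_id, , drop = FALSE]
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- vapply(split(ex, ex$transcript_id), function(df) {
    chrom <- df$chrom[1L]
    if (!chrom %in% names(chrom_len)) {
      stop("chromosome ", chrom, " absent from genome")
    }
    if (max(df$end) > chrom_len[[chrom]]) {
      stop("exon of transcript ", df$transcript_id[1L],
           " extends beyond chromosome ", chrom,
           " (length ", chrom_len[[chrom]], ")")
    }
    seq <- paste0(vapply(seq_len(nrow(df)), function(i) {
      as.character(Biostrings::subseq(genome[[chrom]],
                                      start = df$start[i] + 1L,
                                      end = df$end[i]))
    }, character(1L)), collapse = "")
    if (df$strand[1L] == "-") {
      seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    seq
  }, character(1L))
  out
}

#' Attach genome-derived sequences to a transcript set
#' @param ts a `transcript_set`
#' @param genome a [Biostrings::DNAStringSet]
#' @return `ts` with its `sequences` slot filled
#' @export
add_sequences <- function(ts, genome) {
  transcript_set(ts$exons, sequences = extract_sequence(ts, genome),
                 merge_bookended = FALSE)
}
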