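#' Transcript sets
#'
#' A `transcript_set` is the container that flows through the whole pipeline:
#' an exon table (one row per exon) plus optional transcript sequences. All
#' coordinates are internal 0-based half-open; conversion to/from GTF's
#' 1-based closed convention happens only at the file boundary
#' (see [read_annotation()] / [write_annotation()]).
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (one of `"+"`, `"-"`, `"*"`; `"*"` means
#'   unknown orientation, e.g. transcripts assembled from single-end
#'   libraries only).
#' @param sequences optional named character vector of transcript nucleotide
#'   sequences; names are transcript ids and each sequence must have the
#'   transcript's total exonic length.
#' @param merge_bookended merge exons whose end equals the next exon's start
#'   (zero-length "introns") instead of rejecting them.
#'
#' @return An object of class `transcript_set`: a list with elements
#'   `exons` (validated, sorted exon table) and `sequences`.
#' @export
transcript_set <- function(exons, sequences = NULL, merge_bookended = TRUE) {
  required <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L) {
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons)[required]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)

  if (any(!exons$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  bad <- exons$start < 0 | exons$end <= exons$start
  if (any(bad)) {
    stop("invalid exon interval (need 0 <= start < end) for transcript(s): ",
         paste(unique(exons$transcript_id[bad]), collapse = ", "))
  }

  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  pieces <- split(exons, exons$transcript_id)
  pieces <- lapply(pieces, function(df) {
    if (length(unique(df$chrom)) > 1L || length(unique(df$strand)) > 1L) {
      stop("transcript ", df$transcript_id[1L],
           " has exons on multiple chromosomes or strands")
    }
    if (length(unique(df$gene_id)) > 1L) {
      stop("transcript ", df$transcript_id[1L], " maps to multiple gene_ids")
    }
    if (nrow(df) > 1L) {
      if (merge_bookended) {
        keep <- logical(nrow(df))
        keep[1L] <- TRUE
        cur <- 1L
        for (i in seq_len(nrow(df))[-1L]) {
          if (df$start[i] == df$end[cur]) {
            df$end[cur] <- df$end[i]          # bookended: extend
          } else {
            cur <- i
            keep[i] <- TRUE
          }
        }
        df <- df[keep, , drop = FALSE]
      }
      if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)])) {
        stop("transcript ", df$transcript_id[1L], " has overlapping exons")
      }
    }
    df
  })
  exons <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  exons <- exons[order(exons$chrom, exons$start, exons$transcript_id), ,
                 drop = FALSE]
  rownames(exons) <- NULL

  if (!is.null(sequences)) {
    sequences <- vapply(sequences, toupper, character(1L))
    len <- exonic_length_from(exons)
    for (id in names(sequences)) {
      if (!id %in% names(len)) {
        stop("sequence supplied for unknown transcript ", id)
      }
      if (nchar(sequences[[id]]) != len[[id]]) {
        stop("sequence length for ", id, " (", nchar(sequences[[id]]),
             ") does not match exonic length (", len[[id]], ")")
      }
    }
  }

  structure(list(exons = exons, sequences = sequences),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", length(transcript_ids(x)), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$exons$chrom)), "chromosome(s)\n")
  invisible(x)
}

exonic_length_from <- function(exons) {
  tapply(exons$end - exons$start, exons$transcript_id, sum)
}

#' Transcript ids of a transcript set
#' @param ts a `transcript_set`
#' @return character vector of transcript ids (sorted)
#' @export
transcript_ids <- function(ts) sort(unique(ts$exons$transcript_id))

#' Total exonic length per transcript
#' @param ts a `transcript_set`
#' @return named numeric vector, bp of exonic sequence per transcript
#' @export
exonic_lengths <- function(ts) {
  len <- exonic_length_from(ts$exons)
  stats::setNames(as.numeric(len), names(len))
}

#' Genomic span of each transcript
#'
#' One row per transcript with the transcript's chromosome, strand, gene and
#' the [min start, max end) genomic footprint.
#' @param ts a `transcript_set`
#' @return data.frame with columns transcript_id, gene_id, chrom, start, end,
#'   strand
#' @export
transcript_spans <- function(ts) {
  ex <- ts$exons
  first <- !duplicated(ex$transcript_id)
  sp <- ex[first, c("transcript_id", "gene_id", "chrom", "strand")]
  sp$start <- as.numeric(tapply(ex$start, ex$transcript_id, min)[sp$transcript_id])
  sp$end <- as.numeric(tapply(ex$end, ex$transcript_id, max)[sp$transcript_id])
  rownames(sp) <- NULL
  sp[, c("transcript_id", "gene_id", "chrom", "start", "end", "strand")]
}

#' Introns of a transcript set
#'
#' Gaps between consecutive exons of each transcript; mono-exonic transcripts
#' contribute no rows. Bookended exons were merged on construction, so every
#' intron has length >= 1.
#'
#' @param ts a `transcript_set`
#' @param transcript_id optional subset of transcript ids
#' @return data.frame with columns transcript_id, chrom, start, end, strand
#'   (0-based half-open intron intervals)
#' @export
derive_introns <- function(ts, transcript_id = NULL) {
  ex <- ts$exons
  if (!is.null(transcript_id)) {
    ex <- ex[ex$transcript_id %in% transcript_id, , drop = FALSE]
  }
  out <- lapply(split(ex, ex$transcript_id), function(df) {
    if (nrow(df) < 2L) return(NULL)
    data.frame(transcript_id = df$transcript_id[1L],
               chrom = df$chrom[1L],
               start = df$end[-nrow(df)],
               end = df$start[-1L],
               strand = df$strand[1L],
               stringsAsFactors = FALSE)
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exons as a GRanges object
#'
#' Converts to 1-based closed coordinates as GRanges expects.
#' @param ts a `transcript_set`
#' @return a [GenomicRanges::GRanges] with transcript_id and gene_id metadata
#' @export
exons_as_granges <- function(ts) {
  ex <- ts$exons
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand,
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id)
}

#' Subset a transcript set by transcript id
#' @param ts a `transcript_set`
#' @param ids transcript ids to keep
#' @return a `transcript_set`
#' @export
subset_transcripts <- function(ts, ids) {
  ex <- ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE]
  if (nrow(ex) == 0L) stop("no transcripts left after subsetting")
  seqs <- ts$sequences
  if (!is.null(seqs)) seqs <- seqs[names(seqs) %in% ids]
  transcript_set(ex, sequences = seqs, merge_bookended = FALSE)
}
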