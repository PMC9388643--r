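#' Overlap configuration for biotype classification
#'
#' @param min_fraction_exonic minimum fraction of the lncRNA's exonic length
#'   that must overlap a reference gene's exons (per reference gene,
#'   inclusive) to call sense-exonic / NAT; mirrors `intersectBed -f 0.1`
#' @param overlap_basis `"exonic"` measures overlap between exon base sets
#'   and divides by exonic length (default); `"span"` uses genomic spans
#' @param strand_policy how to treat unknown-strand (`"*"`) transcripts for
#'   the strand-dependent labels: `"skip"` assigns neither sense-exonic nor
#'   NAT and lets the transcript fall through to the intronic/lincRNA tests
#'   (matching orientation-less single-end assemblies); `"both"` tests both
#'   orientations
#' @return a list of class `overlap_config`
#' @export
overlap_config <- function(min_fraction_exonic = 0.1,
                           overlap_basis = c("exonic", "span"),
                           strand_policy = c("skip", "both")) {
  stopifnot(min_fraction_exonic > 0, min_fraction_exonic <= 1)
  structure(list(min_fraction_exonic = min_fraction_exonic,
                 overlap_basis = match.arg(overlap_basis),
                 strand_policy = match.arg(strand_policy)),
            class = "overlap_config")
}

BIOTYPE_LABELS <- c("lincRNA", "NAT", "sense_exonic", "intronic")

# per (query transcript, reference gene, reference strand): overlapping bases
# between the query's exon base set and the union of the gene's exons
overlap_bases_by_gene <- function(q_gr, r_gr) {
  hits <- GenomicRanges::findOverlaps(q_gr, r_gr, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      ref_strand = character(), bases = numeric(),
                      stringsAsFactors = FALSE))
  }
  q <- q_gr[S4Vectors::queryHits(hits)]
  r <- r_gr[S4Vectors::subjectHits(hits)]
  ov <- IRanges::pintersect(IRanges::ranges(q), IRanges::ranges(r))
  df <- data.frame(transcript_id = q$transcript_id,
                   gene_id = r$gene_id,
                   ref_strand = as.character(BiocGenerics::strand(r)),
                   bases = IRanges::width(ov),
                   stringsAsFactors = FALSE)
  out <- stats::aggregate(bases ~ transcript_id + gene_id + ref_strand,
                          data = df, FUN = sum)
  out
}

#' Classify lncRNA transcripts by genomic position
#'
#' Assigns positional biotypes by strand-aware overlap with reference genes,
#' considering all isoforms of each reference gene:
#' * `sense_exonic` — same-strand exonic overlap with some reference gene
#'   covering at least `min_fraction_exonic` of the transcript's exonic
#'   length;
#' * `NAT` — the same test on the opposite strand (natural antisense);
#' * `intronic` — the transcript's whole genomic span lies inside a single
#'   intron of at least one isoform of some gene, and the transcript
#'   overlaps no exon of that gene on either strand;
#' * `lincRNA` — no other label applies; in particular any transcript whose
#'   span overlaps no reference gene at all.
#'
#' Labels accumulate over reference genes, so a transcript wedged between a
#' sense and an antisense gene can be both NAT and sense-exonic. `lincRNA`
#' never co-occurs with another label. Unknown-strand transcripts are
#' handled per `strand_policy`.
#'
#' @param ts candidate `transcript_set` (e.g. Strict Method survivors)
#' @param reference reference `transcript_set` (gene models; isoforms share
#'   a `gene_id`)
#' @param cfg an [overlap_config()]
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `labels` (comma-joined, sorted), `overlapping_genes`
#'   (comma-joined `label:gene` pairs) and one logical column per biotype
#' @export
classify_transcripts <- function(ts, reference, cfg = overlap_config()) {
  ids <- transcript_ids(ts)
  spans <- transcript_spans(ts)
  rownames(spans) <- spans$transcript_id
  if (is.null(reference) || nrow(reference$exons) == 0L) {
    warning("empty reference annotation: every transcript labelled lincRNA")
    return(finish_biotype_calls(ids, spans,
                                stats::setNames(rep(list(character(0)), 0),
                                                character(0))))
  }

  exlen <- exonic_lengths(ts)
  q_gr <- exons_as_granges(ts)
  r_gr <- exons_as_granges(reference)
  if (cfg$overlap_basis == "span") {
    sp <- transcript_spans(ts)
    q_gr <- GenomicRanges::GRanges(sp$chrom,
                                   IRanges::IRanges(sp$start + 1L, sp$end),
                                   strand = sp$strand,
                                   transcript_id = sp$transcript_id,
                                   gene_id = sp$gene_id)
    exlen <- stats::setNames(sp$end - sp$start, sp$transcript_id)
  }
  # reduce reference exons per gene+strand so shared exon bases count once
  r_split <- GenomicRanges::split(r_gr, paste(r_gr$gene_id,
                                              BiocGenerics::strand(r_gr)))
  r_red <- unlist(GenomicRanges::reduce(r_split))
  key <- names(r_red)
  r_red$gene_id <- sub(" [+*-]$", "", key)
  names(r_red) <- NULL

  ov <- overlap_bases_by_gene(q_gr, r_red)
  ov$q_strand <- spans[ov$transcript_id, "strand"]
  ov$fraction <- ov$bases / exlen[ov$transcript_id]

  labels <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  gene_links <- stats::setNames(rep(list(character(0)), length(ids)), ids)

  hit <- ov[ov$fraction >= cfg$min_fraction_exonic, , drop = FALSE]
  for (i in seq_len(nrow(hit))) {
    tid <- hit$transcript_id[i]
    qs <- hit$q_strand[i]
    if (qs == "*") {
      if (cfg$strand_policy == "skip") next
      labs <- c("sense_exonic", "NAT")
    } else {
      labs <- if (qs == hit$ref_strand[i]) "sense_exonic" else "NAT"
    }
    for (lab in labs) {
      labels[[tid]] <- union(labels[[tid]], lab)
      gene_links[[tid]] <- union(gene_links[[tid]],
                                 paste0(lab, ":", hit$gene_id[i]))
    }
  }

  # intronic: span within one intron of some isoform, no exon overlap with
  # that gene (either strand)
  ref_introns <- derive_introns(reference)
  ref_gene_of_tx <- ref_gene_map(reference)
  if (nrow(ref_introns) > 0L) {
    in_gr <- GenomicRanges::GRanges(ref_introns$chrom,
                                    IRanges::IRanges(ref_introns$start + 1L,
                                                     ref_introns$end),
                                    gene_id = ref_gene_of_tx[ref_introns$transcript_id])
    sp_gr <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1L,
                                                     spans$end),
                                    transcript_id = spans$transcript_id)
    hits <- GenomicRanges::findOverlaps(sp_gr, in_gr, type = "within",
                                        ignore.strand = TRUE)
    if (length(hits) > 0L) {
      cand <- unique(data.frame(
        transcript_id = sp_gr$transcript_id[S4Vectors::queryHits(hits)],
        gene_id = in_gr$gene_id[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE))
      # exon contact with the host gene disqualifies (any strand)
      ex_ov <- overlap_bases_by_gene(q_gr, r_red)
      touched <- unique(paste(ex_ov$transcript_id, ex_ov$gene_id))
      cand <- cand[!paste(cand$transcript_id, cand$gene_id) %in% touched, ,
                   drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        tid <- cand$transcript_id[i]
        labels[[tid]] <- union(labels[[tid]], "intronic")
        gene_links[[tid]] <- union(gene_links[[tid]],
                                   paste0("intronic:", cand$gene_id[i]))
      }
    }
  }
  finish_biotype_calls(ids, spans, labels, gene_links)
}

ref_gene_map <- function(reference) {
  ex <- reference$exons
  first <- !duplicated(ex$transcript_id)
  stats::setNames(ex$gene_id[first], ex$transcript_id[first])
}

finish_biotype_calls <- function(ids, spans, labels,
                                 gene_links = NULL) {
  lab_str <- vapply(ids, function(id) {
    labs <- labels[[id]]
    if (is.null(labs) || length(labs) == 0L) labs <- "lincRNA"
    paste(sort(labs), collapse = ",")
  }, character(1L))
  links <- vapply(ids, function(id) {
    gl <- if (is.null(gene_links)) character(0) else gene_links[[id]]
    paste(sort(gl), collapse = ",")
  }, character(1L))
  out <- data.frame(transcript_id = ids,
                    gene_id = spans[ids, "gene_id"],
                    labels = lab_str,
                    overlapping_genes = links,
                    stringsAsFactors = FALSE)
  for (lab in BIOTYPE_LABELS) {
    out[[lab]] <- vapply(strsplit(lab_str, ","), function(v) lab %in% v,
                         logical(1L))
  }
  rownames(out) <- NULL
  out
}

#' Aggregate transcript biotype calls to gene level
#'
#' The gene label set is the union of its isoforms' label sets; genes with
#' more than one label are flagged ambiguous. The distinct gene count equals
#' the sum of per-label gene counts minus the label surplus of multi-label
#' genes.
#'
#' @param calls output of [classify_transcripts()]
#' @return list with `genes` (data.frame gene_id, labels, n_labels,
#'   ambiguous), `label_gene_counts` (genes per label), `n_multi_label`
#'   and `n_distinct_genes`
#' @export
aggregate_gene_biotypes <- function(calls) {
  per_gene <- lapply(split(calls$labels, calls$gene_id), function(v) {
    sort(unique(unlist(strsplit(v, ","))))
  })
  genes <- data.frame(gene_id = names(per_gene),
                      labels = vapply(per_gene, paste, character(1L),
                                      collapse = ","),
                      n_labels = lengths(per_gene),
                      stringsAsFactors = FALSE)
  genes$ambiguous <- genes$n_labels > 1L
  rownames(genes) <- NULL
  label_counts <- vapply(BIOTYPE_LABELS, function(lab) {
    sum(vapply(per_gene, function(v) lab %in% v, logical(1L)))
  }, numeric(1L))
  list(genes = genes,
       label_gene_counts = label_counts,
       n_multi_label = sum(genes$ambiguous),
       n_distinct_genes = nrow(genes))
}

#' Distinct-gene arithmetic from per-label counts
#'
#' Number of distinct genes given per-label gene counts and the total label
#' surplus of multi-label genes: `sum(counts) - surplus`, where surplus is
#' the sum over genes of (number of labels - 1).
#'
#' @param label_gene_counts genes per biotype label
#' @param label_surplus total extra labels carried by multi-label genes
#' @return distinct gene count
#' @export
distinct_gene_count <- function(label_gene_counts, label_surplus) {
  sum(label_gene_counts) - label_surplus
}

#' Compare two transcript annotations by reciprocal full overlap
#'
#' Two transcripts are shared when they lie on the same strand and each
#' covers 100% of the other — i.e. identical genomic spans (the
#' `intersectBed -s -f 1 -F 1` criterion). Gene-level sharing means any
#' isoform pair is shared.
#'
#' @param set_a,set_b `transcript_set`s on the same genome build
#' @return list with `shared_pairs` (data.frame transcript_a, transcript_b),
#'   transcript- and gene-level shared/unique counts for each set
#' @export
compare_annotations <- function(set_a, set_b) {
  sa <- transcript_spans(set_a)
  sb <- transcript_spans(set_b)
  if (length(intersect(sa$chrom, sb$chrom)) == 0L) {
    stop("no shared chromosome names between the two sets; unmatched: ",
         paste(union(sa$chrom, sb$chrom), collapse = ", "))
  }
  key_a <- paste(sa$chrom, sa$start, sa$end, sa$strand)
  key_b <- paste(sb$chrom, sb$start, sb$end, sb$strand)
  m <- merge(data.frame(key = key_a, transcript_a = sa$transcript_id,
                        gene_a = sa$gene_id, stringsAsFactors = FALSE),
             data.frame(key = key_b, transcript_b = sb$transcript_id,
                        gene_b = sb$gene_id, stringsAsFactors = FALSE),
             by = "key")
  shared_a <- unique(m$transcript_a)
  shared_b <- unique(m$transcript_b)
  list(shared_pairs = m[, c("transcript_a", "transcript_b")],
       n_shared_a = length(shared_a),
       n_shared_b = length(shared_b),
       n_unique_a = nrow(sa) - length(shared_a),
       n_unique_b = nrow(sb) - length(shared_b),
       shared_genes_a = unique(m$gene_a),
       shared_genes_b = unique(m$gene_b))
}
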