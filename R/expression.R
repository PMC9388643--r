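#' Convert counts to TPM
#'
#' Standard transcripts-per-million: per sample, `rate = count / length`,
#' `TPM = 1e6 * rate / sum(rate)`. A sample with all-zero counts stays
#' all-zero.
#'
#' @param counts genes-by-samples matrix of non-negative counts
#' @param effective_lengths per-gene effective lengths in bp (recycled by
#'   row name when named)
#' @return TPM matrix with the same dimnames; columns of samples with any
#'   signal sum to 1e6
#' @export
counts_to_tpm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(effective_lengths)) && !is.null(rownames(counts))) {
    effective_lengths <- effective_lengths[rownames(counts)]
  }
  if (any(is.na(effective_lengths)) || any(effective_lengths <= 0)) {
    stop("effective lengths must be positive for every gene")
  }
  rate <- counts / effective_lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2L, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm
}

#' High/low-confidence expression calls
#'
#' A gene is High Confidence (HC) when it reaches the TPM threshold in at
#' least one sample (boundary inclusive: exactly 3 TPM is HC), otherwise Low
#' Confidence (LC).
#'
#' @param tpm TPM matrix (genes x samples)
#' @param threshold TPM threshold, default 3
#' @return data.frame gene_id, max_tpm, status ("HC"/"LC")
#' @export
call_confidence <- function(tpm, threshold = 3) {
  mx <- apply(as.matrix(tpm), 1L, max)
  data.frame(gene_id = rownames(tpm),
             max_tpm = unname(mx),
             status = ifelse(mx >= threshold, "HC", "LC"),
             stringsAsFactors = FALSE)
}

#' Developmental stage bins
#'
#' Five closed integer bins of age in days post-germination: seed
#' germination (Stage1, 3-5 d), leaf development (Stage2, 6-25 d), first
#' inflorescence (Stage3, 26-29 d), flower production (Stage4, 30-47 d) and
#' silique generation (Stage5, 48-51 d).
#'
#' @return data.frame stage, min_days, max_days
#' @export
stage_bins <- function() {
  data.frame(stage = paste0("Stage", 1:5),
             min_days = c(3, 6, 26, 30, 48),
             max_days = c(5, 25, 29, 47, 51),
             stringsAsFactors = FALSE)
}

#' Assign samples to developmental stages
#'
#' Ages outside every bin are labelled `"unbinned"` (with a warning) and are
#' meant to be excluded from stage summaries, not clamped.
#'
#' @param meta sample metadata data.frame with an `age_days` column
#' @param bins a stage-bin table, see [stage_bins()]
#' @return `meta` with a `stage` column appended
#' @export
assign_stage <- function(meta, bins = stage_bins()) {
  stage <- vapply(meta$age_days, function(a) {
    hit <- which(a >= bins$min_days & a <= bins$max_days)
    if (length(hit) == 1L) bins$stage[hit] else "unbinned"
  }, character(1L))
  if (any(stage == "unbinned")) {
    warning(sum(stage == "unbinned"),
            " sample(s) fall outside all stage bins")
  }
  meta$stage <- stage
  meta
}

#' Tissue-specificity index Tau
#'
#' Group expression is the per-group mean of `log2(TPM + 1)` (or raw TPM
#' with `transform = "raw"`). With `x_hat = x / max(x)` over the N groups,
#' `tau = sum(1 - x_hat) / (N - 1)`: 0 for uniform expression, 1 for
#' expression confined to a single group. Genes with zero expression in all
#' groups get no profile.
#'
#' @param tpm TPM matrix (genes x samples)
#' @param grouping named character vector mapping sample id to group (tissue
#'   or stage)
#' @param transform `"log2"` (default) or `"raw"`
#' @return data.frame gene_id, tau, argmax_group
#' @export
compute_tau <- function(tpm, grouping, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  tpm <- as.matrix(tpm)
  grouping <- grouping[colnames(tpm)]
  if (any(is.na(grouping))) stop("grouping must cover every sample")
  groups <- unique(grouping)
  if (length(groups) < 2L) stop("tau needs at least two groups")
  x <- if (transform == "log2") log2(tpm + 1) else tpm
  gm <- vapply(groups, function(g) {
    rowMeans(x[, grouping == g, drop = FALSE])
  }, numeric(nrow(tpm)))
  gm <- matrix(gm, nrow = nrow(tpm),
               dimnames = list(rownames(tpm), groups))
  mx <- apply(gm, 1L, max)
  keep <- mx > 0
  gm <- gm[keep, , drop = FALSE]
  mx <- mx[keep]
  xhat <- gm / mx
  tau <- rowSums(1 - xhat) / (ncol(gm) - 1L)
  data.frame(gene_id = rownames(tpm)[keep],
             tau = unname(tau),
             argmax_group = groups[apply(gm, 1L, which.max)],
             stringsAsFactors = FALSE)
}

#' Flag tissue/stage-specific genes by the mRNA-median Tau cutoff
#'
#' The cutoff is the median Tau over the supplied mRNA (coding gene)
#' profiles — recomputed from data, not hard-coded; a gene is specific when
#' its Tau strictly exceeds it.
#'
#' @param profiles Tau profiles to flag (see [compute_tau()])
#' @param mrna_profiles Tau profiles of the coding genes defining the cutoff
#' @return `profiles` with a `specific` logical column; the cutoff is
#'   attached as attribute `"cutoff"`
#' @export
call_specific <- function(profiles, mrna_profiles) {
  if (nrow(mrna_profiles) == 0L) stop("mRNA profile set is empty")
  cutoff <- stats::median(mrna_profiles$tau)
  profiles$specific <- profiles$tau > cutoff
  attr(profiles, "cutoff") <- cutoff
  profiles
}

#' Per-group expressed and unique-gene summaries
#'
#' A gene is expressed in a group when it reaches the TPM threshold in at
#' least one of the group's samples (aligned with the HC rule by default);
#' it is unique to a group when expressed in exactly one group.
#'
#' @param tpm TPM matrix
#' @param grouping named character vector sample id -> group
#' @param threshold TPM threshold, default 3
#' @return list with `expressed` (logical genes x groups matrix),
#'   `n_expressed` and `n_unique` per group, and `unique_genes` (named list)
#' @export
summarize_by_group <- function(tpm, grouping, threshold = 3) {
  tpm <- as.matrix(tpm)
  grouping <- grouping[colnames(tpm)]
  groups <- unique(grouping)
  expressed <- vapply(groups, function(g) {
    apply(tpm[, grouping == g, drop = FALSE], 1L, max) >= threshold
  }, logical(nrow(tpm)))
  expressed <- matrix(expressed, nrow = nrow(tpm),
                      dimnames = list(rownames(tpm), groups))
  n_groups <- rowSums(expressed)
  unique_genes <- lapply(stats::setNames(groups, groups), function(g) {
    rownames(tpm)[expressed[, g] & n_groups == 1L]
  })
  list(expressed = expressed,
       n_expressed = colSums(expressed),
       n_unique = lengths(unique_genes),
       unique_genes = unique_genes)
}
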