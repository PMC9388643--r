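#' Run the full pipeline on a simulated dataset
#'
#' Executes simulate -> filter -> classify -> quantify -> co-express ->
#' enrich and assembles a run report with the per-stage counts and derived
#' percentages. Deterministic given the seed in `cfg`. When `out_dir` is
#' given, every stage's outputs are written (dataset files, filter trail,
#' biotype tables, Tau/confidence tables, module assignment, eigengenes,
#' enrichment tables and the report JSON).
#'
#' @param cfg a [simulation_config()]
#' @param out_dir optional output directory
#' @param filter_cfg a [filter_config()]
#' @param overlap_cfg an [overlap_config()]
#' @param net_cfg a [network_config()]; the default minimum module size is
#'   lowered to the simulated module size when necessary
#' @param fdr enrichment q-value cutoff
#' @return list with `report` (named list of counts and percentages) and the
#'   per-stage objects (`sim`, `strict`, `biotype`, `gene_biotypes`, `tpm`,
#'   `confidence`, `tau`, `specific`, `modules`, `eigengenes`, `enrichment`,
#'   `lnc_functions`)
#' @export
run_pipeline <- function(cfg = simulation_config(), out_dir = NULL,
                         filter_cfg = filter_config(),
                         overlap_cfg = overlap_config(),
                         net_cfg = network_config(
                           min_module_size = min(50, cfg$module_size)),
                         fdr = 0.01) {
  sim <- simulate_dataset(cfg, dir = out_dir)

  strict <- apply_strict_method(sim$candidates, sim$evidence, filter_cfg)
  survivors <- subset_transcripts(sim$candidates, strict$survivors)

  calls <- classify_transcripts(survivors, sim$reference, overlap_cfg)
  gene_bt <- aggregate_gene_biotypes(calls)

  tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
  confidence <- call_confidence(tpm)
  grouping <- stats::setNames(sim$metadata$tissue, sim$metadata$sample_id)
  tau <- compute_tau(tpm, grouping)
  gene_type <- stats::setNames(sim$manifest$genes$gene_type,
                               sim$manifest$genes$gene_id)
  mrna_tau <- tau[gene_type[tau$gene_id] == "coding", , drop = FALSE]
  lnc_gene_ids <- unique(calls$gene_id)
  lnc_tau <- tau[tau$gene_id %in% lnc_gene_ids, , drop = FALSE]
  specific <- call_specific(lnc_tau, mrna_tau)

  norm <- normalize_counts(sim$counts)
  det <- detect_modules(norm$normalized, net_cfg)
  eig <- compute_eigengenes(norm$normalized, det$modules)
  background <- sim$manifest$genes$gene_id[
    sim$manifest$genes$gene_type == "coding"]
  enr <- enrich_modules(det$modules, sim$go$annotation,
                        background = background, fdr = fdr)
  lnc_fun <- assign_functions_to_lncrnas(det$modules, enr, lnc_gene_ids)

  n_enriched <- sum(vapply(enr, function(tab) any(tab$significant),
                           logical(1L)))
  label_counts <- gene_bt$label_gene_counts
  report <- list(
    n_candidates = length(transcript_ids(sim$candidates)),
    n_survivors = length(strict$survivors),
    n_removed = length(transcript_ids(sim$candidates)) -
      length(strict$survivors),
    n_lnc_genes = gene_bt$n_distinct_genes,
    genes_per_biotype = as.list(label_counts),
    n_multi_label_genes = gene_bt$n_multi_label,
    n_hc = sum(confidence$status == "HC" &
                 confidence$gene_id %in% lnc_gene_ids),
    n_lc = sum(confidence$status == "LC" &
                 confidence$gene_id %in% lnc_gene_ids),
    tau_cutoff = attr(specific, "cutoff"),
    n_specific = sum(specific$specific),
    n_modules = length(det$sizes),
    module_sizes = as.list(as.integer(det$sizes)),
    n_lnc_in_modules = sum(lnc_fun$module > 0),
    n_enriched_modules = n_enriched,
    pct_survivors = report_percentages(
      length(strict$survivors), length(transcript_ids(sim$candidates))),
    pct_specific = if (nrow(specific) > 0)
      report_percentages(sum(specific$specific), nrow(specific)) else NA,
    seed = cfg$seed)

  out <- list(report = report, sim = sim, strict = strict, biotype = calls,
              gene_biotypes = gene_bt, tpm = tpm, confidence = confidence,
              tau = tau, specific = specific, modules = det,
              eigengenes = eig, enrichment = enr, lnc_functions = lnc_fun)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(res$strict$trail, "filter_trail.tsv")
  wt(res$strict$status, "filter_status.tsv")
  wt(res$biotype, "biotypes.tsv")
  wt(res$gene_biotypes$genes, "gene_biotypes.tsv")
  wt(res$confidence, "confidence.tsv")
  wt(res$tau, "tau.tsv")
  wt(res$specific, "tau_specific.tsv")
  wt(data.frame(gene_id = names(res$modules$modules),
                module = res$modules$modules), "modules.tsv")
  wt(data.frame(sample_id = rownames(res$eigengenes$eigengenes),
                res$eigengenes$eigengenes, check.names = FALSE),
     "eigengenes.tsv")
  enr_all <- do.call(rbind, lapply(names(res$enrichment), function(m) {
    tab <- res$enrichment[[m]]
    if (nrow(tab) == 0L) return(NULL)
    cbind(module = m, tab)
  }))
  if (!is.null(enr_all)) wt(enr_all, "enrichment.tsv")
  wt(res$lnc_functions, "lncrna_functions.tsv")
  jsonlite::write_json(res$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Half-up rounding
#'
#' Rounds away from banker's rounding: exact .5 ties go up, matching how
#' percentages are conventionally printed.
#'
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage of a count pair at a printed precision
#'
#' `100 * numerator / denominator`, truncated toward zero at the printed
#' precision by default — the convention that reproduces conventionally
#' printed values like 93.08 for 2275/2444 and 134.70 for 1502/1115 —
#' with half-up rounding available as an option.
#'
#' @param numerator,denominator counts (denominator > 0)
#' @param digits decimal places of the printed percentage
#' @param method `"trunc"` (default) or `"half_up"`
#' @return the percentage
#' @export
report_percentages <- function(numerator, denominator, digits = 2,
                               method = c("trunc", "half_up")) {
  method <- match.arg(method)
  if (any(denominator <= 0)) stop("denominator must be positive")
  x <- 100 * numerator / denominator
  p <- 10^digits
  if (method == "trunc") trunc(x * p) / p else round_half_up(x, digits)
}
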