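#' Read a gene-to-GO annotation table
#'
#' Two-column TSV (gene_id, term_id). When a term parent table is supplied
#' (columns term_id, parent_id), the annotation is closed under ancestry: a
#' gene annotated to a term is annotated to all the term's ancestors.
#'
#' @param path gene-to-term TSV (with header)
#' @param parents_path optional term-parent TSV (with header)
#' @return named list gene_id -> character vector of term ids
#' @export
read_go_annotation <- function(path, parents_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ann <- lapply(split(as.character(df[[2L]]), as.character(df[[1L]])), unique)
  if (!is.null(parents_path)) {
    pp <- utils::read.delim(parents_path, stringsAsFactors = FALSE)
    parents <- split(as.character(pp[[2L]]), as.character(pp[[1L]]))
    ann <- lapply(ann, go_ancestor_closure, parents = parents)
  }
  ann
}

#' Close a term set under ancestry
#' @param terms character vector of term ids
#' @param parents named list term_id -> parent term ids
#' @return terms plus all their ancestors
#' @export
go_ancestor_closure <- function(terms, parents) {
  out <- unique(terms)
  frontier <- out
  while (length(frontier) > 0L) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    up <- setdiff(up, out)
    out <- c(out, up)
    frontier <- up
  }
  out
}

#' Per-term hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric (Fisher) test per GO term: with `N`
#' annotated background genes, `K` of them carrying the term, and a module
#' of `n` annotated genes of which `k` carry the term,
#' `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. Terms absent from the
#' module (`k = 0`) are skipped. Benjamini-Hochberg q-values are computed
#' within the module's term family; significance is `q < fdr` (strict).
#'
#' @param module_genes genes of one module
#' @param background_genes background gene universe (the module must be a
#'   subset); genes without annotation are dropped from both
#' @param annotation named list gene_id -> term ids
#' @param fdr significance level on the q-value (default 0.01)
#' @return data.frame term_id, k, K, n, N, p_value, q_value, significant
#' @export
hypergeom_enrich <- function(module_genes, background_genes, annotation,
                             fdr = 0.01) {
  bg <- intersect(background_genes, names(annotation))
  # genes without annotation (e.g. lncRNAs) drop out of both sets
  mod <- intersect(module_genes, bg)
  stray <- setdiff(intersect(module_genes, names(annotation)),
                   background_genes)
  if (length(stray) > 0L) {
    stop("module genes must be a subset of the background")
  }
  empty <- data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (length(mod) == 0L) {
    warning("module has no annotated genes")
    return(empty)
  }
  N <- length(bg)
  n <- length(mod)
  bg_terms <- table(unlist(annotation[bg], use.names = FALSE))
  mod_terms <- table(unlist(annotation[mod], use.names = FALSE))
  terms <- names(mod_terms)            # k >= 1 by construction
  if (length(terms) == 0L) return(empty)
  k <- as.integer(mod_terms[terms])
  K <- as.integer(bg_terms[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(term_id = terms, k = k, K = K, n = n, N = N,
                    p_value = p, q_value = q,
                    significant = q < fdr,
                    stringsAsFactors = FALSE)
  out[order(out$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m p_(j) / j` over the sorted p-values, capped at 1.
#'
#' @param p p-values in (0, 1]
#' @return q-values in the original order
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Guilt-by-association function transfer to lncRNAs
#'
#' Each lncRNA in a non-zero module inherits the module's significant GO
#' terms; lncRNAs in module 0 or in modules with no significant term inherit
#' none.
#'
#' @param modules named integer vector gene -> module index
#' @param enrichment named list module index (as character) -> enrichment
#'   table from [hypergeom_enrich()]
#' @param lncrna_ids lncRNA gene ids
#' @return data.frame gene_id, module, terms (comma-joined significant term
#'   ids, "" when none), n_terms
#' @export
assign_functions_to_lncrnas <- function(modules, enrichment, lncrna_ids) {
  lnc <- intersect(lncrna_ids, names(modules))
  rows <- lapply(lnc, function(g) {
    m <- modules[[g]]
    terms <- character(0)
    if (m != 0L) {
      tab <- enrichment[[as.character(m)]]
      if (!is.null(tab) && nrow(tab) > 0L) {
        terms <- tab$term_id[tab$significant]
      }
    }
    data.frame(gene_id = g, module = m,
               terms = paste(sort(terms), collapse = ","),
               n_terms = length(terms), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Enrich every module of a module assignment
#'
#' Convenience wrapper running [hypergeom_enrich()] for each non-zero
#' module against a common background.
#'
#' @param modules named integer vector gene -> module index
#' @param annotation named list gene_id -> term ids
#' @param background optional background gene universe; default all genes in
#'   `modules` that carry annotation
#' @param fdr q-value significance level
#' @return named list module index -> enrichment table
#' @export
enrich_modules <- function(modules, annotation, background = NULL,
                           fdr = 0.01) {
  if (is.null(background)) background <- names(modules)
  idx <- sort(unique(modules[modules != 0]))
  out <- lapply(idx, function(m) {
    suppressWarnings(
      hypergeom_enrich(names(modules)[modules == m], background,
                       annotation, fdr = fdr))
  })
  stats::setNames(out, as.character(idx))
}
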