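#' Network configuration
#'
#' Parameters of the signed co-expression network: soft-threshold power
#' `beta` (chosen so the network approximates scale-free topology; see
#' [scale_free_fit()]), the biweight midcorrelation as the correlation
#' measure, a minimum module size of 50 genes and unmerged modules.
#'
#' @param beta soft-threshold power (>= 1)
#' @param min_module_size smallest admissible module (genes)
#' @param cut_method `"static"` (default) cuts the average-linkage
#'   dendrogram at `cut_height` times the maximum merge height, so genes
#'   that only attach to a branch near the top of the tree (background genes
#'   with near-unit TOM dissimilarity to everything) stay unassigned;
#'   `"adaptive"` scans candidate heights and keeps the cut yielding the
#'   most clusters of admissible size
#' @param cut_height static cut height as a fraction of the maximum merge
#'   height
#' @param deep_split 0-4; higher values prefer finer cuts when several
#'   heights yield the same number of admissible clusters
#' @param merge_modules kept `FALSE`: modules are not merged by eigengene
#'   similarity
#' @return a list of class `network_config`
#' @export
network_config <- function(beta = 12, min_module_size = 50,
                           cut_method = c("static", "adaptive"),
                           cut_height = 0.95, deep_split = 2,
                           merge_modules = FALSE) {
  stopifnot(beta >= 1, min_module_size >= 2, deep_split %in% 0:4)
  structure(list(beta = beta, min_module_size = min_module_size,
                 cut_method = match.arg(cut_method),
                 cut_height = cut_height, deep_split = deep_split,
                 merge_modules = merge_modules,
                 network_type = "signed", correlation = "bicor"),
            class = "network_config")
}

#' Median-of-ratios normalization with log transform
#'
#' A variance-stabilizing substitute for count data: library size factors by
#' the median-of-ratios method (median over genes with all-positive counts
#' of the ratio to the gene's geometric mean), then
#' `log2(count / size_factor + 1)`.
#'
#' @param counts genes-by-samples count matrix
#' @return list with `normalized` (matrix) and `size_factors`
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  sf <- median_ratio_size_factors(counts)
  normalized <- log2(sweep(counts, 2L, sf, "/") + 1)
  list(normalized = normalized, size_factors = sf)
}

#' Median-of-ratios library size factors
#' @param counts genes-by-samples count matrix
#' @return numeric vector of size factors, one per sample
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene with positive counts in every sample")
  loggeo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
  unname(sf)
}

bicor_normalize <- function(x, c_const = 9) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {                      # Pearson fallback
    d <- x - mean(x)
    s <- sqrt(sum(d^2))
    if (s == 0) return(rep(NA_real_, length(x)))
    return(d / s)
  }
  u <- (x - med) / (c_const * mad0)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  a <- (x - med) * w
  s <- sqrt(sum(a^2))
  if (s == 0) return(rep(NA_real_, length(x)))
  a / s
}

#' Biweight midcorrelation
#'
#' Robust correlation using median/MAD-based weights
#' `w_i = (1 - u_i^2)^2 1(|u_i| < 1)` with
#' `u_i = (x_i - med(x)) / (9 mad(x))` (unscaled MAD). A vector with zero
#' MAD falls back to Pearson normalization. The result is clipped to
#' \[-1, 1\]; `NA` when a vector has zero variance under both schemes.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in \[-1, 1\], or `NA`
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("bicor needs at least 3 observations")
  a <- bicor_normalize(x)
  b <- bicor_normalize(y)
  if (anyNA(a) || anyNA(b)) return(NA_real_)
  min(1, max(-1, sum(a * b)))
}

#' Biweight midcorrelation matrix
#'
#' Pairwise [bicor()] over the rows of a genes-by-samples matrix, computed
#' by normalizing each gene once and taking cross products.
#'
#' @param x genes-by-samples matrix
#' @return genes-by-genes correlation matrix (diagonal 1)
#' @export
bicor_matrix <- function(x) {
  x <- as.matrix(x)
  a <- t(apply(x, 1L, bicor_normalize))
  cc <- tcrossprod(a)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(x), rownames(x))
  cc
}

#' Signed adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, diagonal set to 1. The signed map keeps
#' anti-correlated genes apart (cor -1 -> 0) instead of folding them
#' together.
#'
#' @param corr correlation matrix in \[-1, 1\]
#' @param beta soft-threshold power
#' @return adjacency matrix in \[0, 1\]
#' @export
signed_adjacency <- function(corr, beta = 12) {
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over u distinct from i and j and connectivity
#' `k_i = sum_{j != i} a_ij`; diagonal 1.
#'
#' @param adjacency adjacency matrix in \[0, 1\] with unit diagonal
#' @return TOM similarity matrix in \[0, 1\]
#' @export
tom_similarity <- function(adjacency) {
  a0 <- adjacency
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  tom
}

#' Scale-free topology fit across soft powers
#'
#' For each power, computes the signed R-squared of the log-log regression
#' of the connectivity distribution (frequency vs binned connectivity) and
#' the mean connectivity — the standard plot used to pick `beta`.
#'
#' @param corr correlation matrix
#' @param beta_grid powers to evaluate
#' @param n_bins connectivity histogram bins
#' @return data.frame beta, r_squared (signed; `NA` when degenerate),
#'   mean_connectivity
#' @export
scale_free_fit <- function(corr, beta_grid = c(1:10, 12, 14, 16, 18, 20),
                           n_bins = 10) {
  rows <- lapply(beta_grid, function(beta) {
    a <- signed_adjacency(corr, beta)
    diag(a) <- 0
    k <- rowSums(a)
    mean_k <- mean(k)
    if (max(k) - min(k) < .Machine$double.eps^0.5) {
      return(data.frame(beta = beta, r_squared = NA_real_,
                        mean_connectivity = mean_k))
    }
    cuts <- cut(k, breaks = n_bins)
    freq <- tapply(k, cuts, length)
    kmid <- tapply(k, cuts, mean)
    ok <- !is.na(freq) & freq > 0 & kmid > 0
    if (sum(ok) < 3L) {
      return(data.frame(beta = beta, r_squared = NA_real_,
                        mean_connectivity = mean_k))
    }
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmid[ok]))
    slope <- stats::coef(fit)[2L]
    r2 <- summary(fit)$r.squared * (-sign(slope))
    data.frame(beta = beta, r_squared = unname(r2),
               mean_connectivity = mean_k)
  })
  do.call(rbind, rows)
}

#' Detect co-expression modules
#'
#' Builds the signed bicor network, converts it to the TOM dissimilarity
#' `1 - TOM`, clusters by average linkage and cuts the tree (adaptive or
#' static height cut) honoring the minimum module size. Clusters below the
#' minimum size are assigned module 0 (unassigned); modules are labelled
#' 1, 2, ... by decreasing size and are not merged.
#'
#' @param normalized genes-by-samples matrix (e.g. [normalize_counts()]
#'   output)
#' @param cfg a [network_config()]
#' @return list with `modules` (named integer vector gene -> module index,
#'   0 = unassigned), `sizes`, `tree` (hclust), `tom` (similarity matrix)
#' @export
detect_modules <- function(normalized, cfg = network_config()) {
  x <- as.matrix(normalized)
  if (nrow(x) < cfg$min_module_size) {
    warning("fewer genes than min_module_size; all genes unassigned")
    mods <- stats::setNames(rep(0L, nrow(x)), rownames(x))
    return(list(modules = mods, sizes = integer(0), tree = NULL, tom = NULL))
  }
  if (ncol(x) < 4L) stop("need at least 4 samples")
  keep <- apply(x, 1L, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance gene(s) set to module 0")
  }
  corr <- bicor_matrix(x[keep, , drop = FALSE])
  adj <- signed_adjacency(corr, cfg$beta)
  tom <- tom_similarity(adj)
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")

  assign_at <- function(h) stats::cutree(tree, h = h)
  heights <- sort(unique(tree$height))
  if (cfg$cut_method == "static") {
    best_cl <- assign_at(cfg$cut_height * max(heights))
  } else {
    # adaptive: the cut producing the most admissible-size clusters;
    # ties broken by deep_split (<=2 prefers the coarser cut)
    cand_h <- unique(stats::quantile(heights, probs = seq(0.05, 1, 0.01),
                                     names = FALSE))
    best_cl <- NULL
    best_score <- -1L
    for (h in if (cfg$deep_split <= 2) rev(cand_h) else cand_h) {
      cl <- assign_at(h)
      score <- sum(table(cl) >= cfg$min_module_size)
      if (score > best_score) {
        best_score <- score
        best_cl <- cl
      }
    }
  }
  sizes <- table(best_cl)
  ok_clusters <- names(sizes)[sizes >= cfg$min_module_size]
  mods <- rep(0L, nrow(x))
  names(mods) <- rownames(x)
  cl_full <- stats::setNames(rep(0L, nrow(x)), rownames(x))
  cl_full[names(best_cl)] <- ifelse(best_cl %in% as.integer(ok_clusters),
                                    best_cl, 0L)
  # PAM-like refinement: an unassigned gene joins the cluster with the
  # highest mean TOM similarity, provided it reaches at least half that
  # cluster's internal mean TOM (background genes stay far below this)
  if (length(ok_clusters) > 0L && any(cl_full == 0L)) {
    cl_ids <- as.integer(ok_clusters)
    members <- lapply(cl_ids, function(cc) names(cl_full)[cl_full == cc])
    internal <- vapply(members, function(gs) {
      tm <- tom[gs, gs]
      mean(tm[upper.tri(tm)])
    }, numeric(1L))
    for (g in intersect(names(cl_full)[cl_full == 0L], rownames(tom))) {
      s <- vapply(members, function(gs) mean(tom[g, gs]), numeric(1L))
      j <- which.max(s)
      if (s[j] >= 0.5 * internal[j]) cl_full[g] <- cl_ids[j]
    }
  }
  # relabel by decreasing size
  kept <- sort(table(cl_full[cl_full != 0]), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(names(kept)), names(kept))
  mods[names(cl_full)] <- ifelse(cl_full == 0L, 0L,
                                 relabel[as.character(cl_full)])
  list(modules = mods,
       sizes = table(mods[mods != 0]),
       tree = tree, tom = tom)
}

#' Module eigengenes
#'
#' Per module, gene expression rows are z-scored and the eigengene is the
#' first right-singular vector of the genes-by-samples matrix (unit norm),
#' sign-oriented to correlate positively with the module's mean z-scored
#' profile. Also reports each member gene's correlation with its module
#' eigengene (module membership).
#'
#' @param normalized genes-by-samples matrix
#' @param modules named integer vector gene -> module (0 = unassigned,
#'   skipped)
#' @return list with `eigengenes` (samples x modules matrix, unit-norm
#'   columns) and `membership` (data.frame gene_id, module, correlation)
#' @export
compute_eigengenes <- function(normalized, modules) {
  x <- as.matrix(normalized)
  idx <- sort(unique(modules[modules != 0]))
  eig <- matrix(NA_real_, nrow = ncol(x), ncol = length(idx),
                dimnames = list(colnames(x), paste0("ME", idx)))
  mem <- list()
  for (j in seq_along(idx)) {
    genes <- names(modules)[modules == idx[j]]
    sub <- x[genes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " zero-variance gene(s) from module ",
              idx[j])
      sub <- sub[sds > 0, , drop = FALSE]
      genes <- rownames(sub)
    }
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1L]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    eig[, j] <- e
    mem[[j]] <- data.frame(gene_id = genes, module = idx[j],
                           correlation = apply(sub, 1L, stats::cor, y = e),
                           stringsAsFactors = FALSE)
  }
  membership <- if (length(mem) == 0L) NULL else do.call(rbind, mem)
  if (!is.null(membership)) rownames(membership) <- NULL
  list(eigengenes = eig, membership = membership)
}
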