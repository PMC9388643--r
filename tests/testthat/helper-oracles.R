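# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package implementation.

# quick transcript_set builder
make_ts <- function(..., sequences = NULL) {
  rows <- list(...)
  ex <- do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript_id = r$id, gene_id = r$gene %||% paste0("g.", r$id),
               chrom = r$chrom %||% "chr1",
               start = r$starts, end = r$ends,
               strand = r$strand %||% "+", stringsAsFactors = FALSE)
  }))
  transcript_set(ex, sequences = sequences)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# naive ORF scan: every ATG in every forward frame, walk to the first stop
oracle_orf <- function(seq, require_stop = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (s in seq_len(max(0L, n - 2L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    len <- 0L
    ended <- FALSE
    p <- s
    while (p + 2L <= n) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% stops && p > s) { ended <- TRUE; break }
      if (cod %in% stops && p == s) break
      len <- len + 1L
      p <- p + 3L
    }
    if (!ended && require_stop) next
    if (len == 0L) next
    if (is.null(best) || len > best$len ||
        (len == best$len && s < best$start)) {
      best <- list(start = s, len = len)
    }
  }
  best
}

# base-by-base biotype oracle mirroring the classification rules
oracle_classify <- function(cand, reference, min_frac = 0.1) {
  ref_ex <- reference$exons
  cand_ex <- cand$exons
  ref_genes <- unique(ref_ex$gene_id)
  out <- list()
  for (tid in unique(cand_ex$transcript_id)) {
    tex <- cand_ex[cand_ex$transcript_id == tid, , drop = FALSE]
    tstrand <- tex$strand[1L]
    tchrom <- tex$chrom[1L]
    tbases <- unlist(lapply(seq_len(nrow(tex)), function(i) {
      seq(tex$start[i], tex$end[i] - 1L)
    }))
    labels <- character(0)
    for (g in ref_genes) {
      gex <- ref_ex[ref_ex$gene_id == g & ref_ex$chrom == tchrom, ,
                    drop = FALSE]
      if (nrow(gex) == 0L) next
      for (gs in unique(gex$strand)) {
        gbases <- unique(unlist(lapply(which(gex$strand == gs), function(i) {
          seq(gex$start[i], gex$end[i] - 1L)
        })))
        ov <- length(intersect(tbases, gbases))
        if (ov / length(tbases) >= min_frac && tstrand != "*") {
          labels <- union(labels,
                          if (tstrand == gs) "sense_exonic" else "NAT")
        }
      }
      # intronic: span within one intron of some isoform, no exon contact
      gall <- unique(unlist(lapply(seq_len(nrow(gex)), function(i) {
        seq(gex$start[i], gex$end[i] - 1L)
      })))
      if (length(intersect(tbases, gall)) == 0L) {
        span <- c(min(tex$start), max(tex$end))
        for (iso in unique(gex$transcript_id)) {
          iex <- gex[gex$transcript_id == iso, , drop = FALSE]
          iex <- iex[order(iex$start), , drop = FALSE]
          if (nrow(iex) < 2L) next
          for (k in seq_len(nrow(iex) - 1L)) {
            if (span[1L] >= iex$end[k] && span[2L] <= iex$start[k + 1L]) {
              labels <- union(labels, "intronic")
            }
          }
        }
      }
    }
    if (length(labels) == 0L) labels <- "lincRNA"
    out[[tid]] <- paste(sort(labels), collapse = ",")
  }
  out
}

# literal TOM definition with explicit loops
oracle_tom <- function(adj) {
  n <- nrow(adj)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(adj[i, -i])
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

# upper-tail hypergeometric by direct enumeration of choose() terms
oracle_hyper <- function(k, K, n, N) {
  jmax <- min(K, n)
  sum(vapply(k:jmax, function(j) {
    choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }, numeric(1L)))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  npairs <- choose(length(a), 2)
  expected <- sum_a * sum_b / npairs
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small factor-model expression matrix with planted correlated blocks
simulate_blocks <- function(n_blocks = 2, block_size = 60, n_samples = 60,
                            rho = 0.8, n_background = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  truth <- integer(0)
  for (b in seq_len(n_blocks)) {
    f <- rnorm(n_samples)
    sigma <- sqrt(var(f) * (1 - rho) / rho)
    block <- t(vapply(seq_len(block_size), function(i) {
      f + rnorm(n_samples, 0, sigma)
    }, numeric(n_samples)))
    rows[[b]] <- block
    truth <- c(truth, rep(b, block_size))
  }
  if (n_background > 0) {
    rows[[n_blocks + 1L]] <- matrix(rnorm(n_background * n_samples),
                                    nrow = n_background)
    truth <- c(truth, rep(0L, n_background))
  }
  x <- do.call(rbind, rows)
  rownames(x) <- sprintf("gene%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%03d", seq_len(n_samples))
  list(x = x, truth = stats::setNames(truth, rownames(x)))
}

# a small simulation config that keeps unit tests fast
small_sim_config <- function(seed = 1) {
  simulation_config(seed = seed, n_chroms = 3, chrom_length_bp = 200000,
                    n_coding_genes = 80, n_lincRNA = 4, n_NAT = 3,
                    n_sense_exonic = 2, n_intronic = 3, n_dual = 2,
                    n_tissues = 6, samples_per_tissue = 6,
                    n_modules = 2, module_size = 30, lnc_per_module = 3,
                    n_lc_lncrnas = 2)
}

# the default-world pipeline run shared by the acceptance tests (built once)
.shared <- new.env()
default_run <- function() {
  if (is.null(.shared$run)) {
    .shared$run <- suppressWarnings(run_pipeline(simulation_config(seed = 1)))
  }
  .shared$run
}
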