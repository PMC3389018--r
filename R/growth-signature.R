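#' Correlation of a gene set's average expression with growth rate
#'
#' Averages the set's log2 expression per sample and returns both the
#' Pearson and the Spearman rank correlation with the per-sample maximum
#' specific growth rate.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param genes Non-empty character vector of gene ids present in `expr`.
#' @param mumax Per-sample growth rates, aligned with the columns of `expr`
#'   (or named by sample).
#' @return A list: `pearson`, `spearman`, and `averaged`, a tibble with one
#'   row per sample (`sample`, `avg_expr`, `mu_max`).
#' @export
geneset_correlation <- function(expr, genes, mumax) {
  if (!length(genes)) abort_ferm("gene set is empty", "validation")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    abort_ferm(paste0("genes not in matrix: ", paste(utils::head(missing, 3),
                                                     collapse = ", ")), "key")
  }
  if (!is.null(names(mumax))) mumax <- mumax[colnames(expr)]
  stopifnot(length(mumax) == ncol(expr), ncol(expr) >= 3)
  avg <- colMeans(expr[genes, , drop = FALSE])
  if (stats::sd(avg) == 0 || stats::sd(mumax) == 0) {
    abort_ferm("correlation undefined: constant averaged expression or mu_max",
               "validation")
  }
  list(pearson = stats::cor(avg, mumax),
       spearman = stats::cor(avg, mumax, method = "spearman"),
       averaged = tibble(sample = colnames(expr), avg_expr = unname(avg),
                         mu_max = unname(mumax)))
}

# Sample m distinct-within-row k-subsets of 1..p, rows sorted ascending.
sample_combos <- function(p, k, m) {
  C <- matrix(sample.int(p, m * k, replace = TRUE), m, k)
  repeat {
    C <- t(apply(C, 1, sort.int))
    if (k == 1) break
    bad <- rowSums(C[, -1, drop = FALSE] == C[, -k, drop = FALSE]) > 0
    if (!any(bad)) break
    C[bad, ] <- matrix(sample.int(p, sum(bad) * k, replace = TRUE), sum(bad), k)
  }
  C
}

#' Iterative grouped-gene growth-rate signature discovery
#'
#' Finds a gene set whose *average* expression tracks the maximum specific
#' growth rate, by iterating over growing group sizes: iteration k scores
#' groups of k genes drawn from the current gene pool by the absolute
#' Pearson correlation of their average expression with the per-fermentation
#' growth rate, keeps the `top_n` best-correlated groups, and passes the
#' union of their member genes to the next iteration as the new (smaller)
#' pool with group size k + 1. Genes that matter for the correlation recur
#' in many top groups, so the pool shrinks; the procedure stops as soon as
#' an iteration fails to shrink the pool (the previous pool is the result)
#' or the group size exceeds the pool size.
#'
#' Groups are enumerated exhaustively whenever the number of k-subsets of
#' the pool is at most `max_candidates` (making the result seed-independent
#' there), and by seeded uniform sampling of `max_candidates` distinct
#' k-subsets otherwise.
#'
#' @param expr Log2 expression matrix, genes x samples (>= 5 samples).
#' @param mumax Per-sample growth rates (named by sample or aligned).
#' @param top_n Number of best-correlated groups retained per iteration
#'   (default 300).
#' @param max_candidates Cap on groups evaluated per iteration (default
#'   200000).
#' @param seed Integer seed for the sampling branch.
#' @return A list of class `growth_signature`: `genes` (the final set),
#'   `trace` (one row per iteration: `k`, `n_candidates`, `n_retained`,
#'   `pool_before`, `pool_after`), `pearson`, `spearman` (of the final set's
#'   averaged expression vs growth rate), and `averaged` (per-sample
#'   averaged expression for plotting).
#' @export
iterate_signature <- function(expr, mumax, top_n = 300, max_candidates = 200000,
                              seed = 1L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (!is.null(names(mumax))) mumax <- mumax[colnames(expr)]
  if (length(mumax) != ncol(expr)) {
    abort_ferm("mumax must align with the samples of expr", "validation")
  }
  if (ncol(expr) < 5) abort_ferm("need >= 5 samples", "validation")
  if (nrow(expr) < top_n) {
    abort_ferm("fewer genes than top_n at the start", "validation")
  }
  if (stats::sd(mumax) == 0) {
    abort_ferm("constant mu_max: correlation undefined", "validation")
  }
  set.seed(seed)
  yc <- mumax - mean(mumax)
  ynorm <- sqrt(sum(yc^2))

  pool <- rownames(expr)
  trace <- list()
  k <- 0L
  final <- pool
  repeat {
    k <- k + 1L
    p <- length(pool)
    if (k > p) { final <- pool; break }
    Z <- expr[pool, , drop = FALSE]
    Z <- Z - rowMeans(Z)
    s <- as.vector(Z %*% yc)
    if (k == 1L) {
      den <- sqrt(rowSums(Z^2)) * ynorm
      r <- ifelse(den > 0, s / den, 0)
      keep <- order(-abs(r))[seq_len(min(top_n, p))]
      newpool <- pool[sort.int(keep)]
      n_cand <- p
    } else {
      n_comb <- choose(p, k)
      C <- if (n_comb <= max_candidates) {
        t(utils::combn(p, k))
      } else {
        sample_combos(p, k, max_candidates)
      }
      G <- Z %*% t(Z)
      num <- rowSums(matrix(s[C], nrow(C), k))
      den2 <- numeric(nrow(C))
      for (a in seq_len(k)) for (b in seq_len(k)) {
        den2 <- den2 + G[cbind(C[, a], C[, b])]
      }
      r <- ifelse(den2 > 0, num / (sqrt(den2) * ynorm), 0)
      keep <- order(-abs(r))[seq_len(min(top_n, nrow(C)))]
      newpool <- pool[sort.int(unique(as.vector(C[keep, , drop = FALSE])))]
      n_cand <- nrow(C)
    }
    trace[[k]] <- tibble(k = k, n_candidates = n_cand,
                         n_retained = min(top_n, n_cand),
                         pool_before = p, pool_after = length(newpool))
    if (length(newpool) >= p) { final <- pool; break }
    pool <- newpool
    final <- pool
  }

  gc_res <- geneset_correlation(expr, final, mumax)
  structure(list(genes = final, trace = dplyr::bind_rows(trace),
                 pearson = gc_res$pearson, spearman = gc_res$spearman,
                 averaged = gc_res$averaged,
                 top_n = top_n, seed = seed),
            class = "growth_signature")
}

#' @export
print.growth_signature <- function(x, ...) {
  cat("Growth-rate signature:", length(x$genes), "genes after",
      nrow(x$trace), "iteration(s)\n")
  cat(sprintf("Averaged-expression correlation with mu_max: Pearson %.3f, Spearman %.3f\n",
              x$pearson, x$spearman))
  invisible(x)
}

#' Write the outputs of a growth-signature search
#'
#' Writes the final gene set (TSV), the per-sample averaged expression
#' (TSV, the scatter data), and the iteration trace (JSON).
#'
#' @param sig A `growth_signature`.
#' @param dir Output directory (created if needed).
#' @export
write_signature <- function(sig, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble(gene_id = sig$genes),
                   file.path(dir, "signature_genes.tsv"), progress = FALSE)
  readr::write_tsv(sig$averaged, file.path(dir, "signature_averaged.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(trace = sig$trace, pearson = sig$pearson,
                            spearman = sig$spearman),
                       file.path(dir, "signature_trace.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
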