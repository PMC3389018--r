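#' Parameters for the Bayesian-regularized t-test
#'
#' @param window Odd count of expression-rank neighbours over which the
#'   background variance prior is estimated (default 101).
#' @param lambda Weight of the prior in pseudo-observations (default 10);
#'   `lambda = 0` reduces the test exactly to the ordinary pooled-variance
#'   two-sample t-test.
#' @param fdr_threshold Significance threshold on the BH-adjusted q-value
#'   (default 0.05).
#' @return A list of class `cybert_params`.
#' @export
cybert_params <- function(window = 101L, lambda = 10, fdr_threshold = 0.05) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort_ferm("window must be an odd positive integer", "config")
  }
  if (lambda < 0) abort_ferm("lambda must be >= 0", "config")
  structure(list(window = window, lambda = lambda,
                 fdr_threshold = fdr_threshold), class = "cybert_params")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort_ferm("p-values must lie in [0, 1]", "validation")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Bayesian-regularized two-class differential expression
#'
#' A CyberT-style regularized t-test: per gene, the pooled two-class sample
#' variance is shrunk toward a background variance estimated as the mean
#' pooled variance over a sliding window of genes of similar mean expression.
#' With prior weight `lambda` (in pseudo-observations),
#' `s2_reg = (lambda * s2_bg + (nA + nB - 2) * s2_pooled) / (lambda + nA + nB - 2)`
#' and the statistic is referred to a Student t distribution with
#' `lambda + nA + nB - 2` degrees of freedom (two-sided). Multiple testing is
#' controlled by Benjamini-Hochberg FDR over all genes.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param group_a,group_b Disjoint character vectors of sample (column)
#'   names, each of size >= 2. The reported `ratio` is
#'   `2^(mean_A - mean_B)`, i.e. > 1 when expression is higher in group A.
#' @param params A [cybert_params()].
#' @return A tibble of class `ferm_de`: `gene_id`, `mean_a`, `mean_b`,
#'   `ratio`, `t`, `df`, `p`, `q`, `significant`, in input gene order.
#' @export
cybert_test <- function(expr, group_a, group_b, params = cybert_params()) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (length(intersect(group_a, group_b))) {
    abort_ferm("groups must be disjoint", "validation")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort_ferm("each group needs at least 2 samples", "validation")
  }
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing)) {
    abort_ferm(paste0("samples not in expression matrix: ",
                      paste(missing, collapse = ", ")), "validation")
  }
  xa <- expr[, group_a, drop = FALSE]
  xb <- expr[, group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  pooled <- ((na - 1) * row_vars(xa) + (nb - 1) * row_vars(xb)) / (na + nb - 2)

  bg <- if (params$window >= length(pooled)) {
    # window covers the whole gene list: one shared background variance
    rep(mean(pooled), length(pooled))
  } else {
    ord <- order((mean_a + mean_b) / 2)
    out <- numeric(length(pooled))
    out[ord] <- running_mean(pooled[ord], params$window)
    out
  }

  df <- params$lambda + na + nb - 2
  s2 <- (params$lambda * bg + (na + nb - 2) * pooled) / df
  se <- sqrt(s2 * (1 / na + 1 / nb))
  diff <- mean_a - mean_b
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- 2 * stats::pt(-abs(t), df = df)
  q <- bh_fdr(p)
  out <- tibble(gene_id = rownames(expr), mean_a = unname(mean_a),
                mean_b = unname(mean_b), ratio = unname(2^diff),
                t = unname(t), df = df, p = unname(p), q = unname(q),
                significant = unname(q < params$fdr_threshold))
  attr(out, "groups") <- list(a = group_a, b = group_b)
  attr(out, "params") <- params
  class(out) <- c("ferm_de", class(out))
  out
}

#' Differential expression per fermentation factor
#'
#' Runs [cybert_test()] once per condition factor, contrasting the samples
#' at the high level (group A) against the low level (group B), so that
#' `ratio > 1` always means "higher expression at the high level" (37 degC,
#' 300 mM NaCl, 2.0x amino acids, O2). For pH (three levels) the three
#' pairwise contrasts are returned under names `"pH_5.2_vs_5.8"` etc., with
#' the higher pH as group A.
#'
#' @param expr Log2 expression matrix, genes x samples (sample names =
#'   fermentor ids).
#' @param design A `ferm_table` covering the samples.
#' @param factors Condition factors to test (default all five).
#' @param params A [cybert_params()].
#' @return Named list of `ferm_de` tibbles.
#' @export
de_by_factor <- function(expr, design, factors = ferm_condition_cols,
                         params = cybert_params()) {
  design <- design[match(colnames(expr), design$ferm_id), ]
  out <- list()
  for (f in factors) {
    if (f == "pH") {
      lv <- sort(unique(design$pH))
      for (pair in utils::combn(lv, 2, simplify = FALSE)) {
        a <- design$ferm_id[design$pH == pair[2]]  # higher pH = group A
        b <- design$ferm_id[design$pH == pair[1]]
        out[[paste0("pH_", pair[1], "_vs_", pair[2])]] <-
          cybert_test(expr, a, b, params)
      }
    } else {
      w <- level_weight(f, design[[f]])
      a <- design$ferm_id[w == 1]
      b <- design$ferm_id[w == 0]
      out[[f]] <- cybert_test(expr, a, b, params)
    }
  }
  out
}

#' Write a differential-expression table
#'
#' @param de A `ferm_de` tibble.
#' @param path Output TSV path.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(as_tibble(de), path, progress = FALSE)
  invisible(path)
}
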