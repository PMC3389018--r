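#' Dichotomize a phenotype into low/high classes
#'
#' Median split: values at or below the median become `"low"`, the rest
#' `"high"`. Invariant under monotone transforms of the values. A
#' tertile-extremes split (`rule = "tertile"`) keeps only the lower and
#' upper thirds (middle third becomes `NA`).
#'
#' @param values Numeric vector (>= 4 samples for the median rule).
#' @param rule `"median"` (default) or `"tertile"`.
#' @return Character vector of `"low"`/`"high"` labels (with names preserved).
#' @export
#' @examples
#' dichotomize(c(1, 2, 3, 4))
dichotomize <- function(values, rule = c("median", "tertile")) {
  rule <- match.arg(rule)
  if (length(unique(values[!is.na(values)])) < 2) {
    abort_ferm("all values identical: no low/high split possible", "validation")
  }
  if (rule == "median") {
    if (length(values) < 4) abort_ferm("need >= 4 samples for a median split", "validation")
    med <- stats::median(values, na.rm = TRUE)
    lab <- ifelse(values <= med, "low", "high")
  } else {
    qs <- stats::quantile(values, c(1 / 3, 2 / 3), na.rm = TRUE)
    lab <- ifelse(values <= qs[1], "low", ifelse(values > qs[2], "high", NA))
  }
  if (all(lab[!is.na(lab)] == "low") || all(lab[!is.na(lab)] == "high")) {
    abort_ferm("degenerate split: one class is empty", "validation")
  }
  names(lab) <- names(values)
  lab
}

#' Random-forest gene importances for a dichotomized phenotype
#'
#' Grows a classification forest (Gini criterion, sqrt(p) candidate features
#' per split) predicting the low/high phenotype class from the transcriptome,
#' and ranks genes by mean decrease in Gini impurity. Deterministic given the
#' seed.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param labels `"low"`/`"high"` labels, named by sample or aligned with the
#'   columns of `expr`; samples with `NA` labels are dropped.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed (mandatory).
#' @param phenotype Optional phenotype name recorded as metadata.
#' @return A tibble of class `rf_importance`: `gene_id`, `importance`
#'   (mean decrease Gini), `rank` (1 = most important; ties broken by gene
#'   order).
#' @export
rf_importances <- function(expr, labels, n_trees = 1000, seed, phenotype = NULL) {
  stopifnot(is.matrix(expr))
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  if (length(labels) != ncol(expr)) {
    abort_ferm("labels must align with the samples of expr", "validation")
  }
  keep <- !is.na(labels)
  labels <- factor(labels[keep])
  if (nlevels(labels) < 2) abort_ferm("labels contain a single class", "validation")
  if (any(table(labels) < 2)) abort_ferm("each class needs >= 2 samples", "validation")
  x <- t(expr[, keep, drop = FALSE])
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = labels, ntree = n_trees)
  imp <- rf$importance[, "MeanDecreaseGini"]
  out <- tibble(gene_id = rownames(expr), importance = unname(imp[rownames(expr)]),
                rank = rank(-unname(imp[rownames(expr)]), ties.method = "first"))
  attr(out, "phenotype") <- phenotype
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  class(out) <- c("rf_importance", class(out))
  out
}

#' Overlap of the top-k genes of two importance rankings
#'
#' @param rank_a,rank_b `rf_importance` tibbles over the same gene universe.
#' @param k Top-list size.
#' @return Character vector: the intersection of the two top-k gene sets.
#' @export
top_overlap <- function(rank_a, rank_b, k = 10) {
  if (!setequal(rank_a$gene_id, rank_b$gene_id)) {
    abort_ferm("rankings cover different gene universes", "validation")
  }
  if (k > nrow(rank_a)) abort_ferm("k exceeds the number of genes", "validation")
  intersect(rank_a$gene_id[rank_a$rank <= k], rank_b$gene_id[rank_b$rank <= k])
}

#' Cross-contrast significance and direction concordance
#'
#' Counts the genes significant in both of two differential-expression
#' contrasts, and among those, how many change in the same direction
#' (expression ratios deviating from 1 with the same sign).
#'
#' @param de_a,de_b `ferm_de` tibbles over the same gene universe.
#' @return A list: `n_both_significant`, `n_same_direction`.
#' @export
concordance <- function(de_a, de_b) {
  if (!setequal(de_a$gene_id, de_b$gene_id)) {
    abort_ferm("DE tables cover different gene universes", "validation")
  }
  b <- de_b[match(de_a$gene_id, de_b$gene_id), ]
  both <- de_a$significant & b$significant
  da <- sign(log2(de_a$ratio)); db <- sign(log2(b$ratio))
  same <- both & da != 0 & da == db
  list(n_both_significant = sum(both), n_same_direction = sum(same))
}
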