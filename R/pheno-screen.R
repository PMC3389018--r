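#' Mann-Whitney U test with exact or tie-corrected approximate p
#'
#' Two-sided Mann-Whitney U test. In `"auto"` mode the p-value comes from
#' exact enumeration of the U distribution when the combined sample size is
#' at most 12 and the data are tie-free, and from the tie-corrected normal
#' approximation (with continuity correction) otherwise. The reported U is
#' the U statistic of group A.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return One-row tibble: `u` (U of group A), `p` (two-sided), `direction`
#'   (`"+"` if group B has the higher median, `"-"` if group A does,
#'   `NA` when the medians tie) and `method`.
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))
mwu_test <- function(values_a, values_b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(values_a) || !length(values_b)) {
    abort_ferm("both groups must be non-empty", "validation")
  }
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- switch(mode,
                  exact = TRUE,
                  approx = FALSE,
                  auto = n <= 12 && !ties)
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  med_a <- stats::median(values_a); med_b <- stats::median(values_b)
  direction <- if (med_a == med_b) NA_character_ else if (med_b > med_a) "+" else "-"
  tibble(u = unname(wt$statistic), p = wt$p.value, direction = direction,
         method = if (exact && !ties) "exact" else "normal_approx")
}

# The comparisons of the screen: one per two-level factor plus the three pH
# level pairs. Group A is the lower level, group B the higher, so "+" means
# the phenotype is higher at the higher level.
screen_comparisons <- function(design) {
  cmp <- list()
  for (f in setdiff(ferm_condition_cols, "pH")) {
    lv <- default_factor_levels()[[f]]
    cmp[[f]] <- list(factor = f, low = lv[1], high = lv[2], label = f)
  }
  lv <- sort(unique(design$pH))
  for (pair in utils::combn(lv, 2, simplify = FALSE)) {
    lab <- paste0("pH_", pair[1], "_vs_", pair[2])
    cmp[[lab]] <- list(factor = "pH", low = pair[1], high = pair[2], label = lab)
  }
  cmp
}

#' Mann-Whitney U screen of factors against phenotypes
#'
#' Correlates every fermentation factor with every physiological phenotype
#' present in the study table: one two-sided Mann-Whitney U test per
#' (comparison x phenotype) cell, with one comparison per two-level factor
#' and all three level pairs for pH. q-values are Benjamini-Hochberg
#' adjusted across the whole screen (all cells as one family).
#'
#' @param table A `ferm_table` with phenotype columns.
#' @param include_f30 Keep fermentors lacking an in-growth transcriptome
#'   sample (the `transcriptome = FALSE` flag) in this phenotype-only screen
#'   (default `TRUE`; they carry valid phenotypes).
#' @param phenotypes Phenotype columns to screen (default: all present).
#' @param mode Passed to [mwu_test()].
#' @return A tibble of class `pheno_screen` (long format): `comparison`,
#'   `phenotype`, `n_low`, `n_high`, `u`, `p`, `q`, `direction`.
#' @export
phenotype_screen <- function(table, include_f30 = TRUE, phenotypes = NULL,
                             mode = "auto") {
  tab <- as_tibble(table)
  if (!include_f30 && "transcriptome" %in% names(tab)) {
    tab <- tab[tab$transcriptome, ]
  }
  if (is.null(phenotypes)) {
    phenotypes <- intersect(ferm_phenotype_cols(), names(tab))
    phenotypes <- phenotypes[vapply(phenotypes,
                                    function(p) any(!is.na(tab[[p]])), logical(1))]
  }
  cmp <- screen_comparisons(tab)
  rows <- list()
  for (cm in cmp) {
    lo <- tab[!is.na(tab[[cm$factor]]) & tab[[cm$factor]] == cm$low, ]
    hi <- tab[!is.na(tab[[cm$factor]]) & tab[[cm$factor]] == cm$high, ]
    if (nrow(lo) < 2 || nrow(hi) < 2) {
      warn(paste0("comparison '", cm$label, "' has fewer than 2 records per ",
                  "level; skipped"))
      next
    }
    for (ph in phenotypes) {
      a <- lo[[ph]][!is.na(lo[[ph]])]
      b <- hi[[ph]][!is.na(hi[[ph]])]
      if (!length(a) || !length(b)) next
      res <- mwu_test(a, b, mode = mode)
      rows[[length(rows) + 1L]] <-
        dplyr::bind_cols(tibble(comparison = cm$label, phenotype = ph,
                                n_low = length(a), n_high = length(b)), res)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  out <- out[, c("comparison", "phenotype", "n_low", "n_high", "u", "p", "q",
                 "direction", "method")]
  class(out) <- c("pheno_screen", class(out))
  out
}

#' Wide grid view of a phenotype screen
#'
#' @param screen A `pheno_screen`.
#' @param digits Significant digits in the formatted cells.
#' @return A tibble, comparisons as rows and phenotypes as columns, each cell
#'   `"p|q|direction"`.
#' @export
screen_grid <- function(screen, digits = 3) {
  x <- as_tibble(screen)
  x$cell <- paste(signif(x$p, digits), signif(x$q, digits),
                  ifelse(is.na(x$direction), ".", x$direction), sep = "|")
  tidyr::pivot_wider(x[, c("comparison", "phenotype", "cell")],
                     names_from = "phenotype", values_from = "cell")
}
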