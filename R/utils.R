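#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Condition factors of the fermentation design, in canonical column order.
ferm_condition_cols <- c("nacl_mM", "aa_factor", "temperature_C", "pH", "aeration")

# Organic-acid phenotypes quantified at the fermentation endpoint (mM).
ferm_acid_cols <- c("lactate", "pyruvate", "acetate", "citrate", "succinate", "formate")

ferm_phenotype_cols <- function() c("od_max", "mu_max", ferm_acid_cols)

# Declared level sets. Levels are categorical codes and compared as exact
# printed values, never with floating tolerances.
default_factor_levels <- function() {
  list(
    nacl_mM       = c(0, 300),
    aa_factor     = c(1.1, 2.0),
    temperature_C = c(28, 37),
    pH            = c(5.2, 5.8, 6.4),
    aeration      = c("N2", "O2")
  )
}

abort_ferm <- function(msg, class) {
  abort(msg, class = c(paste0("fermgenomics_error_", class), "fermgenomics_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a packaged example data file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' ferm_example()
#' ferm_example("table1_fermentations.tsv")
ferm_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fermgenomics")))
  }
  path <- system.file("extdata", file, package = "fermgenomics")
  if (!nzchar(path)) abort_ferm(paste0("no packaged file '", file, "'"), "key")
  path
}

#' Read and write a log2 expression matrix
#'
#' Expression matrices are stored as tab-delimited text with genes as rows
#' (first column `gene_id`) and samples as columns, values on the log2 scale.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns a numeric matrix with gene-id
#'   rownames; `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(tab)) {
    abort_ferm("expression matrix file must have a 'gene_id' first column", "format")
  }
  m <- as.matrix(tab[setdiff(names(tab), "gene_id")])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "double"
  m
}

#' @param expr A numeric matrix, genes as rows with rownames, samples as columns.
#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  tab <- dplyr::bind_cols(tibble(gene_id = rownames(expr)), as_tibble(expr))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

# Running mean of v with a centred window of width w (odd), clipped at the
# edges; O(n) via cumulative sums.
running_mean <- function(v, w) {
  n <- length(v)
  h <- (w - 1) %/% 2
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Row variances of a matrix (unbiased), without extra dependencies.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}
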