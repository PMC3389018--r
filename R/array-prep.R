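#' Read a two-channel probe table
#'
#' Probe tables are tab-delimited with fixed columns `array_id`, `probe_id`,
#' `gene_id`, `cy5`, `cy3` (linear intensities, both positive); each probe
#' maps to exactly one gene and `(array_id, probe_id)` is unique.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_probe_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("array_id", "probe_id", "gene_id", "cy5", "cy3")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort_ferm(paste0("probe table missing column(s): ",
                      paste(missing, collapse = ", ")), "format")
  }
  validate_probe_table(tab)
  tab
}

validate_probe_table <- function(tab) {
  if (anyDuplicated(paste(tab$array_id, tab$probe_id, sep = "\r"))) {
    abort_ferm("(array_id, probe_id) pairs must be unique", "validation")
  }
  map <- unique(tab[, c("probe_id", "gene_id")])
  if (anyDuplicated(map$probe_id)) {
    abort_ferm("every probe must map to exactly one gene", "validation")
  }
  if (any(tab$cy5 <= 0 | tab$cy3 <= 0, na.rm = TRUE)) {
    abort_ferm("intensities must be positive", "validation")
  }
  invisible(tab)
}

#' Intensity-dependent (lowess) normalization of a two-channel array
#'
#' Removes the intensity-dependent dye bias of each array: the log-ratio
#' M = log2(cy5/cy3) is detrended against the mean log-intensity
#' A = (log2 cy5 + log2 cy3)/2 by subtracting a lowess fit (tricube weights,
#' robustness iterations), and the correction is split symmetrically between
#' the channels so each probe's average intensity A is preserved exactly.
#' A constant channel bias (cy5 = c * cy3) is removed completely.
#'
#' @param probes Probe tibble (columns `array_id`, `probe_id`, `gene_id`,
#'   `cy5`, `cy3`); multiple arrays are normalized independently.
#' @param frac Lowess smoother span (default 0.4).
#' @param iter Robustness iterations (default 3).
#' @return The tibble with columns `a` (mean log2 intensity), `m` (normalized
#'   log ratio), `cy5_norm`, `cy3_norm` (normalized linear intensities) and
#'   `intensity` (normalized absolute log2 level, equal to `a`).
#' @export
lowess_normalize <- function(probes, frac = 0.4, iter = 3) {
  validate_probe_table(probes)
  parts <- split(probes, probes$array_id)
  out <- lapply(parts, function(p) {
    if (nrow(p) < 20) {
      abort_ferm(paste0("array ", p$array_id[1], " has fewer than 20 probes"),
                 "validation")
    }
    a <- (log2(p$cy5) + log2(p$cy3)) / 2
    m <- log2(p$cy5) - log2(p$cy3)
    fit <- stats::lowess(a, m, f = frac, iter = iter)
    trend <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
    m_norm <- m - trend
    p$a <- a
    p$m <- m_norm
    p$cy5_norm <- 2^(a + m_norm / 2)
    p$cy3_norm <- 2^(a - m_norm / 2)
    p$intensity <- a
    p
  })
  res <- dplyr::bind_rows(out)
  # restore original row order
  key <- paste(probes$array_id, probes$probe_id, sep = "\r")
  res[match(key, paste(res$array_id, res$probe_id, sep = "\r")), ]
}

#' Inter-slide intensity scaling
#'
#' Corrects for inter-slide differences on the basis of the total signal per
#' slide: each array's linear intensities are multiplied by one scalar so
#' that every array reaches the same total signal, the geometric mean of the
#' observed totals.
#'
#' @param probes Normalized probe tibble covering >= 2 arrays (a single array
#'   is returned unchanged with a warning). Channel columns `cy5_norm` and
#'   `cy3_norm` are scaled when present, otherwise `cy5`/`cy3`.
#' @return The rescaled tibble, with `a`/`intensity` recomputed when present;
#'   an attribute `scale_factors` carries the per-array scalars.
#' @export
interslide_scale <- function(probes) {
  if (nrow(probes) == 0) abort_ferm("empty probe table", "validation")
  chans <- if (all(c("cy5_norm", "cy3_norm") %in% names(probes))) {
    c("cy5_norm", "cy3_norm")
  } else c("cy5", "cy3")
  arrays <- unique(probes$array_id)
  if (length(arrays) < 2) {
    warn("single array: inter-slide scaling is a no-op")
    attr(probes, "scale_factors") <- stats::setNames(1, arrays)
    return(probes)
  }
  totals <- vapply(arrays, function(a) {
    sel <- probes$array_id == a
    if (!any(sel)) abort_ferm("empty array", "validation")
    sum(probes[[chans[1]]][sel] + probes[[chans[2]]][sel])
  }, numeric(1))
  target <- exp(mean(log(totals)))
  scale <- target / totals
  sc <- scale[match(probes$array_id, arrays)]
  for (ch in chans) probes[[ch]] <- probes[[ch]] * sc
  if (all(c("a", "m") %in% names(probes))) {
    probes$a <- probes$a + log2(sc)
    probes$intensity <- probes$a
  }
  attr(probes, "scale_factors") <- stats::setNames(scale, arrays)
  probes
}

#' Collapse probes to gene expression levels
#'
#' The gene expression level of a gene on an array is the median intensity
#' over that gene's probes (for an even probe count, the mean of the two
#' middle values). Genes with no probe on some array get `NA` there, with a
#' message.
#'
#' @param probes Probe tibble with a per-probe log2 `intensity` column (as
#'   produced by [lowess_normalize()]); alternatively name the column with
#'   `value`.
#' @param value Name of the per-probe value column (default `"intensity"`).
#' @return A log2 expression matrix, genes x arrays.
#' @export
collapse_probes <- function(probes, value = "intensity") {
  if (!value %in% names(probes)) {
    abort_ferm(paste0("no '", value, "' column; run lowess_normalize() first ",
                      "or name the value column"), "format")
  }
  genes <- unique(probes$gene_id)
  arrays <- unique(probes$array_id)
  med <- tapply(probes[[value]],
                list(factor(probes$gene_id, levels = genes),
                     factor(probes$array_id, levels = arrays)),
                stats::median)
  m <- matrix(med, length(genes), length(arrays),
              dimnames = list(genes, arrays))
  if (anyNA(m)) {
    inform(paste0(sum(is.na(m)), " gene/array cell(s) had no probes; set to NA"))
  }
  m
}
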