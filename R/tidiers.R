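#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summary methods for fermentation-genomics results
#'
#' broom-style accessors: `tidy()` returns the per-item table of a result,
#' `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Ignored.
#' @name ferm-tidiers
NULL

#' @rdname ferm-tidiers
#' @method tidy growth_signature
#' @export
tidy.growth_signature <- function(x, ...) x$trace

#' @rdname ferm-tidiers
#' @method glance growth_signature
#' @export
glance.growth_signature <- function(x, ...) {
  tibble(n_genes = length(x$genes), iterations = nrow(x$trace),
         pearson = x$pearson, spearman = x$spearman)
}

#' @rdname ferm-tidiers
#' @method glance ferm_de
#' @export
glance.ferm_de <- function(x, ...) {
  tibble(n_genes = nrow(x), n_significant = sum(x$significant),
         n_up = sum(x$significant & x$ratio > 1),
         n_down = sum(x$significant & x$ratio < 1))
}

#' @rdname ferm-tidiers
#' @method glance pheno_screen
#' @export
glance.pheno_screen <- function(x, ...) {
  tibble(n_cells = nrow(x), n_p_significant = sum(x$p < 0.05),
         n_q_significant = sum(x$q < 0.05))
}

#' @rdname ferm-tidiers
#' @method tidy motif_set
#' @export
tidy.motif_set <- function(x, ...) {
  if (!length(x)) {
    return(tibble(consensus = character(), arm = character(),
                  arm_len = integer(), spacer_len = integer(),
                  k_fg = integer(), n_fg = integer(), k_bg = integer(),
                  n_bg = integer(), p_value = numeric(), q_value = numeric()))
  }
  purrr::map_dfr(x, function(m) {
    tibble(consensus = m$consensus, arm = m$arm, arm_len = m$arm_len,
           spacer_len = m$spacer_len, k_fg = m$k_fg, n_fg = m$n_fg,
           k_bg = m$k_bg, n_bg = m$n_bg, p_value = m$p_value,
           q_value = m$q_value)
  })
}

#' @rdname ferm-tidiers
#' @method tidy balance_report
#' @export
tidy.balance_report <- function(x, ...) x$levels

#' @rdname ferm-tidiers
#' @method tidy sim_truth
#' @export
tidy.sim_truth <- function(x, ...) {
  ts <- truth_sets(x)
  tibble(structure = names(ts), n_genes = lengths(ts))
}

#' Plot methods for fermentation-genomics results
#'
#' `autoplot()` renders the canonical figure of each result type: a volcano
#' plot for differential expression, a p-value grid for the phenotype
#' screen, the averaged-expression vs growth-rate scatter for a growth
#' signature, and the per-column information-content profile for a motif.
#'
#' @param object A result object.
#' @param ... Ignored.
#' @return A ggplot.
#' @name ferm-autoplot
NULL

#' @rdname ferm-autoplot
#' @method autoplot ferm_de
#' @export
autoplot.ferm_de <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$ratio), y = -log10(.data$p),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 expression ratio (A vs B)", y = "-log10 p",
                  colour = "q < threshold") +
    ggplot2::theme_minimal()
}

#' @rdname ferm-autoplot
#' @method autoplot pheno_screen
#' @export
autoplot.pheno_screen <- function(object, ...) {
  d <- as_tibble(object)
  d$label <- ifelse(d$p < 0.05, ifelse(is.na(d$direction), "*", d$direction), "")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phenotype, y = .data$comparison,
                                  fill = -log10(.data$p))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 4) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname ferm-autoplot
#' @method autoplot growth_signature
#' @export
autoplot.growth_signature <- function(object, ...) {
  ggplot2::ggplot(object$averaged,
                  ggplot2::aes(x = .data$mu_max, y = .data$avg_expr)) +
    ggplot2::geom_point(shape = 18, size = 3, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = expression(mu[max] ~ (h^-1)),
                  y = "mean log2 expression of signature genes",
                  title = sprintf("%d genes, Pearson r = %.2f, Spearman rho = %.2f",
                                  length(object$genes), object$pearson,
                                  object$spearman)) +
    ggplot2::theme_minimal()
}

#' @rdname ferm-autoplot
#' @method autoplot motif_model
#' @export
autoplot.motif_model <- function(object, ...) {
  d <- tibble(position = seq_along(object$ic), bits = object$ic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$bits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = d$position,
                                labels = strsplit(object$consensus, "")[[1]]) +
    ggplot2::labs(x = paste0("consensus: ", object$consensus),
                  y = "information content (bits)",
                  title = sprintf("Inverted repeat, %d/%d foreground promoters, p = %.2g",
                                  object$k_fg, object$n_fg, object$p_value)) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
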