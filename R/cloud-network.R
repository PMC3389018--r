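#' Build per-factor response clouds
#'
#' A gene belongs to a factor's response cloud when its expression change
#' between the factor's levels is both statistically significant
#' (`q < q_max`) and large enough (`max(ratio, 1/ratio) > fold_min`);
#' direction is `"up"` when expression is higher at the high level
#' (ratio > 1 with the [de_by_factor()] convention).
#'
#' @param de_by_factor Named list of `ferm_de` tibbles (one per factor) over
#'   a shared gene universe.
#' @param q_max FDR threshold (default 0.05).
#' @param fold_min Fold-change threshold (> 1; default 1.5).
#' @return A named list of class `response_clouds`: per factor a tibble
#'   `gene_id`, `direction` (`"up"`/`"down"`), `ratio`, `q`. Thresholds are
#'   carried as attributes.
#' @export
build_clouds <- function(de_by_factor, q_max = 0.05, fold_min = 1.5) {
  if (fold_min < 1) abort_ferm("fold_min must be >= 1", "config")
  stopifnot(is.list(de_by_factor), length(de_by_factor) > 0)
  uni <- de_by_factor[[1]]$gene_id
  clouds <- lapply(de_by_factor, function(de) {
    if (!setequal(de$gene_id, uni)) {
      abort_ferm("DE results do not share a gene universe", "validation")
    }
    sel <- de$q < q_max & pmax(de$ratio, 1 / de$ratio) > fold_min
    tibble(gene_id = de$gene_id[sel],
           direction = ifelse(de$ratio[sel] > 1, "up", "down"),
           ratio = de$ratio[sel], q = de$q[sel])
  })
  structure(clouds, class = "response_clouds",
            q_max = q_max, fold_min = fold_min, universe = uni)
}

#' Collapse the three pH contrasts into one pH response cloud
#'
#' A gene is pH-responsive when it passes the thresholds in *any* of the
#' three pairwise pH contrasts; its direction (and reported ratio/q) is
#' taken from the widest contrast, pH 5.2 vs 6.4.
#'
#' @param de_52_58,de_52_64,de_58_64 `ferm_de` tibbles for the pairwise pH
#'   contrasts (higher pH as group A).
#' @inheritParams build_clouds
#' @return A single cloud tibble (`gene_id`, `direction`, `ratio`, `q`).
#' @export
ph_cloud <- function(de_52_58, de_52_64, de_58_64, q_max = 0.05, fold_min = 1.5) {
  if (fold_min < 1) abort_ferm("fold_min must be >= 1", "config")
  pass <- function(de) de$q < q_max & pmax(de$ratio, 1 / de$ratio) > fold_min
  any_pass <- pass(de_52_58) |
    pass(de_52_64)[match(de_52_58$gene_id, de_52_64$gene_id)] |
    pass(de_58_64)[match(de_52_58$gene_id, de_58_64$gene_id)]
  ref <- de_52_64[match(de_52_58$gene_id, de_52_64$gene_id), ]
  tibble(gene_id = de_52_58$gene_id[any_pass],
         direction = ifelse(ref$ratio[any_pass] > 1, "up", "down"),
         ratio = ref$ratio[any_pass], q = ref$q[any_pass])
}

#' Partition cloud genes by their response signature
#'
#' Every gene belonging to at least one response cloud is assigned to
#' exactly one group: the set of factors whose clouds contain it (its
#' "single or shared response" signature). The groups partition the cloud
#' members.
#'
#' @param clouds A `response_clouds` list (or named list of cloud tibbles).
#' @return A list with `membership` (tibble `gene_id`, `signature`, factors
#'   joined by `"+"`) and `groups` (tibble `signature`, `n`, `genes`
#'   list-column, ordered by decreasing size).
#' @export
partition_by_signature <- function(clouds) {
  mem <- purrr::map_dfr(names(clouds), function(f) {
    tibble(gene_id = clouds[[f]]$gene_id, factor = f)
  })
  if (nrow(mem) == 0) {
    return(list(membership = tibble(gene_id = character(), signature = character()),
                groups = tibble(signature = character(), n = integer(),
                                genes = list())))
  }
  membership <- mem %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(signature = paste(sort(unique(.data$factor)), collapse = "+"),
                     .groups = "drop")
  groups <- membership %>%
    dplyr::group_by(.data$signature) %>%
    dplyr::summarise(n = dplyr::n(), genes = list(.data$gene_id), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$n))
  list(membership = membership, groups = groups)
}

#' Build the condition-response regulatory network
#'
#' Bipartite graph linking fermentation factors to the genes whose
#' expression they significantly alter: one edge per (factor, cloud gene)
#' with a `direction` attribute, gene vertices annotated with their response
#' signature group.
#'
#' @param clouds A `response_clouds` list.
#' @return An `igraph` graph with vertex attributes `type`
#'   (`"factor"`/`"gene"`) and `group`, and edge attribute `direction`.
#' @export
network_from_clouds <- function(clouds) {
  edges <- purrr::map_dfr(names(clouds), function(f) {
    cl <- clouds[[f]]
    if (nrow(cl) == 0) return(tibble())
    tibble(from = f, to = cl$gene_id, direction = cl$direction)
  })
  if (nrow(edges) == 0) abort_ferm("all clouds are empty: nothing to build", "validation")
  part <- partition_by_signature(clouds)
  factors <- unique(edges$from)
  genes <- unique(edges$to)
  verts <- tibble(name = c(factors, genes),
                  type = c(rep("factor", length(factors)),
                           rep("gene", length(genes))),
                  group = c(rep(NA_character_, length(factors)),
                            part$membership$signature[
                              match(genes, part$membership$gene_id)]))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export a regulatory network for Cytoscape
#'
#' SIF uses the relations `responds_up`/`responds_down`; GraphML carries the
#' `direction` edge attribute and the `group`/`type` vertex attributes.
#' Re-importing either format reproduces the node and edge multisets.
#'
#' @param network An `igraph` graph from [network_from_clouds()].
#' @param format `"sif"` or `"graphml"`.
#' @param path Output file path.
#' @export
export_network <- function(network, format = c("sif", "graphml"), path) {
  format <- match.arg(format)
  if (igraph::ecount(network) == 0) {
    abort_ferm("empty network: nothing to export", "validation")
  }
  if (format == "sif") {
    el <- igraph::as_data_frame(network, what = "edges")
    lines <- paste(el$from,
                   ifelse(el$direction == "up", "responds_up", "responds_down"),
                   el$to, sep = "\t")
    writeLines(lines, path)
  } else {
    igraph::write_graph(network, path, format = "graphml")
  }
  invisible(path)
}

#' @param format `"sif"` or `"graphml"`.
#' @rdname export_network
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    el <- tibble(from = vapply(parts, `[`, "", 1),
                 direction = ifelse(vapply(parts, `[`, "", 2) == "responds_up",
                                    "up", "down"),
                 to = vapply(parts, `[`, "", 3))
    igraph::graph_from_data_frame(el[, c("from", "to", "direction")],
                                  directed = TRUE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}

#' Hypergeometric functional-class overrepresentation
#'
#' For each functional class, tests whether the gene set contains more class
#' members than expected from the universe: upper-tail hypergeometric
#' p = P\[X >= k\] with N = |universe|, K = class size in the universe and
#' n = |gene set|; q-values are BH-adjusted across classes.
#'
#' @param geneset Character vector, a subset of `universe`.
#' @param classification Tibble/data frame with columns `gene_id`, `class`
#'   (a flat gene -> class map; a gene may carry several classes).
#' @param universe Character vector of all genes considered.
#' @return Tibble, one row per class: `class`, `n_class`, `overlap`, `p`,
#'   `q`, ordered by `p`.
#' @export
enrichment <- function(geneset, classification, universe) {
  bad <- setdiff(geneset, universe)
  if (length(bad)) {
    abort_ferm(paste0("gene set is not a subset of the universe (e.g. ",
                      bad[1], ")"), "validation")
  }
  cls <- classification[classification$gene_id %in% universe, ]
  if (nrow(cls) == 0) abort_ferm("classification covers no universe gene", "validation")
  N <- length(unique(universe))
  n <- length(unique(geneset))
  out <- cls %>%
    dplyr::group_by(class = .data$class) %>%
    dplyr::summarise(n_class = dplyr::n_distinct(.data$gene_id),
                     overlap = dplyr::n_distinct(intersect(.data$gene_id, geneset)),
                     .groups = "drop")
  out$p <- stats::phyper(out$overlap - 1, out$n_class, N - out$n_class, n,
                         lower.tail = FALSE)
  out$q <- bh_fdr(out$p)
  dplyr::arrange(out, .data$p)
}
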