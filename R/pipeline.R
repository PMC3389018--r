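#' Pipeline project configuration
#'
#' A declarative configuration for the file-based project store: where
#' outputs live, the global seed driving every stochastic stage, the stage
#' list, and per-stage parameter overrides. May be read from a YAML file.
#'
#' @param out_dir Project directory (created on first run).
#' @param seed Global integer seed; every stochastic stage derives its
#'   randomness from it.
#' @param stages Character vector of stages to run, from: `"simulate"`,
#'   `"prep"`, `"de"`, `"screen"`, `"rf"`, `"signature"`, `"network"`,
#'   `"enrich"`, `"motif"`, `"recovery"`.
#' @param params Named list of per-stage parameter lists (e.g.
#'   `list(simulate = list(n_genes = 500), signature = list(top_n = 100))`).
#' @param yaml Optional path to a YAML file supplying any of the above
#'   fields (explicit arguments win).
#' @return A list of class `project_config`.
#' @export
project_config <- function(out_dir = NULL, seed = 1L,
                           stages = c("simulate", "de", "screen", "rf",
                                      "signature", "network", "enrich",
                                      "motif", "recovery"),
                           params = list(), yaml = NULL) {
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    out_dir <- out_dir %||% y$out_dir
    if (missing(seed) && !is.null(y$seed)) seed <- y$seed
    if (missing(stages) && !is.null(y$stages)) stages <- y$stages
    if (!length(params) && !is.null(y$params)) params <- y$params
  }
  if (is.null(out_dir)) abort_ferm("out_dir is required", "config")
  known <- c("simulate", "prep", "de", "screen", "rf", "signature",
             "network", "enrich", "motif", "recovery")
  bad <- setdiff(stages, known)
  if (length(bad)) abort_ferm(paste0("unknown stage: ", bad[1]), "config")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, params = params),
            class = "project_config")
}

# file -> producing stage, for dependency errors and checksum verification
stage_outputs <- function() {
  list(simulate = c("design.tsv", "expr.tsv", "promoters.fasta", "truth.json",
                    "classification.tsv"),
       prep = "expr_from_probes.tsv",
       de = paste0("de_", de_factor_names(), ".tsv"),
       screen = "screen.tsv",
       rf = c("rf_citrate.tsv", "rf_succinate.tsv", "rf_shared_top10.tsv"),
       signature = c("signature_genes.tsv", "signature_averaged.tsv",
                     "signature_trace.json"),
       network = c("network.sif", "network.graphml", "response_groups.tsv",
                   "clouds.tsv"),
       enrich = "enrichment_aeration.tsv",
       motif = "motifs.tsv",
       recovery = "recovery.tsv")
}

require_input <- function(config, file, needed_by) {
  path <- file.path(config$out_dir, file)
  if (!file.exists(path)) {
    provider <- NULL
    for (st in names(stage_outputs())) {
      if (file %in% stage_outputs()[[st]]) provider <- st
    }
    abort_ferm(paste0("stage '", needed_by, "' needs '", file, "'",
                      if (!is.null(provider)) paste0(" produced by stage '",
                                                     provider, "'"),
                      "; run that stage first"), "dependency")
  }
  # verify against the checksum recorded by the producing manifest, if any
  for (mf in Sys.glob(file.path(config$out_dir, "manifest_*.json"))) {
    man <- jsonlite::read_json(mf)
    if (!is.null(man$outputs[[file]])) {
      now <- unname(tools::md5sum(path))
      if (!identical(now, man$outputs[[file]])) {
        abort_ferm(paste0("checksum mismatch for '", file,
                          "': file changed since it was produced"), "validation")
      }
    }
  }
  path
}

write_manifest <- function(config, stage, inputs, outputs, params) {
  man <- list(stage = stage, seed = config$seed, params = params,
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)))
  names(man$inputs) <- basename(inputs)
  names(man$outputs) <- basename(outputs)
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

de_factor_names <- function() {
  c("nacl_mM", "aa_factor", "temperature_C", "aeration",
    "pH_5.2_vs_5.8", "pH_5.2_vs_6.4", "pH_5.8_vs_6.4")
}

read_de_tables <- function(config, needed_by) {
  out <- list()
  for (nm in de_factor_names()) {
    path <- require_input(config, paste0("de_", nm, ".tsv"), needed_by)
    de <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    class(de) <- c("ferm_de", class(de))
    out[[nm]] <- de
  }
  out
}

clouds_from_de <- function(des, q_max = 0.05, fold_min = 1.5) {
  two_level <- des[c("nacl_mM", "aa_factor", "temperature_C", "aeration")]
  clouds <- build_clouds(two_level, q_max = q_max, fold_min = fold_min)
  clouds$pH <- ph_cloud(des$pH_5.2_vs_5.8, des$pH_5.2_vs_6.4,
                        des$pH_5.8_vs_6.4, q_max = q_max, fold_min = fold_min)
  clouds
}

#' Run one pipeline stage
#'
#' Executes a named stage against the project store: inputs are located (and
#' their checksums verified against the manifests of the producing stages),
#' outputs are written atomically, and a JSON manifest recording parameters,
#' seed and input/output checksums is dropped next to them.
#'
#' @param config A [project_config()].
#' @param stage Stage name.
#' @return Invisibly, the paths written.
#' @export
run_stage <- function(config, stage) {
  stopifnot(inherits(config, "project_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  pars <- config$params[[stage]] %||% list()
  t0 <- Sys.time()
  inputs <- character()
  outputs <- character()
  p <- function(f) file.path(od, f)

  if (stage == "simulate") {
    cfg <- do.call(sim_config, c(list(seed = config$seed), pars))
    sim <- simulate_study(cfg)
    write_fermentation_table(sim$design, p("design.tsv"))
    write_expression_matrix(sim$expr, p("expr.tsv"))
    if (!is.null(sim$promoters)) write_promoters(sim$promoters, p("promoters.fasta"))
    if (!is.null(sim$probes)) readr::write_tsv(sim$probes, p("probes.tsv"),
                                               progress = FALSE)
    jsonlite::write_json(c(truth_sets(sim$truth),
                           list(universe = sim$truth$universe,
                                samples = sim$truth$samples)),
                         p("truth.json"), auto_unbox = FALSE, digits = NA)
    # functional classification: planted structures as classes, the rest
    # spread over generic classes
    set.seed(config$seed + 17L)
    cls <- tibble(gene_id = sim$truth$universe,
                  class = paste0("C", sample.int(10, length(sim$truth$universe),
                                                 replace = TRUE)))
    for (nm in names(truth_sets(sim$truth))) {
      if (nm == "motif_promoters") next
      cls$class[cls$gene_id %in% truth_sets(sim$truth)[[nm]]] <- nm
    }
    readr::write_tsv(cls, p("classification.tsv"), progress = FALSE)
    outputs <- p(c("design.tsv", "expr.tsv", "truth.json", "classification.tsv"))
    if (!is.null(sim$promoters)) outputs <- c(outputs, p("promoters.fasta"))
    if (!is.null(sim$probes)) outputs <- c(outputs, p("probes.tsv"))
  } else if (stage == "prep") {
    inputs <- require_input(config, "probes.tsv", stage)
    probes <- readr::read_tsv(inputs, show_col_types = FALSE, progress = FALSE)
    norm <- interslide_scale(lowess_normalize(probes))
    expr <- collapse_probes(norm)
    write_expression_matrix(expr, p("expr_from_probes.tsv"))
    outputs <- p("expr_from_probes.tsv")
  } else if (stage == "de") {
    inputs <- c(require_input(config, "expr.tsv", stage),
                require_input(config, "design.tsv", stage))
    expr <- read_expression_matrix(inputs[1])
    design <- load_fermentation_table(inputs[2], strict = FALSE)
    des <- do.call(de_by_factor, c(list(expr = expr, design = design), pars))
    outputs <- vapply(names(des), function(nm) {
      write_de_table(des[[nm]], p(paste0("de_", nm, ".tsv")))
    }, character(1))
  } else if (stage == "screen") {
    inputs <- require_input(config, "design.tsv", stage)
    design <- load_fermentation_table(inputs, strict = FALSE)
    screen <- do.call(phenotype_screen, c(list(table = design), pars))
    readr::write_tsv(as_tibble(screen), p("screen.tsv"), progress = FALSE)
    outputs <- p("screen.tsv")
  } else if (stage == "rf") {
    inputs <- c(require_input(config, "expr.tsv", stage),
                require_input(config, "design.tsv", stage))
    expr <- read_expression_matrix(inputs[1])
    design <- load_fermentation_table(inputs[2], strict = FALSE)
    n_trees <- pars$n_trees %||% 1000
    ranks <- list()
    for (acid in c("citrate", "succinate")) {
      v <- stats::setNames(design[[acid]], design$ferm_id)[colnames(expr)]
      lab <- dichotomize(v)
      ranks[[acid]] <- rf_importances(expr, lab, n_trees = n_trees,
                                      seed = config$seed, phenotype = acid)
      readr::write_tsv(as_tibble(ranks[[acid]]), p(paste0("rf_", acid, ".tsv")),
                       progress = FALSE)
    }
    shared <- top_overlap(ranks$citrate, ranks$succinate, k = pars$k %||% 10)
    readr::write_tsv(tibble(gene_id = shared), p("rf_shared_top10.tsv"),
                     progress = FALSE)
    outputs <- p(c("rf_citrate.tsv", "rf_succinate.tsv", "rf_shared_top10.tsv"))
  } else if (stage == "signature") {
    inputs <- c(require_input(config, "expr.tsv", stage),
                require_input(config, "design.tsv", stage))
    expr <- read_expression_matrix(inputs[1])
    design <- load_fermentation_table(inputs[2], strict = FALSE)
    mu <- stats::setNames(design$mu_max, design$ferm_id)[colnames(expr)]
    sig <- iterate_signature(expr, mu, top_n = pars$top_n %||% 300,
                             max_candidates = pars$max_candidates %||% 200000,
                             seed = config$seed)
    write_signature(sig, od)
    outputs <- p(c("signature_genes.tsv", "signature_averaged.tsv",
                   "signature_trace.json"))
  } else if (stage == "network") {
    des <- read_de_tables(config, stage)
    inputs <- p(paste0("de_", de_factor_names(), ".tsv"))
    clouds <- clouds_from_de(des, q_max = pars$q_max %||% 0.05,
                             fold_min = pars$fold_min %||% 1.5)
    net <- network_from_clouds(clouds)
    export_network(net, "sif", p("network.sif"))
    export_network(net, "graphml", p("network.graphml"))
    part <- partition_by_signature(clouds)
    readr::write_tsv(part$membership, p("response_groups.tsv"), progress = FALSE)
    cloud_tab <- purrr::map_dfr(names(clouds), function(f) {
      dplyr::bind_cols(tibble(factor = rep(f, nrow(clouds[[f]]))), clouds[[f]])
    })
    readr::write_tsv(cloud_tab, p("clouds.tsv"), progress = FALSE)
    outputs <- p(c("network.sif", "network.graphml", "response_groups.tsv",
                   "clouds.tsv"))
  } else if (stage == "enrich") {
    des <- read_de_tables(config, stage)
    inputs <- c(p(paste0("de_", de_factor_names(), ".tsv")),
                require_input(config, "classification.tsv", stage))
    cls <- readr::read_tsv(p("classification.tsv"), show_col_types = FALSE,
                           progress = FALSE)
    clouds <- clouds_from_de(des)
    cloud <- clouds$aeration
    enr <- enrichment(cloud$gene_id, cls, des[[1]]$gene_id)
    readr::write_tsv(enr, p("enrichment_aeration.tsv"), progress = FALSE)
    outputs <- p("enrichment_aeration.tsv")
  } else if (stage == "motif") {
    des <- read_de_tables(config, stage)
    inputs <- c(p(paste0("de_", de_factor_names(), ".tsv")),
                require_input(config, "promoters.fasta", stage))
    promoters <- read_promoters(p("promoters.fasta"))
    clouds <- clouds_from_de(des)
    fg_genes <- clouds$aeration$gene_id[clouds$aeration$direction == "up"]
    fg <- promoters[intersect(fg_genes, names(promoters))]
    set.seed(config$seed + 23L)
    bg_pool <- setdiff(names(promoters), fg_genes)
    bg <- promoters[sample(bg_pool, min(200, length(bg_pool)))]
    motifs <- find_inverted_repeats(fg, bg)
    readr::write_tsv(generics::tidy(motifs), p("motifs.tsv"), progress = FALSE)
    outputs <- p("motifs.tsv")
  } else if (stage == "recovery") {
    inputs <- require_input(config, "truth.json", stage)
    truth_raw <- jsonlite::read_json(inputs, simplifyVector = TRUE)
    truth <- structure(list(universe = truth_raw$universe), class = "sim_truth")
    results <- list()
    if (file.exists(p("signature_genes.tsv"))) {
      results$mumax_signature <- readr::read_tsv(p("signature_genes.tsv"),
                                                 show_col_types = FALSE,
                                                 progress = FALSE)$gene_id
    }
    if (file.exists(p("rf_shared_top10.tsv"))) {
      results$metabolite_assoc <- readr::read_tsv(p("rf_shared_top10.tsv"),
                                                  show_col_types = FALSE,
                                                  progress = FALSE)$gene_id
    }
    if (file.exists(p("clouds.tsv"))) {
      cl <- readr::read_tsv(p("clouds.tsv"), show_col_types = FALSE,
                            progress = FALSE)
      for (f in unique(cl$factor)) {
        for (d in c("up", "down")) {
          results[[paste0("responsive_", f, "_", d)]] <-
            cl$gene_id[cl$factor == f & cl$direction == d]
        }
      }
    }
    rep_tab <- purrr::map_dfr(names(results), function(nm) {
      if (is.null(truth_raw[[nm]])) return(tibble())
      dplyr::bind_cols(tibble(structure = nm),
                       recovery_metrics(truth_raw[[nm]], results[[nm]]))
    })
    readr::write_tsv(rep_tab, p("recovery.tsv"), progress = FALSE)
    outputs <- p("recovery.tsv")
  } else {
    abort_ferm(paste0("unknown stage: ", stage), "config")
  }

  write_manifest(config, stage, inputs, outputs, pars)
  inform(sprintf("stage '%s' finished in %.1f s", stage,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(outputs)
}

#' Run the configured pipeline end to end
#'
#' Runs every stage of the configuration in dependency order (the order of
#' `config$stages`). An empty stage list is a no-op with a warning.
#'
#' @param config A [project_config()].
#' @return Invisibly, a named list of the paths each stage wrote.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "project_config"))
  if (!length(config$stages)) {
    warn("no stages configured: nothing to run")
    return(invisible(list()))
  }
  out <- list()
  for (st in config$stages) out[[st]] <- run_stage(config, st)
  invisible(out)
}
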