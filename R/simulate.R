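#' Configuration for a synthetic fermentation study
#'
#' Builds the parameter object for [simulate_study()]. The defaults emulate
#' the scale and structure of a 3099-gene transcriptome measured over the
#' 30-fermentor fractional factorial design (29 fermentors with in-growth
#' transcriptome samples): planted condition-responsive gene sets per factor,
#' a planted gene group whose expression tracks the maximum growth rate, a
#' small set of genes coupled to a latent citrate-to-succinate conversion
#' activity (inducing the citrate/succinate anti-correlation), and a planted
#' palindromic promoter motif in oxygen-induced genes.
#'
#' @param n_genes Number of genes on the simulated array (default 3099).
#' @param design `"table1"` for the packaged 30-fermentor design, or a
#'   `ferm_table` supplying conditions (phenotypes are re-simulated).
#' @param seed Integer seed; one global seed drives an explicit hierarchy of
#'   per-component generator streams, so disabling one component never
#'   perturbs the draws of another.
#' @param effects Named list, factor -> named numeric vector of additive
#'   phenotype effects applied at the high level of the factor (for pH,
#'   scaled linearly from 0 at pH 5.2 to 1 at pH 6.4). `list()` plants no
#'   condition-phenotype effects.
#' @param responsive Named list, factor -> `list(n_up, n_down, log2fc)`
#'   describing condition-responsive gene sets; `NULL` plants none.
#' @param mumax_signature `list(n_genes, strength)`: a gene group whose
#'   expression is an affine function of the per-sample growth rate plus
#'   noise, with per-gene Pearson correlation targeting `strength`; `NULL`
#'   plants none.
#' @param metabolite_assoc `list(n_genes, effect)`: genes coupled to the
#'   latent conversion activity shared by the citrate and succinate
#'   phenotypes, shifting by `effect` log2 units per SD of that activity;
#'   `NULL` plants none.
#' @param conversion `list(low, high, sd, citrate_scale, succinate_scale)`
#'   for the latent citrate->succinate conversion activity (high at 0 mM
#'   NaCl), or `NULL` to make all organic acids independent noise.
#' @param noise_sd Residual log2 expression noise (default 0.5).
#' @param phenotype_noise Named list of phenotype noise SDs.
#' @param baseline_phenotypes Named list of phenotype baselines (OD units,
#'   per hour, mM).
#' @param probe_level If `TRUE` also emit a two-channel probe table
#'   (`n_probes` probes/gene) with a smooth intensity-dependent dye bias of
#'   amplitude `dye_bias` (log2) added to the Cy5 channel, for exercising
#'   normalization.
#' @param n_probes,probe_sd,dye_bias,channel_sd Probe-level parameters.
#' @param motif `list(core, flank5, flank3, fraction)`: an inverted-repeat
#'   core (default the 10-bp palindrome `TTGTGCACAA`) inserted, on a random
#'   strand at a random offset, into `fraction` of the oxygen-up-responsive
#'   promoters; `NULL` plants none.
#' @param promoter_length,promoter_gc Promoter length (bp) and GC content.
#' @param promoters If `FALSE`, skip promoter generation entirely.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 3099,
                       design = "table1",
                       seed = 1L,
                       effects = list(
                         temperature_C = c(mu_max = 0.2),
                         pH            = c(mu_max = -0.1, od_max = -0.6, formate = 3),
                         nacl_mM       = c(od_max = -1.0),
                         aeration      = c(acetate = 8)
                       ),
                       responsive = list(
                         nacl_mM       = list(n_up = 40, n_down = 40, log2fc = 2),
                         aa_factor     = list(n_up = 40, n_down = 40, log2fc = 2),
                         temperature_C = list(n_up = 40, n_down = 40, log2fc = 2),
                         pH            = list(n_up = 40, n_down = 40, log2fc = 2),
                         aeration      = list(n_up = 40, n_down = 40, log2fc = 2)
                       ),
                       mumax_signature = list(n_genes = 47, strength = 0.9),
                       metabolite_assoc = list(n_genes = 5, effect = 3),
                       conversion = list(low = 0.3, high = 0.7, sd = 0.4,
                                         citrate_scale = 6, succinate_scale = 6),
                       noise_sd = 0.5,
                       phenotype_noise = list(mu_max = 0.05, od_max = 0.4, acid = 0.5),
                       baseline_phenotypes = list(mu_max = 0.5, od_max = 6,
                                                  lactate = 150, pyruvate = 2,
                                                  acetate = 15, formate = 5,
                                                  citrate = 8, succinate = 2),
                       probe_level = FALSE, n_probes = 3, probe_sd = 0.3,
                       dye_bias = 0.6, channel_sd = 0.1,
                       motif = list(core = "TTGTGCACAA", flank5 = "AG",
                                    flank3 = "TT", fraction = 0.8),
                       promoter_length = 300, promoter_gc = 0.45,
                       promoters = TRUE) {
  if (noise_sd < 0) abort_ferm("noise_sd must be >= 0", "config")
  if (!is.null(motif) && (motif$fraction < 0 || motif$fraction > 1)) {
    abort_ferm("motif fraction must be in [0, 1]", "config")
  }
  n_planted <- sum(vapply(responsive %||% list(),
                          function(r) r$n_up + r$n_down, numeric(1))) +
    (mumax_signature$n_genes %||% 0) + (metabolite_assoc$n_genes %||% 0)
  if (n_planted > n_genes) {
    abort_ferm(paste0("planted gene counts (", n_planted,
                      ") exceed n_genes (", n_genes, ")"), "config")
  }
  structure(list(n_genes = n_genes, design = design, seed = as.integer(seed),
                 effects = effects %||% list(), responsive = responsive,
                 mumax_signature = mumax_signature,
                 metabolite_assoc = metabolite_assoc, conversion = conversion,
                 noise_sd = noise_sd, phenotype_noise = phenotype_noise,
                 baseline_phenotypes = baseline_phenotypes,
                 probe_level = probe_level, n_probes = n_probes,
                 probe_sd = probe_sd, dye_bias = dye_bias,
                 channel_sd = channel_sd, motif = motif,
                 promoter_length = promoter_length, promoter_gc = promoter_gc,
                 promoters = promoters),
            class = "sim_config")
}

#' A fully null simulation configuration
#'
#' Convenience wrapper: no planted effects of any kind, only noise; used for
#' type-I error calibration of the downstream screens.
#'
#' @inheritParams sim_config
#' @param ... Passed on to [sim_config()].
#' @export
null_sim_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(effects = list(), responsive = NULL, mumax_signature = NULL,
                   metabolite_assoc = NULL, conversion = NULL, motif = NULL)
  for (nm in names(defaults)) {
    # single-bracket assignment keeps NULL entries in the list
    if (!nm %in% names(args)) args[nm] <- defaults[nm]
  }
  do.call(sim_config, c(list(seed = seed), args))
}

# Fraction in [0,1] encoding how "high" a sample's level of a factor is.
level_weight <- function(factor, values) {
  lv <- default_factor_levels()[[factor]]
  if (factor == "pH") {
    (values - min(lv)) / diff(range(lv))
  } else if (factor == "aeration") {
    as.numeric(values == "O2")
  } else {
    as.numeric(values == max(lv))
  }
}

#' Simulate a complete fermentation-genomics study
#'
#' Generates a study table with phenotypes (baseline + planted condition
#' effects + Gaussian noise), a log2 gene-expression matrix over the
#' transcriptome-sampled fermentors with planted condition-responsive sets, a
#' growth-rate-tracking gene group and metabolite-coupled genes, optionally a
#' two-channel probe-level table, promoter sequences with a planted
#' inverted-repeat motif, and the ground truth of everything planted.
#' Bit-identical outputs are guaranteed for identical config (and seed).
#'
#' @param config A [sim_config()].
#' @return A list of class `ferm_simulation`: `design` (a `ferm_table` with
#'   simulated phenotypes), `expr` (log2 matrix, genes x samples), `probes`
#'   (tibble or `NULL`), `promoters` (named character vector or `NULL`) and
#'   `truth` (class `sim_truth`).
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 200, seed = 42))
#' dim(sim$expr)
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 6)

  design <- if (identical(config$design, "table1")) {
    table1_fermentations()
  } else config$design
  stopifnot(inherits(design, "ferm_table"))
  n_rec <- nrow(design)

  ## -- phenotypes (stream 1) ------------------------------------------------
  set.seed(streams[1])
  base <- config$baseline_phenotypes
  pn <- config$phenotype_noise
  pheno <- as_tibble(design)[, c("ferm_id", ferm_condition_cols,
                                 intersect(c("day", "replicate_group",
                                             "transcriptome"), names(design)))]
  conv <- NULL
  if (!is.null(config$conversion)) {
    cv <- config$conversion
    conv <- ifelse(design$nacl_mM == 0, cv$high, cv$low) + rnorm(n_rec, 0, cv$sd)
  }
  acid_noise <- pn$acid %||% 1
  vals <- list(
    mu_max   = pmax(0.02, base$mu_max + rnorm(n_rec, 0, pn$mu_max)),
    od_max   = pmax(0.1, base$od_max + rnorm(n_rec, 0, pn$od_max)),
    lactate  = pmax(0, base$lactate + rnorm(n_rec, 0, 5 * acid_noise)),
    pyruvate = pmax(0, base$pyruvate + rnorm(n_rec, 0, 0.5 * acid_noise)),
    acetate  = pmax(0, base$acetate + rnorm(n_rec, 0, acid_noise)),
    formate  = pmax(0, base$formate + rnorm(n_rec, 0, acid_noise)),
    citrate  = pmax(0, base$citrate -
                      (if (is.null(conv)) 0 else config$conversion$citrate_scale * conv) +
                      rnorm(n_rec, 0, acid_noise)),
    succinate = pmax(0, base$succinate +
                       (if (is.null(conv)) 0 else config$conversion$succinate_scale * conv) +
                       rnorm(n_rec, 0, acid_noise))
  )
  for (f in names(config$effects)) {
    w <- level_weight(f, design[[f]])
    eff <- config$effects[[f]]
    for (ph in names(eff)) vals[[ph]] <- pmax(0.02, vals[[ph]] + eff[[ph]] * w)
  }
  ord <- c("od_max", "mu_max", ferm_acid_cols)
  for (ph in ord) pheno[[ph]] <- vals[[ph]]
  pheno <- pheno[, c("ferm_id", ferm_condition_cols, ord,
                     intersect(c("day", "replicate_group", "transcriptome"),
                               names(pheno)))]
  design_out <- new_ferm_table(pheno, attr(design, "factor_levels"))

  ## -- gene universe and planted allocations --------------------------------
  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  ptr <- 0L
  take <- function(n) {
    if (ptr + n > config$n_genes) abort_ferm("planted genes exceed n_genes", "config")
    out <- gene_ids[ptr + seq_len(n)]
    ptr <<- ptr + n
    out
  }
  responsive_truth <- list()
  for (f in names(config$responsive %||% list())) {
    r <- config$responsive[[f]]
    responsive_truth[[f]] <- list(up = take(r$n_up), down = take(r$n_down))
  }
  sig_genes <- if (!is.null(config$mumax_signature)) take(config$mumax_signature$n_genes)
  met_genes <- if (!is.null(config$metabolite_assoc)) take(config$metabolite_assoc$n_genes)

  ## -- expression matrix (streams 2, 3) -------------------------------------
  samples <- if ("transcriptome" %in% names(design_out)) {
    design_out$ferm_id[design_out$transcriptome]
  } else design_out$ferm_id
  ns <- length(samples)
  set.seed(streams[2])
  baseline_g <- rnorm(config$n_genes, mean = 8, sd = 2)
  set.seed(streams[3])
  expr <- matrix(baseline_g, config$n_genes, ns) +
    matrix(rnorm(config$n_genes * ns, 0, config$noise_sd), config$n_genes, ns)
  rownames(expr) <- gene_ids
  colnames(expr) <- samples

  sdes <- design_out[match(samples, design_out$ferm_id), ]
  for (f in names(responsive_truth)) {
    w <- level_weight(f, sdes[[f]])
    fc <- config$responsive[[f]]$log2fc
    expr[responsive_truth[[f]]$up, ] <-
      expr[responsive_truth[[f]]$up, , drop = FALSE] +
      matrix(fc * w, length(responsive_truth[[f]]$up), ns, byrow = TRUE)
    expr[responsive_truth[[f]]$down, ] <-
      expr[responsive_truth[[f]]$down, , drop = FALSE] -
      matrix(fc * w, length(responsive_truth[[f]]$down), ns, byrow = TRUE)
  }
  if (!is.null(sig_genes)) {
    mu <- sdes$mu_max
    rho <- config$mumax_signature$strength
    slope <- if (config$noise_sd > 0) {
      rho / sqrt(1 - rho^2) * config$noise_sd / stats::sd(mu)
    } else 1 / stats::sd(mu)
    expr[sig_genes, ] <- expr[sig_genes, , drop = FALSE] +
      matrix(slope * (mu - mean(mu)), length(sig_genes), ns, byrow = TRUE)
  }
  if (!is.null(met_genes)) {
    driver <- if (!is.null(conv)) conv[match(samples, design_out$ferm_id)] else sdes$citrate
    z <- as.numeric(scale(driver))
    expr[met_genes, ] <- expr[met_genes, , drop = FALSE] +
      matrix(config$metabolite_assoc$effect * z, length(met_genes), ns,
             byrow = TRUE)
  }

  ## -- probe level (stream 4) ------------------------------------------------
  probes <- NULL
  if (config$probe_level) {
    set.seed(streams[4])
    np <- config$n_probes
    probe_off <- matrix(rnorm(config$n_genes * np, 0, config$probe_sd),
                        config$n_genes, np)
    rows <- vector("list", ns)
    for (s in seq_len(ns)) {
      v <- rep(expr[, s], each = np) + as.vector(t(probe_off))
      bias <- config$dye_bias * stats::plogis((v - 8) / 2)
      l5 <- v + bias / 2 + rnorm(length(v), 0, config$channel_sd)
      l3 <- v - bias / 2 + rnorm(length(v), 0, config$channel_sd)
      rows[[s]] <- tibble(array_id = samples[s],
                          probe_id = paste0(rep(gene_ids, each = np), "_p",
                                            rep(seq_len(np), config$n_genes)),
                          gene_id = rep(gene_ids, each = np),
                          cy5 = 2^l5, cy3 = 2^l3)
    }
    probes <- dplyr::bind_rows(rows)
  }

  ## -- promoters and planted motif (streams 5, 6) ----------------------------
  promoters <- NULL
  motif_truth <- character(0)
  if (isTRUE(config$promoters)) {
    set.seed(streams[5])
    L <- config$promoter_length
    gc <- config$promoter_gc
    bases <- sample(c("A", "C", "G", "T"), config$n_genes * L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    cols <- split(bases, rep(seq_len(L), each = config$n_genes))
    promoters <- do.call(paste0, cols)
    names(promoters) <- gene_ids
    if (!is.null(config$motif) && !is.null(responsive_truth$aeration)) {
      set.seed(streams[6])
      site <- toupper(paste0(config$motif$flank5, config$motif$core,
                             config$motif$flank3))
      w <- nchar(site)
      fg <- responsive_truth$aeration$up
      n_seed <- round(config$motif$fraction * length(fg))
      motif_truth <- sort(sample(fg, n_seed))
      for (g in motif_truth) {
        ins <- if (runif(1) < 0.5) site else reverse_complement(site)
        off <- sample.int(L - w + 1L, 1L)
        substr(promoters[[g]], off, off + w - 1L) <- ins
      }
    }
  }

  truth <- structure(list(universe = gene_ids, samples = samples,
                          responsive = responsive_truth,
                          mumax_signature = sig_genes %||% character(0),
                          metabolite_assoc = met_genes %||% character(0),
                          motif_promoters = motif_truth,
                          conversion = conv, effects = config$effects),
                     class = "sim_truth")
  structure(list(design = design_out, expr = expr, probes = probes,
                 promoters = promoters, truth = truth),
            class = "ferm_simulation")
}

#' Planted gene sets of a simulation truth
#'
#' @param truth A `sim_truth`.
#' @return Named list of character vectors (one per planted structure).
#' @export
truth_sets <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- list()
  for (f in names(truth$responsive)) {
    out[[paste0("responsive_", f, "_up")]] <- truth$responsive[[f]]$up
    out[[paste0("responsive_", f, "_down")]] <- truth$responsive[[f]]$down
  }
  if (length(truth$mumax_signature)) out$mumax_signature <- truth$mumax_signature
  if (length(truth$metabolite_assoc)) out$metabolite_assoc <- truth$metabolite_assoc
  if (length(truth$motif_promoters)) out$motif_promoters <- truth$motif_promoters
  out
}

#' Set-overlap metrics for one recovered gene set
#'
#' @param truth_set,found_set Character vectors of gene ids.
#' @return One-row tibble with `n_truth`, `n_found`, `tp`, `precision`,
#'   `recall` and `jaccard`.
#' @export
recovery_metrics <- function(truth_set, found_set) {
  tp <- length(intersect(truth_set, found_set))
  un <- length(union(truth_set, found_set))
  tibble(n_truth = length(truth_set), n_found = length(found_set), tp = tp,
         precision = if (length(found_set)) tp / length(found_set) else NA_real_,
         recall = if (length(truth_set)) tp / length(truth_set) else NA_real_,
         jaccard = if (un) tp / un else NA_real_)
}

#' Score recovered structures against the planted truth
#'
#' @param truth A `sim_truth` from [simulate_study()].
#' @param results Named list of recovered gene-id sets; names must match the
#'   planted structures (see [truth_sets()]), and every gene must belong to
#'   the truth's gene universe.
#' @return Tibble with one row per scored structure (precision, recall,
#'   Jaccard).
#' @export
truth_recovery_report <- function(truth, results) {
  stopifnot(inherits(truth, "sim_truth"), is.list(results))
  ts <- truth_sets(truth)
  bad <- setdiff(unique(unlist(results)), truth$universe)
  if (length(bad)) {
    abort_ferm(paste0("recovered genes outside the simulated universe: ",
                      paste(utils::head(bad, 3), collapse = ", ")), "validation")
  }
  keys <- intersect(names(results), names(ts))
  if (!length(keys)) abort_ferm("no result names match any planted structure", "validation")
  purrr::map_dfr(keys, function(k) {
    dplyr::bind_cols(tibble(structure = k), recovery_metrics(ts[[k]], results[[k]]))
  })
}
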