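test_that("identical config and seed give bit-identical studies", {
  cfg <- sim_config(n_genes = 300, seed = 11,
                    responsive = list(aeration = list(n_up = 10, n_down = 10,
                                                      log2fc = 2)),
                    mumax_signature = list(n_genes = 15, strength = 0.9),
                    metabolite_assoc = list(n_genes = 5, effect = 3))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$expr, s2$expr)
  expect_identical(tibble::as_tibble(s1$design), tibble::as_tibble(s2$design))
  expect_identical(s1$promoters, s2$promoters)
  expect_identical(truth_sets(s1$truth), truth_sets(s2$truth))
})

test_that("with zero noise the signature genes are exactly affine in mu_max", {
  cfg <- sim_config(n_genes = 100, seed = 3, noise_sd = 0, promoters = FALSE,
                    responsive = NULL, metabolite_assoc = NULL,
                    mumax_signature = list(n_genes = 8, strength = 0.9))
  sim <- simulate_study(cfg)
  mu <- sim$design$mu_max[match(colnames(sim$expr), sim$design$ferm_id)]
  for (g in sim$truth$mumax_signature) {
    fit <- lm(sim$expr[g, ] ~ mu)
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("a strong planted signature correlates >= 0.9 with growth rate", {
  sim <- simulate_study(sim_config(seed = 1))
  mu <- stats::setNames(sim$design$mu_max, sim$design$ferm_id)[colnames(sim$expr)]
  gc <- geneset_correlation(sim$expr, sim$truth$mumax_signature, mu)
  expect_gte(gc$pearson, 0.9)
})

test_that("planted gene counts beyond the universe are a config error", {
  expect_error(sim_config(n_genes = 50,
                          responsive = list(aeration = list(n_up = 30, n_down = 30,
                                                            log2fc = 2))),
               class = "fermgenomics_error_config")
})

test_that("doubling a planted effect never weakens the median test statistic", {
  med_t <- function(fc, seed) {
    cfg <- sim_config(n_genes = 300, seed = seed, promoters = FALSE,
                      responsive = list(aeration = list(n_up = 15, n_down = 15,
                                                        log2fc = fc)),
                      mumax_signature = NULL, metabolite_assoc = NULL)
    sim <- simulate_study(cfg)
    de <- de_by_factor(sim$expr, sim$design, factors = "aeration")$aeration
    planted <- unlist(sim$truth$responsive$aeration)
    median(abs(de$t[de$gene_id %in% planted]))
  }
  for (seed in 1:3) {
    expect_gte(med_t(2, seed), med_t(1, seed))
  }
})

test_that("recovery metrics report precision, recall and Jaccard correctly", {
  truth <- sprintf("g%02d", 1:40)
  expect_equal(recovery_metrics(truth, truth)$jaccard, 1)
  expect_equal(recovery_metrics(truth, sprintf("x%02d", 1:10))$jaccard, 0)
  half <- recovery_metrics(truth, truth[1:20])
  expect_equal(half$recall, 0.5)
  expect_equal(half$precision, 1)
})

test_that("recovery reports validate the gene universe", {
  sim <- simulate_study(sim_config(n_genes = 120, seed = 5, promoters = FALSE,
                                   responsive = list(aeration = list(
                                     n_up = 10, n_down = 10, log2fc = 2)),
                                   mumax_signature = NULL,
                                   metabolite_assoc = NULL))
  rep <- truth_recovery_report(sim$truth, list(
    responsive_aeration_up = sim$truth$responsive$aeration$up))
  expect_equal(rep$jaccard, 1)
  expect_error(truth_recovery_report(sim$truth, list(
    responsive_aeration_up = c("not_a_gene"))),
    class = "fermgenomics_error_validation")
})
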