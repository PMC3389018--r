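make_probes <- function(a, m, array_id = "a1") {
  tibble::tibble(array_id = array_id,
                 probe_id = paste0(array_id, "_p", seq_along(a)),
                 gene_id = paste0("g", seq_along(a)),
                 cy5 = 2^(a + m / 2), cy3 = 2^(a - m / 2))
}

test_that("equal channels normalize to zero log-ratio", {
  set.seed(1)
  a <- rnorm(50, 8, 1.5)
  norm <- lowess_normalize(make_probes(a, rep(0, 50)))
  expect_lt(max(abs(norm$m)), 1e-12)
  expect_equal(norm$a, a, tolerance = 1e-12)
})

test_that("a constant 2x channel bias is removed and intensity preserved", {
  set.seed(2)
  a <- rnorm(60, 8, 1.5)
  probes <- make_probes(a, rep(1, 60))  # cy5 = 2 * cy3 everywhere
  norm <- lowess_normalize(probes)
  expect_lt(max(abs(norm$m)), 1e-6)
  # per-probe average intensity unchanged by detrending
  expect_equal(norm$a, (log2(probes$cy5) + log2(probes$cy3)) / 2,
               tolerance = 1e-12)
  # idempotence: renormalizing changes nothing appreciably
  renorm <- lowess_normalize(
    dplyr::mutate(norm[, c("array_id", "probe_id", "gene_id")],
                  cy5 = norm$cy5_norm, cy3 = norm$cy3_norm))
  expect_lt(max(abs(renorm$m - norm$m)), 1e-6)
})

test_that("a smooth rank-dependent dye bias is flattened", {
  set.seed(3)
  a <- rnorm(200, 8, 1.5)
  bias <- 0.5 * rank(a) / length(a)
  norm <- lowess_normalize(make_probes(a, bias))
  expect_lt(abs(median(norm$m)), 0.05)
})

test_that("degenerate probe tables are rejected", {
  set.seed(4)
  a <- rnorm(10, 8, 1)
  expect_error(lowess_normalize(make_probes(a, rep(0, 10))),
               class = "fermgenomics_error_validation")  # < 20 probes
  bad <- make_probes(rnorm(30, 8, 1), rep(0, 30))
  bad$cy5[1] <- -1
  expect_error(lowess_normalize(bad), class = "fermgenomics_error_validation")
})

test_that("inter-slide scaling equalizes totals at the geometric mean", {
  set.seed(5)
  a <- rnorm(30, 8, 1)
  p1 <- make_probes(a, rep(0, 30), "a1")
  p2 <- make_probes(a, rep(0, 30), "a2")
  p2$cy5 <- 3 * p2$cy5; p2$cy3 <- 3 * p2$cy3
  sc <- interslide_scale(dplyr::bind_rows(p1, p2))
  tot <- tapply(sc$cy5 + sc$cy3, sc$array_id, sum)
  expect_equal(unname(tot[1]), unname(tot[2]), tolerance = 1e-9)

  # totals 1:2:4 -> factors 2, 1, 0.5 against the geometric-mean target
  q1 <- make_probes(a, rep(0, 30), "b1")
  q2 <- q1; q2$array_id <- "b2"; q2$cy5 <- 2 * q2$cy5; q2$cy3 <- 2 * q2$cy3
  q4 <- q1; q4$array_id <- "b3"; q4$cy5 <- 4 * q4$cy5; q4$cy3 <- 4 * q4$cy3
  sc3 <- interslide_scale(dplyr::bind_rows(q1, q2, q4))
  expect_equal(unname(attr(sc3, "scale_factors")), c(2, 1, 0.5),
               tolerance = 1e-12)

  expect_warning(one <- interslide_scale(p1), "single array")
  expect_equal(one$cy5, p1$cy5)
})

test_that("probe collapse takes the median with the even-count convention", {
  tab <- tibble::tibble(array_id = "a1",
                        probe_id = paste0("p", 1:6),
                        gene_id = c("g1", "g1", "g1", "g2", "g2", "g3"),
                        intensity = c(1, 2, 9, 1, 3, 7))
  m <- collapse_probes(tab)
  expect_equal(unname(m["g1", "a1"]), 2)  # odd count: middle value
  expect_equal(unname(m["g2", "a1"]), 2)  # even count: mean of middle two
  expect_equal(unname(m["g3", "a1"]), 7)  # single probe: identity

  # permutation invariance in probe order
  perm <- tab[sample(6), ]
  expect_equal(collapse_probes(perm)[rownames(m), ], m[, 1])

  # a gene absent from one array yields NA with a message
  two <- dplyr::bind_rows(tab, tibble::tibble(array_id = "a2", probe_id = "q1",
                                              gene_id = "g1", intensity = 5))
  expect_message(m2 <- collapse_probes(two), "NA")
  expect_true(is.na(m2["g3", "a2"]))
})

test_that("the probe-level pipeline reconstructs the true expression", {
  cfg <- sim_config(n_genes = 120, seed = 3, probe_level = TRUE, promoters = FALSE,
                    responsive = list(aeration = list(n_up = 5, n_down = 5,
                                                      log2fc = 2)),
                    mumax_signature = list(n_genes = 10, strength = 0.9),
                    metabolite_assoc = list(n_genes = 5, effect = 3))
  sim <- simulate_study(cfg)
  expr <- collapse_probes(interslide_scale(lowess_normalize(sim$probes)))
  expect_equal(dim(expr), dim(sim$expr))
  expect_gt(cor(as.vector(expr[rownames(sim$expr), colnames(sim$expr)]),
                as.vector(sim$expr)), 0.98)
})
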