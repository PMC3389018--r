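test_that("cloud membership applies both thresholds exactly", {
  de <- fake_de(c("gA", "gB", "gC"), ratio = c(2.0, 1.2, 3.0),
                q = c(0.01, 0.01, 0.2))
  clouds <- build_clouds(list(temperature_C = de))
  cl <- clouds$temperature_C
  expect_equal(cl$gene_id, "gA")           # q and fold both pass
  expect_equal(cl$direction, "up")
  # gB fails the fold filter, gC fails the q filter
  expect_false(any(c("gB", "gC") %in% cl$gene_id))
  expect_error(build_clouds(list(t = de), fold_min = 0.5),
               class = "fermgenomics_error_config")
})

test_that("clouds grow monotonically as thresholds relax", {
  set.seed(8)
  de <- fake_de(sprintf("g%03d", 1:200), ratio = 2^rnorm(200, 0, 1),
                q = runif(200))
  tight <- build_clouds(list(f = de), q_max = 0.05, fold_min = 1.5)$f
  loose <- build_clouds(list(f = de), q_max = 0.10, fold_min = 1.2)$f
  expect_true(all(tight$gene_id %in% loose$gene_id))
})

test_that("signature partition groups genes by their exact factor set", {
  clouds <- list(
    temperature_C = tibble::tibble(gene_id = c("a", "b", "c"),
                                   direction = "up", ratio = 2, q = 0.01),
    pH = tibble::tibble(gene_id = c("c", "d", "e"),
                        direction = "down", ratio = 0.5, q = 0.01))
  part <- partition_by_signature(clouds)
  expect_equal(sort(part$groups$n), c(1L, 2L, 2L))
  expect_equal(part$membership$signature[part$membership$gene_id == "c"],
               "pH+temperature_C")
  # partition property: disjoint and covering
  expect_equal(sort(part$membership$gene_id), c("a", "b", "c", "d", "e"))
  expect_equal(anyDuplicated(part$membership$gene_id), 0L)
})

test_that("SIF and GraphML exports round-trip nodes, edges and direction", {
  clouds <- list(
    temperature_C = tibble::tibble(gene_id = c("g1", "g2"), direction = "up",
                                   ratio = 2, q = 0.01),
    aeration = tibble::tibble(gene_id = c("g2", "g3"),
                              direction = c("down", "up"),
                              ratio = c(0.4, 3), q = 0.01))
  net <- network_from_clouds(clouds)
  expect_equal(igraph::ecount(net), 4)
  expect_equal(igraph::vcount(net), 5)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, "sif", sif)
  back <- import_network(sif, "sif")
  key <- function(g) {
    el <- igraph::as_data_frame(g, what = "edges")
    sort(paste(el$from, el$to, el$direction))
  }
  expect_equal(key(back), key(net))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  back2 <- import_network(gml, "graphml")
  expect_equal(key(back2), key(net))
  expect_setequal(igraph::V(back2)$name, igraph::V(net)$name)
  # every edge keeps its direction attribute through GraphML
  expect_false(any(is.na(igraph::E(back2)$direction)))

  empty <- build_clouds(list(f = fake_de("g1", 1.0, 0.9)))
  expect_error(network_from_clouds(empty),
               class = "fermgenomics_error_validation")
})

test_that("hypergeometric enrichment matches the closed form", {
  universe <- paste0("g", 1:10)
  cls <- tibble::tibble(gene_id = universe,
                        class = rep(c("K", "other"), c(5, 5)))
  res <- enrichment(paste0("g", 1:3), cls, universe)
  expect_equal(res$p[res$class == "K"], choose(5, 3) / choose(10, 3))

  # zero overlap is never significant; the full universe is always p = 1
  res0 <- enrichment(paste0("g", 6:8), cls, universe)
  expect_equal(res0$p[res0$class == "K"], 1)
  resU <- enrichment(universe, cls, universe)
  expect_equal(resU$p, rep(1, 2))

  expect_error(enrichment(c("g1", "zz"), cls, universe),
               class = "fermgenomics_error_validation")
})

test_that("enrichment p agrees with Monte-Carlo resampling", {
  set.seed(21)
  universe <- sprintf("u%03d", 1:50)
  cls <- tibble::tibble(gene_id = universe, class = rep(c("A", "B"), c(15, 35)))
  geneset <- sample(universe, 10)
  k <- sum(geneset %in% universe[1:15])
  p_cf <- enrichment(geneset, cls, universe)$p[1]
  p_cf <- enrichment(geneset, cls, universe)
  p_cf <- p_cf$p[p_cf$class == "A"]
  draws <- replicate(20000, sum(sample(universe, 10) %in% universe[1:15]) >= k)
  p_mc <- mean(draws)
  se <- sqrt(p_mc * (1 - p_mc) / 20000)
  expect_lt(abs(p_cf - p_mc), 3 * se + 1e-6)
})
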