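test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAC"), "GTT")
  # the oxygen-response core is a perfect inverted repeat
  expect_equal(reverse_complement("TTGTGCACAA"), "TTGTGCACAA")
  expect_equal(reverse_complement("acGTn"), "NACGT")
  set.seed(2)
  for (s in random_seqs(5, 40, seed = 2)) {
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGU"), class = "fermgenomics_error_validation")
})

test_that("upstream extraction follows the half-open coordinate convention", {
  set.seed(3)
  genome <- c(chr = paste0(sample(c("A", "C", "G", "T"), 400, TRUE),
                           collapse = ""))
  coords <- tibble::tibble(gene_id = c("plus", "minus", "edge"),
                           seqname = "chr",
                           start = c(100, 20, 10), end = c(150, 200, 40),
                           strand = c("+", "-", "+"))
  up <- extract_upstream(coords, genome, length = 50)
  expect_equal(up$seq[up$gene_id == "plus"], substr(genome[["chr"]], 51, 100))
  expect_equal(up$seq[up$gene_id == "minus"],
               reverse_complement(substr(genome[["chr"]], 201, 250)))
  expect_equal(up$seq[up$gene_id == "edge"], substr(genome[["chr"]], 1, 10))
  expect_true(up$truncated[up$gene_id == "edge"])
  expect_false(any(up$truncated[up$gene_id != "edge"]))

  bad <- coords
  bad$seqname <- "nope"
  expect_error(extract_upstream(bad, genome), class = "fermgenomics_error_key")
})

test_that("a planted inverted repeat is recovered as the top motif", {
  sim <- simulate_study(sim_config(seed = 7))
  fg_genes <- sim$truth$responsive$aeration$up
  fg <- sim$promoters[fg_genes]
  set.seed(99)
  bg <- sim$promoters[sample(setdiff(names(sim$promoters), fg_genes), 50)]
  ms <- find_inverted_repeats(fg, bg)
  expect_gt(length(ms), 0)
  top <- ms[[1]]
  expect_true(grepl("TTGTGCACAA", top$consensus) ||
                grepl(top$consensus, "TTGTGCACAA"))
  expect_lt(top$p_value, 1e-6)
  # planted promoters are the recovered sites
  rec <- unique(top$sites$seq_id[top$sites$set == "foreground"])
  expect_gt(length(intersect(rec, sim$truth$motif_promoters)) /
              length(sim$truth$motif_promoters), 0.8)
  # PWM sanity: columns stochastic, IC within [0, 2] bits
  expect_equal(colSums(top$pwm), rep(1, ncol(top$pwm)), tolerance = 1e-9)
  expect_true(all(top$ic >= 0 & top$ic <= 2 + 1e-9))
})

test_that("sites planted only on the reverse strand are still found", {
  fg <- random_seqs(10, 120, seed = 5)
  site <- "AGTTGTGCACAATT"
  for (i in 1:8) {
    substr(fg[[i]], 40, 39 + nchar(site)) <- reverse_complement(site)
  }
  bg <- random_seqs(50, 120, seed = 6)
  ms <- find_inverted_repeats(fg, bg)
  expect_gt(length(ms), 0)
  expect_true(grepl("TTGTGCACAA", ms[[1]]$consensus))
  expect_gte(ms[[1]]$k_fg, 8)
})

test_that("discovery is invariant under reverse-complementing every input", {
  sim <- simulate_study(sim_config(n_genes = 400, seed = 12,
                                   responsive = list(aeration = list(
                                     n_up = 12, n_down = 12, log2fc = 2)),
                                   mumax_signature = NULL,
                                   metabolite_assoc = NULL))
  fg <- sim$promoters[sim$truth$responsive$aeration$up]
  set.seed(13)
  bg <- sim$promoters[sample(setdiff(names(sim$promoters),
                                     names(fg)), 40)]
  m1 <- tidy(find_inverted_repeats(fg, bg))
  m2 <- tidy(find_inverted_repeats(reverse_complement(fg),
                                   reverse_complement(bg)))
  cols <- c("arm", "spacer_len", "k_fg", "k_bg", "p_value")
  expect_equal(m1[order(m1$p_value, m1$arm), cols],
               m2[order(m2$p_value, m2$arm), cols])
})

test_that("random foregrounds rarely yield a significant motif", {
  clean <- vapply(1:5, function(s) {
    fg <- random_seqs(10, 300, seed = 100 + 2 * s)
    bg <- random_seqs(50, 300, seed = 101 + 2 * s)
    sum(tidy(find_inverted_repeats(fg, bg))$q_value < 0.05) == 0
  }, logical(1))
  expect_gte(sum(clean), 4)
  expect_error(find_inverted_repeats(random_seqs(3, 50), random_seqs(3, 50),
                                     arm_range = c(2, 4)),
               class = "fermgenomics_error_config")
})

test_that("PWM construction and information content behave at the limits", {
  pwm <- build_pwm("ACGT", pseudocount = 0)
  expect_equal(colSums(pwm), rep(1, 4))
  expect_equal(pwm_information_content(pwm), rep(2, 4))
  pwm2 <- build_pwm(c("AAAA", "AAAA", "CCCC"), pseudocount = 0.5)
  expect_equal(colSums(pwm2), rep(1, 4), tolerance = 1e-12)
  expect_true(all(pwm_information_content(pwm2) < 2))
})

test_that("PWM scanning reports hits on both strands with thresholds", {
  site <- "AGTTGTGCACAATT"  # not its own reverse complement
  pwm <- build_pwm(site, pseudocount = 0.01)
  hits <- scan_motif(pwm, c(fwd = site), score_threshold = 0.95)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")

  hits_rc <- scan_motif(pwm, c(rc = reverse_complement(site)),
                        score_threshold = 0.95)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score)

  none <- scan_motif(pwm, c(n = strrep("N", 50)))
  expect_equal(nrow(none), 0)
  expect_warning(scan_motif(pwm, c(short = "ACGT")), "shorter")
})
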