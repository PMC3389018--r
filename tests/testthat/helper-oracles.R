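# Independent oracles and small fixture builders used across the suite.

# Full-enumeration Mann-Whitney oracle: the exact two-sided p of U_A over all
# C(nA+nB, nA) labelings of the pooled tie-free sample.
mwu_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  us <- utils::combn(n, na, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Step-up BH oracle: q_k = min over i >= k of p_(i) * m / i, mapped back.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Small named expression matrix of pure noise.
noise_expr <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, sd), n_genes, n_samples)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  m
}

# Random promoter sequences.
random_seqs <- function(n, len = 300, seed = 1, gc = 0.45) {
  set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
           collapse = "")
  }, character(1))
  names(out) <- sprintf("p%03d", seq_len(n))
  out
}

# Minimal differential-expression table for threshold/concordance fixtures.
fake_de <- function(gene_id, ratio, q, threshold = 0.05) {
  d <- tibble::tibble(gene_id = gene_id, mean_a = 0, mean_b = 0,
                      ratio = ratio, t = 0, df = 10, p = q, q = q,
                      significant = q < threshold)
  class(d) <- c("ferm_de", class(d))
  d
}

table1 <- table1_fermentations()
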