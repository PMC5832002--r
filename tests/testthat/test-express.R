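test_that("RPM is the analytic ratio and errors on bad totals", {
  expect_equal(rpm(0, 1e6), 0)
  expect_equal(rpm(7, 1e6), 7)
  expect_equal(rpm(5, 2e6), 2.5)
  expect_error(rpm(5, 0), "> 0")
  ## linear in counts, invariant to doubling both count and total
  set.seed(2)
  k <- sample(1:100, 20); t <- sample(1e5:1e7, 20)
  expect_equal(rpm(2 * k, t), 2 * rpm(k, t))
  expect_equal(rpm(2 * k, 2 * t), rpm(k, t))
})

ev1 <- function(entries) {
  data.table::rbindlist(lapply(entries, function(e)
    data.table::data.table(chrom = "1", start = 1000L, end = 2000L,
                           strand = "+", sample_id = e[[1]], method = e[[2]],
                           read_count = as.integer(e[[3]]))))
}

test_that("circRNA matrix applies the count rule then RPM, zeros when absent", {
  ev <- ev1(list(list("s1", "ciri", 5)))
  m <- circrna_matrix(ev, c(s1 = 1e6, s2 = 1e6))
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(m["1:1001-2000:+", "s1"], 5.0)
  expect_equal(m["1:1001-2000:+", "s2"], 0.0)   # absent from s2
  expect_equal(attr(m, "unit"), "RPM")

  ev2 <- ev1(list(list("s1", "ciri", 3), list("s1", "findcirc", 5)))
  expect_equal(circrna_matrix(ev2, c(s1 = 1e6))[1, 1], 5)    # max rule
  expect_equal(circrna_matrix(ev2, c(s1 = 1e6), "sum")[1, 1], 8)
  expect_equal(circrna_matrix(ev2, c(s1 = 1e6), "mean")[1, 1], 4)
  expect_equal(circrna_matrix(ev2, c(s1 = 2e6))[1, 1], 2.5)  # RPM scaling

  expect_error(circrna_matrix(ev2, c(s9 = 1e6)), "no total_mapped_reads")
})

test_that("log2 fold change uses the pseudocount and is antisymmetric", {
  expect_equal(log2fc(3, 3, 1), 0)
  expect_equal(log2fc(4, 1, 0), 2)
  expect_equal(log2fc(0, 0, 1), 0)
  expect_error(log2fc(0, 5, 0), "pseudocount")
  expect_error(log2fc(-1, 5), ">= 0")
  set.seed(8)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(log2fc(a, b, 1), -log2fc(b, a, 1))
  expect_equal(log2fc(a, b, 0.5), -log2fc(b, a, 0.5))
})

test_that("fold-change threshold counts split up- and downregulated", {
  expect_equal(fc_threshold_counts(rep(0, 5), 1.5),
               c(n_up = 0L, n_down = 0L))
  expect_equal(fc_threshold_counts(c(2, -2, 1), 1.5),
               c(n_up = 1L, n_down = 1L))
  ## boundary is exclusive: |fc| must exceed the threshold
  expect_equal(fc_threshold_counts(c(1.5, -1.5), 1.5),
               c(n_up = 0L, n_down = 0L))
  set.seed(4)
  fc <- round(rnorm(200, 0, 2), 2)
  got <- fc_threshold_counts(fc, 1.5)
  expect_equal(unname(got["n_up"]), sum(vapply(fc, function(x) x > 1.5, TRUE)))
  expect_equal(unname(got["n_down"]), sum(vapply(fc, function(x) x < -1.5, TRUE)))
})

test_that("cumulative share counts top rows reaching the expression fraction", {
  m <- matrix(c(75, 25), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(cumulative_share(m, "s1", 0.75), 1L)
  u <- matrix(rep(10, 8), ncol = 1, dimnames = list(letters[1:8], "s1"))
  expect_equal(cumulative_share(u, "s1", 1.0), 8L)
  z <- matrix(0, ncol = 1, nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_error(cumulative_share(z, "s1", 0.5), "no expression")

  set.seed(12)
  for (rep in 1:25) {
    v <- round(runif(sample(3:40, 1), 0, 1000), 1)
    if (sum(v) == 0) next
    mm <- matrix(v, ncol = 1, dimnames = list(NULL, "s"))
    for (f in c(0.1, 0.5, 0.75, 0.9, 1)) {
      expect_equal(cumulative_share(mm, "s", f), prefix_share_oracle(v, f))
    }
    ## non-decreasing in the fraction
    ks <- vapply(c(0.25, 0.5, 0.75, 1), function(f)
      cumulative_share(mm, "s", f), integer(1))
    expect_true(all(diff(ks) >= 0))
  }
})

corr_setup <- function(circ_vals, gene_vals) {
  samples <- paste0("s", seq_along(circ_vals))
  cm <- matrix(circ_vals, nrow = 1, dimnames = list("c1", samples))
  gm <- matrix(gene_vals, nrow = 1, dimnames = list("g1", samples))
  ann <- data.table::data.table(circ_id = "c1", category = "exonic",
                                gene_ids = "g1", gene_names = "G1")
  list(cm = cm, gm = gm, ann = ann)
}

test_that("perfect monotone pairs give rho of +1 and -1", {
  s <- corr_setup(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(correlate(s$cm, s$gm, s$ann)$rho, 1.0)
  s <- corr_setup(c(1, 2, 3, 4), c(40, 30, 20, 10))
  expect_equal(correlate(s$cm, s$gm, s$ann)$rho, -1.0)
})

test_that("tied vectors match the hand-computed average-rank correlation", {
  s <- corr_setup(c(1, 1, 2, 3), c(2, 5, 5, 9))
  got <- correlate(s$cm, s$gm, s$ann)
  expect_equal(got$rho, spearman_oracle(c(1, 1, 2, 3), c(2, 5, 5, 9)))
  expect_equal(got$n_samples, 4L)
  ## rho invariant under strictly increasing transforms
  s2 <- corr_setup(exp(c(1, 1, 2, 3)), c(2, 5, 5, 9)^3)
  expect_equal(correlate(s2$cm, s2$gm, s2$ann)$rho, got$rho)
})

test_that("non-computable pairs are omitted and counted", {
  ## constant circRNA vector
  s <- corr_setup(c(2, 2, 2, 2), c(1, 2, 3, 4))
  got <- correlate(s$cm, s$gm, s$ann)
  expect_equal(nrow(got), 0L)
  expect_equal(attr(got, "n_noncomputable"), 1L)
  ## too few shared samples
  s <- corr_setup(c(1, 2), c(5, 9))
  expect_equal(nrow(correlate(s$cm, s$gm, s$ann, min_samples = 3L)), 0L)
  expect_equal(nrow(correlate(s$cm, s$gm, s$ann, min_samples = 2L)), 1L)
  ## intergenic circRNAs (no gene) produce no pair at all
  ann0 <- data.table::data.table(circ_id = "c1", category = "intergenic",
                                 gene_ids = "", gene_names = "")
  s <- corr_setup(c(1, 2, 3, 4), c(1, 2, 3, 4))
  got0 <- correlate(s$cm, s$gm, ann0)
  expect_equal(nrow(got0), 0L)
  expect_equal(attr(got0, "n_noncomputable"), 0L)
})

test_that("gene matrices assemble FPKM by gene and sample", {
  mk <- function(sid, genes, fpkm) {
    structure(list(sample_id = sid,
                   expr = data.table::data.table(gene_id = genes, FPKM = fpkm,
                                                 raw_count = 1L),
                   total_mapped_reads = 1e6), class = "sample_expression")
  }
  gm <- gene_matrix(list(mk("s1", c("g1", "g2"), c(1, 2)),
                         mk("s2", c("g2", "g3"), c(5, 7))))
  expect_equal(dim(gm), c(3L, 2L))
  expect_equal(gm["g2", ], c(s1 = 2, s2 = 5))
  expect_equal(gm["g3", "s1"], 0)
  expect_error(gene_matrix(list(mk("s1", "g", 1), mk("s1", "g", 1))),
               "duplicate sample")
})
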