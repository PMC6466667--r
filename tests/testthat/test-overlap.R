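test_that("pearson_with_p matches closed forms and a reference t CDF", {
  x <- 1:20
  id <- pearson_with_p(x, x)
  expect_equal(id$r, 1)
  expect_equal(id$p, 0)

  # r ~ 0 gives p ~ 1: construct an exactly-orthogonal pair
  y <- c(1, -1, 1, -1, 1, -1)
  z <- c(1, 1, -1, -1, 1, -1) * 0 + rep(c(2, 2, 2), 2)  # constant -> flagged
  expect_true(pearson_with_p(y, z)$flagged)
  xo <- c(-1, 0, 1); yo <- c(1, -2, 1)   # cor exactly 0
  p0 <- pearson_with_p(xo, yo)
  expect_equal(p0$r, 0, tolerance = 1e-15)
  expect_equal(p0$p, 1, tolerance = 1e-12)

  # r = 0.5, n = 30: t = 0.5 sqrt(28) / sqrt(0.75) = 3.0551...
  t_ref <- 0.5 * sqrt(28) / sqrt(1 - 0.25)
  expect_equal(t_ref, 3.05505, tolerance = 1e-5)
  p_ref <- 2 * (1 - pt(t_ref, 28))   # independent CDF orientation
  # build vectors with cor exactly 0.5 via rotation
  set.seed(211)
  a <- rnorm(30); b <- rnorm(30)
  a <- (a - mean(a)) / sd(a); b <- resid(lm(b ~ a)); b <- b / sd(b)
  v <- 0.5 * a + sqrt(0.75) * b
  res <- pearson_with_p(a, v)
  expect_equal(res$r, 0.5, tolerance = 1e-10)
  expect_equal(res$p, p_ref, tolerance = 1e-10)
  expect_equal(res$p, 4.9e-3, tolerance = 2e-4)
})

test_that("GEBV-expression correlation records match an exhaustive loop", {
  set.seed(221)
  n <- 30
  g <- random_genotypes(n, 20, chrom_len = 1.2e6, seed = 222)
  a <- rnorm(20)
  w <- make_windows(g$variants)
  lg <- local_gebv(g, a, w)
  genes <- data.frame(gene = c("g1", "g2"), chrom = 1L,
                      start = c(2e5, 9e5), end = c(2.5e5, 9.5e5))
  counts <- matrix(rnbinom(2 * n, size = 3, mu = 25), 2, n)
  e <- toy_expression(counts, genes)
  co <- correlate_gebv_expression(lg, e, radius = 3e5, residualize = FALSE)
  # exhaustive double loop with pearson_with_p
  Y <- log1p(counts)
  cnt <- 0
  for (k in seq_len(nrow(w)))
    for (i in 1:2) {
      near <- genes$end[i] >= w$start[k] - 3e5 &
        genes$start[i] < w$end[k] + 3e5
      if (!near) next
      cnt <- cnt + 1
      ref <- pearson_with_p(lg$gebv[k, ], Y[i, ])
      row <- co[co$window == w$window[k] & co$gene == genes$gene[i], ]
      expect_equal(nrow(row), 1)
      if (!is.na(ref$r)) {
        expect_equal(row$r, ref$r, tolerance = 1e-10)
        expect_equal(row$p, ref$p, tolerance = 1e-10)
      }
    }
  expect_equal(nrow(co), cnt)

  # planted identity: a gene whose expression equals a window's GEBV
  e2 <- e
  k <- which.max(lg$var)
  e2$counts[1, ] <- round(expm1(pmax(lg$gebv[k, ], 0)))
  e2$genes$start[1] <- w$start[k]; e2$genes$end[1] <- w$start[k] + 1e4
  gebv_like <- log1p(e2$counts[1, ])
  co2 <- correlate_gebv_expression(lg, e2, radius = 3e5, residualize = FALSE)
  row <- co2[co2$window == w$window[k] & co2$gene == "g1", ]
  expect_equal(row$r, cor(lg$gebv[k, ], gebv_like), tolerance = 1e-10)

  # gene far beyond the radius of every window yields no record
  e3 <- e
  e3$genes$chrom <- 9L
  expect_equal(nrow(correlate_gebv_expression(lg, e3, radius = 3e5)), 0)
})

test_that("genotype-GEBV correlations match pearson_with_p by hand", {
  dos <- cbind(c(0, 1, 2, 1, 0), c(2, 2, 0, 1, 1))
  g <- toy_genotypes(dos, pos = c(1000, 2000))
  w <- make_windows(g$variants)
  a <- c(1.5, -0.5)
  lg <- local_gebv(g, a, w)
  gg <- correlate_genotype_gebv(g, lg)
  for (r in seq_len(nrow(gg))) {
    k <- which(lg$windows$window == gg$window[r])
    j <- match(gg$variant[r], g$variants$id)
    ref <- pearson_with_p(dos[, j], lg$gebv[k, ])
    expect_equal(gg$r[r], ref$r, tolerance = 1e-12)
    expect_equal(gg$p[r], ref$p, tolerance = 1e-12)
  }
  # single-variant window: |r| = 1 with its own GEBV
  g1 <- toy_genotypes(dos[, 1, drop = FALSE], pos = 1000)
  w1 <- make_windows(g1$variants)
  lg1 <- local_gebv(g1, 2, w1)
  gg1 <- correlate_genotype_gebv(g1, lg1)
  expect_equal(abs(gg1$r), rep(1, nrow(gg1)))
})

test_that("permutation comparison is deterministic with calibrated nulls", {
  g <- random_genotypes(60, 24, chrom_len = 1.2e6, seed = 231)
  a <- rnorm(24)
  w <- make_windows(g$variants)
  genes <- data.frame(gene = paste0("g", 1:3), chrom = 1L,
                      start = c(2e5, 6e5, 1e6), end = c(2.2e5, 6.2e5, 1.02e6))
  set.seed(232)
  e <- toy_expression(matrix(rnbinom(3 * 60, size = 3, mu = 25), 3, 60), genes)
  pc1 <- permutation_comparison(g, a, w, e, reps = 5, seed = 3)
  pc2 <- permutation_comparison(g, a, w, e, reps = 5, seed = 3)
  expect_identical(pc1$permuted, pc2$permuted)
  # all effects zero: observed and permuted counts all zero (constant GEBVs
  # are flagged, never counted)
  pc0 <- permutation_comparison(g, rep(0, 24), w, e, reps = 3, seed = 4)
  expect_equal(pc0$observed, 0L)
  expect_true(all(pc0$permuted == 0L))
})

test_that("top-k selection matches a sort oracle and reports shares", {
  set.seed(241)
  nw <- 10
  start <- seq(1, by = 3e5, length.out = nw)
  w <- data.frame(window = 1:nw, chrom = 1L, start = start, end = start + 250000)
  v <- runif(nw, 0, 5)
  lg <- structure(list(windows = w, gebv = matrix(0, nw, 2), var = v),
                  class = "LocalGebvSet")
  rk <- rank_nonoverlapping(lg)   # disjoint windows: all accepted
  expect_equal(rk$U, nw)
  top3 <- select_top_k(rk, 3)
  expect_equal(top3$window, order(-v)[1:3])
  expect_equal(attr(top3, "share_pct"), 100 * sum(sort(v, TRUE)[1:3]) / sum(v),
               tolerance = 1e-10)
  top1 <- select_top_k(rk, 1)
  expect_equal(top1$window, which.max(v))
  all_k <- select_top_k(rk, nw)
  expect_equal(attr(all_k, "share_pct"), 100, tolerance = 1e-10)
  over <- select_top_k(rk, nw + 5)
  expect_true(attr(over, "short"))
  expect_equal(nrow(over), nw)
})

test_that("random-k selection is deterministic, uniform and non-overlapping", {
  nw <- 8
  start <- seq(1, by = 3e5, length.out = nw)   # all disjoint
  w <- data.frame(window = 1:nw, chrom = 1L, start = start,
                  end = start + 250000)
  s1 <- select_random_k(w, 8, seed = 5)
  expect_setequal(s1$window, 1:8)              # k = size of disjoint set
  expect_identical(select_random_k(w, 3, seed = 9)$window,
                   select_random_k(w, 3, seed = 9)$window)
  # uniformity: k = 1 draws each window ~ 1/8 of the time
  draws <- vapply(1:1000, function(s) select_random_k(w, 1, seed = s)$window,
                  integer(1))
  freq <- tabulate(draws, nw) / 1000
  se <- sqrt((1 / 8) * (7 / 8) / 1000)
  expect_true(all(abs(freq - 1 / 8) < 3.5 * se))
  # overlapping candidates never co-selected
  w2 <- data.frame(window = 1:3, chrom = 1L, start = c(1, 100001, 600001),
                   end = c(250001, 350001, 850001))
  for (s in 1:20) {
    sel <- select_random_k(w2, 2, seed = s)
    expect_false(all(c(1, 2) %in% sel$window))
  }
  expect_error(select_random_k(w2, 3, seed = 1), "non-overlapping")
})

test_that("enrichment predicates follow the filter chain on planted cases", {
  # one window with a shared causal variant: eQTL hit + genotype-GEBV hit +
  # GEBV-expression correlation with consistent signs -> all predicates
  w <- data.frame(window = 1:2, chrom = 1L, start = c(1, 600001),
                  end = c(250001, 850001))
  genes <- data.frame(gene = c("gA", "gB"), chrom = 1L,
                      start = c(5e4, 6.5e5), end = c(6e4, 6.6e5))
  eqtl_stats <- data.frame(
    variant = c("v1", "v9"), chrom = 1L, pos = c(1e5, 7e5),
    gene = c("gA", "gB"), beta = c(1, 1), se = 1, z = 5,
    p = c(1e-8, 1e-8), n = 100, direction = c(1, 1), study = "e")
  geno_gebv <- data.frame(window = c(1L, 2L), variant = c("v1", "v9"),
                          chrom = 1L, pos = c(1e5, 7e5), r = c(0.9, 0.9),
                          p = c(1e-8, 0.5))
  gebv_expr <- data.frame(window = c(1L, 2L), chrom = 1L,
                          start = w$start, end = w$end,
                          gene = c("gA", "gB"), r = c(0.8, 0.8),
                          p = c(1e-6, 0.5), n = 100,
                          selected = c(TRUE, FALSE))
  fl <- enrichment_flags(w, eqtl_stats, geno_gebv, gebv_expr, genes)
  # window 1: E, G, EG, C, EC, EGC all hold (signs: +1 * +0.9 -> + matches +0.8)
  expect_equal(unname(fl[1, ]), rep(TRUE, 6))
  # window 2: eQTL only
  expect_equal(unname(fl[2, ]), c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))

  cts <- enrichment_counts(w, fl, "both")
  expect_equal(cts$nE, 2); expect_equal(cts$nEGC, 1)
  # chain invariants
  expect_lte(cts$nEG, min(cts$nE, cts$nG))
  expect_lte(cts$nEC, min(cts$nE, cts$nC))
  expect_lte(cts$nEGC, cts$nEG)

  # inconsistent sign breaks EGC but not EG
  gebv_expr2 <- gebv_expr; gebv_expr2$r[1] <- -0.8
  fl2 <- enrichment_flags(w, eqtl_stats, geno_gebv, gebv_expr2, genes)
  expect_true(fl2[1, "EG"]); expect_false(fl2[1, "EGC"])

  # empty set -> all zero
  cts0 <- enrichment_counts(w[0, ], fl, "empty")
  expect_true(all(cts0[, c("nE", "nG", "nEG", "nC", "nEC", "nEGC")] == 0))
})

test_that("the FDR estimator reproduces its defining identities", {
  # exactly as many significant calls as expected by chance -> FDR = 1
  expect_equal(fdr(100, 1e5, 1e-3), 1)
  # homogeneity: doubling n_sign and n_tests leaves FDR unchanged
  expect_equal(fdr(50, 1e4, 1e-3), fdr(100, 2e4, 1e-3))
  expect_warning(out <- fdr(0, 100, 0.01), "undefined")
  expect_true(is.na(out))
  expect_error(fdr(10, 5, 0.01))
})
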