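test_that("variant filtering applies the MAF floor and removes r2 = 1 pairs", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 0)
  dup <- cbind(x, x, 2 - x)               # col2 duplicates col1, col3 mirrors
  rare <- c(rep(0, 7), 1)                 # MAF 1/16 = 0.0625
  g <- toy_genotypes(cbind(dup, rare))
  f <- filter_variants(g, maf_floor = 0.1, r2_cap = 0.9)
  # duplicate and mirrored columns pruned (r2 = 1), rare column dropped by MAF
  expect_identical(attr(f, "kept"), 1L)

  # MAF boundary: a frequency exactly at the floor is retained
  n <- 1000
  low <- c(rep(1, 2), rep(0, n - 2))      # af = 0.001
  at <- c(rep(1, 4), rep(0, n - 4))       # af = 0.002
  g2 <- toy_genotypes(cbind(low, at, rbinom(n, 2, 0.5)))
  f2 <- filter_variants(g2, maf_floor = 0.002, r2_cap = 0.9)
  expect_identical(attr(f2, "kept"), c(2L, 3L))
})

test_that("greedy LD pruning matches an exhaustive sweep oracle", {
  set.seed(21)
  for (rep in 1:5) {
    g <- random_genotypes(40, 6, seed = 100 + rep)
    # make some columns correlated
    g$dosages[, 2] <- g$dosages[, 1]
    g$dosages[, 5] <- pmin(2, g$dosages[, 4] + rbinom(40, 1, 0.1))
    g <- toy_genotypes(g$dosages, pos = g$variants$pos)
    cap <- 0.6
    # oracle: literal greedy left-to-right sweep over all pairs
    kept <- integer(0)
    for (j in 1:6) {
      ok <- TRUE
      for (k in kept) {
        r <- suppressWarnings(cor(g$dosages[, j], g$dosages[, k]))
        if (!is.na(r) && r^2 > cap) ok <- FALSE
      }
      if (ok) kept <- c(kept, j)
    }
    f <- filter_variants(g, maf_floor = 0, r2_cap = cap, window_bp = 1e9)
    expect_identical(attr(f, "kept"), kept)
  }
})

test_that("GRM equals the hand-computed VanRaden matrix", {
  dos <- rbind(c(0, 1, 2, 1),
               c(1, 2, 0, 1),
               c(2, 1, 1, 0))
  g <- toy_genotypes(dos)
  p <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * p)
  G_hand <- Z %*% t(Z) / (2 * sum(p * (1 - p)))
  grm <- compute_grm(g)
  expect_equal(unname(grm$mat), unname(G_hand), tolerance = 1e-12)
  expect_equal(grm$mat, t(grm$mat))
  expect_equal(colSums(Z), rep(0, 4), tolerance = 1e-12)

  # clones: off-diagonal equals the diagonal entries
  dos2 <- rbind(c(0, 2, 1, 1), c(0, 2, 1, 1), c(2, 0, 1, 2))
  g2 <- toy_genotypes(dos2)
  G2 <- compute_grm(g2)$mat
  expect_equal(G2[1, 2], G2[1, 1], tolerance = 1e-12)
  expect_equal(G2[1, 2], G2[2, 2], tolerance = 1e-12)
  expect_error(compute_grm(toy_genotypes(matrix(2, 4, 3))), "polymorphic")
})

test_that("null-model REML behaves on null and heritable phenotypes", {
  set.seed(31)
  n <- 1000
  g <- random_genotypes(n, 300, seed = 32)
  grm <- compute_grm(g)
  X <- matrix(1, n, 1)

  y_null <- rnorm(n)
  vc0 <- fit_null_variance(y_null, X, grm)
  expect_lt(vc0$h2, 0.1)

  # heritable: genetic values from the GRM-implied covariance
  ed <- eigen(grm$mat, symmetric = TRUE)
  gval <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * rnorm(n))
  gval <- gval / sd(gval) * sqrt(0.5)
  y <- drop(gval) + rnorm(n, sd = sqrt(0.5))
  vc <- fit_null_variance(y, X, grm)
  expect_gt(vc$h2, 0.35)
  expect_lt(vc$h2, 0.65)

  expect_error(fit_null_variance(rep(1, n), X, grm), "zero variance")
  expect_error(fit_null_variance(y, cbind(X, X), grm), "singular")
})

test_that("EMMAX with identity GRM reproduces OLS exactly", {
  set.seed(41)
  n <- 150
  g <- random_genotypes(n, 50, seed = 42)
  breed <- rep(c("A", "B"), length.out = n)
  g$individuals$breed <- breed
  X <- model.matrix(~ breed)
  y <- rnorm(n) + 0.3 * g$dosages[, 7]
  vc <- fit_null_variance(y, X, grm = NULL)
  st <- gwas_scan(g, y, X, grm = NULL, vc = vc)
  for (j in c(1, 7, 20)) {
    f <- summary(lm(y ~ g$dosages[, j] + breed))$coefficients
    expect_equal(st$beta[j], f[2, "Estimate"], tolerance = 1e-10)
    expect_equal(st$se[j], f[2, "Std. Error"], tolerance = 1e-10)
    expect_equal(st$p[j], f[2, "Pr(>|t|)"], tolerance = 1e-8)
  }
  # z = beta / se invariant
  ok <- !is.na(st$z)
  expect_lt(max(abs(st$z[ok] - st$beta[ok] / st$se[ok])), 1e-6)
  # monomorphic variant yields missing statistics, not an error
  g$dosages[, 3] <- 1
  st2 <- gwas_scan(g, y, X, grm = NULL, vc = vc)
  expect_true(is.na(st2$p[3]))
})

test_that("a QTL explaining 5% of variance is detected at n = 2000", {
  hits <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 2000
    x <- rbinom(n, 2, 0.3)
    y <- x * sqrt(0.05 / var(x)) + rnorm(n, sd = sqrt(0.95))
    g <- toy_genotypes(cbind(x, rbinom(n, 2, 0.4)))
    st <- gwas_scan(g, y, matrix(1, n, 1), grm = NULL,
                    vc = fit_null_variance(y, matrix(1, n, 1), NULL))
    if (st$p[1] < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("scan p-values are calibrated under permutation", {
  set.seed(51)
  n <- 300; m <- 400
  g <- random_genotypes(n, m, seed = 52)
  y <- sample(rnorm(n))
  st <- gwas_scan(g, y, matrix(1, n, 1), grm = NULL,
                  vc = fit_null_variance(y, matrix(1, n, 1), NULL))
  frac <- mean(st$p < 0.01, na.rm = TRUE)
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / m))
})

test_that("weighted z-score meta-analysis closed forms hold", {
  mk <- function(z, n) {
    p <- 2 * pnorm(-abs(z))
    structure(data.frame(variant = "v1", chrom = 1L, pos = 100L,
                         beta = z, se = 1, z = z, p = p, n = n,
                         direction = sign(z), study = "s"),
              class = c("AssocStats", "data.frame"))
  }
  one <- meta_weighted_z(list(mk(1.7, 100)))
  expect_equal(one$z, 1.7, tolerance = 1e-12)

  two <- meta_weighted_z(list(mk(2.2, 400), mk(2.2, 400)))
  expect_equal(two$z, 2.2 * sqrt(2), tolerance = 1e-12)

  cancel <- meta_weighted_z(list(mk(2, 400), mk(-2, 400)))
  expect_equal(cancel$z, 0, tolerance = 1e-12)
  expect_equal(cancel$p, 1, tolerance = 1e-12)

  # meta of a stratum with itself preserves the p-value ordering
  set.seed(61)
  zs <- rnorm(20)
  sts <- structure(data.frame(variant = paste0("v", 1:20), chrom = 1L,
                              pos = 1:20 * 100L, beta = zs, se = 1, z = zs,
                              p = 2 * pnorm(-abs(zs)), n = 50,
                              direction = sign(zs), study = "s"),
                   class = c("AssocStats", "data.frame"))
  m2 <- meta_weighted_z(list(sts, sts))
  expect_identical(order(m2$p), order(sts$p))
})

test_that("QTL selection follows the greedy spacing rule", {
  mk_stats <- function(pos, p, chrom = rep(1L, length(pos))) {
    structure(data.frame(variant = paste0("v", seq_along(pos)), chrom = chrom,
                         pos = pos, beta = 1, se = 1, z = 1, p = p,
                         n = 10, direction = 1, study = "s"),
              class = c("AssocStats", "data.frame"))
  }
  # hand-walk: 1.0, 1.5, 2.6 Mb with p 1e-9, 1e-8, 1e-7 -> leads at 1.0, 2.6
  st <- mk_stats(c(1.0e6, 1.5e6, 2.6e6), c(1e-9, 1e-8, 1e-7))
  q <- select_qtl(st, 1e-6, 1e6)
  expect_equal(q$pos, c(1.0e6, 2.6e6))

  # boundary: exactly 1 Mb apart -> both kept ("at least 1 Mb between")
  st2 <- mk_stats(c(1e6, 2e6), c(1e-9, 1e-8))
  expect_equal(nrow(select_qtl(st2, 1e-6, 1e6)), 2)

  # no significant variant -> empty
  expect_equal(nrow(select_qtl(mk_stats(1e6, 1e-3), 1e-6, 1e6)), 0)

  # order invariance given the tie-break rule
  set.seed(71)
  pos <- sort(sample.int(1e7, 30))
  p <- 10^-runif(30, 5, 12)
  st3 <- mk_stats(pos, p)
  shuf <- sample.int(30)
  st4 <- mk_stats(pos[shuf], p[shuf])
  q3 <- select_qtl(st3, 1e-6, 1e6)
  q4 <- select_qtl(st4, 1e-6, 1e6)
  expect_equal(q3$pos, q4$pos)
})
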