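test_that("genotype simulation is deterministic and respects its invariants", {
  g1 <- simulate_genotypes(c(A = 80, B = 40), m_variants = 300,
                           chrom_lengths = c(3e6, 3e6), seed = 5)
  g2 <- simulate_genotypes(c(A = 80, B = 40), m_variants = 300,
                           chrom_lengths = c(3e6, 3e6), seed = 5)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% 0:2))
  for (ch in 1:2) {
    pos <- g1$variants$pos[g1$variants$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_error(simulate_genotypes(c(A = 0), m_variants = 10),
               "non-positive")
  expect_error(simulate_genotypes(c(A = 10), m_variants = 1), "m_variants")
})

test_that("dosage means track breed allele frequencies", {
  # combined sampling variance: founder pool of K haplotypes plus 2n draws
  g <- simulate_genotypes(c(A = 400), m_variants = 400,
                          chrom_lengths = 4e6, fst = 0, n_founders = 30,
                          seed = 11)
  p_target <- attr(g, "breed_af")[, "A"]
  p_obs <- colMeans(g$dosages) / 2
  se <- sqrt(p_target * (1 - p_target) * (1 / 60 + 1 / (2 * 400)))
  frac_ok <- mean(abs(p_obs - p_target) <= 4 * se)
  expect_gt(frac_ok, 0.99)
})

test_that("cross-breed allele frequency divergence follows Balding-Nichols", {
  # fst = 0.1, ancestral p drawn in (0.05, 0.95): E[(p_A - p_B)^2] per variant
  # is 2 * p(1-p) * fst; check the standardized mean over many variants.
  g <- simulate_genotypes(c(A = 30, B = 30), m_variants = 3000,
                          chrom_lengths = c(5e6, 5e6), fst = 0.1, seed = 13)
  ba <- attr(g, "breed_af")
  # recover ancestral expectation per variant from the Beta construction:
  # var(p_b) = p(1-p) fst around the ancestral p, breeds independent
  d2 <- (ba[, 1] - ba[, 2])^2
  p_mid <- (ba[, 1] + ba[, 2]) / 2
  ratio <- mean(d2) / mean(2 * 0.1 * p_mid * (1 - p_mid))
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.35)

  g0 <- simulate_genotypes(c(A = 30, B = 30), m_variants = 500,
                           chrom_lengths = 5e6, fst = 0, seed = 13)
  ba0 <- attr(g0, "breed_af")
  expect_identical(ba0[, 1], ba0[, 2])  # no divergence beyond sampling
})

test_that("LD decays with distance and vanishes at tiny block scale", {
  g <- simulate_genotypes(c(A = 300), m_variants = 400, chrom_lengths = 4e6,
                          ld_block_scale = 5e4, fst = 0, seed = 17)
  v <- g$variants
  cc <- suppressWarnings(cor(g$dosages))
  d <- abs(outer(v$pos, v$pos, "-")) + ifelse(outer(v$chrom, v$chrom, "!="), 1e9, 0)
  ut <- upper.tri(d)
  near <- mean(cc[ut][d[ut] < 0.1 * 5e4]^2, na.rm = TRUE)
  far <- mean(cc[ut][d[ut] > 10 * 5e4 & d[ut] < 1e8]^2, na.rm = TRUE)
  expect_gt(near, far)

  gf <- simulate_genotypes(c(A = 300), m_variants = 200, chrom_lengths = 2e6,
                           ld_block_scale = 1, fst = 0, seed = 18)
  ccf <- suppressWarnings(cor(gf$dosages))
  mean_r2 <- mean(ccf[upper.tri(ccf)]^2, na.rm = TRUE)
  expect_lt(mean_r2, 3 / 300)  # consistent with sampling noise ~ 1/n
})

test_that("implant_truth handles overlap structure and determinism", {
  g <- random_genotypes(60, 100, seed = 2)
  full <- implant_truth(g, 5, 5, 5, seed = 3)
  expect_setequal(full$trait_causals$variant, full$expr_causals$variant)
  expect_length(full$shared, 5)

  disj <- implant_truth(g, 5, 5, 0, seed = 3)
  expect_length(intersect(disj$trait_causals$variant,
                          disj$expr_causals$variant), 0)

  t1 <- implant_truth(g, 4, 6, 2, seed = 9)
  t2 <- implant_truth(g, 4, 6, 2, seed = 9)
  expect_identical(t1, t2)
  expect_error(implant_truth(g, 5, 5, 6, seed = 1), "n_shared")
  # all causals respect the MAF floor
  maf <- pmin(g$variants$af, 1 - g$variants$af)
  expect_true(all(maf[t1$trait_causals$variant] >= 0.05))
})

test_that("phenotypes are exact in the noise-free limit and recover h2", {
  g <- random_genotypes(200, 50, seed = 4)
  tr <- implant_truth(g, 5, 5, 2, seed = 5)
  ph <- simulate_phenotypes(g, tr, h2 = 0.3,
                            accuracy = c(male = 1, female = 1), seed = 6)
  gv <- attr(ph, "genetic_values")$trait
  expect_equal(ph$deviation, unname(gv), tolerance = 1e-12)
  expect_equal(var(gv), 0.3, tolerance = 1e-10)  # rescaled exactly

  # realized genetic/phenotypic variance ratio approximates h2 when
  # accuracy = sqrt(h2) (an own-performance record)
  gl <- random_genotypes(5000, 60, seed = 7)
  trl <- implant_truth(gl, 10, 10, 0, seed = 8)
  h2 <- 0.5
  phl <- simulate_phenotypes(gl, trl, h2 = h2,
                             accuracy = c(male = sqrt(h2),
                                          female = sqrt(h2)), seed = 9)
  ratio <- var(attr(phl, "genetic_values")$trait) / var(phl$deviation)
  expect_gt(ratio, 0.9 * h2)
  expect_lt(ratio, 1.1 * h2)
  expect_error(simulate_phenotypes(g, tr, h2 = 0.3,
                                   accuracy = c(male = 1.2, female = 0.5)),
               "accuracy")
})

test_that("null phenotypes show no association with causal dosages", {
  g <- random_genotypes(400, 100, seed = 10)
  tr <- implant_truth(g, 20, 5, 0, seed = 11)
  tr$trait_causals$effect[] <- 0
  ph <- simulate_phenotypes(g, tr, h2 = 0.3, seed = 12)
  y <- ph$deviation
  z <- apply(g$dosages[, tr$trait_causals$variant], 2, function(x) {
    f <- summary(lm(y ~ x))$coefficients
    f["x", "t value"]
  })
  expect_gte(mean(abs(z) < 4), 0.99)
})

test_that("expression counts follow the generative model", {
  g <- random_genotypes(131, 40, seed = 13)
  tr <- implant_truth(g, 2, 2, 0, expr_effect_sd = 1.5, seed = 14)
  e <- simulate_expression(g, tr, n_genes = 30, cows = seq_len(131), seed = 15)
  expect_s3_class(e, "ExpressionSet")
  expect_true(all(e$counts >= 0))
  expect_true(all(e$counts == round(e$counts)))
  expect_equal(ncol(e$counts), 131)
  expect_identical(nrow(e$counts), 30L)
  # determinism
  e2 <- simulate_expression(g, tr, n_genes = 30, cows = seq_len(131), seed = 15)
  expect_identical(e$counts, e2$counts)
  # registry genes carry their eQTL signal: dosage association of log counts
  eq <- tr$expr_causals[1, ]
  y <- log1p(e$counts[eq$gene, ])
  x <- g$dosages[, eq$variant]
  f <- summary(lm(y ~ x))$coefficients
  expect_lt(f["x", "Pr(>|t|)"], 1e-4)
  expect_equal(sign(f["x", "Estimate"]), sign(eq$effect))
})

test_that("zero eQTL effect gives calibrated null slopes", {
  set.seed(16)
  zs <- replicate(120, {
    g <- random_genotypes(100, 1, seed = sample.int(1e6, 1))
    x <- g$dosages[, 1]
    mu <- exp(3)
    y <- log1p(rnbinom(100, size = 1 / 0.3, mu = mu))
    if (sd(x) == 0) return(0)
    summary(lm(y ~ x))$coefficients["x", "t value"]
  })
  expect_gte(mean(abs(zs) < 4), 0.99)
})

test_that("vanishing dispersion approaches the Poisson limit", {
  g <- random_genotypes(200, 5, seed = 17)
  tr <- implant_truth(g, 1, 1, 0, seed = 18)
  e <- simulate_expression(g, tr, n_genes = 10, cows = seq_len(200),
                           dispersion = 0, baseline_log_mean = 5,
                           covariate_effects = list(breed = 0, parity = 0,
                                                    dim = 0, batch = 0),
                           seed = 19)
  bg <- setdiff(e$genes$gene, tr$expr_causals$gene)
  cnt <- e$counts[bg, ]
  mu <- exp(5)
  # Poisson: mean ~ mu and var ~ mu (a negative binomial would exceed it)
  expect_lt(abs(mean(cnt) - mu) / mu, 0.05)
  expect_lt(var(as.numeric(cnt)) / mu, 1.5)
  expect_error(simulate_expression(g, tr, n_genes = 10, dispersion = -1),
               "dispersion")
})
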