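# Mixed-model single-variant association machinery: variant filtering, the
# genomic relationship matrix, null-model REML, an EMMAX-style scan, weighted
# z-score meta-analysis and greedy QTL lead selection.

P_FLOOR <- 1e-300  # representable p-value floor used before meta z transforms

#' Filter variants by MAF and greedy LD pruning
#'
#' Removes variants whose minor allele frequency falls below `maf_floor`, then
#' prunes by LD with a greedy left-to-right sweep: a variant is kept iff its
#' squared correlation with every already-kept variant within `window_bp`
#' upstream is at most `r2_cap` (the earlier variant is always the one kept).
#'
#' @param g a `GenotypeSet`.
#' @param maf_floor minimum minor allele frequency (default 0.002).
#' @param r2_cap maximum allowed pairwise r-squared (default 0.9).
#' @param window_bp trailing scan window in bp for the pruning sweep.
#' @return A filtered `GenotypeSet`; kept column indices relative to the
#'   input are stored in `attr(, "kept")`.
#' @export
filter_variants <- function(g, maf_floor = 0.002, r2_cap = 0.9,
                            window_bp = 5e5) {
  stopifnot(maf_floor >= 0, maf_floor < 0.5, r2_cap > 0, r2_cap <= 1)
  af <- colMeans(g$dosages) / 2
  maf <- pmin(af, 1 - af)
  cand <- which(maf >= maf_floor)
  n <- nrow(g$dosages)
  X <- g$dosages
  sds <- apply(X, 2, sd)
  kept <- integer(0)
  for (ch in unique(g$variants$chrom)) {
    idx <- cand[g$variants$chrom[cand] == ch]
    buf <- integer(0)  # kept variants on this chromosome
    for (j in idx) {
      if (length(buf)) {
        near <- buf[g$variants$pos[buf] > g$variants$pos[j] - window_bp]
        if (length(near) && sds[j] > 0) {
          xc <- (X[, j] - mean(X[, j])) / sds[j]
          r <- colSums(xc * ((X[, near, drop = FALSE] -
                                rep(colMeans(X[, near, drop = FALSE]),
                                    each = n)) /
                               rep(sds[near], each = n))) / (n - 1)
          r[!is.finite(r)] <- 0
          if (any(r^2 > r2_cap)) next
        }
      }
      buf <- c(buf, j)
    }
    kept <- c(kept, buf)
  }
  kept <- sort(kept)
  out <- subset_genotypes(g, variants = kept)
  attr(out, "kept") <- kept
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p (1 - p))` where `Z` is the dosage matrix centered by
#' twice the allele frequency. A small ridge is *not* added here; it is added
#' before eigendecomposition in [fit_null_variance()].
#'
#' @param g a `GenotypeSet` with at least two polymorphic variants.
#' @return An object of class `Grm`: list with elements `mat` (n x n) and
#'   `ids`.
#' @export
compute_grm <- function(g) {
  p <- colMeans(g$dosages) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic variants for a GRM")
  Z <- sweep(g$dosages, 2, 2 * p)
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  mat <- tcrossprod(Z) / denom
  structure(list(mat = mat, ids = g$individuals$id), class = "Grm")
}

#' @export
print.Grm <- function(x, ...) {
  cat(sprintf("Grm: %d x %d, mean diagonal %.3f\n",
              nrow(x$mat), ncol(x$mat), mean(diag(x$mat))))
  invisible(x)
}

# Eigendecomposition of G + ridge*I, reusable across traits/genes.
grm_eigen <- function(grm, ridge = 1e-6) {
  if (is.null(grm)) return(NULL)
  ed <- eigen(grm$mat + diag(ridge, nrow(grm$mat)), symmetric = TRUE)
  if (min(ed$values) < -1e-8)
    stop("GRM is not positive semi-definite after ridge")
  ed$values <- pmax(ed$values, 0)
  ed
}

# Profile REML log-likelihood on the GRM eigenbasis for a given ratio
# lambda = sigma2_g / sigma2_e. yr, Xr are rotated responses/designs.
reml_ll <- function(log_lambda, yr, Xr, d) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  w <- 1 / v
  Xw <- Xr * sqrt(w)
  yw <- yr * sqrt(w)
  A <- crossprod(Xw)
  bhat <- solve(A, crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% bhat)^2)
  n <- length(yr); p <- ncol(Xr)
  -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) +
            determinant(A, logarithm = TRUE)$modulus[1])
}

#' REML variance components under the null model
#'
#' Restricted maximum likelihood estimates of the genetic and residual
#' variance for `y = X b + g + e`, `g ~ N(0, sigma2_g G)`, obtained by 1-D
#' optimisation of the profile REML likelihood over the variance ratio on the
#' GRM eigenbasis. A ridge of `1e-6` is added to the GRM diagonal before
#' decomposition.
#'
#' @param y phenotype vector.
#' @param covariates fixed-effect design matrix (including intercept).
#' @param grm a `Grm`, or `NULL` for an identity relationship matrix.
#' @param eigen_grm optional precomputed result of the internal
#'   eigendecomposition, to share across traits.
#' @return A list of class `VarComp`: `sigma2_g`, `sigma2_e`, `lambda`, `h2`,
#'   `loglik`, plus the rotation (`eigen`) reused by [gwas_scan()].
#' @export
fit_null_variance <- function(y, covariates, grm, eigen_grm = NULL) {
  X <- as.matrix(covariates)
  if (length(y) != nrow(X)) stop("length(y) must match the design")
  if (var(y) == 0) stop("phenotype has zero variance")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is singular")
  if (is.null(grm) && is.null(eigen_grm)) {
    # identity relationships: variance ratio is unidentifiable; fall back to
    # an OLS residual variance split
    rss <- sum(qr.resid(qr(X), y)^2)
    s2 <- rss / (length(y) - ncol(X))
    return(structure(list(sigma2_g = 0, sigma2_e = s2, lambda = 0,
                          h2 = 0, loglik = NA_real_, eigen = NULL),
                     class = "VarComp"))
  }
  ed <- if (is.null(eigen_grm)) grm_eigen(grm) else eigen_grm
  yr <- drop(crossprod(ed$vectors, y))
  Xr <- crossprod(ed$vectors, X)
  opt <- optimize(reml_ll, c(-12, 12), yr = yr, Xr = Xr, d = ed$values,
                  maximum = TRUE, tol = 1e-8)
  lambda <- exp(opt$maximum)
  v <- lambda * ed$values + 1
  w <- 1 / v
  Xw <- Xr * sqrt(w); yw <- yr * sqrt(w)
  bhat <- solve(crossprod(Xw), crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% bhat)^2)
  sigma2_e <- rss / (length(y) - ncol(X))
  structure(list(sigma2_g = lambda * sigma2_e, sigma2_e = sigma2_e,
                 lambda = lambda, h2 = lambda / (lambda + 1),
                 loglik = opt$objective, eigen = ed),
            class = "VarComp")
}

# Core per-variant GLS scan on a (possibly rotated) basis with weights w.
# Returns beta, se, z (= t statistic), p from a t test with n - p - 1 df;
# the residual scale is re-estimated per variant while the covariance
# *structure* stays fixed at the null-model estimate (EMMAX approximation).
gls_scan_core <- function(yw, Xw, Zw, n_eff) {
  p <- ncol(Xw)
  A <- crossprod(Xw)
  Ainv <- solve(A)
  f <- drop(crossprod(Xw, yw))
  B <- crossprod(Xw, Zw)              # p x m
  cj <- colSums(Zw^2)
  dj <- drop(crossprod(Zw, yw))
  AinvB <- Ainv %*% B
  denom <- cj - colSums(B * AinvB)
  num <- dj - drop(crossprod(B, Ainv %*% f))
  rss0 <- sum(yw^2) - drop(crossprod(f, Ainv %*% f))
  bad0 <- !is.finite(denom) | denom <= 1e-12
  denom[bad0] <- NA
  beta <- num / denom
  rss <- pmax(rss0 - beta^2 * denom, 0)
  df <- n_eff - p - 1
  se <- suppressWarnings(sqrt(rss / df / denom))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  bad <- !is.finite(beta) | bad0 | !is.finite(se) | se == 0
  beta[bad] <- NA; se[bad] <- NA; tstat[bad] <- NA; pval[bad] <- NA
  list(beta = beta, se = se, z = tstat, p = pval)
}

new_assoc_stats <- function(df) {
  df$p <- ifelse(is.na(df$p), NA, pmax(df$p, P_FLOOR))
  structure(df, class = c("AssocStats", "data.frame"))
}

#' Mixed-model GWAS scan (EMMAX approximation)
#'
#' Per-variant generalized-least-squares effect and test with the covariance
#' structure fixed at the null REML estimate. With an identity relationship
#' matrix the scan reduces exactly to ordinary least squares with the same
#' fixed effects. Monomorphic variants are returned with missing statistics
#' rather than raising an error.
#'
#' @param g a `GenotypeSet`.
#' @param y phenotype vector, one entry per individual in `g`.
#' @param covariates fixed-effect design matrix (intercept, breed, ...).
#' @param grm a `Grm` or `NULL` (identity).
#' @param vc `VarComp` from [fit_null_variance()] on the same `(y, grm)`.
#' @param study label stored in the `study` column.
#' @return An `AssocStats` data frame: `variant`, `chrom`, `pos`, `beta`,
#'   `se`, `z`, `p`, `n`, `direction`, `study`.
#' @export
gwas_scan <- function(g, y, covariates, grm = NULL, vc = NULL,
                      study = "gwas") {
  X <- as.matrix(covariates)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(g$dosages) == n)
  if (is.null(vc)) vc <- fit_null_variance(y, X, grm)
  Z <- g$dosages
  if (!is.null(vc$eigen)) {
    U <- vc$eigen$vectors
    w <- 1 / (vc$lambda * vc$eigen$values + 1)
    sw <- sqrt(w)
    yw <- drop(crossprod(U, y)) * sw
    Xw <- crossprod(U, X) * sw
    Zw <- crossprod(U, Z) * sw
  } else {
    yw <- y; Xw <- X; Zw <- Z
  }
  res <- gls_scan_core(yw, Xw, Zw, n)
  mono <- apply(g$dosages, 2, function(x) var(x) == 0)
  for (f in c("beta", "se", "z", "p")) res[[f]][mono] <- NA
  new_assoc_stats(data.frame(
    variant = g$variants$id, chrom = g$variants$chrom, pos = g$variants$pos,
    beta = res$beta, se = res$se, z = res$z, p = res$p,
    n = n, direction = sign(res$beta), study = study))
}

#' Sample-size weighted z-score meta-analysis
#'
#' Combines per-stratum association statistics with the weighted z-score
#' model: `z_i = direction * qnorm(1 - p_i / 2)`, weights `w_i = sqrt(n_i)`,
#' `z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))`, two-sided normal p-value.
#' Variants missing in every stratum stay missing.
#'
#' @param stats_by_stratum list of `AssocStats` sharing variant order.
#' @param study label for the output.
#' @return An `AssocStats` data frame with meta `z` and `p` (betas are not
#'   combined and are reported missing).
#' @export
meta_weighted_z <- function(stats_by_stratum, study = "meta") {
  stopifnot(length(stats_by_stratum) >= 1)
  v0 <- stats_by_stratum[[1]]$variant
  for (s in stats_by_stratum)
    if (!identical(s$variant, v0)) stop("strata must share variant order")
  m <- length(v0)
  num <- rep(0, m); den <- rep(0, m); any_ok <- rep(FALSE, m); ntot <- rep(0, m)
  for (s in stats_by_stratum) {
    ok <- !is.na(s$p) & !is.na(s$direction)
    z <- rep(NA_real_, m)
    z[ok] <- s$direction[ok] * qnorm(pmax(s$p[ok], P_FLOOR) / 2,
                                     lower.tail = FALSE)
    w <- sqrt(s$n)
    num[ok] <- num[ok] + (w * z)[ok]
    den[ok] <- den[ok] + (w^2)[ok]
    ntot[ok] <- ntot[ok] + s$n[ok]
    any_ok <- any_ok | ok
  }
  zm <- ifelse(any_ok, num / sqrt(den), NA_real_)
  pm <- 2 * pnorm(-abs(zm))
  new_assoc_stats(data.frame(
    variant = v0, chrom = stats_by_stratum[[1]]$chrom,
    pos = stats_by_stratum[[1]]$pos,
    beta = NA_real_, se = NA_real_, z = zm, p = pm,
    n = ntot, direction = sign(zm), study = study))
}

#' Greedy QTL lead selection with a spacing constraint
#'
#' Repeatedly takes the smallest-p remaining variant with `p <= p_thresh` and
#' suppresses all variants strictly within `spacing` bp on the same
#' chromosome; two variants exactly `spacing` apart are both eligible. Ties
#' on p are broken by (chromosome, position) ascending.
#'
#' @param stats an `AssocStats` data frame.
#' @param p_thresh selection threshold (default `1e-6`).
#' @param spacing minimum distance between leads in bp (default 1 Mb).
#' @param trait trait id attached to the calls.
#' @return A data frame of class `QtlCall`: `variant`, `chrom`, `pos`, `p`,
#'   `trait`, ordered by selection.
#' @export
select_qtl <- function(stats, p_thresh = 1e-6, spacing = 1e6,
                       trait = "trait") {
  s <- stats[!is.na(stats$p) & stats$p <= p_thresh, , drop = FALSE]
  s <- s[order(s$p, s$chrom, s$pos), , drop = FALSE]
  taken <- s[0, , drop = FALSE]
  while (nrow(s)) {
    lead <- s[1, , drop = FALSE]
    taken <- rbind(taken, lead)
    keep <- !(s$chrom == lead$chrom & abs(s$pos - lead$pos) < spacing)
    s <- s[keep, , drop = FALSE]
  }
  out <- data.frame(variant = taken$variant, chrom = taken$chrom,
                    pos = taken$pos, p = taken$p,
                    trait = rep(trait, nrow(taken)))
  structure(out, class = c("QtlCall", "data.frame"))
}
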