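# Bayes R: four-class normal-mixture Bayesian regression on all variants
# simultaneously, fitted by Gibbs sampling (compiled core in src/bayesr.cpp).
# The posterior-mean effects feed the local-GEBV window machinery.

#' Sampler configuration for Bayes R
#'
#' @param iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging; at least 100 post-burn-in
#'   sweeps are required.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param gamma ascending class-variance multipliers with `gamma[1] = 0`; the
#'   prior variance of an effect in class k is `gamma[k] * sigma2_a` where
#'   `sigma2_a` is the sampled class-variance scale.
#' @param seed integer seed; the fit is bit-identical under a fixed seed.
#' @return A list of class `SamplerConfig`.
#' @export
bayesr_config <- function(iterations = 10000L, burn_in = 2000L, thin = 10L,
                          gamma = c(0, 1e-4, 1e-3, 1e-2), seed = 1L) {
  stopifnot(iterations > burn_in, burn_in >= 0, thin >= 1)
  if (gamma[1] != 0 || is.unsorted(gamma))
    stop("gamma must be ascending with gamma[1] = 0")
  if (iterations - burn_in < 100)
    stop("need at least 100 post-burn-in sweeps")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 gamma = gamma, seed = as.integer(seed)),
            class = "SamplerConfig")
}

#' Fit Bayes R variant effects by Gibbs sampling
#'
#' Each sweep samples, for every variant, its mixture-class membership
#' (likelihood-weighted across the four classes) and its effect from the
#' conditional normal; then the mixture proportions from a
#' Dirichlet(1 + class counts), the residual variance from its scaled inverse
#' chi-square conditional, and the class-variance scale from its scaled
#' inverse chi-square conditional given the current effects. An intercept and
#' breed indicators are included as fixed effects with flat priors. The
#' reported genetic variance `sigma2_g` is the posterior mean of the
#' per-sweep variance of the genomic values.
#'
#' @param g a `GenotypeSet`.
#' @param y phenotype vector, one entry per individual in `g`.
#' @param cfg a [bayesr_config()].
#' @return An object of class `EffectEstimates`: `effects` data frame
#'   (`variant`, `chrom`, `pos`, `effect`, `p_class1..4`), posterior-mean
#'   mixture proportions `pi`, `sigma2_e`, `sigma2_a`, `sigma2_g`, `fixed`.
#' @export
bayes_r_fit <- function(g, y, cfg = bayesr_config()) {
  stopifnot(inherits(cfg, "SamplerConfig"))
  if (length(y) != n_individuals(g))
    stop("phenotype length must match the genotype set")
  if (var(y) == 0) stop("phenotype has zero variance")
  X <- g$dosages
  storage.mode(X) <- "double"
  X <- sweep(X, 2, colMeans(X))  # centering improves mixing; effects unchanged
  Fdes <- if (length(unique(g$individuals$breed)) > 1)
    stats::model.matrix(~ breed, data = g$individuals)
  else matrix(1, n_individuals(g), 1)
  if (qr(Fdes)$rank < ncol(Fdes)) Fdes <- Fdes[, 1, drop = FALSE]
  nu0 <- 4
  vary <- var(y)
  s_e0 <- 0.5 * vary * (nu0 - 2) / nu0  # prior mean sigma2_e = vary / 2
  s_a0 <- 0.5 * vary * (nu0 - 2) / nu0
  set.seed(cfg$seed)
  fit <- bayes_r_gibbs(X, y, Fdes, cfg$gamma, cfg$iterations, cfg$burn_in,
                       cfg$thin, nu0, s_e0, s_a0)
  eff <- data.frame(variant = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos, effect = fit$effect)
  cp <- fit$class_prob
  colnames(cp) <- paste0("p_class", seq_len(ncol(cp)))
  eff <- cbind(eff, cp)
  structure(list(effects = eff, pi = fit$pi, sigma2_e = fit$sigma2_e,
                 sigma2_a = fit$sigma2_a, sigma2_g = fit$sigma2_g,
                 fixed = fit$fixed, n_samples = fit$n_samples,
                 config = cfg),
            class = "EffectEstimates")
}

#' @export
print.EffectEstimates <- function(x, ...) {
  cat(sprintf(
    "EffectEstimates: %d variants; pi = (%s); sigma2_g = %.4g, sigma2_e = %.4g\n",
    nrow(x$effects), paste(sprintf("%.3f", x$pi), collapse = ", "),
    x$sigma2_g, x$sigma2_e))
  invisible(x)
}

# Align an EffectEstimates (or bare effect vector) with a genotype set's
# variant map; errors on mismatch.
aligned_effects <- function(g, eff) {
  if (is.numeric(eff)) {
    if (length(eff) != n_variants(g))
      stop("effect vector length does not match the genotype set")
    return(as.numeric(eff))
  }
  stopifnot(inherits(eff, "EffectEstimates"))
  key_g <- paste(g$variants$chrom, g$variants$pos)
  key_e <- paste(eff$effects$chrom, eff$effects$pos)
  idx <- match(key_g, key_e)
  if (any(is.na(idx)))
    stop("variant sets are not aligned between genotypes and effects")
  eff$effects$effect[idx]
}

#' Genome-wide GEBV from estimated effects
#'
#' `GEBV_i = sum_j dosage_ij * a_j` over all variants, after aligning the
#' effect estimates to the genotype set by (chromosome, position).
#'
#' @param g_new a `GenotypeSet` (e.g. the expression cohort).
#' @param eff an `EffectEstimates` or a bare effect vector aligned with
#'   `g_new`.
#' @return Named numeric vector of per-individual GEBVs.
#' @export
gebv_predict <- function(g_new, eff) {
  a <- aligned_effects(g_new, eff)
  setNames(drop(g_new$dosages %*% a), g_new$individuals$id)
}
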