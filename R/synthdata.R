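#' @useDynLib eqtloverlap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor var rnorm runif rbeta rbinom rnbinom rpois sd
#'   qnorm pnorm pt qt optimize rchisq rgamma setNames lm resid model.matrix
#'   complete.cases as.formula
#' @importFrom utils read.table write.table combn head
NULL

# Derive a stage-level seed from a master seed and a stage name, so that each
# pipeline stage has its own reproducible stream. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483573)
}

#' Construct a genotype set
#'
#' Container for a diploid dosage matrix with variant map and individual
#' metadata. Dosages count copies of the alternate allele (0, 1 or 2).
#'
#' @param dosages numeric matrix, individuals x variants, values in 0..2.
#' @param variants data frame with columns `id`, `chrom`, `pos` (1-based bp)
#'   and `af` (alternate allele frequency); positions must be strictly
#'   increasing within each chromosome.
#' @param individuals data frame with columns `id`, `breed`, `sex`.
#' @return An object of class `GenotypeSet`.
#' @export
genotype_set <- function(dosages, variants, individuals) {
  stopifnot(is.matrix(dosages),
            nrow(dosages) == nrow(individuals),
            ncol(dosages) == nrow(variants))
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("variant positions must be strictly increasing within chromosome ", ch)
  }
  rownames(dosages) <- individuals$id
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants,
                 individuals = individuals),
            class = "GenotypeSet")
}

#' @export
print.GenotypeSet <- function(x, ...) {
  cat(sprintf("GenotypeSet: %d individuals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))))
  invisible(x)
}

n_variants <- function(g) nrow(g$variants)
n_individuals <- function(g) nrow(g$individuals)

#' Subset a genotype set
#'
#' @param g a `GenotypeSet`.
#' @param individuals optional vector of row indices or individual ids.
#' @param variants optional vector of column indices.
#' @return A `GenotypeSet` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, individuals = NULL, variants = NULL) {
  dos <- g$dosages
  ind <- g$individuals
  var <- g$variants
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, ind$id)
    dos <- dos[individuals, , drop = FALSE]
    ind <- ind[individuals, , drop = FALSE]
  }
  if (!is.null(variants)) {
    dos <- dos[, variants, drop = FALSE]
    var <- var[variants, , drop = FALSE]
  }
  var$af <- colMeans(dos) / 2
  genotype_set(dos, var, ind)
}

#' Simulate multi-breed dosage genotypes with distance-decaying LD
#'
#' Genotypes are generated by a mosaic-haplotype scheme: each breed has a pool
#' of founder haplotypes drawn site-wise from breed allele frequencies, and
#' each individual haplotype is a mosaic of founders with switch probability
#' `1 - exp(-d / ld_block_scale)` between variants `d` bp apart. The finite
#' founder pool induces linkage disequilibrium that decays with distance, as
#' in livestock populations. Breed allele frequencies diverge from a shared
#' ancestral frequency under the Balding-Nichols model, i.e. with variance
#' `p (1 - p) fst`.
#'
#' @param n_per_breed named integer vector of individuals per breed.
#' @param m_variants total number of variants across the genome.
#' @param chrom_lengths numeric vector of chromosome lengths in bp.
#' @param fst cross-breed divergence in `[0, 0.5]`.
#' @param ld_block_scale expected haplotype segment length in bp; small values
#'   give effectively LD-free genotypes.
#' @param n_founders founder haplotypes per breed (controls background LD).
#' @param seed integer seed; output is bit-identical under a fixed seed.
#' @return A [genotype_set()]. Per-breed target allele frequencies are stored
#'   in `attr(, "breed_af")` (variants x breeds).
#' @export
simulate_genotypes <- function(n_per_breed = c(A = 105L, B = 26L),
                               m_variants = 1000L,
                               chrom_lengths = c(5e6, 5e6),
                               fst = 0.1,
                               ld_block_scale = 5e4,
                               n_founders = 20L,
                               seed = 1L) {
  if (m_variants < 2) stop("m_variants must be >= 2")
  if (any(n_per_breed <= 0) || any(chrom_lengths <= 0))
    stop("non-positive dimensions are not allowed")
  if (fst < 0 || fst > 0.5) stop("fst must be in [0, 0.5]")
  if (ld_block_scale <= 0) stop("ld_block_scale must be positive")
  set.seed(stage_seed(seed, "genotypes"))

  n_breeds <- length(n_per_breed)
  if (is.null(names(n_per_breed)))
    names(n_per_breed) <- LETTERS[seq_len(n_breeds)]
  n_chrom <- length(chrom_lengths)
  m_per_chrom <- diff(round(seq(0, m_variants,
                                length.out = n_chrom + 1)))

  variants <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    mv <- m_per_chrom[ch]
    pos <- sort(sample.int(chrom_lengths[ch], mv))
    data.frame(id = sprintf("%d_%d", ch, pos), chrom = ch, pos = pos)
  }))
  m <- nrow(variants)

  p_anc <- runif(m, 0.05, 0.95)
  breed_af <- sapply(names(n_per_breed), function(b) {
    if (fst == 0) p_anc
    else rbeta(m, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
  })

  n_total <- sum(n_per_breed)
  dosages <- matrix(0L, n_total, m)
  individuals <- data.frame(
    id = sprintf("ind%04d", seq_len(n_total)),
    breed = rep(names(n_per_breed), n_per_breed),
    sex = character(n_total))

  chrom_of <- variants$chrom
  pos_of <- variants$pos
  # per-chromosome switch probabilities between consecutive variants
  psw <- numeric(m)
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom_of == ch)
    d <- diff(pos_of[idx])
    psw[idx] <- c(1, 1 - exp(-d / ld_block_scale))  # first site: fresh founder
  }

  row <- 0L
  for (b in seq_len(n_breeds)) {
    K <- n_founders
    founders <- matrix(rbinom(K * m, 1L, rep(breed_af[, b], each = K)), K, m)
    for (i in seq_len(n_per_breed[b])) {
      row <- row + 1L
      hap <- integer(m)
      for (h in 1:2) {
        sw <- runif(m) < psw
        seg <- cumsum(sw)
        seg[seg == 0L] <- 1L
        fid <- sample.int(K, max(seg), replace = TRUE)[seg]
        hap <- hap + founders[cbind(fid, seq_len(m))]
      }
      dosages[row, ] <- hap
    }
    individuals$sex[individuals$breed == names(n_per_breed)[b]] <-
      rep_len(c("male", "female"), n_per_breed[b])
  }

  variants$af <- colMeans(dosages) / 2
  g <- genotype_set(dosages, variants, individuals)
  attr(g, "breed_af") <- breed_af
  attr(g, "n_founders") <- n_founders
  g
}

#' Construct a ground-truth causal registry
#'
#' @param trait_causals data frame with columns `variant` (index into the
#'   genotype set), `trait`, `effect`, `share`.
#' @param expr_causals data frame with columns `variant`, `gene`, `effect`.
#' @param g the `GenotypeSet` the indices refer to.
#' @return An object of class `GroundTruth` with a `shared` element, the
#'   variant indices causal for both a trait and a gene.
#' @export
ground_truth <- function(trait_causals, expr_causals, g) {
  m <- n_variants(g)
  idx <- c(trait_causals$variant, expr_causals$variant)
  if (length(idx) && (any(idx < 1) || any(idx > m)))
    stop("causal variant index outside the genotype set")
  structure(list(trait_causals = trait_causals,
                 expr_causals = expr_causals,
                 shared = intersect(unique(trait_causals$variant),
                                    unique(expr_causals$variant))),
            class = "GroundTruth")
}

#' Implant trait and expression causal variants
#'
#' Draws causal variants without replacement among variants with minor allele
#' frequency at least `maf_min`. `n_shared` of them are causal for both the
#' trait and the expression of a gene, mimicking a QTL that acts as an eQTL.
#'
#' @param g a `GenotypeSet`.
#' @param n_trait_qtl,n_eqtl,n_shared counts of trait-causal, expression-causal
#'   and shared variants; `n_shared <= min(n_trait_qtl, n_eqtl)`.
#' @param effect_sd standard deviation of trait allele-substitution effects
#'   (trait units; rescaled later so the trait reaches its target
#'   heritability).
#' @param expr_effect_sd standard deviation of expression effects on the
#'   natural-log mean count per alternate allele.
#' @param trait trait identifier attached to the trait effects.
#' @param maf_min eligibility floor for causal variants.
#' @param seed integer seed.
#' @return A [ground_truth()] registry.
#' @export
implant_truth <- function(g, n_trait_qtl, n_eqtl, n_shared,
                          effect_sd = 1, expr_effect_sd = 1,
                          trait = "trait", maf_min = 0.05, seed = 1L) {
  if (n_shared > min(n_trait_qtl, n_eqtl))
    stop("n_shared must not exceed min(n_trait_qtl, n_eqtl)")
  set.seed(stage_seed(seed, "truth"))
  maf <- pmin(g$variants$af, 1 - g$variants$af)
  eligible <- which(maf >= maf_min)
  need <- n_trait_qtl + n_eqtl - n_shared
  if (length(eligible) < need)
    stop("not enough polymorphic variants with MAF >= ", maf_min)
  picks <- sample(eligible, need)
  shared <- picks[seq_len(n_shared)]
  trait_only <- picks[seq_len(n_trait_qtl - n_shared) + n_shared]
  expr_only <- picks[seq_len(n_eqtl - n_shared) + n_trait_qtl]

  tv <- c(shared, trait_only)
  ev <- c(shared, expr_only)
  t_eff <- rnorm(length(tv), 0, effect_sd)
  p <- g$variants$af[tv]
  raw_share <- 2 * p * (1 - p) * t_eff^2
  trait_causals <- data.frame(variant = tv, trait = trait, effect = t_eff,
                              share = if (sum(raw_share) > 0)
                                raw_share / sum(raw_share) else raw_share)
  expr_causals <- data.frame(
    variant = ev,
    gene = sprintf("gene_eq%03d", seq_along(ev)),
    effect = rnorm(length(ev), 0, expr_effect_sd))
  ground_truth(trait_causals, expr_causals, g)
}

#' Simulate trait deviations with sex-dependent accuracy
#'
#' True genetic values are built from the registry's effects, rescaled so the
#' realized genetic variance equals `h2` (phenotypic variance is 1 for an
#' individual whose accuracy equals `sqrt(h2)`, i.e. an own-performance
#' record). Each individual's deviation is the genetic value plus noise with
#' variance `sigma2_g (1 - acc^2) / acc^2`, so the squared correlation between
#' deviation and genetic value equals `acc^2` in expectation. Bull-like
#' records (progeny-averaged deviations) get high accuracy, cow-like records
#' low accuracy.
#'
#' @param g a `GenotypeSet`.
#' @param truth a `GroundTruth`.
#' @param h2 heritability in (0, 1).
#' @param accuracy named vector mapping sex to accuracy in (0, 1].
#' @param seed integer seed.
#' @return A data frame of class `PhenotypeTable` with columns `individual`,
#'   `trait`, `deviation`, `accuracy`, `n_records`; the effect-rescaled
#'   registry is in `attr(, "truth")` and the genetic values per trait in
#'   `attr(, "genetic_values")`.
#' @export
simulate_phenotypes <- function(g, truth, h2 = 0.25,
                                accuracy = c(male = 0.95, female = 0.6),
                                seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0,1)")
  if (any(accuracy <= 0 | accuracy > 1)) stop("accuracy must be in (0, 1]")
  set.seed(stage_seed(seed, "phenotypes"))
  acc <- accuracy[g$individuals$sex]
  if (any(is.na(acc))) stop("accuracy must be supplied for every sex label")
  n <- n_individuals(g)
  traits <- unique(truth$trait_causals$trait)
  if (!length(traits)) traits <- "trait"

  out <- list(); gvals <- list()
  tc <- truth$trait_causals
  for (tr in traits) {
    rows <- which(tc$trait == tr)
    gval <- rep(0, n)
    if (length(rows)) {
      Z <- g$dosages[, tc$variant[rows], drop = FALSE]
      gval <- drop(Z %*% tc$effect[rows])
      vg <- var(gval)
      if (vg > 0) {
        s <- sqrt(h2 / vg)
        tc$effect[rows] <- tc$effect[rows] * s
        gval <- gval * s
      }
    }
    noise_sd <- sqrt(h2 * (1 - acc^2) / acc^2)
    dev <- gval + rnorm(n) * noise_sd
    n_rec <- pmax(1, round(pmin(acc, 0.999)^2 * (1 - h2) /
                             ((1 - pmin(acc, 0.999)^2) * h2)))
    out[[tr]] <- data.frame(individual = g$individuals$id, trait = tr,
                            deviation = dev, accuracy = unname(acc),
                            n_records = n_rec)
    gvals[[tr]] <- gval
  }
  truth$trait_causals <- tc
  pt <- do.call(rbind, out)
  rownames(pt) <- NULL
  structure(pt, class = c("PhenotypeTable", "data.frame"),
            truth = truth, sigma2_g = h2, genetic_values = gvals)
}

#' Construct an expression set
#'
#' @param genes data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param counts integer matrix genes x cows of non-negative read counts.
#' @param covariates data frame (one row per cow) with columns `cow`, `breed`,
#'   `parity`, `dim` (days in milk) and `batch`.
#' @param cell_type label for the expression study (e.g. "milk", "blood").
#' @return An object of class `ExpressionSet`.
#' @export
expression_set <- function(genes, counts, covariates, cell_type = "milk") {
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == nrow(covariates),
            all(genes$start <= genes$end), all(counts >= 0))
  if (any(!complete.cases(covariates)))
    stop("covariates must be complete for every cow")
  rownames(counts) <- genes$gene
  colnames(counts) <- covariates$cow
  structure(list(genes = genes, counts = counts, covariates = covariates,
                 cell_type = cell_type),
            class = "ExpressionSet")
}

#' @export
print.ExpressionSet <- function(x, ...) {
  cat(sprintf("ExpressionSet (%s): %d genes x %d cows\n",
              x$cell_type, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Simulate RNA-seq read counts with cis-eQTL effects
#'
#' Counts are drawn negative-binomially with log-mean equal to a baseline plus
#' the eQTL effect times the alternate-allele dosage plus breed, parity,
#' days-in-milk and sequencing-batch terms. Genes carrying an implanted eQTL
#' are placed so their span lies near the causal variant; remaining genes get
#' random spans.
#'
#' @param g a `GenotypeSet`.
#' @param truth a `GroundTruth` (its `expr_causals` define the eQTL genes).
#' @param n_genes total number of genes (>= number of eQTL genes).
#' @param cows individual ids (or indices) forming the expression cohort;
#'   default draws 105 females of the first breed and 26 of the second,
#'   mirroring a two-breed expression study (falls back to what is available).
#' @param baseline_log_mean baseline natural-log mean count.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param covariate_effects list with elements `breed`, `parity`, `dim`,
#'   `batch`: additive terms on the log-mean.
#' @param chrom_lengths chromosome lengths (defaults to max position per
#'   chromosome in `g`), used for random gene placement.
#' @param cell_type label for the study.
#' @param seed integer seed.
#' @return An [expression_set()]; the cohort ids are in
#'   `attr(, "cohort")`.
#' @export
simulate_expression <- function(g, truth, n_genes = 100L, cows = NULL,
                                baseline_log_mean = 3, dispersion = 0.3,
                                covariate_effects = list(breed = 0.2,
                                                         parity = 0.05,
                                                         dim = -0.001,
                                                         batch = 0.1),
                                chrom_lengths = NULL, cell_type = "milk",
                                seed = 1L) {
  if (dispersion < 0) stop("dispersion must be non-negative")
  eq <- truth$expr_causals
  if (n_genes < nrow(eq)) stop("n_genes must cover all registry genes")
  set.seed(stage_seed(seed, paste0("expression_", cell_type)))

  ind <- g$individuals
  if (is.null(cows)) {
    breeds <- unique(ind$breed)
    want <- c(105L, 26L)[seq_along(breeds)]
    cows <- unlist(lapply(seq_along(breeds), function(b) {
      f <- ind$id[ind$breed == breeds[b] & ind$sex == "female"]
      head(f, want[b])
    }))
  }
  if (is.numeric(cows)) cows <- ind$id[cows]
  ci <- match(cows, ind$id)
  if (any(is.na(ci))) stop("unknown cow id in expression cohort")
  nc <- length(ci)

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(g$variants$pos, g$variants$chrom, max)
  }
  chroms <- as.integer(names(chrom_lengths))
  if (any(is.na(chroms))) chroms <- seq_along(chrom_lengths)

  # eQTL genes near their causal variant
  genes <- data.frame(gene = character(0), chrom = integer(0),
                      start = numeric(0), end = numeric(0))
  if (nrow(eq)) {
    vpos <- g$variants$pos[eq$variant]
    vchr <- g$variants$chrom[eq$variant]
    len <- round(runif(nrow(eq), 5e3, 5e4))
    off <- round(runif(nrow(eq), -2e5, 2e5))
    start <- pmax(1, vpos + off - len %/% 2)
    genes <- data.frame(gene = eq$gene, chrom = vchr, start = start,
                        end = start + len)
  }
  n_rand <- n_genes - nrow(eq)
  if (n_rand > 0) {
    rchr <- sample(chroms, n_rand, replace = TRUE)
    len <- round(runif(n_rand, 5e3, 5e4))
    start <- sapply(seq_len(n_rand), function(i)
      sample.int(max(1, chrom_lengths[match(rchr[i], chroms)] - len[i]), 1))
    genes <- rbind(genes, data.frame(
      gene = sprintf("gene_bg%04d", seq_len(n_rand)),
      chrom = rchr, start = start, end = start + len))
  }
  ord <- order(genes$chrom, genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL

  covariates <- data.frame(
    cow = cows,
    breed = ind$breed[ci],
    parity = sample(1:5, nc, replace = TRUE),
    dim = round(runif(nc, 5, 305)),
    batch = sample(1:3, nc, replace = TRUE))

  eta_cov <- covariate_effects$breed * (as.integer(factor(covariates$breed)) - 1) +
    covariate_effects$parity * (covariates$parity - 1) +
    covariate_effects$dim * (covariates$dim - 150) +
    covariate_effects$batch * (covariates$batch - 1)

  counts <- matrix(0L, nrow(genes), nc)
  eff <- setNames(rep(0, nrow(genes)), genes$gene)
  eff[eq$gene] <- eq$effect
  vidx <- setNames(rep(NA_integer_, nrow(genes)), genes$gene)
  vidx[eq$gene] <- eq$variant
  for (i in seq_len(nrow(genes))) {
    eta <- baseline_log_mean + eta_cov
    if (!is.na(vidx[i]))
      eta <- eta + eff[i] * g$dosages[ci, vidx[i]]
    mu <- exp(eta)
    counts[i, ] <- if (dispersion == 0) rpois(nc, mu)
    else rnbinom(nc, size = 1 / dispersion, mu = mu)
  }
  e <- expression_set(genes, counts, covariates, cell_type)
  attr(e, "cohort") <- cows
  e
}
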