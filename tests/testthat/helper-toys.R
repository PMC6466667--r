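# Small deterministic fixtures built in code, shared across test files.

# Hand-specified genotype set: dosage matrix given variants-in-columns.
toy_genotypes <- function(dosages, pos = NULL, chrom = NULL,
                          breed = NULL, sex = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(breed)) breed <- rep("A", n)
  if (is.null(sex)) sex <- rep("female", n)
  variants <- data.frame(id = sprintf("%d_%d", chrom, pos), chrom = chrom,
                         pos = pos, af = colMeans(dosages) / 2)
  individuals <- data.frame(id = sprintf("t%03d", seq_len(n)), breed = breed,
                            sex = sex)
  genotype_set(dosages, variants, individuals)
}

# Random LD-free genotype set with controlled MAF range.
random_genotypes <- function(n, m, chrom = 1L, chrom_len = m * 1e4,
                             maf_range = c(0.1, 0.5), seed = 1) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- sapply(p, function(pp) rbinom(n, 2, pp))
  pos <- sort(sample.int(chrom_len, m))
  toy_genotypes(dos, pos = pos, chrom = rep(chrom, m))
}

# Minimal expression set from a log-scale expression matrix (counts are
# exp(x) rounded so that log1p approximately recovers x).
toy_expression <- function(counts, genes, covariates = NULL,
                           cell_type = "milk") {
  nc <- ncol(counts)
  if (is.null(covariates))
    covariates <- data.frame(cow = sprintf("t%03d", seq_len(nc)),
                             breed = rep("A", nc),
                             parity = rep(1L, nc), dim = rep(100, nc),
                             batch = rep(1L, nc))
  expression_set(genes, counts, covariates, cell_type)
}

# Independent greedy non-overlap oracle: literal restatement of the rule,
# structured differently from the implementation (explicit pairwise scan).
oracle_rank_nonoverlapping <- function(chrom, start, end, sigma2) {
  ord <- order(-sigma2, chrom, start)
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in acc)
      if (chrom[i] == chrom[j] && !(end[i] <= start[j] || end[j] <= start[i]))
        ok <- FALSE
    if (ok) acc <- c(acc, i)
  }
  acc
}
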