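# Colocalisation: loci around QTL and eQTL leads, LD matrices,
# configuration-enumeration fine-mapping posteriors per study, per-variant
# colocalisation posterior probabilities (CLPP) and summary counting.

#' Pairwise LD matrix over selected variants
#'
#' Pearson correlation of dosages with a ridge added to the diagonal.
#'
#' @param g a `GenotypeSet`.
#' @param members variant indices.
#' @param ridge diagonal ridge (default `1e-4`).
#' @return Square correlation matrix with `1 + ridge` on the diagonal.
#' @export
ld_matrix <- function(g, members, ridge = 1e-4) {
  stopifnot(length(members) >= 1)
  X <- g$dosages[, members, drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("monomorphic variant(s) in LD matrix: ",
         paste(g$variants$id[members[sds == 0]], collapse = ", "))
  S <- cor(X)
  S + diag(ridge, length(members))
}

#' Build colocalisation loci around QTL and eQTL anchors
#'
#' For each QTL lead, every gene within `radius` defines a locus of all
#' variants within `radius` of the gene span; for each eQTL call, one locus
#' of variants within `radius` of its gene. Only variants with marginal
#' statistics in both studies (GWAS z and eQTL z for that gene) are kept,
#' and loci are capped to the `cap` variants with the largest
#' `max(|z_gwas|, |z_eqtl|)`. Loci with no eligible variant are dropped.
#'
#' @param qtl `QtlCall` data frame from [select_qtl()].
#' @param eqtl `EqtlCall` data frame from [select_eqtl()].
#' @param g cohort `GenotypeSet` used for LD.
#' @param gwas `AssocStats` of the GWAS (or meta-analysis).
#' @param eqtl_stats `AssocStats` from [eqtl_scan()].
#' @param genes gene table (`gene`, `chrom`, `start`, `end`).
#' @param radius anchor radius in bp (default 1 Mb).
#' @param cap maximum variants per locus (default 50).
#' @return List of `Locus` objects: `anchor` ("qtl"/"eqtl"), `trait`, `qtl`
#'   (lead variant id or NA), `gene`, `members`, `variant`, `z_gwas`,
#'   `z_eqtl`, `Sigma`.
#' @export
build_loci <- function(qtl, eqtl, g, gwas, eqtl_stats, genes,
                       radius = 1e6, cap = 50L) {
  loci <- list()
  add_locus <- function(anchor, trait, qtl_id, gene_row) {
    on_chr <- which(g$variants$chrom == gene_row$chrom)
    pos <- g$variants$pos[on_chr]
    mem <- on_chr[pos >= gene_row$start - radius & pos <= gene_row$end + radius]
    if (!length(mem)) return(NULL)
    vid <- g$variants$id[mem]
    zg <- gwas$z[match(vid, gwas$variant)]
    er <- eqtl_stats[eqtl_stats$gene == gene_row$gene, , drop = FALSE]
    ze <- er$z[match(vid, er$variant)]
    ok <- is.finite(zg) & is.finite(ze) &
      apply(g$dosages[, mem, drop = FALSE], 2, sd) > 0
    mem <- mem[ok]; vid <- vid[ok]; zg <- zg[ok]; ze <- ze[ok]
    if (!length(mem)) return(NULL)
    if (length(mem) > cap) {
      top <- order(-pmax(abs(zg), abs(ze)))[seq_len(cap)]
      top <- sort(top)
      mem <- mem[top]; vid <- vid[top]; zg <- zg[top]; ze <- ze[top]
    }
    list(anchor = anchor, trait = trait, qtl = qtl_id, gene = gene_row$gene,
         members = mem, variant = vid, z_gwas = zg, z_eqtl = ze,
         Sigma = ld_matrix(g, mem))
  }
  if (nrow(qtl)) {
    for (i in seq_len(nrow(qtl))) {
      near <- genes[genes$chrom == qtl$chrom[i] &
                      genes$end >= qtl$pos[i] - radius &
                      genes$start <= qtl$pos[i] + radius, , drop = FALSE]
      for (j in seq_len(nrow(near))) {
        lc <- add_locus("qtl", qtl$trait[i], qtl$variant[i], near[j, ])
        if (!is.null(lc)) loci[[length(loci) + 1]] <- lc
      }
    }
  }
  if (nrow(eqtl)) {
    for (i in seq_len(nrow(eqtl))) {
      gr <- genes[genes$gene == eqtl$gene[i], , drop = FALSE]
      if (!nrow(gr)) next
      lc <- add_locus("eqtl", NA_character_, NA_character_, gr[1, ])
      if (!is.null(lc)) loci[[length(loci) + 1]] <- lc
    }
  }
  loci
}

#' Fine-mapping posterior inclusion probabilities by enumeration
#'
#' Enumerates causal configurations `c` with at most `max_causals` causal
#' variants. The likelihood of the observed z-vector under configuration `c`
#' is multivariate normal with mean 0 and covariance
#' `Sigma + ncp_sd^2 Sigma diag(c) Sigma`; the prior is
#' `gamma^|c| (1 - gamma)^(m - |c|)` (the null configuration is included in
#' the normalization). `PIP_i` sums the posterior over configurations
#' containing variant i.
#'
#' @param z observed z-scores.
#' @param Sigma LD matrix (with ridge) over the same variants.
#' @param gamma per-variant prior causal probability (default 0.01).
#' @param ncp_sd non-centrality scale of a causal effect (default 5.2).
#' @param max_causals maximum causal variants per configuration (default 2).
#' @return Numeric PIP vector.
#' @export
finemap_pips <- function(z, Sigma, gamma = 0.01, ncp_sd = 5.2,
                         max_causals = 2L) {
  m <- length(z)
  stopifnot(all(is.finite(z)), nrow(Sigma) == m, ncol(Sigma) == m)
  max_causals <- min(max_causals, m)
  configs <- list(integer(0))
  for (k in seq_len(max_causals))
    configs <- c(configs, combn(m, k, simplify = FALSE))
  logpost <- vapply(configs, function(cset) {
    V <- Sigma
    if (length(cset)) {
      Sc <- Sigma[, cset, drop = FALSE]
      V <- V + ncp_sd^2 * tcrossprod(Sc)
    }
    ch <- tryCatch(chol(V), error = function(e)
      stop("singular configuration covariance"))
    ll <- -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, z, transpose = TRUE)^2)
    ll + length(cset) * log(gamma) + (m - length(cset)) * log(1 - gamma)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  pip <- numeric(m)
  for (i in seq_along(configs))
    pip[configs[[i]]] <- pip[configs[[i]]] + w[i]
  pmin(pmax(pip, 0), 1)  # guard rounding at the boundaries
}

#' Colocalisation posterior probabilities
#'
#' `CLPP_i = PIP_gwas,i * PIP_eqtl,i`; variants with `CLPP >= threshold` are
#' flagged as shared between the two studies.
#'
#' @param pip_gwas,pip_eqtl PIP vectors of equal length.
#' @param threshold sharing threshold (default 0.01).
#' @param variant,trait,gene,qtl optional annotation columns.
#' @return Data frame of class `ClppRecord`: `variant`, `trait`, `gene`,
#'   `qtl`, `pip_gwas`, `pip_eqtl`, `clpp`, `shared`.
#' @export
clpp <- function(pip_gwas, pip_eqtl, threshold = 0.01, variant = NULL,
                 trait = NA_character_, gene = NA_character_,
                 qtl = NA_character_) {
  stopifnot(length(pip_gwas) == length(pip_eqtl),
            all(pip_gwas >= 0 & pip_gwas <= 1),
            all(pip_eqtl >= 0 & pip_eqtl <= 1))
  cl <- pip_gwas * pip_eqtl
  out <- data.frame(
    variant = if (is.null(variant)) seq_along(cl) else variant,
    trait = trait, gene = gene, qtl = qtl,
    pip_gwas = pip_gwas, pip_eqtl = pip_eqtl,
    clpp = cl, shared = cl >= threshold)
  structure(out, class = c("ClppRecord", "data.frame"))
}

#' Run fine-mapping and CLPP over a list of loci
#'
#' @param loci result of [build_loci()].
#' @param gamma,ncp_sd,max_causals passed to [finemap_pips()].
#' @param threshold CLPP sharing threshold.
#' @return A `ClppRecord` data frame over all loci (one row per variant per
#'   locus, with an `anchor` column).
#' @export
coloc_scan <- function(loci, gamma = 0.01, ncp_sd = 5.2, max_causals = 2L,
                       threshold = 0.01) {
  out <- lapply(loci, function(lc) {
    pg <- finemap_pips(lc$z_gwas, lc$Sigma, gamma, ncp_sd, max_causals)
    pe <- finemap_pips(lc$z_eqtl, lc$Sigma, gamma, ncp_sd, max_causals)
    rec <- clpp(pg, pe, threshold, variant = lc$variant, trait = lc$trait,
                gene = lc$gene, qtl = lc$qtl)
    rec$anchor <- lc$anchor
    rec
  })
  res <- if (length(out)) do.call(rbind, out) else
    cbind(clpp(numeric(0), numeric(0)), anchor = character(0))
  rownames(res) <- NULL
  structure(res, class = c("ClppRecord", "data.frame"))
}

#' Colocalisation summary counts
#'
#' Counts how many QTL have at least one shared variant (CLPP above the
#' threshold) among their loci, and how many eQTL genes do.
#'
#' @param records `ClppRecord` data frame from [coloc_scan()].
#' @param qtl `QtlCall` data frame.
#' @param eqtl `EqtlCall` data frame.
#' @return One-row data frame: `n_QTL`, `coloc_QTL`, `n_eQTL`, `coloc_eQTL`.
#' @export
colocalisation_summary <- function(records, qtl, eqtl) {
  shared <- records[records$shared, , drop = FALSE]
  coloc_qtl <- length(unique(shared$qtl[shared$anchor == "qtl" &
                                          !is.na(shared$qtl)]))
  coloc_eqtl <- length(unique(shared$gene[shared$anchor == "eqtl"]))
  data.frame(n_QTL = nrow(qtl), coloc_QTL = coloc_qtl,
             n_eQTL = nrow(eqtl), coloc_eQTL = coloc_eqtl)
}
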