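# Expression preprocessing and cis-eQTL scanning: expression filter, log
# transform, cis-pair construction, an EMMAX-style per-gene mixed-model scan
# with covariates and relatedness, and per-gene eQTL lead selection.

#' Filter genes by expression breadth
#'
#' Retains genes with a non-zero count in at least `min_expressed` cows.
#'
#' @param e an `ExpressionSet`.
#' @param min_expressed minimum number of cows with count > 0 (default 25).
#' @return The filtered `ExpressionSet`.
#' @export
filter_genes <- function(e, min_expressed = 25L) {
  keep <- rowSums(e$counts > 0) >= min_expressed
  expression_set(e$genes[keep, , drop = FALSE],
                 e$counts[keep, , drop = FALSE],
                 e$covariates, e$cell_type)
}

#' Natural-log transform of read counts
#'
#' Elementwise `ln(count + 1)`.
#'
#' @param counts non-negative count matrix.
#' @return Matrix of the same shape.
#' @export
log_transform <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  log1p(counts)
}

#' Enumerate cis variant-gene pairs
#'
#' A pair is included iff the variant position lies within
#' `[gene start - radius, gene end + radius]` on the gene's chromosome.
#'
#' @param g a `GenotypeSet`.
#' @param e an `ExpressionSet`.
#' @param radius cis radius in bp (default 1 Mb).
#' @return A data frame of class `CisPair`: `variant` (index into `g`),
#'   `gene`, `distance` (0 if inside the gene span).
#' @export
cis_pairs <- function(g, e, radius = 1e6) {
  out <- list()
  for (i in seq_len(nrow(e$genes))) {
    gn <- e$genes[i, ]
    on_chr <- which(g$variants$chrom == gn$chrom)
    pos <- g$variants$pos[on_chr]
    hit <- on_chr[pos >= gn$start - radius & pos <= gn$end + radius]
    if (!length(hit)) next
    p <- g$variants$pos[hit]
    d <- pmax(0, pmax(gn$start - p, p - gn$end))
    out[[length(out) + 1]] <- data.frame(variant = hit, gene = gn$gene,
                                         distance = d)
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = integer(0), gene = character(0),
               distance = numeric(0))
  rownames(pairs) <- NULL
  structure(pairs, class = c("CisPair", "data.frame"))
}

# Expression covariate design: intercept + breed + parity + days in milk +
# sequencing batch (breed and batch as factors). Constant covariates are
# dropped so degenerate cohorts keep a full-rank design.
expression_design <- function(covariates) {
  terms <- c(breed = "breed", parity = "parity", dim = "dim",
             batch = "factor(batch)")
  keep <- vapply(c("breed", "parity", "dim", "batch"), function(cn)
    length(unique(covariates[[cn]])) > 1, logical(1))
  rhs <- if (any(keep)) paste(terms[keep], collapse = " + ") else "1"
  stats::model.matrix(stats::as.formula(paste("~", rhs)), data = covariates)
}

#' Cis-eQTL mixed-model scan
#'
#' For every cis pair, an EMMAX-style generalized-least-squares test of the
#' variant dosage on log expression, with breed, parity, days in milk and
#' sequencing batch as fixed effects and a GRM over the expression cows for
#' relatedness. Variance components are fitted once per gene under the null.
#' With an identity relationship matrix the test reduces exactly to OLS.
#'
#' @param g a `GenotypeSet` over the expression cows (same order as the
#'   columns of `e$counts`).
#' @param e an `ExpressionSet`, already gene-filtered; counts are
#'   log-transformed internally unless `log_expr` is supplied.
#' @param grm a `Grm` over the expression cows, or `NULL` for identity.
#' @param pairs result of [cis_pairs()].
#' @param log_expr optional pre-computed log-expression matrix.
#' @return An `AssocStats` data frame with one row per cis pair (extra `gene`
#'   and `distance` columns); genes with a singular covariate design are
#'   skipped with a warning and recorded in `attr(, "skipped_genes")`.
#' @export
eqtl_scan <- function(g, e, grm = NULL, pairs = cis_pairs(g, e),
                      log_expr = NULL) {
  stopifnot(ncol(e$counts) == n_individuals(g))
  Y <- if (is.null(log_expr)) log_transform(e$counts) else log_expr
  X <- expression_design(e$covariates)
  ed <- if (is.null(grm)) NULL else grm_eigen(grm)
  n <- ncol(Y)
  out <- list(); skipped <- character(0)
  for (gn in unique(pairs$gene)) {
    pr <- pairs[pairs$gene == gn, , drop = FALSE]
    y <- Y[gn, ]
    Xg <- X
    if (qr(Xg)$rank < ncol(Xg) || var(y) == 0) {
      skipped <- c(skipped, gn)
      next
    }
    vc <- fit_null_variance(y, Xg, grm = if (is.null(ed)) NULL else grm,
                            eigen_grm = ed)
    Z <- g$dosages[, pr$variant, drop = FALSE]
    if (!is.null(vc$eigen)) {
      U <- vc$eigen$vectors
      sw <- sqrt(1 / (vc$lambda * vc$eigen$values + 1))
      yw <- drop(crossprod(U, y)) * sw
      Xw <- crossprod(U, Xg) * sw
      Zw <- crossprod(U, Z) * sw
    } else {
      yw <- y; Xw <- Xg; Zw <- Z
    }
    res <- gls_scan_core(yw, Xw, Zw, n)
    mono <- apply(Z, 2, var) == 0
    for (f in c("beta", "se", "z", "p")) res[[f]][mono] <- NA
    out[[length(out) + 1]] <- data.frame(
      variant = g$variants$id[pr$variant],
      chrom = g$variants$chrom[pr$variant],
      pos = g$variants$pos[pr$variant],
      gene = gn, distance = pr$distance,
      beta = res$beta, se = res$se, z = res$z, p = res$p,
      n = n, direction = sign(res$beta), study = paste0("eqtl_", e$cell_type))
  }
  if (length(skipped))
    warning("skipped genes with singular design or constant expression: ",
            paste(skipped, collapse = ", "))
  stats_df <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = character(0), chrom = integer(0), pos = integer(0),
               gene = character(0), distance = numeric(0), beta = numeric(0),
               se = numeric(0), z = numeric(0), p = numeric(0),
               n = integer(0), direction = numeric(0), study = character(0))
  rownames(stats_df) <- NULL
  res <- new_assoc_stats(stats_df)
  attr(res, "skipped_genes") <- skipped
  res
}

#' Per-gene eQTL lead selection
#'
#' For each gene the lead is its smallest-p cis variant (ties broken by
#' chromosome then position ascending); a call is emitted iff the lead
#' p-value is at most `p_thresh`, giving at most one eQTL per gene.
#'
#' @param stats an `AssocStats` from [eqtl_scan()] (must carry a `gene`
#'   column).
#' @param p_thresh selection threshold (default `1e-5`).
#' @return A data frame of class `EqtlCall`: `gene`, `variant`, `chrom`,
#'   `pos`, `p`, `direction`.
#' @export
select_eqtl <- function(stats, p_thresh = 1e-5) {
  s <- stats[!is.na(stats$p), , drop = FALSE]
  s <- s[order(s$p, s$chrom, s$pos), , drop = FALSE]
  lead <- s[!duplicated(s$gene), , drop = FALSE]
  lead <- lead[lead$p <= p_thresh, , drop = FALSE]
  out <- data.frame(gene = lead$gene, variant = lead$variant,
                    chrom = lead$chrom, pos = lead$pos, p = lead$p,
                    direction = lead$direction)
  rownames(out) <- NULL
  structure(out, class = c("EqtlCall", "data.frame"))
}
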