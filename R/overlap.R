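# Overlap analyses: Pearson correlations between local GEBV and gene
# expression, genotype-GEBV correlations, the within-window permutation
# comparison, top-k / random-k enrichment with the nE/nG/nEG/nC/nEC/nEGC
# filter chain, and the study's own FDR estimator.

#' Pearson correlation with a two-sided p-value
#'
#' The p-value comes from `t = r sqrt(df) / sqrt(1 - r^2)` on `df` degrees of
#' freedom (default `n - 2`); `|r| = 1` returns `p = 0`. A constant input
#' returns missing values with a `flagged` marker rather than an error.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param df degrees of freedom; supply `n - 2 - q` when the inputs are
#'   residuals from a q-covariate adjustment.
#' @return List with `r`, `p` and `flagged`.
#' @export
pearson_with_p <- function(x, y, df = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (is.null(df)) df <- n - 2
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, flagged = TRUE))
  r <- cor(x, y)
  p <- if (abs(r) >= 1 - 1e-15) 0
  else 2 * pt(-abs(r * sqrt(df) / sqrt(1 - r^2)), df)
  list(r = r, p = p, flagged = FALSE)
}

# Row-standardize a matrix (rows are variables, columns observations);
# constant rows become NA.
row_standardize <- function(M) {
  mu <- rowMeans(M)
  s <- sqrt(rowSums((M - mu)^2))
  Ms <- (M - mu) / s
  Ms[s == 0, ] <- NA_real_
  Ms
}

# Correlations for an explicit (i, j) pair list between row-standardized
# matrices A (kA x n) and B (kB x n); returns r and p (t test, df dof).
paired_cor <- function(As, Bs, ia, ib, df) {
  r <- rowSums(As[ia, , drop = FALSE] * Bs[ib, , drop = FALSE])
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) >= 1 - 1e-15, 0,
              2 * pt(-abs(r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-300))), df))
  list(r = r, p = p)
}

# Residualize log-expression rows on the covariate design (intercept kept
# implicit in the correlation). Returns the residual matrix and the number of
# non-intercept columns removed, for df accounting.
residualize_expression <- function(Y, covariates) {
  X <- expression_design(covariates)
  q <- qr(X)
  R <- t(qr.resid(q, t(Y)))
  list(Y = R, q_removed = ncol(X) - 1)
}

#' Correlate local GEBV with gene expression
#'
#' One record per (window, gene) pair whose gene span lies within `radius`
#' of the window; Pearson r across the expression cows with a two-sided
#' t-based p-value. Expression is residualized on breed, parity, days in milk
#' and batch by default (degrees of freedom adjusted accordingly).
#'
#' @param lg a `LocalGebvSet` computed for the expression cows.
#' @param e an `ExpressionSet` (filtered; counts are log-transformed
#'   internally).
#' @param radius gene-to-window radius in bp (default 1 Mb).
#' @param p_select selection threshold for the `selected` flag (default
#'   `1e-5`).
#' @param residualize adjust expression for the covariates first?
#' @return A data frame of class `CorrelationRecord`: `window`, `chrom`,
#'   `start`, `end`, `gene`, `r`, `p`, `n`, `selected`.
#' @export
correlate_gebv_expression <- function(lg, e, radius = 1e6, p_select = 1e-5,
                                      residualize = TRUE) {
  w <- as.data.frame(lg$windows)
  n <- ncol(lg$gebv)
  stopifnot(n == ncol(e$counts), n >= 3)
  Y <- log_transform(e$counts)
  q_rm <- 0
  if (residualize) {
    rz <- residualize_expression(Y, e$covariates)
    Y <- rz$Y; q_rm <- rz$q_removed
  }
  pairs <- window_gene_pairs(w, e$genes, radius)
  if (!nrow(pairs))
    return(structure(data.frame(window = integer(0), chrom = integer(0),
                                start = numeric(0), end = numeric(0),
                                gene = character(0), r = numeric(0),
                                p = numeric(0), n = integer(0),
                                selected = logical(0)),
                     class = c("CorrelationRecord", "data.frame")))
  df <- n - 2 - q_rm
  Gs <- row_standardize(lg$gebv)
  Es <- row_standardize(Y)
  pc <- paired_cor(Gs, Es, pairs$wi, pairs$gi, df)
  out <- data.frame(window = w$window[pairs$wi], chrom = w$chrom[pairs$wi],
                    start = w$start[pairs$wi], end = w$end[pairs$wi],
                    gene = e$genes$gene[pairs$gi], r = pc$r, p = pc$p,
                    n = n, selected = !is.na(pc$p) & pc$p <= p_select)
  rownames(out) <- NULL
  structure(out, class = c("CorrelationRecord", "data.frame"))
}

# (window index, gene index) pairs with gene span intersecting
# [start - radius, end + radius).
window_gene_pairs <- function(w, genes, radius) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gn <- genes[i, ]
    hit <- which(w$chrom == gn$chrom &
                   gn$end >= w$start - radius &
                   gn$start < w$end + radius)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(wi = hit, gi = i)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(wi = integer(0), gi = integer(0))
}

#' Correlate variant genotypes with their window's local GEBV
#'
#' For every window and every member variant, the Pearson correlation between
#' the variant's dosage and the window's local GEBV across the cohort.
#' Variants monomorphic in the cohort are flagged with missing statistics.
#'
#' @param g the cohort `GenotypeSet` (the one `lg` was computed on).
#' @param lg a `LocalGebvSet`.
#' @return Data frame: `window`, `variant`, `chrom`, `pos`, `r`, `p`.
#' @export
correlate_genotype_gebv <- function(g, lg) {
  w <- as.data.frame(lg$windows)
  n <- ncol(lg$gebv)
  out <- vector("list", nrow(w))
  for (k in seq_len(nrow(w))) {
    mem <- w$members[[k]]
    X <- g$dosages[, mem, drop = FALSE]
    gv <- lg$gebv[k, ]
    if (sd(gv) == 0) {
      r <- rep(NA_real_, length(mem)); p <- r
    } else {
      sds <- apply(X, 2, sd)
      r <- suppressWarnings(drop(cor(X, gv)))
      r[sds == 0] <- NA_real_
      r <- pmin(pmax(r, -1), 1)
      p <- ifelse(is.na(r), NA_real_,
                  ifelse(abs(r) >= 1 - 1e-15, 0,
                         2 * pt(-abs(r * sqrt(n - 2) /
                                       sqrt(pmax(1 - r^2, 1e-300))), n - 2)))
    }
    out[[k]] <- data.frame(window = w$window[k], variant = g$variants$id[mem],
                           chrom = g$variants$chrom[mem],
                           pos = g$variants$pos[mem], r = r, p = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation comparison of significant GEBV-expression correlations
#'
#' Counts (window, gene) correlations with `p <= p_select` using the
#' estimated effects, then repeats the count `reps` times with effects
#' permuted within each window, testing whether the observed correlations
#' could arise from LD alone.
#'
#' @param g cohort `GenotypeSet`.
#' @param eff `EffectEstimates` (or effect vector).
#' @param windows [make_windows()] result.
#' @param e filtered `ExpressionSet`.
#' @param reps number of permutation replicates (default 100).
#' @param p_select correlation selection threshold (default `1e-5`).
#' @param radius gene-to-window radius (default 1 Mb).
#' @param residualize adjust expression for covariates?
#' @param seed integer seed.
#' @return List of class `PermutationComparison`: `observed` count,
#'   `permuted` (length-`reps` vector) and `n_pairs`.
#' @export
permutation_comparison <- function(g, eff, windows, e, reps = 100L,
                                   p_select = 1e-5, radius = 1e6,
                                   residualize = TRUE, seed = 1L) {
  lg <- local_gebv(g, eff, windows)
  w <- as.data.frame(windows)
  n <- ncol(lg$gebv)
  Y <- log_transform(e$counts)
  q_rm <- 0
  if (residualize) {
    rz <- residualize_expression(Y, e$covariates)
    Y <- rz$Y; q_rm <- rz$q_removed
  }
  pairs <- window_gene_pairs(w, e$genes, radius)
  df <- n - 2 - q_rm
  Es <- row_standardize(Y)
  count_sig <- function(gebv) {
    Gs <- row_standardize(gebv)
    pc <- paired_cor(Gs, Es, pairs$wi, pairs$gi, df)
    sum(!is.na(pc$p) & pc$p <= p_select)
  }
  observed <- if (nrow(pairs)) count_sig(lg$gebv) else 0L
  permuted <- integer(reps)
  for (r in seq_len(reps)) {
    perm <- permute_effects_within_windows(eff, windows,
                                           seed = stage_seed(seed, paste0("rep", r)))
    lgp <- local_gebv_permuted(g, perm)
    permuted[r] <- if (nrow(pairs)) count_sig(lgp$gebv) else 0L
  }
  structure(list(observed = observed, permuted = permuted,
                 n_pairs = nrow(pairs)),
            class = "PermutationComparison")
}

#' Top-k non-overlapping windows by variance
#'
#' The first `k` windows in acceptance (variance) order of a
#' [rank_nonoverlapping()] result, together with their share of the total
#' accepted variance. If fewer than `k` windows were accepted, all are
#' returned and the result is flagged.
#'
#' @param ranking a `NonOverlapRanking`.
#' @param k set size (default 300).
#' @return Data frame of the selected windows; `attr(, "share_pct")` gives
#'   their percentage of `sum_var`, `attr(, "short")` flags a short set.
#' @export
select_top_k <- function(ranking, k = 300L) {
  w <- ranking$windows
  acc <- w[w$accepted, , drop = FALSE]
  acc <- acc[order(acc$accept_order), , drop = FALSE]
  short <- nrow(acc) < k
  top <- head(acc, k)
  share <- if (ranking$sum_var > 0) 100 * sum(top$sigma2) / ranking$sum_var else 0
  attr(top, "share_pct") <- share
  attr(top, "short") <- short
  top
}

#' Random non-overlapping window set
#'
#' Uniform sequential sampling of windows without replacement, rejecting any
#' pick that overlaps a previously accepted pick, until `k` windows are
#' accepted.
#'
#' @param windows all candidate windows ([make_windows()] result or the
#'   `windows` element of a ranking).
#' @param k set size (default 300).
#' @param seed integer seed.
#' @param allow_short if `TRUE`, return the maximal non-overlapping set found
#'   (flagged via `attr(, "short")`) instead of erroring when `k` picks
#'   cannot be placed.
#' @return Data frame of the selected windows (in acceptance order).
#' @export
select_random_k <- function(windows, k = 300L, seed = 1L,
                            allow_short = FALSE) {
  w <- as.data.frame(windows)
  set.seed(stage_seed(seed, "randomk"))
  ord <- sample.int(nrow(w))
  chosen <- integer(0)
  for (i in ord) {
    ov <- any(w$chrom[chosen] == w$chrom[i] &
                w$start[chosen] < w$end[i] & w$start[i] < w$end[chosen])
    if (!ov) {
      chosen <- c(chosen, i)
      if (length(chosen) == k) break
    }
  }
  if (length(chosen) < k && !allow_short)
    stop("cannot place ", k, " non-overlapping windows")
  out <- w[chosen, , drop = FALSE]
  attr(out, "short") <- length(chosen) < k
  out
}

#' Per-window overlap predicates (E, G, EG, C, EC, EGC)
#'
#' Evaluates, for every window, the filter chain used to compare window
#' sets: E - some variant in the window is an eQTL (p <= p_E) for a gene
#' within `radius`; G - some member variant's genotype correlates with the
#' window's local GEBV (p <= p_G); EG - one variant satisfies both for the
#' same gene; C - the window's local GEBV correlates with the expression of a
#' gene within `radius` (p <= p_C); EC - E and C hold for the same gene;
#' EGC - EG and C hold for the same gene with consistent effect directions
#' (sign of the variant's expression effect times the sign of its GEBV
#' correlation equals the sign of the GEBV-expression correlation).
#'
#' @param windows all windows (the universe the sets are drawn from).
#' @param eqtl_stats `AssocStats` from [eqtl_scan()].
#' @param geno_gebv result of [correlate_genotype_gebv()].
#' @param gebv_expr result of [correlate_gebv_expression()].
#' @param genes gene table (`gene`, `chrom`, `start`, `end`).
#' @param p_E,p_G,p_C thresholds (defaults `1e-5`, `1e-5`, `1e-3`).
#' @param radius gene-to-window radius (default 1 Mb).
#' @return Logical matrix windows x c(E, G, EG, C, EC, EGC) with window ids
#'   as rownames.
#' @export
enrichment_flags <- function(windows, eqtl_stats, geno_gebv, gebv_expr,
                             genes, p_E = 1e-5, p_G = 1e-5, p_C = 1e-3,
                             radius = 1e6) {
  w <- as.data.frame(windows)
  nw <- nrow(w)
  flags <- matrix(FALSE, nw, 6,
                  dimnames = list(w$window, c("E", "G", "EG", "C", "EC", "EGC")))
  es <- eqtl_stats[!is.na(eqtl_stats$p) & eqtl_stats$p <= p_E, , drop = FALSE]
  gg <- geno_gebv[!is.na(geno_gebv$p) & geno_gebv$p <= p_G, , drop = FALSE]
  ce <- gebv_expr[!is.na(gebv_expr$p), , drop = FALSE]
  gspan <- genes[match(es$gene, genes$gene), c("chrom", "start", "end")]

  for (k in seq_len(nw)) {
    wid <- w$window[k]
    # eQTL hits whose variant lies in this window and whose gene is near it
    in_win <- es$chrom == w$chrom[k] & es$pos >= w$start[k] & es$pos < w$end[k] &
      gspan$chrom == w$chrom[k] &
      gspan$end >= w$start[k] - radius & gspan$start < w$end[k] + radius
    hits_E <- es[in_win, , drop = FALSE]
    g_hits <- gg[gg$window == wid, , drop = FALSE]
    c_hits <- ce[ce$window == wid & ce$p <= p_C, , drop = FALSE]

    E <- nrow(hits_E) > 0
    G <- nrow(g_hits) > 0
    eg <- merge(hits_E[, c("variant", "gene", "direction")],
                g_hits[, c("variant", "r")], by = "variant")
    EG <- nrow(eg) > 0
    C <- nrow(c_hits) > 0
    EC <- E && C && any(hits_E$gene %in% c_hits$gene)
    EGC <- FALSE
    if (EG && C) {
      egc <- merge(eg, c_hits[, c("gene", "r")], by = "gene",
                   suffixes = c("_geno", "_expr"))
      if (nrow(egc))
        EGC <- any(sign(egc$direction) * sign(egc$r_geno) == sign(egc$r_expr))
    }
    flags[k, ] <- c(E, G, EG, C, EC, EGC)
  }
  flags
}

#' Enrichment counts for a window set
#'
#' Sums the per-window predicates over the members of a window set (e.g. a
#' top-k or random-k set).
#'
#' @param set window set (data frame with a `window` column).
#' @param flags result of [enrichment_flags()] over the full window universe.
#' @param label set label (e.g. "top300", "random300_01").
#' @return One-row data frame of class `EnrichmentCounts`: `label`, `nE`,
#'   `nG`, `nEG`, `nC`, `nEC`, `nEGC`, `size`.
#' @export
enrichment_counts <- function(set, flags, label = "set") {
  idx <- match(as.character(set$window), rownames(flags))
  if (any(is.na(idx))) stop("set contains windows absent from the flag table")
  s <- colSums(flags[idx, , drop = FALSE])
  out <- data.frame(label = label, nE = s["E"], nG = s["G"], nEG = s["EG"],
                    nC = s["C"], nEC = s["EC"], nEGC = s["EGC"],
                    size = length(idx))
  rownames(out) <- NULL
  structure(out, class = c("EnrichmentCounts", "data.frame"))
}

#' False discovery rate estimator
#'
#' Expected false positives over observed positives: `(t * n_tests) / n_sign`
#' for `n_sign` tests significant at threshold `t` out of `n_tests`. Returns
#' `NA` (flagged undefined) when `n_sign = 0`.
#'
#' @param n_sign number of tests with `p <= t`.
#' @param n_tests total number of tests.
#' @param t significance threshold in (0, 1).
#' @return Estimated FDR (may exceed 1 when significant calls are fewer than
#'   expected by chance).
#' @export
fdr <- function(n_sign, n_tests, t) {
  stopifnot(t > 0, t < 1, n_sign >= 0, n_sign <= n_tests)
  if (n_sign == 0) {
    warning("n_sign = 0: FDR undefined")
    return(NA_real_)
  }
  (t * n_tests) / n_sign
}
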