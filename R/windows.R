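# Local GEBV machinery: sliding-window construction, per-window GEBVs and
# variances, the greedy non-overlapping ranking behind sum(sigma2_locGEBV),
# and the within-window effect permutation used for the LD null.

#' Build sliding windows over a variant map
#'
#' Per chromosome, candidate starts are `1 + k * step` for `k = 0, 1, ...`
#' while the start does not exceed the largest variant position. Windows are
#' half-open `[start, start + size)`; windows containing no variant are
#' dropped.
#'
#' @param variants data frame with `chrom` and `pos` columns (or a
#'   `GenotypeSet`), sorted by position within chromosome.
#' @param size window size in bp (default 250 kb).
#' @param step distance between adjacent window starts (default 50 kb);
#'   `size` must be a multiple of `step`.
#' @return A data frame of class `gebv_windows`: `window`, `chrom`, `start`,
#'   `end` (exclusive) and a `members` list column of variant indices into
#'   the supplied variant table.
#' @export
make_windows <- function(variants, size = 250000L, step = 50000L) {
  if (inherits(variants, "GenotypeSet")) variants <- variants$variants
  stopifnot(size %% step == 0)
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    pos <- variants$pos[idx]
    if (is.unsorted(pos)) stop("variant positions must be sorted")
    starts <- seq(1, max(pos), by = step)
    lo <- findInterval(starts - 1, pos) + 1          # first member index
    hi <- findInterval(starts + size - 1, pos)       # last member (pos < end)
    keep <- hi >= lo
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = starts[keep], end = starts[keep] + size,
      members = I(lapply(which(keep), function(k) idx[lo[k]:hi[k]])))
  }
  w <- do.call(rbind, out)
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  w <- cbind(window = seq_len(nrow(w)), w)
  rownames(w) <- NULL
  structure(w, class = c("gebv_windows", "data.frame"))
}

#' Local GEBVs and window variances
#'
#' `locGEBV[w, i] = sum_{j in w} dosage_ij * a_j`; the per-window variance is
#' the sample variance (denominator n - 1) of the local GEBV across
#' individuals.
#'
#' @param g a `GenotypeSet` (typically the expression cohort).
#' @param eff an `EffectEstimates` or bare effect vector aligned with `g`.
#' @param windows result of [make_windows()] over the variants of `g`.
#' @return A list of class `LocalGebvSet`: `windows`, `gebv` (windows x
#'   individuals) and `var` (per-window variance).
#' @export
local_gebv <- function(g, eff, windows) {
  a <- aligned_effects(g, eff)
  m <- n_variants(g)
  mem <- windows$members
  if (any(unlist(mem) > m | unlist(mem) < 1))
    stop("window references unknown variants")
  contrib <- sweep(g$dosages, 2, a, `*`)             # n x m
  M <- Matrix::sparseMatrix(
    i = unlist(mem),
    j = rep(seq_along(mem), lengths(mem)),
    x = 1, dims = c(m, length(mem)))
  gebv <- t(as.matrix(contrib %*% M))                # W x n
  dimnames(gebv) <- NULL
  v <- apply(gebv, 1, var)
  structure(list(windows = windows, gebv = gebv, var = v),
            class = "LocalGebvSet")
}

#' @export
print.LocalGebvSet <- function(x, ...) {
  cat(sprintf("LocalGebvSet: %d windows x %d individuals\n",
              nrow(x$gebv), ncol(x$gebv)))
  invisible(x)
}

#' Greedy non-overlapping window ranking
#'
#' Windows are swept in descending variance (ties broken by chromosome then
#' start ascending); a window is accepted iff its bp range overlaps no
#' previously accepted window on the same chromosome. `sum_var` is the sum of
#' accepted variances (the total local-GEBV variance) and `var_pct` expresses
#' every window's variance as a percentage of that sum.
#'
#' @param lg a `LocalGebvSet`.
#' @return A list of class `NonOverlapRanking`: `windows` (with `sigma2`,
#'   `var_pct`, `accepted`, `accept_order`), `accepted` (window ids in
#'   acceptance order), `U` (accepted count) and `sum_var`.
#' @export
rank_nonoverlapping <- function(lg) {
  w <- as.data.frame(lg$windows)
  stopifnot(nrow(w) >= 1)
  w$sigma2 <- lg$var
  ord <- order(-w$sigma2, w$chrom, w$start)
  accepted <- integer(0)
  acc_order <- rep(NA_integer_, nrow(w))
  for (i in ord) {
    ov <- FALSE
    for (j in accepted) {
      if (w$chrom[j] == w$chrom[i] &&
          w$start[j] < w$end[i] && w$start[i] < w$end[j]) { ov <- TRUE; break }
    }
    if (!ov) {
      accepted <- c(accepted, i)
      acc_order[i] <- length(accepted)
    }
  }
  sum_var <- sum(w$sigma2[accepted])
  w$var_pct <- if (sum_var > 0) 100 * w$sigma2 / sum_var else 0
  w$accepted <- !is.na(acc_order)
  w$accept_order <- acc_order
  structure(list(windows = w, accepted = w$window[accepted],
                 U = length(accepted), sum_var = sum_var),
            class = "NonOverlapRanking")
}

#' @export
print.NonOverlapRanking <- function(x, ...) {
  cat(sprintf("NonOverlapRanking: U = %d non-overlapping windows, sum sigma2 = %.4g\n",
              x$U, x$sum_var))
  invisible(x)
}

#' Permute effects within each window
#'
#' For each window independently, the multiset of member effects is randomly
#' reassigned to member positions. Because sliding windows overlap, a variant
#' shared by several windows is permuted separately within each of them; the
#' result is therefore stored per window.
#'
#' @param eff an `EffectEstimates` or bare effect vector.
#' @param windows result of [make_windows()].
#' @param seed integer seed; deterministic under a fixed seed.
#' @return A list of class `PermutedEffects` with per-window permuted member
#'   effects, consumable by [local_gebv_permuted()].
#' @export
permute_effects_within_windows <- function(eff, windows, seed = 1L) {
  a <- if (is.numeric(eff)) eff else eff$effects$effect
  set.seed(stage_seed(seed, "permute"))
  perm <- lapply(windows$members, function(mem) {
    v <- a[mem]
    if (length(v) > 1) v <- v[sample.int(length(v))]
    v
  })
  structure(list(windows = windows, effects_by_window = perm),
            class = "PermutedEffects")
}

#' Local GEBVs from within-window permuted effects
#'
#' @param g a `GenotypeSet`.
#' @param perm a `PermutedEffects` from [permute_effects_within_windows()].
#' @return A `LocalGebvSet` whose window GEBVs use each window's permuted
#'   member effects.
#' @export
local_gebv_permuted <- function(g, perm) {
  stopifnot(inherits(perm, "PermutedEffects"))
  w <- perm$windows
  n <- n_individuals(g)
  gebv <- matrix(0, nrow(w), n)
  for (k in seq_len(nrow(w))) {
    mem <- w$members[[k]]
    gebv[k, ] <- drop(g$dosages[, mem, drop = FALSE] %*%
                        perm$effects_by_window[[k]])
  }
  v <- apply(gebv, 1, var)
  structure(list(windows = w, gebv = gebv, var = v),
            class = "LocalGebvSet")
}
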