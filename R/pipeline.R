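# Orchestration and I/O: YAML-configurable end-to-end runs tying together
# simulation, GWAS + meta-analysis, Bayes R, local-GEBV windows, cis-eQTL,
# overlap analyses and colocalisation, with TSV/BED/VCF outputs.
# All internal and TSV coordinates are 1-based; BED exports are 0-based
# half-open.

#' Default run configuration
#'
#' Returns the full nested configuration driving [run_all()]. Every value can
#' be overridden via `...` (top-level sections) or by editing the returned
#' list; [read_config()] loads the same structure from YAML.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param ... named top-level sections to replace (e.g.
#'   `genotypes = list(...)`); replacement is per-field within a section.
#' @return Nested list of class `RunConfig`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genotypes = list(n_per_breed = c(A = 1500L, B = 500L),
                     m_variants = 5000L,
                     chrom_lengths = c(6e7, 6e7),
                     fst = 0.1, ld_block_scale = 5e4, n_founders = 20L),
    truth = list(n_trait_qtl = 30L, n_eqtl = 30L, n_shared = 10L,
                 effect_sd = 1, expr_effect_sd = 1),
    phenotypes = list(h2 = 0.25,
                      accuracy = c(male = 0.95, female = 0.6)),
    expression = list(n_genes = 300L, baseline_log_mean = 3,
                      dispersion = 0.3, cell_types = "milk",
                      cohort_sizes = c(105L, 26L)),
    filters = list(maf_floor = 0.002, r2_cap = 0.9, prune_window = 5e5),
    gwas = list(p_thresh = 1e-6, spacing = 1e6),
    bayesr = list(iterations = 2500L, burn_in = 500L, thin = 4L),
    windows = list(size = 250000L, step = 50000L),
    eqtl = list(min_expressed = 25L, radius = 1e6, p_thresh = 1e-5),
    overlap = list(p_select = 1e-5, p_E = 1e-5, p_G = 1e-5, p_C = 1e-3,
                   perm_reps = 100L, k = 300L, random_reps = 100L,
                   residualize = TRUE),
    coloc = list(gamma = 0.01, ncp_sd = 5.2, max_causals = 2L,
                 cap = 50L, clpp_threshold = 0.01))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (f in names(dots[[nm]])) cfg[[nm]][[f]] <- dots[[nm]][[f]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  th <- c(cfg$gwas$p_thresh, cfg$eqtl$p_thresh, cfg$overlap$p_select,
          cfg$overlap$p_C, cfg$coloc$clpp_threshold)
  if (any(th <= 0 | th >= 1)) stop("thresholds must be in (0, 1)")
  if (cfg$overlap$perm_reps < 1 || cfg$overlap$random_reps < 1)
    stop("replicate counts must be >= 1")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields missing from the file keep their defaults.
#' @return A `RunConfig`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1L
  y$seed <- NULL
  do.call(default_config, c(list(seed = seed), y))
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(cfg), f)
  unname(tools::md5sum(f))
}

tsv_header <- function(cfg) {
  c(sprintf("# eqtloverlap %s", as.character(utils::packageVersion("eqtloverlap"))),
    sprintf("# config_hash=%s seed=%d", config_hash(cfg), cfg$seed),
    "# coordinates are 1-based; windows are half-open [start, end)")
}

write_tsv <- function(df, path, cfg = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) writeLines(tsv_header(cfg), con)
  df <- as.data.frame(df)
  df$members <- NULL  # list columns are not serializable
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data frame with `chrom`, `start` (1-based), `end` (exclusive).
#' @param path output path.
#' @param names optional name column values.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path, names = NULL) {
  bed <- data.frame(chrom = df$chrom, start = df$start - 1, end = df$end - 1,
                    name = if (is.null(names)) "." else names)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write genotypes to a dosage TSV or VCF
#'
#' The TSV carries sample metadata in `##individual` comment lines followed
#' by a variant-per-row table (`id`, `chrom`, `pos`, then one dosage column
#' per individual). The VCF stores rounded genotypes in GT and the dosage in
#' a DS FORMAT field, with breed/sex in `##SAMPLE` header lines.
#'
#' @param g a `GenotypeSet`.
#' @param path output path; format chosen by extension (`.vcf` or anything
#'   else for TSV) unless `format` is given.
#' @param format "tsv" or "vcf".
#' @return The path, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("##individual\t%s\t%s\t%s", g$individuals$id,
                       g$individuals$breed, g$individuals$sex), con)
    tab <- cbind(g$variants[, c("id", "chrom", "pos")],
                 as.data.frame(t(g$dosages)))
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
                 sprintf("##SAMPLE=<ID=%s,Breed=%s,Sex=%s>", g$individuals$id,
                         g$individuals$breed, g$individuals$sex),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", g$individuals$id),
                       collapse = "\t")), con)
    gt <- c("0/0", "0/1", "1/1")[pmin(pmax(round(t(g$dosages)), 0), 2) + 1]
    gt <- matrix(gt, nrow = ncol(g$dosages))
    body <- apply(cbind(g$variants$chrom, g$variants$pos, g$variants$id,
                        "A", "G", ".", "PASS", ".", "GT:DS",
                        matrix(paste0(gt, ":",
                                      format(t(g$dosages), trim = TRUE)),
                               nrow = ncol(g$dosages))),
                  1, paste, collapse = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read genotypes from a dosage TSV or VCF
#'
#' Missing dosages are mean-imputed per variant and the imputation count is
#' reported in `attr(, "n_imputed")` and a message. An unsorted chromosome
#' raises an error naming the offending position.
#'
#' @param path file written by [write_genotypes()] (or any VCF with GT and
#'   optionally DS).
#' @return A `GenotypeSet`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_genotypes_vcf(path))
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##individual")]
  ind <- do.call(rbind, strsplit(meta, "\t"))
  individuals <- data.frame(id = ind[, 2], breed = ind[, 3], sex = ind[, 4])
  tab <- read.table(text = lines[!startsWith(lines, "##")], header = TRUE,
                    sep = "\t", check.names = FALSE)
  variants <- data.frame(id = as.character(tab$id), chrom = tab$chrom,
                         pos = tab$pos)
  check_sorted_variants(variants)
  dos <- t(as.matrix(tab[, individuals$id, drop = FALSE]))
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    for (j in seq_len(ncol(dos))) {
      miss <- is.na(dos[, j])
      if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
    }
    message("mean-imputed ", n_imp, " missing dosage(s)")
  }
  variants$af <- colMeans(dos) / 2
  g <- genotype_set(dos, variants, individuals)
  attr(g, "n_imputed") <- n_imp
  g
}

check_sorted_variants <- function(variants) {
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    bad <- which(diff(p) <= 0)
    if (length(bad))
      stop("variants not sorted on chromosome ", ch, " near position ",
           p[bad[1] + 1])
  }
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  variants <- data.frame(id = fix[, "ID"],
                         chrom = as.integer(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]))
  check_sorted_variants(variants)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(al)
        sum(as.numeric(al)), numeric(1))
    })
  }
  dos <- t(ds)
  n_imp <- sum(is.na(dos))
  if (n_imp > 0) {
    for (j in seq_len(ncol(dos))) {
      miss <- is.na(dos[, j])
      if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
    }
    message("mean-imputed ", n_imp, " missing dosage(s)")
  }
  meta <- v@meta[grepl("^##SAMPLE=", v@meta)]
  ids <- colnames(v@gt)[-1]
  breed <- rep("A", length(ids)); sex <- rep("female", length(ids))
  if (length(meta)) {
    sid <- sub(".*ID=([^,>]+).*", "\\1", meta)
    sb <- sub(".*Breed=([^,>]+).*", "\\1", meta)
    ss <- sub(".*Sex=([^,>]+).*", "\\1", meta)
    mi <- match(ids, sid)
    breed <- ifelse(is.na(mi), breed, sb[mi])
    sex <- ifelse(is.na(mi), sex, ss[mi])
  }
  individuals <- data.frame(id = ids, breed = breed, sex = sex)
  variants$af <- colMeans(dos) / 2
  g <- genotype_set(dos, variants, individuals)
  attr(g, "n_imputed") <- n_imp
  g
}

#' Run the full pipeline
#'
#' Executes simulation, genotype filtering, sex-stratified GWAS with
#' meta-analysis, Bayes R effect estimation, local-GEBV windows and ranking,
#' cis-eQTL scanning, the overlap analyses (correlations, permutation
#' comparison, top-k vs random-k enrichment, FDR summaries) and
#' colocalisation, writing stage outputs as TSV/BED into `out_dir`. A rerun
#' with the same configuration is bit-identical. A stage failure aborts with
#' a stage-named error, keeping the outputs already written.
#'
#' @param cfg a `RunConfig` (or a path to a YAML config).
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with the main stage objects and a `summary`
#'   list (also written to `summary.yaml`).
#' @export
run_all <- function(cfg = default_config(), out_dir = tempfile("run"),
                    quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say("stage %-10s %6.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  seed <- cfg$seed

  sim <- stage("simulate", {
    g <- do.call(simulate_genotypes, c(cfg$genotypes, list(seed = seed)))
    truth <- do.call(implant_truth, c(list(g = g), cfg$truth,
                                      list(seed = seed)))
    ph <- simulate_phenotypes(g, truth, h2 = cfg$phenotypes$h2,
                              accuracy = unlist(cfg$phenotypes$accuracy),
                              seed = seed)
    truth <- attr(ph, "truth")  # effects rescaled to the target h2
    exprs <- lapply(cfg$expression$cell_types, function(ct)
      simulate_expression(g, truth, n_genes = cfg$expression$n_genes,
                          baseline_log_mean = cfg$expression$baseline_log_mean,
                          dispersion = cfg$expression$dispersion,
                          cell_type = ct, seed = seed))
    names(exprs) <- cfg$expression$cell_types
    list(g = g, truth = truth, ph = ph, exprs = exprs)
  })
  write_tsv(sim$ph, file.path(out_dir, "phenotypes.tsv"), cfg)
  write_tsv(data.frame(sim$truth$trait_causals),
            file.path(out_dir, "truth_trait.tsv"), cfg)
  write_tsv(data.frame(sim$truth$expr_causals),
            file.path(out_dir, "truth_expr.tsv"), cfg)

  gf <- stage("filter", do.call(filter_variants,
                                c(list(g = sim$g), cfg$filters[c("maf_floor", "r2_cap")],
                                  list(window_bp = cfg$filters$prune_window))))

  trait <- unique(sim$ph$trait)[1]
  pht <- sim$ph[sim$ph$trait == trait, ]
  y <- pht$deviation

  assoc <- stage("gwas", {
    strata <- lapply(c(male = "male", female = "female"), function(sx) {
      idx <- which(gf$individuals$sex == sx)
      gs <- subset_genotypes(gf, individuals = idx)
      X <- stats::model.matrix(~ breed, data = gs$individuals)
      if (qr(X)$rank < ncol(X)) X <- X[, 1, drop = FALSE]
      grm <- compute_grm(gs)
      vc <- fit_null_variance(y[idx], X, grm)
      gwas_scan(gs, y[idx], X, grm, vc, study = paste0("gwas_", sx))
    })
    meta <- meta_weighted_z(strata, study = "meta")
    qtl <- select_qtl(meta, cfg$gwas$p_thresh, cfg$gwas$spacing, trait)
    list(strata = strata, meta = meta, qtl = qtl)
  })
  write_tsv(assoc$meta, file.path(out_dir, "gwas_meta.tsv"), cfg)
  write_tsv(assoc$qtl, file.path(out_dir, "qtl_calls.tsv"), cfg)
  if (nrow(assoc$qtl))
    write_bed(data.frame(chrom = assoc$qtl$chrom, start = assoc$qtl$pos,
                         end = assoc$qtl$pos + 1),
              file.path(out_dir, "qtl_calls.bed"), names = assoc$qtl$variant)

  eff <- stage("bayesr", {
    bcfg <- bayesr_config(cfg$bayesr$iterations, cfg$bayesr$burn_in,
                          cfg$bayesr$thin, seed = stage_seed(seed, "bayesr"))
    bayes_r_fit(gf, y, bcfg)
  })
  write_tsv(eff$effects, file.path(out_dir, "effects.tsv"), cfg)

  e1 <- sim$exprs[[1]]
  cohort <- attr(e1, "cohort")
  gco <- subset_genotypes(gf, individuals = cohort)

  win <- stage("windows", {
    windows <- make_windows(gco$variants, cfg$windows$size, cfg$windows$step)
    lg <- local_gebv(gco, aligned_effects(gco, eff), windows)
    ranking <- rank_nonoverlapping(lg)
    list(windows = windows, lg = lg, ranking = ranking)
  })
  write_tsv(cbind(win$ranking$windows[, c("window", "chrom", "start", "end",
                                          "sigma2", "var_pct", "accepted",
                                          "accept_order")],
                  n_variants = lengths(win$windows$members)),
            file.path(out_dir, "windows.tsv"), cfg)
  acc <- win$ranking$windows[win$ranking$windows$accepted, ]
  write_bed(acc, file.path(out_dir, "windows_accepted.bed"),
            names = acc$window)

  eq <- stage("eqtl", {
    gseq <- filter_variants(subset_genotypes(sim$g, individuals = cohort),
                            maf_floor = cfg$filters$maf_floor, r2_cap = 1)
    res <- lapply(sim$exprs, function(e) {
      ef <- filter_genes(e, cfg$eqtl$min_expressed)
      grm <- compute_grm(gseq)
      pairs <- cis_pairs(gseq, ef, cfg$eqtl$radius)
      st <- eqtl_scan(gseq, ef, grm, pairs)
      list(e = ef, stats = st, calls = select_eqtl(st, cfg$eqtl$p_thresh))
    })
    list(gseq = gseq, res = res)
  })
  eq1 <- eq$res[[1]]
  write_tsv(eq1$stats, file.path(out_dir, "eqtl_stats.tsv"), cfg)
  write_tsv(eq1$calls, file.path(out_dir, "eqtl_calls.tsv"), cfg)

  ov <- stage("overlap", {
    corr <- correlate_gebv_expression(win$lg, eq1$e, cfg$eqtl$radius,
                                      cfg$overlap$p_select,
                                      cfg$overlap$residualize)
    gg <- correlate_genotype_gebv(gco, win$lg)
    perm <- permutation_comparison(gco, aligned_effects(gco, eff),
                                   win$windows, eq1$e,
                                   reps = cfg$overlap$perm_reps,
                                   p_select = cfg$overlap$p_select,
                                   radius = cfg$eqtl$radius,
                                   residualize = cfg$overlap$residualize,
                                   seed = stage_seed(seed, "perm"))
    flags <- enrichment_flags(win$windows, eq1$stats, gg, corr, eq1$e$genes,
                              cfg$overlap$p_E, cfg$overlap$p_G,
                              cfg$overlap$p_C, cfg$eqtl$radius)
    topk <- select_top_k(win$ranking, cfg$overlap$k)
    top_counts <- enrichment_counts(topk, flags,
                                    paste0("top", cfg$overlap$k))
    rand_counts <- do.call(rbind, lapply(seq_len(cfg$overlap$random_reps),
      function(r) {
        rs <- select_random_k(win$windows, min(cfg$overlap$k, nrow(topk)),
                              seed = stage_seed(seed, paste0("rk", r)),
                              allow_short = TRUE)
        enrichment_counts(rs, flags, sprintf("random%d_%03d",
                                             cfg$overlap$k, r))
      }))
    fdr_tab <- data.frame(
      analysis = c("gwas", "eqtl", "correlation"),
      t = c(cfg$gwas$p_thresh, cfg$eqtl$p_thresh, cfg$overlap$p_select),
      n_tests = c(sum(!is.na(assoc$meta$p)), sum(!is.na(eq1$stats$p)),
                  nrow(corr)),
      n_sign = c(sum(assoc$meta$p <= cfg$gwas$p_thresh, na.rm = TRUE),
                 sum(eq1$stats$p <= cfg$eqtl$p_thresh, na.rm = TRUE),
                 sum(corr$selected)))
    fdr_tab$fdr <- mapply(function(s, nt, t)
      if (s > 0) fdr(s, nt, t) else NA_real_,
      fdr_tab$n_sign, fdr_tab$n_tests, fdr_tab$t)
    list(corr = corr, gg = gg, perm = perm, flags = flags, topk = topk,
         top_counts = top_counts, rand_counts = rand_counts,
         fdr_tab = fdr_tab)
  })
  write_tsv(ov$corr, file.path(out_dir, "correlations.tsv"), cfg)
  write_tsv(rbind(ov$top_counts, ov$rand_counts),
            file.path(out_dir, "enrichment.tsv"), cfg)
  write_tsv(data.frame(replicate = c(0, seq_along(ov$perm$permuted)),
                       type = c("observed", rep("permuted",
                                                length(ov$perm$permuted))),
                       count = c(ov$perm$observed, ov$perm$permuted)),
            file.path(out_dir, "permutation.tsv"), cfg)
  write_tsv(ov$fdr_tab, file.path(out_dir, "fdr_summary.tsv"), cfg)

  col <- stage("coloc", {
    loci <- build_loci(assoc$qtl, eq1$calls, eq$gseq, assoc$meta, eq1$stats,
                       eq1$e$genes, cfg$eqtl$radius, cfg$coloc$cap)
    records <- coloc_scan(loci, cfg$coloc$gamma, cfg$coloc$ncp_sd,
                          cfg$coloc$max_causals, cfg$coloc$clpp_threshold)
    summary <- colocalisation_summary(records, assoc$qtl, eq1$calls)
    list(loci = loci, records = records, summary = summary)
  })
  write_tsv(col$records, file.path(out_dir, "clpp.tsv"), cfg)
  write_tsv(col$summary, file.path(out_dir, "coloc_summary.tsv"), cfg)

  summary <- list(
    config_hash = config_hash(cfg), seed = seed,
    n_individuals = n_individuals(sim$g),
    n_variants_simulated = n_variants(sim$g),
    n_variants_filtered = n_variants(gf),
    n_qtl = nrow(assoc$qtl),
    n_windows = nrow(win$windows), U = win$ranking$U,
    sum_var = win$ranking$sum_var,
    n_eqtl_genes = nrow(eq1$calls),
    n_sig_correlations = ov$perm$observed,
    mean_permuted_correlations = mean(ov$perm$permuted),
    topk_share_pct = attr(ov$topk, "share_pct"),
    topk_nE = ov$top_counts$nE, topk_nEGC = ov$top_counts$nEGC,
    random_mean_nE = mean(ov$rand_counts$nE),
    random_mean_nEGC = mean(ov$rand_counts$nEGC),
    fdr_gwas = ov$fdr_tab$fdr[1], fdr_eqtl = ov$fdr_tab$fdr[2],
    n_QTL_coloc = col$summary$coloc_QTL,
    n_eQTL_coloc = col$summary$coloc_eQTL)
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  say("run complete: %s", out_dir)
  invisible(list(sim = sim, filtered = gf, assoc = assoc, eff = eff,
                 win = win, eqtl = eq, overlap = ov, coloc = col,
                 summary = summary, out_dir = out_dir))
}
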