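#' Run all requested association tests at every SNP of a sample
#'
#' The PC basis and the case-control subsample are computed once per
#' dataset and shared, so the two PC-based methods see identical
#' adjustment inputs.
#'
#' @param sample a [combined_sample()].
#' @param methods subset of `c("chen_lin", "zhu", "zhang")`.
#' @param L number of principal components for the PC-based methods.
#' @param snp SNP id(s) or indices; default all.
#' @param alpha_h level of the Chen & Lin homogeneity pre-test.
#' @param cc_rule case-control subsampling rule (see
#'   [build_cc_subsample()]).
#' @return data frame, one row per SNP x method, standard result columns
#'   first, method diagnostics after.
#' @export
association_scan <- function(sample,
                             methods = c("chen_lin", "zhu", "zhang"),
                             L = 10L, snp = NULL, alpha_h = 0.05,
                             cc_rule = "probands_plus_unrelated_controls_plus_control_offspring") {
  stopifnot(inherits(sample, "combined_sample"))
  methods <- match.arg(methods, c("chen_lin", "zhu", "zhang"),
                       several.ok = TRUE)
  cols <- resolve_snp_cols(sample, snp)
  out <- list()

  if (any(methods %in% c("zhu", "zhang"))) {
    ctx <- prepare_adjustment(sample, L)
    if ("zhu" %in% methods) out$zhu <- zhu_scan(ctx, cols)
    if ("zhang" %in% methods) {
      zctx <- prepare_zhang(sample, L, ctx = ctx)
      out$zhang <- zhang_scan(zctx, cols)
    }
  }
  if ("chen_lin" %in% methods) {
    cc <- build_cc_subsample(sample, rule = cc_rule)
    out$chen_lin <- do.call(rbind, lapply(cols, function(j)
      chen_lin_test(sample, j, cc = cc, alpha_h = alpha_h)))
  }
  out <- out[intersect(c("chen_lin", "zhu", "zhang"), names(out))]
  merge_result_frames(out)
}

merge_result_frames <- function(frames) {
  all_cols <- unique(unlist(lapply(frames, names)))
  core <- intersect(result_columns, all_cols)
  all_cols <- c(core, setdiff(all_cols, core))
  frames <- lapply(frames, function(f) {
    for (nm in setdiff(all_cols, names(f))) f[[nm]] <- NA
    f[, all_cols, drop = FALSE]
  })
  do.call(rbind, c(frames, list(make.row.names = FALSE)))
}

#' Experiment configuration for the replicate harness
#'
#' @param n_replicates number of simulation replicates.
#' @param alpha nominal significance level.
#' @param methods methods to run.
#' @param spurious_exclusion SNP ids excluded from the noncausal stratum
#'   in the "spurious genes removed" column of [rejection_rates()].
#' @param L number of principal components.
#' @param seed harness seed (overrides the population config seed when
#'   not `NULL`).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_replicates = 200L, alpha = 0.05,
                              methods = c("chen_lin", "zhu", "zhang"),
                              spurious_exclusion = character(0L),
                              L = 10L, seed = NULL) {
  stopifnot(n_replicates >= 1L, alpha > 0, alpha < 1)
  structure(list(n_replicates = as.integer(n_replicates), alpha = alpha,
                 methods = match.arg(methods,
                                     c("chen_lin", "zhu", "zhang"),
                                     several.ok = TRUE),
                 spurious_exclusion = spurious_exclusion,
                 L = as.integer(L), seed = seed),
            class = "experiment_config")
}

#' Run the replicate simulation experiment
#'
#' For each replicate, generates a sample from the population config
#' (fixed genotypes, redrawn phenotypes by default), runs every requested
#' method at every SNP, and collects the p-values.  Method failures at a
#' SNP are recorded in `status` and the run continues.  Per-replicate
#' results can be checkpointed to a directory and are re-used on rerun.
#'
#' @param pop_config a [population_config()].
#' @param model a [liability_model()]; `NULL` gives the all-null model.
#' @param exp_config an [experiment_config()].
#' @param checkpoint_dir optional directory for per-replicate RDS
#'   checkpoints.
#' @param verbose print per-replicate progress.
#' @return list of class `assoc_experiment`: `results` (data frame with
#'   `replicate` + the scan columns), `snp_info`, `pop_config`,
#'   `exp_config`.
#' @export
run_experiment <- function(pop_config, model = NULL, exp_config,
                           checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(pop_config, "population_config"),
            inherits(exp_config, "experiment_config"))
  if (!is.null(exp_config$seed)) pop_config$seed <- as.integer(exp_config$seed)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)

  snp_info <- NULL
  res <- vector("list", exp_config$n_replicates)
  for (r in seq_len(exp_config$n_replicates)) {
    ck <- if (is.null(checkpoint_dir)) NULL
          else file.path(checkpoint_dir, sprintf("replicate_%04d.rds", r))
    if (!is.null(ck) && file.exists(ck)) {
      chunk <- readRDS(ck)
    } else {
      rep_data <- generate_replicate(pop_config, model, replicate = r)
      if (is.null(snp_info)) snp_info <- rep_data$snp_info
      scan <- association_scan(rep_data$sample,
                               methods = exp_config$methods,
                               L = exp_config$L)
      chunk <- cbind(replicate = r, scan)
      if (!is.null(ck)) saveRDS(chunk, ck)
    }
    res[[r]] <- chunk
    if (verbose) {
      n_bad <- sum(chunk$status != "ok")
      message(sprintf("replicate %d/%d: %d SNP-tests, %d not ok",
                      r, exp_config$n_replicates, nrow(chunk), n_bad))
    }
  }
  if (is.null(snp_info))
    snp_info <- generate_replicate(pop_config, model, replicate = 1L)$snp_info
  structure(list(results = do.call(rbind, res), snp_info = snp_info,
                 pop_config = pop_config, exp_config = exp_config),
            class = "assoc_experiment")
}

#' Empirical rejection rates for noncausal and causal SNPs
#'
#' Average, per method, of `1{p <= alpha}` over SNP x replicate cells
#' within each stratum, in the layout of a noncausal/causal rejection-rate
#' table: all noncausal SNPs, noncausal SNPs with a configured "spurious"
#' exclusion list removed, and causal SNPs.
#'
#' @param results scan results (`data.frame` with `method`, `snp_id`,
#'   `p_value`, `status`) or an `assoc_experiment`.
#' @param snp_info data frame with `snp_id` and `causal` (taken from the
#'   experiment object when one is supplied).
#' @param alpha nominal level.
#' @param exclusions noncausal SNP ids to drop in the exclusion column.
#' @param degenerate `"nonreject"` (default): tests without a p-value
#'   count as non-rejections; `"drop"`: they are removed from the
#'   denominator.
#' @return data frame, one row per method: `rate_noncausal_all`,
#'   `rate_noncausal_excl_spurious`, `rate_causal`, the per-stratum
#'   denominators, and `n_degenerate`.
#' @export
rejection_rates <- function(results, snp_info = NULL, alpha = 0.05,
                            exclusions = character(0L),
                            degenerate = c("nonreject", "drop")) {
  degenerate <- match.arg(degenerate)
  if (inherits(results, "assoc_experiment")) {
    snp_info <- results$snp_info
    alpha <- results$exp_config$alpha
    if (length(results$exp_config$spurious_exclusion) > 0L &&
        length(exclusions) == 0L)
      exclusions <- results$exp_config$spurious_exclusion
    results <- results$results
  }
  if (is.null(snp_info)) stop("snp_info required")
  causal_ids <- snp_info$snp_id[snp_info$causal]
  is_causal <- results$snp_id %in% causal_ids
  rate <- function(df) {
    if (nrow(df) == 0L) return(c(rate = NA_real_, n = 0))
    rej <- !is.na(df$p_value) & df$p_value <= alpha
    if (degenerate == "drop") {
      keep <- df$status == "ok"
      rej <- rej[keep]
    }
    c(rate = mean(rej), n = length(rej))
  }
  out <- lapply(split(seq_len(nrow(results)), results$method), function(idx) {
    df <- results[idx, , drop = FALSE]
    nc <- df[!is_causal[idx], , drop = FALSE]
    nce <- nc[!(nc$snp_id %in% exclusions), , drop = FALSE]
    ca <- df[is_causal[idx], , drop = FALSE]
    a <- rate(nc); b <- rate(nce); d <- rate(ca)
    data.frame(method = df$method[1L],
               rate_noncausal_all = a[["rate"]],
               rate_noncausal_excl_spurious = b[["rate"]],
               rate_causal = d[["rate"]],
               n_noncausal = a[["n"]], n_noncausal_excl = b[["n"]],
               n_causal = d[["n"]],
               n_degenerate = sum(df$status != "ok"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-SNP power and stratum means by MAF class and effect size
#'
#' Empirical power of each method at each causal SNP (the mean over
#' replicates of `1{p <= alpha}`; degenerate tests count as
#' non-rejections), plus mean power within (method, MAF class) strata —
#' the per-SNP table underlying a power-versus-effect-size display
#' faceted by rare/moderate/common MAF.
#'
#' @param results scan results or an `assoc_experiment`.
#' @param snp_info data frame with `snp_id`, `causal`, `beta`,
#'   `maf_class`.
#' @param alpha nominal level.
#' @return list with `per_snp` (method, snp_id, beta, maf_class, power,
#'   n_replicates) and `by_stratum` (method, maf_class, mean_power,
#'   n_snps).
#' @export
power_by_strata <- function(results, snp_info = NULL, alpha = 0.05) {
  if (inherits(results, "assoc_experiment")) {
    snp_info <- results$snp_info
    alpha <- results$exp_config$alpha
    results <- results$results
  }
  causal <- snp_info[snp_info$causal, , drop = FALSE]
  df <- results[results$snp_id %in% causal$snp_id, , drop = FALSE]
  rej <- !is.na(df$p_value) & df$p_value <= alpha
  key <- interaction(df$method, df$snp_id, drop = TRUE)
  per <- data.frame(method = tapply(df$method, key, `[`, 1L),
                    snp_id = tapply(df$snp_id, key, `[`, 1L),
                    power = as.vector(tapply(rej, key, mean)),
                    n_replicates = as.vector(tapply(rej, key, length)),
                    stringsAsFactors = FALSE)
  m <- match(per$snp_id, causal$snp_id)
  per$beta <- causal$beta[m]
  per$maf_class <- causal$maf_class[m]
  per <- per[order(per$method, per$snp_id),
             c("method", "snp_id", "beta", "maf_class", "power",
               "n_replicates")]
  rownames(per) <- NULL
  agg <- stats::aggregate(power ~ method + maf_class, data = per, mean,
                          drop = TRUE)
  names(agg)[names(agg) == "power"] <- "mean_power"
  cnt <- stats::aggregate(power ~ method + maf_class, data = per, length)
  agg$n_snps <- cnt$power
  list(per_snp = per, by_stratum = agg)
}

#' Method-comparison table of SNPs with at least modest power
#'
#' Wide table of per-SNP empirical power (one column per method) for the
#' SNPs where at least one method reaches `min_power`, with the best
#' method per SNP flagged (ties flagged jointly and noted).
#'
#' @param results scan results or an `assoc_experiment`.
#' @param snp_info data frame with `snp_id`, `causal`, `beta`, `maf`.
#' @param alpha nominal level.
#' @param min_power inclusion threshold on the per-SNP maximum power.
#' @return data frame: `snp_id`, `beta`, `maf`, one power column per
#'   method, `best` (comma-joined on ties), `tie`.
#' @export
top_snp_table <- function(results, snp_info = NULL, alpha = 0.05,
                          min_power = 0.2) {
  if (inherits(results, "assoc_experiment")) {
    snp_info <- results$snp_info
    alpha <- results$exp_config$alpha
    results <- results$results
  }
  per <- power_by_strata(results, snp_info, alpha)$per_snp
  if (nrow(per) == 0L) return(empty_top_table())
  wide <- stats::reshape(per[, c("snp_id", "method", "power")],
                         direction = "wide", idvar = "snp_id",
                         timevar = "method")
  names(wide) <- sub("^power\\.", "", names(wide))
  meth <- setdiff(names(wide), "snp_id")
  pw <- as.matrix(wide[, meth, drop = FALSE])
  keep <- apply(pw, 1L, max, na.rm = TRUE) >= min_power
  wide <- wide[keep, , drop = FALSE]
  pw <- pw[keep, , drop = FALSE]
  if (nrow(wide) == 0L) return(empty_top_table())
  best <- apply(pw, 1L, function(x) {
    top <- which(x == max(x, na.rm = TRUE))
    paste(meth[top], collapse = ",")
  })
  m <- match(wide$snp_id, snp_info$snp_id)
  out <- data.frame(snp_id = wide$snp_id, beta = snp_info$beta[m],
                    maf = snp_info$maf[m], stringsAsFactors = FALSE)
  out <- cbind(out, wide[, meth, drop = FALSE])
  out$best <- best
  out$tie <- grepl(",", best)
  rownames(out) <- NULL
  out[order(out$snp_id), , drop = FALSE]
}

empty_top_table <- function() {
  data.frame(snp_id = character(0L), beta = numeric(0L), maf = numeric(0L),
             best = character(0L), tie = logical(0L),
             stringsAsFactors = FALSE)
}
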