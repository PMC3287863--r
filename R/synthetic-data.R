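#' Population / design configuration for the synthetic mini-exome generator
#'
#' Defaults reproduce the evaluation design used throughout: 697 unrelated
#' case-control subjects and 194 complete trios (582 family members), with
#' a rare-skewed minor-allele-frequency spectrum, and a fixed genotype
#' matrix across replicates (phenotypes are redrawn each replicate).
#'
#' @param n_snps number of SNPs.
#' @param maf_spectrum `"rare_skewed"` (default; a mixture placing
#'   `rare_weight` of SNPs log-uniformly below 0.01), `"uniform"`, or
#'   `"fixed_list"` (supply `maf_params$mafs`).
#' @param maf_params spectrum parameters; see [draw_mafs()].
#' @param n_unrelated,n_trios design sizes.
#' @param trio_ascertainment `"mixed"` (default; keep a configured
#'   case:control trio ratio), `"offspring_affected"` (case trios only), or
#'   `"random"` (keep trios regardless of offspring status).
#' @param case_trio_fraction fraction of trios ascertained on an affected
#'   offspring under `"mixed"`.
#' @param unrelated_case_fraction if `NULL` (default) unrelated subjects
#'   are a random population draw (case fraction = prevalence); otherwise
#'   unrelated subjects are ascertained to this case fraction.
#' @param stratification `NULL` (default, homogeneous population — no
#'   stratification is simulated unless requested) or a list
#'   `list(n_subpops = 2, fst = , liability_shift = )` giving
#'   Balding-Nichols allele-frequency divergence between equally sized
#'   subpopulations and a liability offset for the second subpopulation.
#' @param fixed_genotypes if `TRUE` (default) the genotype matrix is a
#'   deterministic function of `seed` and identical across replicates;
#'   only phenotypes are redrawn.
#' @param pool_factor size of the trio pool, as a multiple of `n_trios`,
#'   from which ascertained trios are drawn.
#' @param seed master seed; per-replicate substreams are derived from it.
#' @return list of class `population_config`.
#' @export
population_config <- function(n_snps = 2000L,
                              maf_spectrum = c("rare_skewed", "uniform", "fixed_list"),
                              maf_params = list(),
                              n_unrelated = 697L,
                              n_trios = 194L,
                              trio_ascertainment = c("mixed", "offspring_affected", "random"),
                              case_trio_fraction = 0.5,
                              unrelated_case_fraction = NULL,
                              stratification = NULL,
                              fixed_genotypes = TRUE,
                              pool_factor = 5L,
                              seed = 1L) {
  maf_spectrum <- match.arg(maf_spectrum)
  trio_ascertainment <- match.arg(trio_ascertainment)
  stopifnot(n_snps >= 1L, n_unrelated >= 0L, n_trios >= 0L, pool_factor >= 1L)
  if (!is.null(stratification))
    stopifnot(is.list(stratification), stratification$fst > 0)
  structure(list(n_snps = as.integer(n_snps), maf_spectrum = maf_spectrum,
                 maf_params = maf_params, n_unrelated = as.integer(n_unrelated),
                 n_trios = as.integer(n_trios),
                 trio_ascertainment = trio_ascertainment,
                 case_trio_fraction = case_trio_fraction,
                 unrelated_case_fraction = unrelated_case_fraction,
                 stratification = stratification,
                 fixed_genotypes = fixed_genotypes,
                 pool_factor = as.integer(pool_factor),
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Liability-threshold phenotype model
#'
#' Disease status is 1 when the latent liability
#' \eqn{\ell = \sum_j \beta_j g_j + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma^2)}, exceeds a threshold.  The threshold is either supplied or
#' calibrated (see [calibrate_threshold()]) so that the marginal prevalence
#' is about `target_prevalence`.  The default target of 0.32 mirrors a
#' common, decidedly non-rare disease (prevalence well above 30%).
#'
#' @param mafs per-SNP minor allele frequencies (used for calibration).
#' @param betas per-SNP liability-scale effects; 0 for noncausal SNPs.
#' @param noise_sd standard deviation of the liability noise.
#' @param threshold affection cutoff, or `NULL` to calibrate on demand.
#' @param target_prevalence desired marginal disease prevalence.
#' @return list of class `liability_model`.
#' @export
liability_model <- function(mafs, betas = numeric(length(mafs)), noise_sd = 1,
                            threshold = NULL, target_prevalence = 0.32) {
  stopifnot(length(mafs) == length(betas), noise_sd > 0,
            target_prevalence > 0, target_prevalence < 1)
  structure(list(mafs = mafs, betas = betas, noise_sd = noise_sd,
                 threshold = threshold, target_prevalence = target_prevalence),
            class = "liability_model")
}

#' Default multi-rare-variant liability model
#'
#' Marks a small fraction of SNPs as causal with liability effects drawn
#' uniformly from a moderate-to-strong range, mirroring a mini-exome
#' architecture where common disease risk is carried by multiple rare
#' variants of appreciable penetrance.
#'
#' @param mafs per-SNP minor allele frequencies.
#' @param causal_fraction fraction of SNPs given a nonzero effect.
#' @param beta_range range of the (positive) liability effects.
#' @param ... further arguments to [liability_model()].
#' @return a [liability_model()].
#' @export
default_liability_model <- function(mafs, causal_fraction = 0.02,
                                    beta_range = c(0.1, 1.4), ...) {
  n <- length(mafs)
  n_causal <- max(1L, round(causal_fraction * n))
  betas <- numeric(n)
  idx <- sample.int(n, n_causal)
  betas[idx] <- stats::runif(n_causal, beta_range[1L], beta_range[2L])
  liability_model(mafs, betas, ...)
}

#' Draw a minor allele frequency spectrum
#'
#' `rare_skewed` (the default) draws each MAF from a mixture:
#' with probability `rare_weight` (default 0.7) log-uniform on
#' `rare_range` (default \[2e-4, 0.01\]) and otherwise log-uniform on
#' `common_range` (default \[0.01, 0.5\]), so the majority of SNPs are
#' rare (MAF < 0.01) and MAFs reach the singleton level seen in exome
#' panels.  `uniform` draws from `maf_params$range` (default
#' \[0.05, 0.5\]); `fixed_list` returns `maf_params$mafs` verbatim
#' (recycled to `n_snps`).
#'
#' @param config a [population_config()], or an integer `n_snps`.
#' @param ... with integer `config`, passed on as `maf_params` entries.
#' @return vector of MAFs in (0, 0.5\].
#' @export
draw_mafs <- function(config, ...) {
  if (is.numeric(config))
    config <- population_config(n_snps = config, maf_params = list(...))
  n <- config$n_snps
  p <- config$maf_params
  switch(config$maf_spectrum,
    fixed_list = {
      if (is.null(p$mafs)) stop("fixed_list spectrum needs maf_params$mafs")
      if (any(p$mafs <= 0 | p$mafs > 0.5)) stop("MAFs must lie in (0, 0.5]")
      rep_len(p$mafs, n)
    },
    uniform = {
      r <- if (is.null(p$range)) c(0.05, 0.5) else p$range
      stats::runif(n, r[1L], r[2L])
    },
    rare_skewed = {
      w <- if (is.null(p$rare_weight)) 0.7 else p$rare_weight
      rr <- if (is.null(p$rare_range)) c(2e-4, 0.01) else p$rare_range
      cr <- if (is.null(p$common_range)) c(0.01, 0.5) else p$common_range
      if (w < 0 || w > 1 || any(c(rr, cr) <= 0) || max(c(rr, cr)) > 0.5)
        stop("invalid rare_skewed spectrum parameters")
      rare <- stats::runif(n) < w
      out <- numeric(n)
      out[rare]  <- exp(stats::runif(sum(rare),  log(rr[1L]), log(rr[2L])))
      out[!rare] <- exp(stats::runif(sum(!rare), log(cr[1L]), log(cr[2L])))
      out
    })
}

#' Simulate unrelated genotypes under Hardy-Weinberg equilibrium
#'
#' Entries are independent Binomial(2, freq) draws per SNP — no linkage
#' disequilibrium between SNPs.  Frequencies above 0.5 are allowed so that
#' subpopulation-specific frequencies (which can drift past 0.5) can be
#' simulated; [draw_mafs()] itself only produces minor allele frequencies.
#'
#' @param n number of individuals.
#' @param mafs per-SNP frequencies of the counted allele, in \[0, 1\].
#' @return integer matrix n x length(mafs).
#' @export
simulate_unrelated <- function(n, mafs) {
  stopifnot(all(mafs >= 0 & mafs <= 1))
  m <- length(mafs)
  matrix(stats::rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
}

#' Simulate trio genotypes with Mendelian transmission
#'
#' Parents are independent Hardy-Weinberg draws; each parent transmits one
#' of its two alleles uniformly at random, and the offspring count is the
#' sum of the two transmitted alleles.
#'
#' @param n_trios number of trios.
#' @param mafs per-SNP minor allele frequencies.
#' @return list of integer matrices `father`, `mother`, `offspring`
#'   (each n_trios x length(mafs)).
#' @export
simulate_trio_genotypes <- function(n_trios, mafs) {
  father <- simulate_unrelated(n_trios, mafs)
  mother <- simulate_unrelated(n_trios, mafs)
  offspring <- transmit(father) + transmit(mother)
  list(father = father, mother = mother, offspring = offspring)
}

# one transmitted allele per entry: Bernoulli(g/2)
transmit <- function(g) {
  out <- matrix(stats::rbinom(length(g), 1L, as.vector(g) / 2),
                nrow = nrow(g), ncol = ncol(g))
  out
}

#' Calibrate the liability threshold to a target prevalence
#'
#' Sets the threshold to the empirical (1 - K)-quantile of the liability
#' in a probe cohort of unrelated individuals, so the realised prevalence
#' is about K = `target_prevalence`.  Only causal SNPs contribute to the
#' liability, so the probe simulates genotypes at causal sites only.
#'
#' @param model a [liability_model()].
#' @param n_probe probe cohort size.
#' @return the threshold (numeric scalar).
#' @export
calibrate_threshold <- function(model, n_probe = 1e5) {
  stopifnot(inherits(model, "liability_model"))
  liab <- probe_liability(model, n_probe)
  if (stats::sd(liab) == 0 && all(model$betas == 0))
    return(stats::qnorm(1 - model$target_prevalence, sd = model$noise_sd))
  unname(stats::quantile(liab, 1 - model$target_prevalence, type = 8))
}

probe_liability <- function(model, n_probe) {
  causal <- which(model$betas != 0)
  gen <- if (length(causal) > 0L)
    simulate_unrelated(n_probe, model$mafs[causal]) %*% model$betas[causal]
  else numeric(n_probe)
  as.vector(gen) + stats::rnorm(n_probe, sd = model$noise_sd)
}

#' Assign binary phenotypes under the liability-threshold model
#'
#' @param genotypes integer matrix (individuals x SNPs), columns aligned
#'   with `model$betas`.
#' @param model a [liability_model()] with a threshold set (calibrate
#'   first, or pass `threshold =` explicitly).
#' @param liability_offset optional per-individual liability offset (used
#'   e.g. for a stratified population).
#' @return integer 0/1 vector.
#' @export
assign_phenotypes <- function(genotypes, model, liability_offset = 0) {
  stopifnot(inherits(model, "liability_model"))
  if (is.null(model$threshold))
    stop("liability model has no threshold; call calibrate_threshold() first")
  causal <- which(model$betas != 0)
  gen <- if (length(causal) > 0L)
    as.vector(genotypes[, causal, drop = FALSE] %*% model$betas[causal])
  else numeric(nrow(genotypes))
  liab <- gen + liability_offset + stats::rnorm(nrow(genotypes), sd = model$noise_sd)
  as.integer(liab > model$threshold)
}

# Balding-Nichols subpopulation frequencies around an ancestral MAF
bn_subpop_mafs <- function(mafs, fst) {
  a <- mafs * (1 - fst) / fst
  b <- (1 - mafs) * (1 - fst) / fst
  p <- stats::rbeta(length(mafs), a, b)
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

# deterministic genotype pool for one seed: unrelated subjects + trio pool
build_genotype_pool <- function(config, mafs) {
  strat <- config$stratification
  n_pool <- if (config$trio_ascertainment == "random") config$n_trios
            else config$n_trios * config$pool_factor
  n_unrel_pool <- if (is.null(config$unrelated_case_fraction)) config$n_unrelated
                  else config$n_unrelated * config$pool_factor
  if (is.null(strat)) {
    unrel <- simulate_unrelated(n_unrel_pool, mafs)
    trios <- simulate_trio_genotypes(n_pool, mafs)
    subpop_u <- rep(1L, n_unrel_pool)
    subpop_t <- rep(1L, n_pool)
  } else {
    p1 <- bn_subpop_mafs(mafs, strat$fst)
    p2 <- bn_subpop_mafs(mafs, strat$fst)
    half_u <- n_unrel_pool %/% 2L
    half_t <- n_pool %/% 2L
    unrel <- rbind(simulate_unrelated(half_u, p1),
                   simulate_unrelated(n_unrel_pool - half_u, p2))
    t1 <- simulate_trio_genotypes(half_t, p1)
    t2 <- simulate_trio_genotypes(n_pool - half_t, p2)
    trios <- list(father = rbind(t1$father, t2$father),
                  mother = rbind(t1$mother, t2$mother),
                  offspring = rbind(t1$offspring, t2$offspring))
    subpop_u <- rep(c(1L, 2L), c(half_u, n_unrel_pool - half_u))
    subpop_t <- rep(c(1L, 2L), c(half_t, n_pool - half_t))
  }
  list(unrelated = unrel, trios = trios,
       subpop_unrelated = subpop_u, subpop_trios = subpop_t)
}

#' Generate one simulation replicate
#'
#' Produces a [combined_sample()] with the configured design.  With
#' `fixed_genotypes = TRUE` (the default) the genotype pool is a
#' deterministic function of `config$seed`, identical across replicates,
#' and only phenotypes are redrawn per replicate — the fixed-genotype,
#' redrawn-phenotype replicate design of workshop-style evaluations.
#' Trio ascertainment (`mixed` / `offspring_affected`) selects trios from
#' the pool by realised offspring status; if the pool cannot satisfy the
#' requested counts the replicate errors out rather than biasing the draw.
#'
#' @param config a [population_config()].
#' @param model a [liability_model()] (threshold calibrated on first use,
#'   deterministically under the config seed).
#' @param replicate replicate index (drives the phenotype substream).
#' @return list with `sample` (a [combined_sample()]) and `snp_info`
#'   (data frame: `snp_id`, `maf` (true simulated), `causal`, `beta`,
#'   `maf_class`).
#' @export
generate_replicate <- function(config, model = NULL, replicate = 1L) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  mafs <- draw_mafs(config)
  if (is.null(model)) model <- liability_model(mafs)
  stopifnot(inherits(model, "liability_model"),
            length(model$mafs) == config$n_snps)
  if (is.null(model$threshold)) model$threshold <- calibrate_threshold(model)
  pool <- build_genotype_pool(config, mafs)

  if (!config$fixed_genotypes) {
    set.seed(pheno_seed(config$seed, replicate))
    pool <- build_genotype_pool(config, mafs)
  } else {
    set.seed(pheno_seed(config$seed, replicate))
  }

  shift <- strat_shift(config)
  y_unrel <- assign_phenotypes(pool$unrelated, model,
                               shift * (pool$subpop_unrelated - 1L))
  off_shift <- shift * (pool$subpop_trios - 1L)
  y_father <- assign_phenotypes(pool$trios$father, model, off_shift)
  y_mother <- assign_phenotypes(pool$trios$mother, model, off_shift)
  y_off    <- assign_phenotypes(pool$trios$offspring, model, off_shift)

  keep_u <- select_unrelated(config, y_unrel)
  keep_t <- select_trios(config, y_off)

  assemble_sample(config, model, mafs, pool, keep_u, keep_t,
                  y_unrel, y_father, y_mother, y_off)
}

strat_shift <- function(config) {
  s <- config$stratification
  if (is.null(s) || is.null(s$liability_shift)) 0 else s$liability_shift
}

pheno_seed <- function(seed, replicate) {
  (seed + 1013L * as.integer(replicate)) %% .Machine$integer.max
}

select_unrelated <- function(config, y_unrel) {
  n <- config$n_unrelated
  f <- config$unrelated_case_fraction
  if (is.null(f)) return(seq_len(n))
  n_case <- round(f * n)
  cases <- which(y_unrel == 1L)
  ctrls <- which(y_unrel == 0L)
  if (length(cases) < n_case || length(ctrls) < n - n_case)
    stop("unrelated pool cannot satisfy the requested case fraction; ",
         "increase pool_factor")
  sort(c(cases[seq_len(n_case)], ctrls[seq_len(n - n_case)]))
}

select_trios <- function(config, y_off) {
  n <- config$n_trios
  if (n == 0L) return(integer(0L))
  switch(config$trio_ascertainment,
    random = seq_len(n),
    offspring_affected = {
      idx <- which(y_off == 1L)
      if (length(idx) < n)
        stop("trio pool has too few affected offspring; increase pool_factor")
      idx[seq_len(n)]
    },
    mixed = {
      n_case <- round(config$case_trio_fraction * n)
      cases <- which(y_off == 1L)
      ctrls <- which(y_off == 0L)
      if (length(cases) < n_case || length(ctrls) < n - n_case)
        stop("trio pool cannot satisfy the requested case:control trio ",
             "ratio; increase pool_factor")
      sort(c(cases[seq_len(n_case)], ctrls[seq_len(n - n_case)]))
    })
}

assemble_sample <- function(config, model, mafs, pool, keep_u, keep_t,
                            y_unrel, y_father, y_mother, y_off) {
  snp_ids <- sprintf("S%05d", seq_len(config$n_snps))
  uid <- sprintf("U%04d", keep_u)
  fid_t <- sprintf("T%04d", keep_t)
  id_f <- sprintf("%s_F", fid_t)
  id_m <- sprintf("%s_M", fid_t)
  id_o <- sprintf("%s_O", fid_t)

  ped <- data.frame(
    fid = c(uid, fid_t, fid_t, fid_t),
    id = c(uid, id_f, id_m, id_o),
    father = c(rep(NA_character_, length(uid) + 2L * length(keep_t)), id_f),
    mother = c(rep(NA_character_, length(uid) + 2L * length(keep_t)), id_m),
    sex = c(rep(0L, length(uid)), rep(1L, length(keep_t)),
            rep(2L, length(keep_t)), rep(0L, length(keep_t))),
    affected = c(y_unrel[keep_u], y_father[keep_t], y_mother[keep_t],
                 y_off[keep_t]),
    stringsAsFactors = FALSE)

  geno <- rbind(pool$unrelated[keep_u, , drop = FALSE],
                pool$trios$father[keep_t, , drop = FALSE],
                pool$trios$mother[keep_t, , drop = FALSE],
                pool$trios$offspring[keep_t, , drop = FALSE])
  rownames(geno) <- ped$id
  colnames(geno) <- snp_ids

  snp_info <- data.frame(snp_id = snp_ids, maf = mafs,
                         causal = model$betas != 0, beta = model$betas,
                         maf_class = maf_class(mafs),
                         stringsAsFactors = FALSE)
  list(sample = combined_sample(ped, geno), snp_info = snp_info)
}
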