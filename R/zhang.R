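#' Adjusted population moments for the unrelated subjects
#'
#' The standard principal-components adjustment: the per-individual
#' adjusted trait and genotype means are the fitted values of
#' least-squares regressions (with intercept) of the phenotype and the
#' genotype on the PC scores of the unrelated subjects.  With `L = 0`
#' both reduce to the sample means.
#'
#' @param y 0/1 phenotype vector of the unrelated subjects.
#' @param g genotype vector or matrix (one column per SNP).
#' @param scores PC score matrix for the same individuals (0 columns for
#'   no adjustment).
#' @return list `mu_y` (vector) and `mu_g` (same shape as `g`).
#' @export
adjust_unrelated <- function(y, g, scores) {
  mu_y <- as.vector(ls_fitted(y, scores))
  mu_g <- ls_fitted(g, scores)
  if (is.vector(g)) mu_g <- as.vector(mu_g)
  list(mu_y = mu_y, mu_g = mu_g)
}

#' TDT-like PC adjustment of parental genotypes
#'
#' Removes the principal-component component from the parental genotypes
#' before forming the offspring Mendelian expectation: the PC slopes are
#' estimated by regressing founder genotypes on founder scores, and
#' `g - scores %*% slopes` is returned (no intercept shift, so with
#' `L = 0` the genotypes are returned unchanged and the offspring
#' expectation is exactly \eqn{(g_m + g_f)/2}).
#'
#' @param g parental genotype vector or matrix (one column per SNP).
#' @param scores parental PC scores.
#' @param slopes optional precomputed slope matrix (L x SNPs); when
#'   `NULL`, estimated from `g` and `scores` themselves.
#' @return adjusted genotypes, same shape as `g`.
#' @export
adjust_parents <- function(g, scores, slopes = NULL) {
  if (NCOL(scores) == 0L) return(g)
  gm <- as.matrix(g)
  if (is.null(slopes)) {
    b <- ls_coef(cbind(1, scores), gm)
    slopes <- b[-1L, , drop = FALSE]
  }
  out <- gm - scores %*% slopes
  if (is.vector(g)) as.vector(out) else out
}

#' Mendelian mean and variance of the offspring genotype
#'
#' Under random transmission of one allele per parent, the offspring
#' minor-allele count has mean \eqn{(g_m + g_f)/2} and variance
#' \eqn{(1\{g_m = 1\} + 1\{g_f = 1\})/4} — each heterozygous parent
#' contributes a Bernoulli(1/2) transmission.  The variance is zero
#' exactly when both parents are homozygous.
#'
#' @param g_m,g_f parental minor-allele counts in \{0, 1, 2\} (vectors ok).
#' @return list `e_g` (mean) and `v_g` (variance).
#' @export
mendelian_moments <- function(g_m, g_f) {
  ok <- g_m %in% c(0L, 1L, 2L) & g_f %in% c(0L, 1L, 2L)
  if (!all(ok | is.na(g_m) | is.na(g_f)))
    stop("parental genotypes must be minor-allele counts in {0, 1, 2}")
  list(e_g = (g_m + g_f) / 2,
       v_g = ((g_m == 1L) + (g_f == 1L)) / 4)
}

# Zhang scan over SNP columns (batch matrix path).
# U over unrelated subjects, R over trio offspring, var over both.
zhang_scan <- function(ctx, snp_cols = seq_len(ncol(ctx$geno))) {
  g <- ctx$geno[, snp_cols, drop = FALSE]
  snp_ids <- colnames(ctx$geno)[snp_cols]
  L <- ctx$basis$n_components
  u_rows <- ctx$unrelated_rows
  o_rows <- ctx$offspring_rows
  ped <- ctx$ped

  mono <- apply(g, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || all(v == v[1L])
  })

  n_snp <- ncol(g)
  U <- R <- var_u <- var_r <- rep(0, n_snp)
  status <- rep("ok", n_snp)

  # trait centering for offspring: adjusted mean of the unrelated subjects,
  # falling back to the founder mean when the design has no unrelateds
  if (length(u_rows) > 0L) {
    y_u <- ctx$y[u_rows]
    s_u <- ctx$scores[u_rows, , drop = FALSE]
    g_u <- g[u_rows, , drop = FALSE]
    na_cols <- which(colSums(is.na(g_u)) > 0L)
    g_imp <- g_u
    g_imp[is.na(g_imp)] <- 0L
    adj <- adjust_unrelated(y_u, g_imp, s_u)
    yc <- y_u - adj$mu_y
    gc <- g_imp - adj$mu_g
    U <- colSums(gc * yc)
    sigma2_g <- colMeans(gc^2)
    var_u <- sum(yc^2) * sigma2_g
    # complete-case per marker where unrelated genotypes are missing
    for (j in na_cols) {
      obs <- which(!is.na(g_u[, j]))
      if (length(obs) < 2L) { U[j] <- 0; var_u[j] <- 0; next }
      mu_gj <- as.vector(ls_fitted(g_u[obs, j], s_u[obs, , drop = FALSE]))
      gcj <- g_u[obs, j] - mu_gj
      U[j] <- sum(gcj * yc[obs])
      var_u[j] <- sum(yc[obs]^2) * mean(gcj^2)
    }
    mu_hat_y <- mean(y_u)
  } else {
    mu_hat_y <- mean(ctx$y[ctx$founder_rows])
  }

  if (length(o_rows) > 0L) {
    off_id <- ped$id[o_rows]
    tr <- ctx$trio_geno
    m <- match(off_id, tr$offspring_id)
    gm <- tr$mother[m, snp_cols, drop = FALSE]
    gf <- tr$father[m, snp_cols, drop = FALSE]
    go <- g[o_rows, , drop = FALSE]
    mm <- mendelian_moments(gm, gf)
    # TDT-like PC adjustment of the parental genotypes (slopes from founders)
    if (L > 0L) {
      sm <- ctx$scores_parents$mother[m, , drop = FALSE]
      sf <- ctx$scores_parents$father[m, , drop = FALSE]
      slopes <- ctx$parent_slopes[, snp_cols, drop = FALSE]
      e_adj <- (adjust_parents(gm, sm, slopes) +
                adjust_parents(gf, sf, slopes)) / 2
    } else e_adj <- mm$e_g
    yo <- ctx$y[o_rows] - mu_hat_y
    dev <- go - e_adj
    valid <- !is.na(dev)
    dev[!valid] <- 0
    vg <- mm$v_g
    vg[!valid] <- 0
    R <- colSums(dev * yo)
    var_r <- colSums(vg * yo^2)
  }

  Z <- U + R
  var_z <- var_u + var_r
  stat <- ifelse(var_z > 0, Z^2 / var_z, NA_real_)
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  status[!mono & var_z <= 0] <- "degenerate"
  status[mono] <- "monomorphic"
  stat[status != "ok"] <- NA_real_
  p[status != "ok"] <- NA_real_

  data.frame(snp_id = snp_ids, method = "zhang",
             statistic = stat, p_value = p,
             estimate = ifelse(status == "ok", Z, NA_real_),
             se = ifelse(status == "ok", sqrt(var_z), NA_real_),
             homogeneity_p = NA_real_, status = status,
             U = U, R = R, var_Z = var_z, L = L,
             stringsAsFactors = FALSE)
}

# extend the shared adjustment context with trio-parent genotype lookups
prepare_zhang <- function(sample, L = 10L, basis = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- prepare_adjustment(sample, L, basis)
  tr <- sample$trios
  ctx$trio_geno <- list(
    father = sample$geno[tr$father, , drop = FALSE],
    mother = sample$geno[tr$mother, , drop = FALSE],
    offspring_id = tr$offspring)
  if (ctx$basis$n_components > 0L) {
    ctx$scores_parents <- list(
      father = project_scores(ctx$basis, ctx$trio_geno$father),
      mother = project_scores(ctx$basis, ctx$trio_geno$mother))
    founders_g <- sample$geno[sample$founders, , drop = FALSE]
    if (anyNA(founders_g)) {
      cm <- colMeans(founders_g, na.rm = TRUE)
      idx <- which(is.na(founders_g), arr.ind = TRUE)
      founders_g[idx] <- cm[idx[, 2L]]
    }
    b <- ls_coef(cbind(1, ctx$basis$scores), founders_g)
    ctx$parent_slopes <- b[-1L, , drop = FALSE]
  }
  ctx
}

#' GEE-based score test combining unrelated subjects and trios
#'
#' The score decomposes over two mutually exclusive sets.  Over unrelated
#' subjects, \eqn{U = \sum_i (y_i - \mu_{y,i})(g_i - \mu_{g,i})} with the
#' PC-adjusted means of [adjust_unrelated()].  Over trio offspring,
#' \eqn{R = \sum (y_{ij} - \hat\mu_y)(g_{ij} - e_{g,i})} where
#' \eqn{e_{g,i}} is the Mendelian expectation formed from PC-adjusted
#' parental genotypes ([adjust_parents()], [mendelian_moments()]).
#' Traits are treated as constants, so
#' \eqn{var(Z) = \sum_{unrel}(y_i - \mu_{y,i})^2\,\hat\sigma^2_g +
#'      \sum_{off}(y_{ij} - \hat\mu_y)^2\, v_{g,i}}
#' with \eqn{\hat\sigma^2_g} the residual genotype variance of the
#' unrelated set, and the test refers \eqn{Z^2/var(Z)}, \eqn{Z = U + R},
#' to \eqn{\chi^2_1}.  Offspring with both parents homozygous have
#' \eqn{v_g = 0} and contribute nothing.  Trios with a missing parental
#' genotype at a SNP are excluded at that SNP.
#'
#' @param sample a [combined_sample()].
#' @param snp SNP id(s) or column indices; default all SNPs.
#' @param L number of principal components (0 = no adjustment).
#' @param basis optional precomputed [fit_pcs()] basis.
#' @return data frame, one row per SNP, in the standard result layout plus
#'   `U`, `R`, `var_Z`, `L`.
#' @export
zhang_test <- function(sample, snp = NULL, L = 10L, basis = NULL) {
  stopifnot(inherits(sample, "combined_sample"))
  ctx <- prepare_zhang(sample, L, basis)
  cols <- resolve_snp_cols(sample, snp)
  zhang_scan(ctx, cols)
}
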