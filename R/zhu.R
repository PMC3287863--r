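#' PC-residual covariance statistic with family-robust variance
#'
#' With families indexed by \eqn{i} (\eqn{k_i} members each, unrelated
#' subjects as singleton families, \eqn{N_T} individuals in total), the
#' statistic is the covariance of the genotype and phenotype residuals
#' \deqn{T = \frac{1}{N_T} \sum_{i=1}^{N} \sum_{j=1}^{k_i}
#'       \tilde y_{ij}\, \tilde g_{ij},}
#' and its variance is the family-level empirical second moment
#' \deqn{\widehat{var}(T) = \frac{1}{N_T^2} \sum_{i=1}^{N}
#'       \Big(\sum_{j=1}^{k_i} \tilde y_{ij}\,\tilde g_{ij}\Big)^2,}
#' so within-family correlation inflates the variance but not the
#' statistic.  The Wald statistic \eqn{T^2/\widehat{var}(T)} is referred
#' to \eqn{\chi^2_1}.  Any common scaling of \eqn{T} cancels in the Wald
#' ratio.
#'
#' @param y_res phenotype residuals (length \eqn{N_T}).
#' @param g_res genotype residuals: vector, or matrix with one column per
#'   SNP.
#' @param family family index (unrelated subjects each their own family).
#' @return For vector `g_res`, a list `T`, `var_T`, `wald`, `p`, `status`;
#'   for a matrix, a data frame with one row per SNP.
#' @export
zhu_statistic <- function(y_res, g_res, family) {
  g <- as.matrix(g_res)
  stopifnot(length(y_res) == nrow(g), length(family) == nrow(g))
  nt <- nrow(g)
  fs <- rowsum(g * y_res, family)
  tt <- colSums(fs) / nt
  vt <- colSums(fs^2) / nt^2
  wald <- ifelse(vt > 0, tt^2 / vt, NA_real_)
  p <- stats::pchisq(wald, 1, lower.tail = FALSE)
  status <- ifelse(vt > 0, "ok", "degenerate")
  if (is.vector(g_res))
    return(list(T = unname(tt), var_T = unname(vt), wald = unname(wald),
                p = unname(p), status = status))
  data.frame(T = unname(tt), var_T = unname(vt), wald = unname(wald),
             p = unname(p), status = status, stringsAsFactors = FALSE)
}

# shared adjustment context for the PC-based tests: basis on founders,
# scores for everyone (offspring by projection), family index, role masks.
prepare_adjustment <- function(sample, L = 10L, basis = NULL) {
  ped <- sample$ped
  ids <- ped$id
  aff <- ped$affected
  keep <- !is.na(aff)
  ped <- ped[keep, , drop = FALSE]
  geno <- sample$geno[keep, , drop = FALSE]
  founder_rows <- which(ped$role != "offspring")
  if (is.null(basis))
    basis <- fit_pcs(sample$geno[sample$founders, , drop = FALSE], L)
  scores <- project_scores(basis, geno)
  # family index: trio members share a family, everyone else is a singleton
  fam <- ped$id
  tr <- sample$trios
  for (col in c("father", "mother", "offspring")) {
    m <- match(tr[[col]], ped$id)
    fam[m[!is.na(m)]] <- tr$offspring[!is.na(m)]
  }
  list(ped = ped, geno = geno, y = ped$affected, scores = scores,
       founder_rows = founder_rows,
       unrelated_rows = which(ped$role == "unrelated"),
       offspring_rows = which(ped$role == "offspring"),
       family = fam, basis = basis)
}

# Zhu scan over a set of SNP columns (batch matrix path)
zhu_scan <- function(ctx, snp_cols = seq_len(ncol(ctx$geno))) {
  g <- ctx$geno[, snp_cols, drop = FALSE]
  mono <- apply(g, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || all(v == v[1L])
  })
  g_num <- g
  g_num[is.na(g_num)] <- 0L  # placeholder; NA columns handled per-SNP below
  has_na <- colSums(is.na(g)) > 0L
  y_res <- residualize(ctx$y, ctx$scores, ctx$founder_rows)
  g_res <- residualize(g_num, ctx$scores, ctx$founder_rows)
  res <- zhu_statistic(y_res, g_res, ctx$family)
  # complete-case per marker for SNPs with missing genotypes
  for (j in which(has_na & !mono)) {
    obs <- !is.na(g[, j])
    fit <- intersect(ctx$founder_rows, which(obs))
    yr <- residualize(ctx$y[obs], ctx$scores[obs, , drop = FALSE],
                      match(fit, which(obs)))
    gr <- residualize(g[obs, j], ctx$scores[obs, , drop = FALSE],
                      match(fit, which(obs)))
    zs <- zhu_statistic(yr, gr, ctx$family[obs])
    res[j, c("T", "var_T", "wald", "p", "status")] <-
      list(zs$T, zs$var_T, zs$wald, zs$p, zs$status)
  }
  res$status[mono] <- "monomorphic"
  res[mono, c("T", "var_T", "wald", "p")] <- NA_real_
  snp_ids <- colnames(ctx$geno)[snp_cols]
  data.frame(snp_id = snp_ids, method = "zhu",
             statistic = res$wald, p_value = res$p,
             estimate = res$T, se = sqrt(res$var_T),
             homogeneity_p = NA_real_, status = res$status,
             T = res$T, var_T = res$var_T,
             L = ctx$basis$n_components,
             stringsAsFactors = FALSE)
}

#' PC-residual covariance test at one or more SNPs
#'
#' Principal components are fitted once on the unrelated individuals
#' (trio parents plus unrelated case-control subjects); genotypes and
#' phenotypes are regressed on the scores with coefficients estimated on
#' that set and applied to everyone (offspring receive projected scores),
#' and the residual-covariance Wald test of [zhu_statistic()] is applied
#' with trio members grouped as families.  The estimate column reports
#' `T`, its standard error \eqn{\sqrt{var(T)}}.
#'
#' @param sample a [combined_sample()].
#' @param snp SNP id(s) or column indices; default all SNPs.
#' @param L number of principal components (0 = no adjustment).
#' @param basis optional precomputed [fit_pcs()] basis (must be fitted on
#'   the sample founders).
#' @return data frame, one row per SNP, in the standard result layout plus
#'   `T`, `var_T`, `L`.
#' @export
zhu_test <- function(sample, snp = NULL, L = 10L, basis = NULL) {
  stopifnot(inherits(sample, "combined_sample"))
  ctx <- prepare_adjustment(sample, L, basis)
  cols <- resolve_snp_cols(sample, snp)
  zhu_scan(ctx, cols)
}

resolve_snp_cols <- function(sample, snp) {
  if (is.null(snp)) return(seq_len(ncol(sample$geno)))
  if (is.character(snp)) {
    cols <- match(snp, colnames(sample$geno))
    if (anyNA(cols)) stop("unknown SNP id(s): ",
                          paste(snp[is.na(cols)], collapse = ", "))
    cols
  } else as.integer(snp)
}
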