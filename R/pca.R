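#' Principal components of the unrelated (founder) genotypes
#'
#' Fits the top-L principal components of the standardized genotype matrix
#' of all unrelated individuals — trio parents plus unrelated case-control
#' subjects.  Columns are centered at twice the founder allele frequency
#' and scaled by \eqn{\sqrt{2\hat p(1-\hat p)}}; monomorphic columns are
#' dropped from the basis.  Component signs are fixed by convention (the
#' largest-magnitude loading is positive), so the fit is deterministic.
#'
#' @param geno founder genotype matrix (individuals x SNPs).  `NA` entries
#'   are mean-imputed (zero after standardization) for the basis fit.
#' @param L number of components (`0 <= L < nrow(geno)`); `L = 0` returns
#'   an empty basis (no adjustment).
#' @return list of class `pc_basis`: `n_components`, `loadings`
#'   (kept-SNP x L), `keep` (kept column indices), `center`, `scale`,
#'   `scores` (fitting-set individuals x L), `snp_ids`.
#' @export
fit_pcs <- function(geno, L = 10L) {
  n <- nrow(geno)
  if (L < 0L || (L > 0L && L >= n))
    stop("L must satisfy 0 <= L < number of unrelated individuals")
  p <- colMeans(geno, na.rm = TRUE) / 2
  scale <- sqrt(2 * p * (1 - p))
  keep <- which(is.finite(scale) & scale > 0)
  basis <- list(n_components = as.integer(L), keep = keep,
                center = 2 * p[keep], scale = scale[keep],
                snp_ids = colnames(geno))
  class(basis) <- "pc_basis"
  if (L == 0L) {
    basis$loadings <- matrix(0, length(keep), 0L)
    basis$scores <- matrix(0, n, 0L)
    rownames(basis$scores) <- rownames(geno)
    return(basis)
  }
  x <- standardize_geno(geno, basis)
  sv <- svd(x, nu = L, nv = L)
  flip <- apply(sv$v, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  basis$loadings <- sweep(sv$v, 2L, flip, `*`)
  basis$scores <- x %*% basis$loadings
  rownames(basis$scores) <- rownames(geno)
  basis$eigenvalues <- (sv$d[seq_len(L)]^2) / (n - 1)
  basis
}

standardize_geno <- function(geno, basis) {
  x <- geno[, basis$keep, drop = FALSE]
  x <- sweep(x, 2L, basis$center, `-`)
  x <- sweep(x, 2L, basis$scale, `/`)
  x[is.na(x)] <- 0
  x
}

#' Project individuals onto a fitted PC basis
#'
#' Standardizes genotype rows with the basis center/scale (zero-variance
#' columns excluded identically to the fit) and multiplies by the
#' loadings.  For a fitting-set individual the projection reproduces the
#' fitted score; trio offspring, who are excluded from the fit, receive
#' coordinates this way.
#'
#' @param basis a [fit_pcs()] result.
#' @param geno genotype matrix over the same SNP set as the basis.
#' @return score matrix (individuals x L).
#' @export
project_scores <- function(basis, geno) {
  stopifnot(inherits(basis, "pc_basis"))
  if (ncol(geno) != length(basis$snp_ids))
    stop("genotype matrix does not match the basis SNP set")
  standardize_geno(geno, basis) %*% basis$loadings
}

#' Residualize values on principal-component scores
#'
#' Least-squares regression (with intercept) of `values` on the scores,
#' with coefficients estimated ONLY on the rows in `fit_idx` (the
#' unrelated set) and applied to every row.  Collinear components are
#' dropped with a message.
#'
#' @param values numeric vector or matrix (rows = individuals).
#' @param scores score matrix (individuals x L); `L = 0` reduces to
#'   centering at the fitting-set mean.
#' @param fit_idx rows used to estimate the regression (default: all).
#' @return residuals, same shape as `values`.
#' @export
residualize <- function(values, scores, fit_idx = seq_len(NROW(values))) {
  v <- as.matrix(values)
  x <- cbind(`(Intercept)` = 1, scores)
  b <- ls_coef(x[fit_idx, , drop = FALSE], v[fit_idx, , drop = FALSE])
  res <- v - x %*% b
  if (is.vector(values)) as.vector(res) else res
}

# least-squares coefficients, rank-deficiency tolerant (multi-response)
ls_coef <- function(x, y) {
  qx <- qr(x)
  if (qx$rank < ncol(x))
    message("dropping ", ncol(x) - qx$rank, " collinear component(s)")
  b <- qr.coef(qx, y)
  b[is.na(b)] <- 0
  b
}

# fitted values of the same regression (used for adjusted means)
ls_fitted <- function(values, scores, fit_idx = seq_len(NROW(values))) {
  v <- as.matrix(values)
  x <- cbind(1, scores)
  b <- ls_coef(x[fit_idx, , drop = FALSE], v[fit_idx, , drop = FALSE])
  x %*% b
}
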