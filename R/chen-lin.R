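#' Mendelian transmission probabilities given parental genotypes
#'
#' @param g_father,g_mother parental minor-allele counts in \{0, 1, 2\}.
#' @return matrix (trios x 3) of probabilities that the offspring carries
#'   0, 1 or 2 copies, under random transmission of one allele per parent.
#' @keywords internal
transmission_probs <- function(g_father, g_mother) {
  pf <- g_father / 2
  pm <- g_mother / 2
  cbind((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
}

#' Conditional-on-parental-genotypes (CPG) log likelihood
#'
#' Log likelihood of the case-trio offspring genotypes conditional on the
#' parental genotypes and on the offspring being affected, under the
#' additive log-linear relative-risk model \eqn{RR(g) = e^{\beta g}}:
#' each trio contributes
#' \deqn{\log \frac{\tau(g_o\,|\,g_f,g_m)\, e^{\beta g_o}}
#'                 {\sum_{g'} \tau(g'\,|\,g_f,g_m)\, e^{\beta g'}}}
#' with \eqn{\tau} the Mendelian transmission probability.  Trios with two
#' homozygous parents contribute a constant (they are uninformative for
#' \eqn{\beta}).
#'
#' @param beta log relative risk per minor allele; may be a vector, in
#'   which case the log likelihood is evaluated at each value.
#' @param trios data frame (or list) with integer vectors `father`,
#'   `mother`, `offspring` — case trios, Mendelian-consistent at this SNP.
#' @return numeric vector, `length(beta)` log-likelihood values (each
#'   \eqn{\le 0}).
#' @export
cpg_loglik <- function(beta, trios) {
  tp <- transmission_probs(trios$father, trios$mother)
  go <- trios$offspring
  obs <- tp[cbind(seq_along(go), go + 1L)]
  if (any(obs == 0))
    stop("Mendelian-inconsistent trio passed to cpg_loglik")
  base <- sum(log(obs))
  vapply(beta, function(b) {
    w <- exp(b * (0:2))
    base + b * sum(go) - sum(log(tp %*% w))
  }, numeric(1L))
}

# score and observed information of the CPG log likelihood at beta
cpg_score_info <- function(beta, tp, go) {
  w <- exp(beta * (0:2))
  num <- tp * rep(w, each = nrow(tp))
  denom <- rowSums(num)
  p <- num / denom
  eg <- p[, 2L] + 2 * p[, 3L]
  eg2 <- p[, 2L] + 4 * p[, 3L]
  list(score = sum(go - eg), info = sum(eg2 - eg^2))
}

#' Fit the CPG relative-risk model on case trios
#'
#' Maximises [cpg_loglik()] by safeguarded Newton iteration (analytic score
#' and observed information, step halving, |beta| capped) starting from 0.
#' The log likelihood is concave, so Newton from 0 converges for every
#' non-degenerate instance.  One-sided transmission patterns (the MLE
#' diverges) are detected and flagged.
#'
#' @param trios case trios at one SNP: data frame with `father`, `mother`,
#'   `offspring` minor-allele counts.
#' @param beta_cap bound on |beta|; exceeding it flags separation.
#' @param tol convergence tolerance on the Newton step.
#' @param max_iter maximum Newton iterations.
#' @return list of class `cpg_fit`: `beta_hat`, `se`, `loglik`,
#'   `n_informative_trios`, `status` (`"ok"`, `"no_informative_trios"` or
#'   `"degenerate"`).
#' @export
fit_cpg <- function(trios, beta_cap = 10, tol = 1e-8, max_iter = 50L) {
  trios <- as.data.frame(trios)
  informative <- trios$father == 1L | trios$mother == 1L
  n_inf <- sum(informative)
  out <- list(beta_hat = NA_real_, se = NA_real_, loglik = NA_real_,
              n_informative_trios = n_inf, status = "ok")
  class(out) <- "cpg_fit"
  if (n_inf == 0L) { out$status <- "no_informative_trios"; return(out) }

  tr <- trios[informative, , drop = FALSE]
  tp <- transmission_probs(tr$father, tr$mother)
  go <- tr$offspring
  # MLE diverges iff every informative offspring sits at the top (or bottom)
  # of its attainable range
  lo <- (tr$father == 2L) + (tr$mother == 2L)
  hi <- (tr$father >= 1L) + (tr$mother >= 1L)
  if (all(go == hi) || all(go == lo)) {
    out$status <- "degenerate"
    return(out)
  }

  beta <- 0
  for (it in seq_len(max_iter)) {
    si <- cpg_score_info(beta, tp, go)
    if (si$info <= 0) { out$status <- "degenerate"; return(out) }
    step <- si$score / si$info
    # step halving on the actual objective
    ll0 <- cpg_loglik(beta, tr)
    new <- beta + step
    for (h in 1:20) {
      if (abs(new) <= beta_cap && cpg_loglik(new, tr) >= ll0 - 1e-12) break
      step <- step / 2
      new <- beta + step
    }
    beta <- new
    if (abs(step) < tol) break
  }
  if (abs(beta) >= beta_cap) { out$status <- "degenerate"; return(out) }
  si <- cpg_score_info(beta, tp, go)
  out$beta_hat <- beta
  out$se <- 1 / sqrt(si$info)
  out$loglik <- cpg_loglik(beta, trios)
  out
}

#' Logistic regression of affection on additive genotype
#'
#' Maximum-likelihood logit of case status on the minor-allele count with
#' an intercept, fitted on the case-control subsample; the reported
#' standard error comes from the observed information.
#'
#' @param y 0/1 phenotype vector.
#' @param g additive genotype vector (same length).
#' @return list of class `cc_fit`: `beta_hat` (log odds ratio per allele),
#'   `se`, `n_cases`, `n_controls`, `status`, and internals (`fitted`,
#'   `vcov`) used by [cross_covariance()].
#' @export
fit_cc_logistic <- function(y, g) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- g[keep]
  out <- list(beta_hat = NA_real_, se = NA_real_,
              n_cases = sum(y == 1L), n_controls = sum(y == 0L),
              status = "ok", keep = keep)
  class(out) <- "cc_fit"
  if (length(y) == 0L || length(unique(y)) < 2L || stats::var(g) == 0) {
    out$status <- "degenerate"
    return(out)
  }
  x <- cbind(1, g)
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial()))
  b <- fit$coefficients[2L]
  p <- fit$fitted.values
  w <- p * (1 - p)
  xtwx <- crossprod(x * sqrt(w))
  vc <- tryCatch(solve(xtwx), error = function(e) NULL)
  if (is.null(vc) || !fit$converged || !is.finite(b) || abs(b) > 10) {
    out$status <- "degenerate"
    return(out)
  }
  out$beta_hat <- unname(b)
  out$se <- sqrt(vc[2L, 2L])
  out$fitted <- p
  out$vcov <- vc
  out
}

#' Cross-covariance of the CPG and logistic estimates
#'
#' The two arms share subjects: each case-trio proband contributes to the
#' CPG likelihood through its trio and to the logistic fit as a case.  The
#' covariance of the estimates is taken as the empirical cross-moment of
#' per-unit influence values in a stacked sandwich: a trio's CPG influence
#' is its score over the total information, a subject's logistic influence
#' is the slope row of \eqn{(X'WX)^{-1} x_i (y_i - \hat p_i)}, and units
#' in only one arm contribute zero to the other.
#'
#' @param case_trios the case trios entering the CPG fit, with an
#'   `offspring_id` column naming each proband.
#' @param cc list with `ids`, `y`, `g` for the logistic subsample.
#' @param cpg_fit a [fit_cpg()] result.
#' @param cc_fit a [fit_cc_logistic()] result.
#' @return covariance (numeric scalar); 0 when the arms share no subjects.
#' @export
cross_covariance <- function(case_trios, cc, cpg_fit, cc_fit) {
  if (cpg_fit$status != "ok" || cc_fit$status != "ok") return(NA_real_)
  tr <- as.data.frame(case_trios)
  tp <- transmission_probs(tr$father, tr$mother)
  si <- cpg_score_info(cpg_fit$beta_hat, tp, tr$offspring)
  w <- exp(cpg_fit$beta_hat * (0:2))
  num <- tp * rep(w, each = nrow(tp))
  eg <- (num[, 2L] + 2 * num[, 3L]) / rowSums(num)
  h_cpg <- (tr$offspring - eg) / si$info          # per case trio

  ids <- cc$ids[cc_fit$keep]
  y <- cc$y[cc_fit$keep]; g <- cc$g[cc_fit$keep]
  x <- cbind(1, g)
  infl <- as.vector((x %*% cc_fit$vcov[, 2L]) * (y - cc_fit$fitted))

  m <- match(tr$offspring_id, ids)
  shared <- !is.na(m)
  if (!any(shared)) return(0)
  sum(h_cpg[shared] * infl[m[shared]])
}

#' Wald test of homogeneity of the CPG and logistic effect estimates
#'
#' Tests whether the within-family relative-risk estimate and the
#' population log odds ratio agree:
#' \eqn{(\hat\beta_{CPG} - \hat\beta_{CC})^2 /
#'  (se_{CPG}^2 + se_{CC}^2 - 2\,cov)}, referred to \eqn{\chi^2_1}.
#'
#' @param cpg_fit a [fit_cpg()] result.
#' @param cc_fit a [fit_cc_logistic()] result.
#' @param cross_cov covariance of the two estimates (see
#'   [cross_covariance()]).
#' @return list `statistic`, `p`; both `NA` with a `"degenerate"` status
#'   element when the variance of the difference is non-positive.
#' @export
homogeneity_wald <- function(cpg_fit, cc_fit, cross_cov = 0) {
  v <- cpg_fit$se^2 + cc_fit$se^2 - 2 * cross_cov
  if (!is.finite(v) || v <= 0)
    return(list(statistic = NA_real_, p = NA_real_, status = "degenerate"))
  stat <- (cpg_fit$beta_hat - cc_fit$beta_hat)^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       status = "ok")
}

#' Weighted least-squares combination of the CPG and logistic estimates
#'
#' When the homogeneity pre-test does not reject, the combined effect is
#' \eqn{\beta_c = W_1 \hat\beta_{CPG} + W_2 \hat\beta_{CC}} with weights
#' \eqn{(W_1, W_2)' = \Sigma^{-1} 1 / (1'\Sigma^{-1} 1)} for \eqn{\Sigma}
#' the 2x2 covariance of the estimates, and
#' \eqn{se_c = (1'\Sigma^{-1}1)^{-1/2}}; the test is
#' \eqn{(\beta_c / se_c)^2} against \eqn{\chi^2_1}.  When homogeneity is
#' rejected the within-family (CPG-only) test is reported instead and
#' `homogeneity_rejected` is set.
#'
#' @param cpg_fit a [fit_cpg()] result.
#' @param cc_fit a [fit_cc_logistic()] result.
#' @param cross_cov covariance of the estimates.
#' @param alpha_h level of the homogeneity pre-test.
#' @return list: `estimate`, `se`, `w1`, `w2`, `statistic`, `p`,
#'   `homogeneity_stat`, `homogeneity_p`, `homogeneity_rejected`,
#'   `cross_cov`, `status`.
#' @export
combine_and_test <- function(cpg_fit, cc_fit, cross_cov = 0, alpha_h = 0.05) {
  hw <- homogeneity_wald(cpg_fit, cc_fit, cross_cov)
  out <- list(estimate = NA_real_, se = NA_real_, w1 = NA_real_,
              w2 = NA_real_, statistic = NA_real_, p = NA_real_,
              homogeneity_stat = hw$statistic, homogeneity_p = hw$p,
              homogeneity_rejected = FALSE, cross_cov = cross_cov,
              status = "ok")
  if (hw$status != "ok") { out$status <- "degenerate"; return(out) }
  if (hw$p < alpha_h) {
    out$homogeneity_rejected <- TRUE
    out$estimate <- cpg_fit$beta_hat
    out$se <- cpg_fit$se
    out$w1 <- 1; out$w2 <- 0
  } else {
    sig <- matrix(c(cpg_fit$se^2, cross_cov, cross_cov, cc_fit$se^2), 2L)
    si <- tryCatch(solve(sig), error = function(e) NULL)
    if (is.null(si) || det(sig) <= 0) { out$status <- "degenerate"; return(out) }
    ones <- c(1, 1)
    denom <- as.numeric(crossprod(ones, si %*% ones))
    w <- as.vector(si %*% ones) / denom
    out$w1 <- w[1L]; out$w2 <- w[2L]
    out$estimate <- w[1L] * cpg_fit$beta_hat + w[2L] * cc_fit$beta_hat
    out$se <- sqrt(1 / denom)
  }
  out$statistic <- (out$estimate / out$se)^2
  out$p <- stats::pchisq(out$statistic, 1, lower.tail = FALSE)
  out
}

# assemble the per-SNP inputs for the Chen & Lin arms at one SNP
chen_lin_snp_inputs <- function(sample, snp, cc = NULL) {
  if (is.null(cc)) cc <- build_cc_subsample(sample)
  g <- sample$geno[, snp]
  tr <- sample$trios
  aff <- sample$ped$affected
  names(aff) <- sample$ped$id
  gf <- g[tr$father]; gm <- g[tr$mother]; go <- g[tr$offspring]
  ok <- !is.na(gf) & !is.na(gm) & !is.na(go) &
    mendelian_consistent(gf, gm, go)
  case <- ok & aff[tr$offspring] %in% 1L
  list(case_trios = data.frame(father = gf[case], mother = gm[case],
                               offspring = go[case],
                               offspring_id = tr$offspring[case],
                               stringsAsFactors = FALSE),
       cc = list(ids = cc$ids, y = cc$y, g = unname(g[cc$ids])),
       cc_degenerate = cc$degenerate,
       n_mendel_excluded = sum(!ok & !is.na(gf) & !is.na(gm) & !is.na(go)))
}

#' Chen & Lin combined test at one SNP
#'
#' Runs the full pipeline at a single SNP: CPG fit on Mendelian-consistent
#' case trios, logistic fit on the case-control subsample, stacked-sandwich
#' cross-covariance, homogeneity pre-test, and the weighted combination.
#'
#' @param sample a [combined_sample()].
#' @param snp SNP id or column index.
#' @param cc optional precomputed [build_cc_subsample()] result (computed
#'   once per dataset when scanning many SNPs).
#' @param alpha_h level of the homogeneity pre-test.
#' @param assume_independent if `TRUE` the cross-covariance is set to 0
#'   (sensitivity analysis).
#' @return one-row data frame with the standard result columns plus
#'   `n_informative_trios`, `homogeneity_rejected`, `cross_cov`.
#' @export
chen_lin_test <- function(sample, snp, cc = NULL, alpha_h = 0.05,
                          assume_independent = FALSE) {
  inp <- chen_lin_snp_inputs(sample, snp, cc)
  snp_id <- if (is.character(snp)) snp else colnames(sample$geno)[snp]
  res <- data.frame(snp_id = snp_id, method = "chen_lin",
                    statistic = NA_real_, p_value = NA_real_,
                    estimate = NA_real_, se = NA_real_,
                    homogeneity_p = NA_real_, status = "ok",
                    n_informative_trios = NA_integer_,
                    homogeneity_rejected = NA, cross_cov = NA_real_,
                    stringsAsFactors = FALSE)

  g_all <- sample$geno[, snp]
  v <- stats::var(g_all, na.rm = TRUE)
  if (is.na(v) || v == 0) {
    res$status <- "monomorphic"; return(res)
  }

  cpg <- fit_cpg(inp$case_trios)
  res$n_informative_trios <- cpg$n_informative_trios
  if (cpg$status != "ok") { res$status <- cpg$status; return(res) }

  if (inp$cc_degenerate) { res$status <- "degenerate"; return(res) }
  ccf <- fit_cc_logistic(inp$cc$y, inp$cc$g)
  if (ccf$status != "ok") { res$status <- "degenerate"; return(res) }

  cov12 <- if (assume_independent) 0 else
    cross_covariance(inp$case_trios, inp$cc, cpg, ccf)
  comb <- combine_and_test(cpg, ccf, cov12, alpha_h)
  if (comb$status != "ok") { res$status <- "degenerate"; return(res) }

  res$statistic <- comb$statistic
  res$p_value <- comb$p
  res$estimate <- comb$estimate
  res$se <- comb$se
  res$homogeneity_p <- comb$homogeneity_p
  res$homogeneity_rejected <- comb$homogeneity_rejected
  res$cross_cov <- cov12
  res
}
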