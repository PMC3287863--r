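test_that("cpg_loglik matches hand-computed conditional probabilities", {
  # Aa x Aa parents, offspring heterozygous, beta = 0: Mendelian 1/2
  t1 <- data.frame(father = 1L, mother = 1L, offspring = 1L)
  expect_equal(cpg_loglik(0, t1), log(1 / 2))
  # Aa x aa, offspring carries 1 copy, beta = log 2: e^b/2 / (1/2 + e^b/2)
  t2 <- data.frame(father = 1L, mother = 0L, offspring = 1L)
  expect_equal(cpg_loglik(log(2), t2), log(2 / 3))
  # at beta = 0 the log likelihood is the log Mendelian probability
  set.seed(20)
  tr <- simulate_case_trios(40, 0.3, 0)
  tp <- popfam:::transmission_probs(tr$father, tr$mother)
  expect_equal(cpg_loglik(0, tr),
               sum(log(tp[cbind(1:40, tr$offspring + 1L)])))
  # vectorized in beta and concave around the interior
  ll <- cpg_loglik(c(-1, 0, 1), tr)
  expect_length(ll, 3L)
  expect_true(all(ll <= 0))
})

test_that("fit_cpg solves the score equation and flags degeneracies", {
  # balanced transmissions from Aa x aa parents: MLE exactly 0
  tr <- data.frame(father = c(1L, 1L), mother = c(0L, 0L),
                   offspring = c(1L, 0L))
  f <- fit_cpg(tr)
  expect_equal(f$beta_hat, 0, tolerance = 1e-10)
  expect_equal(f$n_informative_trios, 2L)

  # only hom x hom parents: uninformative
  hom <- data.frame(father = c(0L, 2L), mother = c(0L, 2L),
                    offspring = c(0L, 2L))
  expect_equal(fit_cpg(hom)$status, "no_informative_trios")

  # one-sided transmissions: separation
  one <- data.frame(father = rep(1L, 5), mother = rep(0L, 5),
                    offspring = rep(1L, 5))
  expect_equal(fit_cpg(one)$status, "degenerate")
})

test_that("fit_cpg agrees with a 1e-4 grid search on random instances", {
  set.seed(21)
  for (i in 1:50) {
    beta_true <- runif(1, -1.5, 1.5)
    tr <- simulate_case_trios(sample(10:40, 1), runif(1, 0.15, 0.5),
                              beta_true)
    f <- fit_cpg(tr)
    if (f$status != "ok") next
    expect_lt(abs(f$beta_hat - cpg_grid_mle(tr)), 1e-4)
    expect_true(f$se > 0)
    expect_lte(f$loglik, 0)
  }
})

test_that("the CPG score test on Aa x aa trios reduces to the TDT", {
  # b transmissions of the minor allele, c non-transmissions; score test
  # at beta = 0 (numerical derivatives of the log likelihood) must equal
  # (b - c)^2 / (b + c)
  for (bc in list(c(9, 5), c(3, 11), c(7, 7))) {
    b <- bc[1]; c <- bc[2]
    tr <- data.frame(father = rep(1L, b + c), mother = rep(0L, b + c),
                     offspring = rep(c(1L, 0L), c(b, c)))
    h <- 1e-5
    ll <- cpg_loglik(c(-h, 0, h), tr)
    score <- (ll[3] - ll[1]) / (2 * h)
    info <- -(ll[3] - 2 * ll[2] + ll[1]) / h^2
    expect_equal(score^2 / info, (b - c)^2 / (b + c), tolerance = 1e-4)
  }
})

test_that("the logistic arm matches closed forms", {
  # symmetric table: zero log odds ratio
  y <- rep(c(1, 0), each = 20)
  g <- rep(c(0, 1, 0, 1), each = 10)
  f <- fit_cc_logistic(y, g)
  expect_equal(f$beta_hat, 0, tolerance = 1e-8)

  # binary exposure 2x2: MLE equals the sample log odds ratio
  y2 <- rep(c(1, 0), c(100, 100))
  g2 <- c(rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(10, 90)))
  f2 <- fit_cc_logistic(y2, g2)
  expect_equal(f2$beta_hat, log((30 * 90) / (70 * 10)), tolerance = 1e-6)
  expect_equal(f2$n_cases, 100L)

  expect_equal(fit_cc_logistic(y, rep(1, 40))$status, "degenerate")
  expect_equal(fit_cc_logistic(rep(1, 10), rbinom(10, 2, .3))$status,
               "degenerate")
})

test_that("cross-covariance is zero for disjoint arms and scales as 1/n", {
  set.seed(22)
  tr <- simulate_case_trios(60, 0.3, 0.2)
  cpg <- fit_cpg(tr)
  # CC arm with none of the probands
  y <- rbinom(200, 1, 0.4); g <- rbinom(200, 2, 0.3)
  cc <- list(ids = sprintf("X%03d", 1:200), y = y, g = g)
  ccf <- fit_cc_logistic(y, g)
  expect_identical(cross_covariance(tr, cc, cpg, ccf), 0)

  # shared probands: doubling every unit roughly halves the covariance
  cc1 <- list(ids = c(tr$offspring_id, sprintf("X%03d", 1:150)),
              y = c(rep(1, 60), rbinom(150, 1, 0.35)),
              g = c(tr$offspring, rbinom(150, 2, 0.3)))
  ccf1 <- fit_cc_logistic(cc1$y, cc1$g)
  cv1 <- cross_covariance(tr, cc1, cpg, ccf1)

  tr2 <- rbind(tr, transform(tr, offspring_id = paste0(offspring_id, "b")))
  cc2 <- list(ids = c(tr2$offspring_id, sprintf("X%03d", 1:150),
                      sprintf("Y%03d", 1:150)),
              y = c(rep(1, 120), cc1$y[61:210], cc1$y[61:210]),
              g = c(tr2$offspring, cc1$g[61:210], cc1$g[61:210]))
  cpg2 <- fit_cpg(tr2)
  ccf2 <- fit_cc_logistic(cc2$y, cc2$g)
  cv2 <- cross_covariance(tr2, cc2, cpg2, ccf2)
  expect_gt(cv1, 0)
  expect_equal(cv2 / cv1, 0.5, tolerance = 0.15)
})

test_that("influence cross-covariance agrees with a bootstrap over units", {
  set.seed(23)
  n_tr <- 60; n_un <- 150
  tr <- simulate_case_trios(n_tr, 0.3, 0)
  y_un <- rbinom(n_un, 1, 0.35); g_un <- rbinom(n_un, 2, 0.3)
  cc <- list(ids = c(tr$offspring_id, sprintf("X%03d", 1:n_un)),
             y = c(rep(1, n_tr), y_un), g = c(tr$offspring, g_un))
  cpg <- fit_cpg(tr); ccf <- fit_cc_logistic(cc$y, cc$g)
  cv <- cross_covariance(tr, cc, cpg, ccf)

  boot <- replicate(300, {
    it <- sample(n_tr, replace = TRUE)
    iu <- sample(n_un, replace = TRUE)
    trb <- tr[it, ]
    yb <- c(rep(1, n_tr), y_un[iu]); gb <- c(trb$offspring, g_un[iu])
    fb <- fit_cpg(trb); lb <- fit_cc_logistic(yb, gb)
    if (fb$status != "ok" || lb$status != "ok") c(NA, NA)
    else c(fb$beta_hat, lb$beta_hat)
  })
  boot <- boot[, stats::complete.cases(t(boot))]
  cv_boot <- cov(boot[1, ], boot[2, ])
  # same sign and magnitude within Monte-Carlo error
  expect_lt(abs(cv - cv_boot), 3 * cv_boot / sqrt(ncol(boot)) + 0.002)
  r <- cv / (cpg$se * ccf$se)
  expect_true(abs(r) < 1)
})

test_that("homogeneity Wald test matches its closed form", {
  fa <- list(beta_hat = 0.8, se = 0.2, status = "ok")
  fb <- list(beta_hat = 0.3, se = sqrt(0.05), status = "ok")
  h <- homogeneity_wald(fa, fb, 0)
  expect_equal(h$statistic, 0.25 / 0.09, tolerance = 1e-12)
  expect_equal(h$p, pchisq(0.25 / 0.09, 1, lower.tail = FALSE))
  expect_equal(h$p, 0.0956, tolerance = 1e-2)

  same <- homogeneity_wald(fa, fa, fa$se^2)  # zero variance of difference
  expect_equal(same$status, "degenerate")
  eq <- homogeneity_wald(fa, list(beta_hat = 0.8, se = 0.3), 0)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
})

test_that("the weighted combination follows inverse-variance algebra", {
  fa <- list(beta_hat = 0.5, se = 0.2, status = "ok")   # var 0.04
  fb <- list(beta_hat = 0.4, se = 0.1, status = "ok")   # var 0.01
  cm <- combine_and_test(fa, fb, 0, alpha_h = 0.05)
  expect_equal(c(cm$w1, cm$w2), c(0.2, 0.8))
  expect_equal(cm$estimate, 0.2 * 0.5 + 0.8 * 0.4)
  expect_equal(cm$se, sqrt(0.008))
  expect_false(cm$homogeneity_rejected)

  # equal variances, zero covariance: plain average
  fc <- list(beta_hat = 0.2, se = 0.15, status = "ok")
  fd <- list(beta_hat = 0.6, se = 0.15, status = "ok")
  cm2 <- combine_and_test(fc, fd, 0, alpha_h = 1e-9)
  expect_equal(c(cm2$w1, cm2$w2), c(0.5, 0.5))
  expect_equal(cm2$estimate, 0.4)

  # both estimates zero: combined zero, p = 1
  f0 <- list(beta_hat = 0, se = 0.1, status = "ok")
  cm3 <- combine_and_test(f0, f0, 0)
  expect_equal(cm3$estimate, 0)
  expect_equal(cm3$p, 1)

  # weighted-LS efficiency: se_c <= min(se) whenever cov <= min variance
  set.seed(24)
  for (i in 1:25) {
    v <- runif(2, 0.01, 0.3)
    cv <- runif(1, -0.5, 1) * min(v)
    ca <- list(beta_hat = rnorm(1), se = sqrt(v[1]), status = "ok")
    cb <- list(beta_hat = ca$beta_hat + rnorm(1, 0, 0.01),
               se = sqrt(v[2]), status = "ok")
    cm <- combine_and_test(ca, cb, cv, alpha_h = 1e-12)
    if (cm$status == "ok" && !cm$homogeneity_rejected)
      expect_lte(cm$se, min(ca$se, cb$se) + 1e-12)
    expect_equal(cm$w1 + cm$w2, 1, tolerance = 1e-12)
  }
})

test_that("homogeneity rejection falls back to the within-family test", {
  fa <- list(beta_hat = 2, se = 0.1, status = "ok")
  fb <- list(beta_hat = -2, se = 0.1, status = "ok")
  cm <- combine_and_test(fa, fb, 0, alpha_h = 0.05)
  expect_true(cm$homogeneity_rejected)
  expect_equal(cm$estimate, fa$beta_hat)
  expect_equal(cm$se, fa$se)
})

test_that("chen_lin_test assembles per-SNP results with diagnostics", {
  set.seed(25)
  s <- make_manual_sample(n_case_trios = 30, n_control_trios = 10,
                          n_unrelated = 120,
                          unrelated_affected = rbinom(120, 1, 0.35),
                          mafs = c(0.3, 0.0), seed = 25)
  res <- chen_lin_test(s, 1)
  expect_equal(res$method, "chen_lin")
  expect_equal(res$status, "ok")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_true(res$n_informative_trios > 0)

  res2 <- chen_lin_test(s, 2)  # monomorphic column
  expect_equal(res2$status, "monomorphic")
  expect_true(is.na(res2$p_value))
})
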