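# programmatic fixtures shared across test files

# a hand-built pedigree: n_case_trios case trios, n_control_trios control
# trios, n_unrelated unrelated subjects (affection per unrelated_affected),
# with genotypes drawn at the given MAFs
make_manual_sample <- function(n_case_trios = 2, n_control_trios = 1,
                               n_unrelated = 5,
                               unrelated_affected = rep(0, n_unrelated),
                               mafs = c(0.3, 0.1), seed = 1) {
  set.seed(seed)
  n_trios <- n_case_trios + n_control_trios
  tg <- simulate_trio_genotypes(max(n_trios, 1), mafs)
  ug <- simulate_unrelated(max(n_unrelated, 1), mafs)
  ped <- list(); geno <- list()
  if (n_trios > 0) {
    for (i in seq_len(n_trios)) {
      fid <- sprintf("T%02d", i)
      aff <- if (i <= n_case_trios) 1L else 0L
      ped[[length(ped) + 1]] <- data.frame(
        fid = fid, id = paste0(fid, c("_F", "_M", "_O")),
        father = c(NA, NA, paste0(fid, "_F")),
        mother = c(NA, NA, paste0(fid, "_M")),
        sex = c(1, 2, 0), affected = c(0L, 0L, aff))
      geno[[length(geno) + 1]] <- rbind(tg$father[i, ], tg$mother[i, ],
                                        tg$offspring[i, ])
    }
  }
  if (n_unrelated > 0) {
    ped[[length(ped) + 1]] <- data.frame(
      fid = sprintf("U%02d", seq_len(n_unrelated)),
      id = sprintf("U%02d", seq_len(n_unrelated)),
      father = NA_character_, mother = NA_character_, sex = 0,
      affected = as.integer(unrelated_affected))
    geno[[length(geno) + 1]] <- ug[seq_len(n_unrelated), , drop = FALSE]
  }
  ped <- do.call(rbind, ped)
  g <- do.call(rbind, geno)
  rownames(g) <- ped$id
  colnames(g) <- sprintf("S%03d", seq_along(mafs))
  combined_sample(ped, g)
}

# case trios drawn from the CPG ascertained distribution: parents HWE(maf),
# offspring genotype ~ tau(g|parents) e^{beta g} / sum tau e^{beta g'}
simulate_case_trios <- function(n, maf, beta) {
  gf <- rbinom(n, 2, maf)
  gm <- rbinom(n, 2, maf)
  pf <- gf / 2; pm <- gm / 2
  tp <- cbind((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
  w <- tp * rep(exp(beta * (0:2)), each = n)
  w <- w / rowSums(w)
  u <- runif(n)
  go <- (u > w[, 1]) + (u > w[, 1] + w[, 2])
  data.frame(father = gf, mother = gm, offspring = go,
             offspring_id = sprintf("O%04d", seq_len(n)))
}

# independent grid-search oracle for the CPG MLE
cpg_grid_mle <- function(trios, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- cpg_loglik(grid, trios)
  grid[which.max(ll)]
}

# two-sided chi-square(1) p-value
chisq_p <- function(stat) pchisq(stat, 1, lower.tail = FALSE)
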