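test_that("a minimal three-line pedigree yields one trio and no unrelateds", {
  ped <- data.frame(fid = "F1", id = c("dad", "mum", "kid"),
                    father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
                    sex = c(1, 2, 0), affected = c(0, 0, 1))
  g <- matrix(c(1L, 0L, 1L), 3, 1,
              dimnames = list(ped$id, "rs1"))
  s <- combined_sample(ped, g)
  expect_equal(unname(sample_counts(s)), c(0L, 1L, 3L))
  expect_setequal(s$ped$role, c("parent", "parent", "offspring"))
})

test_that("role inference and counts satisfy n_family_members = 3 * n_trios", {
  s <- make_manual_sample(n_case_trios = 3, n_control_trios = 2,
                          n_unrelated = 7)
  cts <- sample_counts(s)
  expect_equal(unname(cts), c(7L, 5L, 15L))
  expect_equal(cts[["n_family_members"]], 3L * cts[["n_trios"]])
  # founders = parents + unrelated
  expect_equal(length(s$founders), 7L + 2L * 5L)
})

test_that("mendelian_consistent matches enumeration of all 27 trio combinations", {
  # oracle: enumerate transmissible alleles per parent genotype
  alleles <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  for (gf in 0:2) for (gm in 0:2) for (go in 0:2) {
    possible <- any(outer(alleles[[gf + 1L]], alleles[[gm + 1L]], `+`) == go)
    expect_identical(mendelian_consistent(gf, gm, go), possible,
                     info = sprintf("f=%d m=%d o=%d", gf, gm, go))
  }
  expect_true(is.na(mendelian_consistent(NA, 1L, 1L)))
})

test_that("an inconsistent trio is dropped from that SNP's likelihood only", {
  s <- make_manual_sample(n_case_trios = 3, n_control_trios = 0,
                          n_unrelated = 20,
                          unrelated_affected = rep(c(0, 1), 10),
                          mafs = c(0.4, 0.4), seed = 5)
  # corrupt trio 1 at SNP 1: child 2, parents 0/0
  s$geno["T01_F", 1] <- 0L; s$geno["T01_M", 1] <- 0L; s$geno["T01_O", 1] <- 2L
  inp1 <- popfam:::chen_lin_snp_inputs(s, 1)
  inp2 <- popfam:::chen_lin_snp_inputs(s, 2)
  expect_equal(nrow(inp1$case_trios), 2L)
  expect_equal(inp1$n_mendel_excluded, 1L)
  expect_equal(nrow(inp2$case_trios), 3L)
})

test_that("the case-control subsample follows the offspring-augmentation rule", {
  s <- make_manual_sample(n_case_trios = 2, n_control_trios = 1,
                          n_unrelated = 5)
  cc <- build_cc_subsample(s)
  expect_equal(length(cc$ids), 8L)  # 3 offspring + 5 unrelated controls
  expect_false(cc$degenerate)
  expect_equal(sum(cc$y), 2L)
  expect_false(anyDuplicated(cc$ids) > 0)

  cc2 <- build_cc_subsample(s, rule = "probands_plus_unrelated_controls")
  expect_equal(length(cc2$ids), 7L)  # control offspring excluded

  s0 <- make_manual_sample(n_case_trios = 0, n_control_trios = 0,
                           n_unrelated = 6,
                           unrelated_affected = c(1, 1, 0, 0, 0, 1))
  expect_equal(sort(build_cc_subsample(s0)$ids), sort(s0$unrelated))

  s1 <- make_manual_sample(n_case_trios = 2, n_control_trios = 0,
                           n_unrelated = 0)
  expect_true(build_cc_subsample(s1)$degenerate)  # all offspring affected
})

test_that("founder MAF and frequency classes are computed as documented", {
  ped <- data.frame(fid = as.character(1:4), id = sprintf("I%d", 1:4),
                    father = NA_character_, mother = NA_character_,
                    sex = 0, affected = c(0, 1, 0, 1))
  g <- matrix(c(0L, 0L, 1L, 2L,   0L, 0L, 0L, 0L), 4, 2,
              dimnames = list(ped$id, c("s1", "s2")))
  s <- combined_sample(ped, g)
  info <- snp_summaries(s)
  expect_equal(info$maf[1], 3 / 8)   # 3 minor alleles among 8
  expect_equal(info$maf[2], 0)
  expect_true(info$monomorphic[2])
  # frequency classes at the default cutoffs
  expect_equal(as.character(maf_class(c(0.000717, 0.03, 0.164993))),
               c("rare", "moderate", "common"))
})

test_that("founder MAF ignores offspring genotypes", {
  s <- make_manual_sample(n_case_trios = 3, n_control_trios = 1,
                          n_unrelated = 6, mafs = c(0.3, 0.2))
  before <- snp_summaries(s)$maf
  s$geno[s$trios$offspring, ] <- 0L
  expect_equal(snp_summaries(s)$maf, before)
})

test_that("write_sample / read_ped round-trips ids, roles, phenotypes, genotypes", {
  s <- make_manual_sample(n_case_trios = 2, n_control_trios = 1,
                          n_unrelated = 4,
                          unrelated_affected = c(1, 0, 0, 1),
                          mafs = c(0.4, 0.25, 0.1))
  dir <- withr::local_tempdir()
  paths <- write_sample(s, file.path(dir, "sample"))
  s2 <- read_ped(paths["ped"], paths["geno"])
  expect_equal(sort(s2$ped$id), sort(s$ped$id))
  ord <- match(s$ped$id, s2$ped$id)
  expect_equal(s2$ped$role[ord], s$ped$role)
  expect_equal(s2$ped$affected[ord], s$ped$affected)
  expect_equal(s2$geno[rownames(s$geno), ], s$geno)
  expect_equal(unname(sample_counts(s2)), unname(sample_counts(s)))
})

test_that("pedigree parsing errors carry line numbers and id diagnostics", {
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "bad.ped")
  gen <- file.path(dir, "g.tsv")
  writeLines(c("F1 A 0 0 1 1", "F1 B 0 0"), ped)
  writeLines(c("id\ts1", "A\t0", "B\t1"), gen)
  expect_error(read_ped(ped, gen), "line 2")

  writeLines(c("F1 A 0 0 1 1", "F1 A 0 0 2 1"), ped)
  expect_error(read_ped(ped, gen), "duplicate")

  writeLines(c("F1 A 0 0 1 1", "F1 K A ghost 0 2"), ped)
  writeLines(c("id\ts1", "A\t0", "K\t1"), gen)
  expect_error(read_ped(ped, gen), "ghost")
})

test_that("both affection coding dialects are decoded", {
  dir <- withr::local_tempdir()
  gen <- file.path(dir, "g.tsv")
  writeLines(c("id\ts1", "A\t0", "B\t1", "C\t2"), gen)
  ped12 <- file.path(dir, "p12.ped")
  writeLines(c("FA A 0 0 1 1", "FB B 0 0 1 2", "FC C 0 0 1 0"), ped12)
  s <- read_ped(ped12, gen)
  expect_equal(s$ped$affected[match(c("A", "B", "C"), s$ped$id)],
               c(0L, 1L, NA))
  ped01 <- file.path(dir, "p01.ped")
  writeLines(c("FA A 0 0 1 0", "FB B 0 0 1 1", "FC C 0 0 1 -9"), ped01)
  s <- read_ped(ped01, gen)
  expect_equal(s$ped$affected[match(c("A", "B", "C"), s$ped$id)],
               c(0L, 1L, NA))
})

test_that("VCF genotypes convert to minor-allele counts", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "g.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "1\t100\ts1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\ts2\tA\tG\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"), vcf)
  ped <- file.path(dir, "p.ped")
  writeLines(c("FA A 0 0 1 1", "FB B 0 0 1 2", "FC C 0 0 1 2"), ped)
  s <- read_ped(ped, vcf)
  expect_equal(unname(s$geno[c("A", "B", "C"), "s1"]), c(0L, 1L, 2L))
  # s2: ALT is the major allele, so counts are re-oriented to the minor
  expect_equal(unname(s$geno[c("A", "B", "C"), "s2"]), c(0L, 0L, 1L))
})

test_that("results tables round-trip with NA tokens and fixed column order", {
  res <- data.frame(snp_id = rep(c("s1", "s2"), each = 3),
                    method = rep(c("chen_lin", "zhu", "zhang"), 2),
                    statistic = c(1.2, 2.3, 3.4, NA, 0.5, 0.1),
                    p_value = c(0.27, 0.13, 0.06, NA, 0.48, 0.75),
                    estimate = runif(6), se = runif(6),
                    homogeneity_p = c(0.5, NA, NA, NA, NA, NA),
                    status = c(rep("ok", 3), "monomorphic", "ok", "ok"),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- read_results(path)
  expect_equal(nrow(back), 6L)
  expect_equal(names(back)[1:8],
               c("snp_id", "method", "statistic", "p_value", "estimate",
                 "se", "homogeneity_p", "status"))
  expect_true(is.na(back$p_value[back$status == "monomorphic"]))
  expect_equal(back$statistic, res$statistic)
  expect_error(write_results(res[0, ], path), "no results")
})
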