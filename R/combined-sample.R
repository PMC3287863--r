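#' Construct a combined population/family sample
#'
#' Builds the mixed study design used throughout the package: unrelated
#' case-control subjects plus complete case/control-parent trios, with
#' additive-coded genotypes (minor-allele counts 0/1/2) and a binary
#' affection phenotype.
#'
#' Roles are inferred from pedigree links: an individual whose father and
#' mother are both present in the pedigree *and* genotyped becomes a trio
#' offspring and its parents become trio parents; everyone else is
#' unrelated.  Founders are the union of trio parents and unrelated
#' subjects; allele frequencies and principal components are computed on
#' founders only.
#'
#' @param ped data frame with columns `fid`, `id`, `father`, `mother`,
#'   `sex`, `affected`.  `father`/`mother` are `NA` (or `"0"`) for
#'   founders.  `affected` may use either 0/1 coding (`NA` missing) or the
#'   PED 1/2 coding (0 or -9 missing); the dialect is auto-detected.
#' @param geno integer matrix, individuals x SNPs, entries in
#'   \{0, 1, 2, NA\}, with `rownames` matching `ped$id` and `colnames`
#'   giving SNP identifiers.
#' @return An object of class `combined_sample`: a list with elements
#'   `ped` (pedigree with an inferred `role` column), `geno`, `trios`
#'   (data frame of `father`, `mother`, `offspring` ids), and the id
#'   vectors `unrelated` and `founders`.
#' @seealso [read_ped()], [build_cc_subsample()], [snp_summaries()]
#' @export
combined_sample <- function(ped, geno) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  need <- c("fid", "id", "father", "mother", "sex", "affected")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0L)
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  ped$id <- as.character(ped$id)
  ped$father <- norm_parent_id(ped$father)
  ped$mother <- norm_parent_id(ped$mother)
  if (anyDuplicated(ped$id))
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))

  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix must have individual ids as rownames and SNP ids as colnames")
  bad <- geno[!is.na(geno)]
  if (length(bad) > 0L && !all(bad %in% c(0L, 1L, 2L)))
    stop("genotypes must be additive minor-allele counts in {0, 1, 2} or NA")
  storage.mode(geno) <- "integer"

  ped$affected <- decode_affection(ped$affected)

  ref <- setdiff(c(ped$father, ped$mother), c(NA_character_, ped$id))
  if (length(ref) > 0L)
    stop("parent id(s) referenced but absent from the pedigree: ",
         paste(ref, collapse = ", "))

  genotyped <- ped$id %in% rownames(geno)
  names(genotyped) <- ped$id

  has_both <- !is.na(ped$father) & !is.na(ped$mother)
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("individual(s) with exactly one parent recorded are not supported: ",
         paste(ped$id[half], collapse = ", "))

  is_offspring <- has_both & genotyped[ped$id] &
    genotyped[ifelse(has_both, ped$father, ped$id)] &
    genotyped[ifelse(has_both, ped$mother, ped$id)]
  is_offspring[is.na(is_offspring)] <- FALSE

  parent_ids <- unique(c(ped$father[is_offspring], ped$mother[is_offspring]))
  if (any(has_both[ped$id %in% parent_ids]))
    stop("multi-generation pedigrees are not supported (a trio parent has recorded parents)")

  role <- rep("unrelated", nrow(ped))
  role[is_offspring] <- "offspring"
  role[ped$id %in% parent_ids] <- "parent"
  ped$role <- role

  trios <- data.frame(father = ped$father[is_offspring],
                      mother = ped$mother[is_offspring],
                      offspring = ped$id[is_offspring],
                      stringsAsFactors = FALSE)

  ped_g <- ped[genotyped[ped$id], , drop = FALSE]
  geno <- geno[ped_g$id, , drop = FALSE]

  structure(list(ped = ped_g,
                 geno = geno,
                 trios = trios,
                 unrelated = ped_g$id[ped_g$role == "unrelated"],
                 founders = ped_g$id[ped_g$role != "offspring"]),
            class = "combined_sample")
}

norm_parent_id <- function(x) {
  x <- as.character(x)
  x[x %in% c("0", "", "NA")] <- NA_character_
  x
}

# PED files encode affection as 1 = unaffected / 2 = affected with 0 or -9
# missing; simulated files use 0/1 with NA missing.  Presence of a 2 decides.
decode_affection <- function(x) {
  x <- suppressWarnings(as.numeric(as.character(x)))
  if (any(x == 2, na.rm = TRUE)) {
    out <- rep(NA_integer_, length(x))
    out[x == 1] <- 0L
    out[x == 2] <- 1L
  } else {
    x[x == -9] <- NA
    if (!all(x %in% c(0, 1, NA)))
      stop("unrecognised affection coding (expected 0/1 or PED 1/2)")
    out <- as.integer(x)
  }
  out
}

#' @export
print.combined_sample <- function(x, ...) {
  cat("Combined population/family sample\n")
  cat(sprintf("  unrelated subjects : %d\n", length(x$unrelated)))
  cat(sprintf("  complete trios     : %d (%d family members)\n",
              nrow(x$trios), 3L * nrow(x$trios)))
  cat(sprintf("  SNPs               : %d\n", ncol(x$geno)))
  invisible(x)
}

#' Sample size summary
#'
#' @param sample a [combined_sample()].
#' @return Named vector `(n_unrelated, n_trios, n_family_members)` with
#'   `n_family_members = 3 * n_trios`.
#' @export
sample_counts <- function(sample) {
  stopifnot(inherits(sample, "combined_sample"))
  c(n_unrelated = length(sample$unrelated),
    n_trios = nrow(sample$trios),
    n_family_members = 3L * nrow(sample$trios))
}

#' Read a pedigree plus additive genotype matrix
#'
#' Reads a six-column PED/FAM-style pedigree (family, individual, father,
#' mother, sex, phenotype; whitespace-separated, no header) together with a
#' genotype source, and assembles a [combined_sample()].
#'
#' @param ped_path path to the pedigree file.
#' @param genotype_path path to the genotypes: either a TSV matrix
#'   (first column individual id, remaining columns one SNP each, header row
#'   of SNP ids) or a VCF (`format = "vcf"`, requires the `vcfR` package;
#'   GT fields are converted to minor-allele counts).
#' @param format `"auto"` (by file extension), `"tsv"` or `"vcf"`.
#' @return A [combined_sample()].  Individuals with missing phenotype are
#'   retained but excluded from testing downstream.
#' @export
read_ped <- function(ped_path, genotype_path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(ped_path)) stop("pedigree file not found: ", ped_path)
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("malformed pedigree line ", which(nf != 6L)[1L],
         ": expected 6 whitespace-separated fields, found ", nf[nf != 6L][1L])
  ped <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(ped) <- c("fid", "id", "father", "mother", "sex", "affected")

  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", genotype_path, ignore.case = TRUE)) "vcf" else "tsv"
  geno <- if (format == "vcf") read_vcf_genotypes(genotype_path)
          else read_tsv_genotypes(genotype_path)

  combined_sample(ped, geno)
}

read_tsv_genotypes <- function(path) {
  g <- utils::read.delim(path, header = TRUE, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(g)
}

read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  known <- !is.na(gt)
  alt <- vapply(strsplit(gt[known], "[/|]"),
                function(a) sum(a == "1"), integer(1L))
  counts[known] <- alt
  counts <- t(counts)  # individuals x SNPs
  # re-orient to the sample minor allele
  p <- colMeans(counts, na.rm = TRUE) / 2
  flip <- !is.na(p) & p > 0.5
  counts[, flip] <- 2L - counts[, flip]
  counts
}

#' Write a combined sample as pedigree + genotype text files
#'
#' Emits `<prefix>.ped` (six-column pedigree, PED 1/2 affection coding,
#' 0 for missing phenotype) and `<prefix>.geno.tsv` (additive genotype
#' matrix) readable by [read_ped()].
#'
#' @param sample a [combined_sample()].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_sample <- function(sample, prefix) {
  stopifnot(inherits(sample, "combined_sample"))
  ped <- sample$ped
  aff <- ifelse(is.na(ped$affected), 0L, ped$affected + 1L)
  out <- data.frame(fid = ped$fid, id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ped$sex, affected = aff)
  ped_path <- paste0(prefix, ".ped")
  geno_path <- paste0(prefix, ".geno.tsv")
  utils::write.table(out, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- data.frame(id = rownames(sample$geno), sample$geno,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(g, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(ped = ped_path, geno = geno_path))
}

#' Case-control subsample for the logistic-regression arm
#'
#' Assembles the subsample that the population-based (logistic) arm of the
#' combined estimator is fitted on.  Under the default rule this is every
#' trio offspring — affected probands and unaffected control offspring —
#' plus all unrelated subjects; trio parents never enter.
#'
#' @param sample a [combined_sample()].
#' @param rule subsampling rule.
#'   `"probands_plus_unrelated_controls_plus_control_offspring"` (default):
#'   all trio offspring plus all unrelated subjects.
#'   `"probands_plus_unrelated_controls"`: affected trio offspring plus
#'   unrelated subjects only.  `"all_unrelated"`: unrelated subjects only.
#' @return List with `ids`, `y` (0/1 phenotype), and `degenerate` (TRUE
#'   when the subsample is empty or contains a single phenotype class —
#'   consumed downstream as a degenerate flag, not an error).
#' @export
build_cc_subsample <- function(sample,
    rule = c("probands_plus_unrelated_controls_plus_control_offspring",
             "probands_plus_unrelated_controls",
             "all_unrelated")) {
  stopifnot(inherits(sample, "combined_sample"))
  rule <- match.arg(rule)
  ped <- sample$ped
  aff <- ped$affected
  names(aff) <- ped$id
  off <- sample$trios$offspring
  ids <- switch(rule,
    probands_plus_unrelated_controls_plus_control_offspring =
      c(off, sample$unrelated),
    probands_plus_unrelated_controls =
      c(off[aff[off] %in% 1L], sample$unrelated),
    all_unrelated = sample$unrelated)
  ids <- ids[!is.na(aff[ids])]
  y <- as.integer(aff[ids])
  list(ids = ids, y = y,
       degenerate = length(ids) == 0L || length(unique(y)) < 2L)
}

#' Mendelian consistency of a trio genotype triple
#'
#' An offspring minor-allele count is compatible with its parents when it
#' can be written as the sum of one allele transmissible by each parent
#' (a parent with count 0 transmits 0, count 2 transmits 1, count 1 either).
#'
#' @param g_father,g_mother,g_offspring additive genotype vectors in
#'   \{0, 1, 2\}; `NA` propagates.
#' @return Logical vector; `NA` where any genotype is missing.
#' @export
mendelian_consistent <- function(g_father, g_mother, g_offspring) {
  lo <- (g_father == 2L) + (g_mother == 2L)
  hi <- (g_father >= 1L) + (g_mother >= 1L)
  g_offspring >= lo & g_offspring <= hi
}

#' Per-SNP summaries: minor allele frequency and frequency class
#'
#' MAF is computed from founders only (trio parents plus unrelated
#' subjects), so transmitted alleles are not double-counted, and is the
#' frequency of the less common allele.  Frequency classes follow the
#' rare / moderate / common convention.
#'
#' @param sample a [combined_sample()].
#' @param cutoffs named vector `c(rare = , common = )`: MAF < `rare` is
#'   rare, MAF > `common` is common, in between moderate.
#' @return data frame with `snp_id`, `maf`, `maf_class`, `n_founder_alleles`,
#'   `missing_frac` (per-SNP missingness over all genotyped individuals),
#'   and `monomorphic`.
#' @export
snp_summaries <- function(sample, cutoffs = c(rare = 0.01, common = 0.05)) {
  stopifnot(inherits(sample, "combined_sample"))
  gf <- sample$geno[sample$founders, , drop = FALSE]
  n_alleles <- 2L * colSums(!is.na(gf))
  p <- colSums(gf, na.rm = TRUE) / pmax(n_alleles, 1L)
  maf <- pmin(p, 1 - p)
  maf[n_alleles == 0L] <- NA_real_
  data.frame(snp_id = colnames(sample$geno),
             maf = unname(maf),
             maf_class = maf_class(maf, cutoffs),
             n_founder_alleles = unname(n_alleles),
             missing_frac = unname(colMeans(is.na(sample$geno))),
             monomorphic = unname(is.na(maf) | maf == 0),
             stringsAsFactors = FALSE)
}

#' Assign rare / moderate / common MAF classes
#' @param maf numeric vector of minor allele frequencies.
#' @param cutoffs named vector `c(rare = , common = )`.
#' @return factor with levels `rare`, `moderate`, `common`.
#' @export
maf_class <- function(maf, cutoffs = c(rare = 0.01, common = 0.05)) {
  cls <- ifelse(maf < cutoffs[["rare"]], "rare",
         ifelse(maf > cutoffs[["common"]], "common", "moderate"))
  factor(cls, levels = c("rare", "moderate", "common"))
}

result_columns <- c("snp_id", "method", "statistic", "p_value", "estimate",
                    "se", "homogeneity_p", "status")

#' Write per-SNP association results to a TSV file
#'
#' One row per SNP x method.  The core columns (`snp_id`, `method`,
#' `statistic`, `p_value`, `estimate`, `se`, `homogeneity_p`, `status`)
#' come first in a fixed order; any method-specific diagnostic columns
#' follow.  Missing values are emitted as `NA` and the file round-trips
#' through [read_results()].
#'
#' @param results data frame of association results (e.g. from
#'   [association_scan()]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (NROW(results) == 0L) stop("no results to write")
  core <- intersect(result_columns, names(results))
  extra <- setdiff(names(results), core)
  utils::write.table(results[, c(core, extra), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results TSV written by [write_results()]
#' @param path file path.
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE)
}
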