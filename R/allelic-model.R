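#' Expected B-allele frequency of an admixed tumor genotype
#'
#' For a germline-heterozygous SNP (one A and one B copy in normal cells),
#' the expected B-allele frequency of a specimen with tumor purity `p` and
#' tumor genotype `(major, minor)` is, in the B-major orientation,
#' \deqn{BAF = \frac{p \cdot major + (1-p)}{p \cdot (major+minor) + 2(1-p)}.}
#' The A-major orientation is one minus this value, so the mirrored BAF
#' (`max(BAF, 1-BAF)`) equals the value returned here.
#'
#' @param major,minor Allele copy numbers of the tumor genotype (recycled).
#' @param purity Tumor-cell fraction in (0, 1] (recycled).
#' @return Expected B-major BAF, a value in \[0.5, 1\].
#' @examples
#' expected_baf(1, 1, 0.65)  # 0.5: balanced state at any purity
#' expected_baf(1, 0, 0.65)  # 0.7407: hemizygous loss diluted to 65% purity
#' @seealso [expected_log2_ratio()], [estimate_purity()]
#' @export
expected_baf <- function(major, minor, purity) {
  s <- genotype_state(major, minor)
  check_purity(purity)
  (purity * s$major + (1 - purity)) /
    (purity * (s$major + s$minor) + 2 * (1 - purity))
}

#' Expected log2 coverage ratio of an admixed tumor genotype
#'
#' Relative sequencing depth of an arm with tumor total copy number
#' `major + minor` against the sample's balanced-diploid baseline:
#' \deqn{\log_2\frac{p \cdot (major+minor) + 2(1-p)}{2}.}
#' Copy-neutral states (total 2) sit at 0 for every purity; losses are
#' negative, gains positive.
#'
#' @inheritParams expected_baf
#' @return Expected log2 depth ratio against a diploid baseline.
#' @examples
#' expected_log2_ratio(2, 0, 0.8)  # 0: copy-neutral LOH has neutral coverage
#' expected_log2_ratio(1, 0, 1.0)  # -1: half coverage in a pure tumor
#' @export
expected_log2_ratio <- function(major, minor, purity) {
  s <- genotype_state(major, minor)
  check_purity(purity)
  log2((purity * (s$major + s$minor) + 2 * (1 - purity)) / 2)
}

check_purity <- function(purity) {
  if (!is.numeric(purity) || anyNA(purity) || any(purity <= 0) || any(purity > 1)) {
    stop("purity must lie in (0, 1]")
  }
  invisible(purity)
}

#' Estimate tumor purity from the mirrored BAF of an LOH arm
#'
#' Inverts [expected_baf()] for the two LOH states: a hemizygous loss
#' (`mechanism = "loss"`, state (1,0)) gives `p = 2 - 1/m`, a copy-neutral
#' LOH (`mechanism = "cn_loh"`, state (2,0)) gives `p = 2m - 1`, where `m`
#' is the arm's median mirrored BAF.
#'
#' @param mirrored_baf Mirrored BAF in \[0.5, 1\] from a confidently called
#'   LOH arm.
#' @param mechanism Either `"loss"` or `"cn_loh"`.
#' @return Tumor purity in (0, 1].
#' @examples
#' estimate_purity(0.7407407, "loss")   # 0.65
#' estimate_purity(0.825, "cn_loh")     # 0.65
#' @export
estimate_purity <- function(mirrored_baf, mechanism = c("loss", "cn_loh")) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(mirrored_baf) || length(mirrored_baf) != 1L || is.na(mirrored_baf)) {
    stop("mirrored_baf must be a single number")
  }
  if (mirrored_baf < 0.5 || mirrored_baf > 1) {
    stop("mirrored_baf must lie in [0.5, 1]")
  }
  p <- if (mechanism == "loss") 2 - 1 / mirrored_baf else 2 * mirrored_baf - 1
  if (p <= 0) {
    stop("uninformative mirrored BAF: implied purity is not positive")
  }
  min(p, 1)
}

#' Genome-wide ploidy with equal per-chromosome weights
#'
#' Mean total copy number over the 23 chromosomes (autosomes 1..22 plus X),
#' each chromosome weighted equally regardless of physical size. A genome
#' with whole-chromosome single-copy losses of 16 chromosomes and two copies
#' elsewhere gives (16 x 1 + 7 x 2) / 23 = 1.3 (one decimal).
#'
#' @param chrom_states A data frame with columns `chrom` (`"1"`..`"22"`,
#'   `"X"`), `major` and `minor`, exactly one row per chromosome.
#' @return A list with `ploidy` (raw mean), `ploidy_1dp` (rounded to one
#'   decimal, the conventional reporting precision) and `n_chromosomes`.
#' @examples
#' diploid <- data.frame(chrom = c(as.character(1:22), "X"), major = 1, minor = 1)
#' estimate_ploidy(diploid)$ploidy  # 2
#' @export
estimate_ploidy <- function(chrom_states) {
  chroms <- c(as.character(1:22), "X")
  if (!all(c("chrom", "major", "minor") %in% names(chrom_states))) {
    stop("chrom_states needs columns chrom, major, minor")
  }
  chrom_states$chrom <- as.character(chrom_states$chrom)
  missing <- setdiff(chroms, chrom_states$chrom)
  if (length(missing) > 0) {
    stop("missing chromosome(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(chrom_states$chrom)) {
    stop("duplicated chromosome(s) in chrom_states")
  }
  s <- genotype_state(chrom_states$major, chrom_states$minor)
  ploidy <- mean(s$major + s$minor)
  list(ploidy = ploidy, ploidy_1dp = round(ploidy, 1),
       n_chromosomes = nrow(chrom_states))
}
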