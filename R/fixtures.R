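#' Worked per-patient karyotype fixtures
#'
#' Ground-truth specifications for the six worked patients whose arm-level
#' genotype maps are spelled out in the source cohort: 51 (Pattern 1, no
#' alterations), 49 (Pattern 2, losses with one difficult chromosome 13
#' encoded as copy-neutral LOH on 13q), 20 (Pattern 3, whole-chromosome
#' gains), 22 (Pattern 4, copy-neutral LOH plus gains plus AABB chromosomes
#' 5 and 9), 52 (near-homozygous genome: copy-neutral LOH of 20 chromosomes
#' plus X, consistent with endoreduplication) and 56 (near-haploid genome:
#' single-copy loss of 16 chromosomes at 65% tumor purity, with genome
#' doubling recorded as a truth flag).
#'
#' Encoding notes: "part of 5q" in patient 52 is encoded as whole-5q because
#' the pipeline is arm-resolution; patient 56's "chromosome 23" is read as
#' X (the assay covers autosomes + X); sexes of 52 and 56 are not on record
#' and are encoded female so that X LOH is expressible allelically.
#'
#' @param patient_id One of 51, 49, 20, 22, 52, 56.
#' @return A [tumor_spec()].
#' @examples
#' spec <- patient_fixture(56)
#' sum(spec$arm_states$minor == 0)  # arms at single copy
#' @export
patient_fixture <- function(patient_id) {
  id <- as.character(patient_id)
  chrom_arms <- function(chroms) {
    arms <- arm_universe()
    arms$arm_id[arms$chrom %in% as.character(chroms)]
  }
  states <- function(arm_id, major, minor) {
    data.frame(arm_id = arm_id, major = major, minor = minor)
  }
  switch(id,
    "51" = tumor_spec("patient_51", sex = "female", purity = 0.8),
    "49" = tumor_spec("patient_49", sex = "male", purity = 0.8,
      arm_states = rbind(
        states(c("1p", chrom_arms(c(2, 8, 11))), 1L, 0L),
        states("13q", 2L, 0L))),
    "20" = tumor_spec("patient_20", sex = "male", purity = 0.8,
      arm_states = states(chrom_arms(c(3, 7, 8, 9, 12, 19, 21, 22)), 2L, 1L)),
    "22" = tumor_spec("patient_22", sex = "female", purity = 0.8,
      arm_states = rbind(
        states(chrom_arms(c(1, 2, 4, 10, 20, 22)), 2L, 0L),
        states(chrom_arms(c(3, 7, 8, 11, 12, 14, 17, 19, "X")), 2L, 1L),
        states(chrom_arms(c(5, 9)), 2L, 2L))),
    "52" = tumor_spec("patient_52", sex = "female", purity = 0.8,
      doubling = TRUE,
      arm_states = states(
        c(chrom_arms(c(1:4, 6, 8, 10:12, 14:22, "X")), "5q"), 2L, 0L)),
    "56" = tumor_spec("patient_56", sex = "female", purity = 0.65,
      doubling = TRUE,
      arm_states = states(
        chrom_arms(c(1:4, 6, 8, 10, 11, 13, 15, 17, 19:22, "X")), 1L, 0L)),
    stop("unknown patient fixture: ", id)
  )
}
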