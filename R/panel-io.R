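#' Read a SNP panel design table
#'
#' A panel design is a tab-separated table with header columns `locus_id`,
#' `chrom`, `arm` and `pop_baf` (the population B-allele frequency used for
#' germline simulation and tumor-only heterozygosity expectations). Arms are
#' validated against the 41-arm universe and loci are ordered by chromosome,
#' then arm, then input order.
#'
#' @param path Path to a tab-separated panel file.
#' @return A `panel_design` data frame with columns `locus_id`, `chrom`,
#'   `arm`, `pop_baf` and `arm_id`.
#' @export
load_panel <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("locus_id", "chrom", "arm", "pop_baf")
  if (!all(required %in% names(raw))) {
    stop("panel file must have columns ", paste(required, collapse = ", "))
  }
  bad <- !is_valid_arm(raw$chrom, raw$arm)
  if (any(bad)) {
    stop("panel format error: row(s) ", paste(which(bad), collapse = ", "),
         " use invalid arm(s) ",
         paste(unique(paste0(raw$chrom, raw$arm)[bad]), collapse = ", "))
  }
  if (anyDuplicated(raw$locus_id)) {
    stop("panel format error: duplicate locus_id ",
         paste(unique(raw$locus_id[duplicated(raw$locus_id)]), collapse = ", "))
  }
  pop_baf <- as.numeric(raw$pop_baf)
  if (anyNA(pop_baf) || any(pop_baf <= 0) || any(pop_baf >= 1)) {
    stop("panel format error: pop_baf must be strictly inside (0, 1)")
  }
  panel <- data.frame(locus_id = raw$locus_id, chrom = raw$chrom, arm = raw$arm,
                      pop_baf = pop_baf, stringsAsFactors = FALSE)
  panel <- panel[order(chrom_rank(panel$chrom), panel$arm), ]
  rownames(panel) <- NULL
  panel$arm_id <- paste0(panel$chrom, panel$arm)
  covered <- unique(panel$arm_id)
  uncovered <- setdiff(arm_universe()$arm_id, covered)
  if (length(uncovered) > 0) {
    warning("arm coverage incomplete: no loci on ",
            paste(uncovered, collapse = ", "))
  }
  class(panel) <- c("panel_design", "data.frame")
  panel
}

#' Write a panel design table
#'
#' @param panel A `panel_design` data frame as returned by [load_panel()] or
#'   [make_default_panel()].
#' @param path Output path; tab-separated, `pop_baf` at 6 decimals.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(locus_id = panel$locus_id, chrom = panel$chrom,
                    arm = panel$arm, pop_baf = sprintf("%.6f", panel$pop_baf))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample SNP observations
#'
#' Observations are a tab-separated table with columns `locus_id`, `depth`
#' and `b_count`. Loci present in the panel but missing from the file are
#' padded as depth-0 rows, so partial FFPE dropout remains representable.
#' Unknown loci and `b_count > depth` are format errors.
#'
#' @param path Path to a tab-separated observation file.
#' @param panel The `panel_design` the observations belong to.
#' @return A data frame with one row per panel locus, in panel order, with
#'   columns `locus_id`, `depth`, `b_count`.
#' @export
read_observations <- function(path, panel) {
  raw <- utils::read.delim(path, check.names = FALSE)
  required <- c("locus_id", "depth", "b_count")
  if (!all(required %in% names(raw))) {
    stop("observation file must have columns ", paste(required, collapse = ", "))
  }
  unknown <- setdiff(raw$locus_id, panel$locus_id)
  if (length(unknown) > 0) {
    stop("observation format error: unknown locus_id ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(raw$locus_id)) {
    stop("observation format error: duplicate locus_id")
  }
  depth <- as.integer(raw$depth)
  b_count <- as.integer(raw$b_count)
  if (anyNA(depth) || any(depth < 0)) stop("observation format error: depth must be a non-negative integer")
  if (anyNA(b_count) || any(b_count < 0) || any(b_count > depth)) {
    stop("observation format error: b_count must satisfy 0 <= b_count <= depth")
  }
  idx <- match(panel$locus_id, raw$locus_id)
  data.frame(locus_id = panel$locus_id,
             depth = ifelse(is.na(idx), 0L, depth[idx]),
             b_count = ifelse(is.na(idx), 0L, b_count[idx]))
}

#' Write per-sample SNP observations
#'
#' @param observations Data frame with `locus_id`, `depth`, `b_count`.
#' @param path Output path (tab-separated).
#' @return Invisibly, `path`.
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations[, c("locus_id", "depth", "b_count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort annotation table
#'
#' Tab-separated with columns `sample_id`, `lineage` (PIT1, TPIT, SF1 or
#' multilineage), `subtype` (free text), `sex`, `invasive`, `functional`,
#' `recurrent`.
#'
#' @param path Path to the annotation file.
#' @return A validated data frame of cohort records.
#' @export
load_cohort_annotations <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "lineage", "subtype", "sex", "invasive",
                "functional", "recurrent")
  if (!all(required %in% names(raw))) {
    stop("annotation file must have columns ", paste(required, collapse = ", "))
  }
  if (any(!nzchar(raw$lineage)) || any(!nzchar(raw$sex))) {
    stop("annotation format error: lineage and sex must be non-empty")
  }
  if (!all(raw$lineage %in% c("PIT1", "TPIT", "SF1", "multilineage"))) {
    stop("annotation format error: lineage must be PIT1, TPIT, SF1 or multilineage")
  }
  if (!all(raw$sex %in% c("male", "female"))) {
    stop("annotation format error: sex must be male or female")
  }
  raw[, required]
}
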