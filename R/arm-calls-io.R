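#' Write arm-level calls to a SEG-like table
#'
#' One row per scoreable arm, tab-separated, in fixed row order (chromosome
#' 1..22, X; p before q) with stable columns: `chrom`, `arm`,
#' `n_informative`, `median_mirrored_baf`, `median_log2_ratio`, `state`
#' (`major/minor`), `genotype_label`, `mechanism`, `hemizygous`,
#' `low_confidence`, `no_call`. Floats are serialized at 6 decimals.
#'
#' @param calls An `arm_calls` data frame from [call_sample()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_arm_calls <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0) stop("calls must be non-empty")
  calls <- calls[order(chrom_rank(calls$chrom), calls$arm), ]
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  out <- data.frame(
    chrom = calls$chrom,
    arm = calls$arm,
    n_informative = calls$n_informative,
    median_mirrored_baf = fmt(calls$median_mirrored_baf),
    median_log2_ratio = fmt(calls$median_log2_ratio),
    state = paste0(calls$major, "/", calls$minor),
    genotype_label = calls$genotype_label,
    mechanism = calls$mechanism,
    hemizygous = calls$hemizygous,
    low_confidence = calls$low_confidence,
    no_call = calls$no_call
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read arm-level calls written by [write_arm_calls()]
#'
#' @param path Path to an arm-call table.
#' @return An `arm_calls` data frame.
#' @export
read_arm_calls <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  required <- c("chrom", "arm", "n_informative", "median_mirrored_baf",
                "median_log2_ratio", "state", "genotype_label", "mechanism",
                "hemizygous", "low_confidence", "no_call")
  if (!all(required %in% names(raw))) {
    stop("arm-call file must have columns ", paste(required, collapse = ", "))
  }
  state <- strsplit(raw$state, "/", fixed = TRUE)
  calls <- data.frame(
    chrom = raw$chrom,
    arm = raw$arm,
    arm_id = paste0(raw$chrom, raw$arm),
    n_informative = as.integer(raw$n_informative),
    median_mirrored_baf = suppressWarnings(as.numeric(raw$median_mirrored_baf)),
    median_log2_ratio = suppressWarnings(as.numeric(raw$median_log2_ratio)),
    major = as.integer(vapply(state, `[`, "", 1L)),
    minor = as.integer(vapply(state, `[`, "", 2L)),
    genotype_label = raw$genotype_label,
    mechanism = raw$mechanism,
    hemizygous = as.logical(raw$hemizygous),
    low_confidence = as.logical(raw$low_confidence),
    no_call = as.logical(raw$no_call),
    stringsAsFactors = FALSE
  )
  bad <- !is_valid_arm(calls$chrom, calls$arm)
  if (any(bad)) stop("arm-call format error: invalid arm(s) ",
                     paste(unique(calls$arm_id[bad]), collapse = ", "))
  class(calls) <- c("arm_calls", "data.frame")
  calls
}
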