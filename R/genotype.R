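#' Genotype states and their canonical labels
#'
#' An arm-level genotype state is an unordered pair of parental allele copy
#' numbers `(major, minor)` with `major >= minor >= 0` and a total of at most
#' four copies. The canonical labels follow the field's convention for
#' tumor-only SNP genotyping: `AB` (1,1), `A0/0B` (1,0), `AA/BB` (2,0),
#' `AAB/ABB` (2,1) and `AABB` (2,2). States `AA/BB` and `AABB` arise after
#' endoreduplication/genome doubling.
#'
#' @param major,minor Integer vectors of allele copy numbers (recycled).
#' @return `genotype_state()` returns a validated two-column data frame;
#'   `genotype_label()` returns the canonical character labels.
#' @examples
#' genotype_label(2, 0)  # "AA/BB"
#' @export
genotype_state <- function(major, minor) {
  n <- max(length(major), length(minor))
  major <- as.integer(rep_len(major, n))
  minor <- as.integer(rep_len(minor, n))
  if (anyNA(major) || anyNA(minor)) stop("allele copy numbers must be integers")
  if (any(minor < 0)) stop("minor allele copy number must be >= 0")
  if (any(major < minor)) stop("major allele copy number must be >= minor")
  if (any(major + minor > 4L)) stop("total copy number above 4 is outside the state universe")
  data.frame(major = major, minor = minor)
}

#' @rdname genotype_state
#' @export
genotype_label <- function(major, minor) {
  s <- genotype_state(major, minor)
  canonical <- c("1/1" = "AB", "1/0" = "A0/0B", "2/0" = "AA/BB",
                 "2/1" = "AAB/ABB", "2/2" = "AABB", "0/0" = "0")
  key <- paste0(s$major, "/", s$minor)
  out <- unname(canonical[key])
  # states outside the named set get a literal allele string, e.g. (3,1) -> AAAB
  other <- is.na(out)
  out[other] <- paste0(strrep("A", s$major[other]), strrep("B", s$minor[other]))
  out
}

# the five-state universe used by the caller, in tie-break order
STATE_UNIVERSE <- data.frame(
  major = c(1L, 1L, 2L, 2L, 2L),
  minor = c(1L, 0L, 0L, 1L, 2L)
)

# mechanism implied by a called state on a diploid (non-hemizygous) background
state_mechanism <- function(major, minor) {
  key <- paste0(major, "/", minor)
  map <- c("1/1" = "none", "1/0" = "loss", "2/0" = "cn_loh",
           "2/1" = "gain", "2/2" = "balanced_gain", "0/0" = "loss")
  out <- unname(map[key])
  out[is.na(out)] <- "none"
  out
}
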