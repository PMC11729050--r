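#' The scoreable chromosome-arm universe
#'
#' Arm-level analysis scores both arms of every autosome plus the X
#' chromosome, excluding the short arms of the acrocentric chromosomes
#' (13p, 14p, 15p, 21p, 22p), whose repetitive content carries no scoreable
#' unique sequence. This leaves exactly 41 arms.
#'
#' @return A data frame with one row per scoreable arm and columns
#'   `chrom` (character, `"1"`..`"22"`, `"X"`), `arm` (`"p"` or `"q"`) and
#'   `arm_id` (e.g. `"17q"`), ordered by chromosome 1..22, X with p before q.
#' @examples
#' nrow(arm_universe())  # 41
#' @export
arm_universe <- function() {
  chroms <- c(as.character(1:22), "X")
  grid <- expand.grid(arm = c("p", "q"), chrom = chroms,
                      stringsAsFactors = FALSE)[, c("chrom", "arm")]
  grid <- grid[!(paste0(grid$chrom, grid$arm) %in% ACROCENTRIC_P), ]
  grid <- grid[order(chrom_rank(grid$chrom), grid$arm), ]
  rownames(grid) <- NULL
  grid$arm_id <- paste0(grid$chrom, grid$arm)
  grid
}

# short arms with no scoreable unique sequence
ACROCENTRIC_P <- c("13p", "14p", "15p", "21p", "22p")

#' Validate chromosome-arm identifiers
#'
#' @param chrom Character vector of chromosome names (`"1"`..`"22"`, `"X"`).
#' @param arm Character vector, `"p"` or `"q"`, recycled against `chrom`.
#' @return Logical vector: is each (chrom, arm) pair a scoreable arm?
#' @examples
#' is_valid_arm("13", "p")  # FALSE, acrocentric short arm
#' is_valid_arm("13", "q")  # TRUE
#' @export
is_valid_arm <- function(chrom, arm) {
  paste0(as.character(chrom), arm) %in% arm_universe()$arm_id
}

# integer rank of chromosomes for sorting (1..22, X = 23)
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[chrom == "X"] <- 23L
  if (anyNA(r)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(r)]), collapse = ", "))
  r
}

# split "17q" style ids into chrom/arm, with validation
parse_arm_id <- function(arm_id) {
  arm <- substring(arm_id, nchar(arm_id))
  chrom <- substring(arm_id, 1L, nchar(arm_id) - 1L)
  bad <- !is_valid_arm(chrom, arm)
  if (any(bad)) {
    stop("invalid chromosome arm(s): ", paste(unique(arm_id[bad]), collapse = ", "),
         " (valid arms are the 41 autosomal + X arms minus acrocentric p-arms)")
  }
  data.frame(chrom = chrom, arm = arm, arm_id = arm_id,
             stringsAsFactors = FALSE)
}
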