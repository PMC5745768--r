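# Published per-category reference values shipped with the package: the
# five-category strain tables (sagittal block; inversion and eversion
# blocks) and the census / contingency counts from the 81-foot cadaver
# sample the model mirrors.  Per-specimen strain values depend on the
# original (unpublished) digitized coordinates and are used here only as
# inputs to the aggregation utilities, whose summary rows they reproduce.

reference_file <- function(name) {
  path <- system.file("extdata", name, package = "cflsim")
  if (!nzchar(path)) stop("reference file not found: ", name, call. = FALSE)
  path
}

#' Reference per-category strain table
#'
#' @param plane which block: strain during pure sagittal motion, or with
#'   20 degrees of inversion or eversion added.
#' @return Numeric matrix, rows = categories, columns = poses
#'   (`PF30 ... DF20`).
#' @export
reference_strain_table <- function(plane = c("sagittal", "inversion", "eversion")) {
  plane <- match.arg(plane)
  df <- utils::read.csv(reference_file(paste0("reference_strain_", plane, ".csv")),
                        check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$category
  m
}

#' Reference contingency counts
#'
#' Category counts split by sex (51 male / 30 female feet) or by side
#' (the 37 donors with both feet measurable; 74 feet).
#'
#' @param split `"sex"` or `"side"`.
#' @return Integer matrix, rows = groups, columns = categories.
#' @export
reference_counts <- function(split = c("sex", "side")) {
  split <- match.arg(split)
  df <- utils::read.csv(reference_file(paste0("reference_counts_", split, ".csv")),
                        check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$group
  storage.mode(m) <- "integer"
  m
}

#' Reference cohort census
#'
#' @return data.frame with `category` and `n` (total 81 feet).
#' @export
reference_census <- function() {
  utils::read.csv(reference_file("reference_census.csv"),
                  stringsAsFactors = FALSE)
}
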