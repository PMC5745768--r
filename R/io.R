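# Plain-CSV serialization: landmark files (one row per named point) and
# strain tables laid out like the reference publications' tables, with
# unambiguous signed column labels (PF30 ... DF20, INV20/EV20 suffixes).

LANDMARK_COLUMNS <- c("name", "segment", "x_mm", "y_mm", "z_mm")

#' Write landmarks to CSV
#'
#' Full-precision (17 significant digits) so that a write/read round trip
#' reproduces coordinates exactly.
#'
#' @param landmarks an [ankle_landmarks()] set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  landmarks <- validate_ankle_landmarks(landmarks)
  df <- data.frame(name = landmarks$name, segment = landmarks$segment,
                   x_mm = sprintf("%.17g", landmarks$x),
                   y_mm = sprintf("%.17g", landmarks$y),
                   z_mm = sprintf("%.17g", landmarks$z),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmarks from CSV
#'
#' Expects header `name,segment,x_mm,y_mm,z_mm` (and optionally
#' `specimen`); validates landmark names and segment tags and fails loudly,
#' naming any missing required landmark.
#'
#' @param path input file path.
#' @return An [ankle_landmarks()] set, or a named list of them if the file
#'   has a `specimen` column with several specimens.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LANDMARK_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  build <- function(d) {
    ankle_landmarks(d$name, d$segment, as.numeric(d$x_mm),
                    as.numeric(d$y_mm), as.numeric(d$z_mm))
  }
  if ("specimen" %in% names(df) && length(unique(df$specimen)) > 1L) {
    lapply(split(df, df$specimen), build)
  } else {
    build(df)
  }
}

SAGITTAL_LABELS <- c(`-30` = "PF30", `-20` = "PF20", `-10` = "PF10",
                     `0` = "N0", `10` = "DF10", `20` = "DF20")
FRONTAL_SUFFIX <- c(`-20` = "_EV20", `0` = "", `20` = "_INV20")

#' Write a strain table (or cohort of tables) to CSV
#'
#' Columns are ordered plantarflexion 30, 20, 10, neutral, dorsiflexion 10,
#' 20 (labels `PF30 ... DF20`), with the inversion and eversion variants as
#' separate column blocks (suffixes `_INV20`, `_EV20`).  For a cohort
#' (named list of tables, one per category) an `Average_mean` row and an
#' `Average_sd` row (sample SD) are appended.  Values are written half-up
#' rounded to 1 decimal; computation upstream is full precision.
#'
#' @param x a `strain_table` from [sweep_grid()], or a named list of them.
#' @param path output file path.
#' @return The written data.frame, invisibly.
#' @export
write_strain_table <- function(x, path) {
  if (inherits(x, "strain_table")) x <- list(specimen = x)
  if (!length(x)) stop("validation error: empty input", call. = FALSE)
  for (t in x) validate_strain_table(t)
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("specimen_", seq_along(x))
  }
  grid <- expand.grid(sagittal_deg = c(-30, -20, -10, 0, 10, 20),
                      frontal_deg = c(0, 20, -20), KEEP.OUT.ATTRS = FALSE)
  labels <- paste0(SAGITTAL_LABELS[as.character(grid$sagittal_deg)],
                   FRONTAL_SUFFIX[as.character(grid$frontal_deg)])
  vals <- t(vapply(x, function(t) {
    mapply(function(s, f) strain_at(t, s, f), grid$sagittal_deg, grid$frontal_deg)
  }, numeric(nrow(grid))))
  colnames(vals) <- labels
  out <- data.frame(row = names(x), round_half_up(vals, 1),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (length(x) >= 2) {
    summ <- summarize_cohort(x)
    key <- paste(summ$sagittal_deg, summ$frontal_deg)
    ord <- match(paste(grid$sagittal_deg, grid$frontal_deg), key)
    avg <- data.frame(row = c("Average_mean", "Average_sd"),
                      rbind(round_half_up(summ$mean[ord], 1),
                            round_half_up(summ$sd[ord], 1)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(avg) <- names(out)
    out <- rbind(out, avg)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
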