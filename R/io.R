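#' Read a cohort CSV
#'
#' Reads and validates a participant table (comma-separated, UTF-8, "."
#' decimal, header required). Required columns are `id`, `sex`, `age` and the
#' motor battery ([clock_features()]); blood-panel columns are optional. Rows
#' failing validation (non-positive physical quantities, SPPB outside 0-12,
#' unparseable numerics) are dropped with per-row reasons recorded in the
#' `dropped` attribute.
#'
#' @param path Path to the CSV file.
#' @param required Required feature columns (default [clock_features()]).
#' @return Validated cohort data.frame; attribute `dropped` is a data.frame
#'   with `line` (file line number) and `reason` per rejected row.
#' @export
read_cohort <- function(path, required = clock_features()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "sex", "age", required)
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  numeric_cols <- setdiff(names(raw), c("id", "sex"))
  parsed <- raw
  for (v in numeric_cols) {
    suppressWarnings(parsed[[v]] <- as.numeric(raw[[v]]))
  }
  positive_cols <- intersect(
    c("age", "weight", "height", setdiff(required, "sppb")), names(parsed))

  reasons <- character(nrow(parsed))
  for (i in seq_len(nrow(parsed))) {
    r <- character(0)
    rv <- unlist(raw[i, numeric_cols])
    pv <- unlist(parsed[i, numeric_cols])
    bad_parse <- numeric_cols[!is.na(rv) & nzchar(rv) & is.na(pv)]
    if (length(bad_parse)) {
      r <- c(r, paste0("unparseable numeric in ",
                       paste(bad_parse, collapse = ", ")))
    }
    if (!parsed$sex[i] %in% c("F", "M")) r <- c(r, "sex must be F or M")
    nonpos <- positive_cols[!is.na(parsed[i, positive_cols]) &
                              parsed[i, positive_cols] <= 0]
    if (length(nonpos)) {
      r <- c(r, paste0(paste(nonpos, collapse = ", "), " not positive"))
    }
    if ("sppb" %in% names(parsed) && !is.na(parsed$sppb[i]) &&
        (parsed$sppb[i] < 0 || parsed$sppb[i] > 12)) {
      r <- c(r, "sppb out of range")
    }
    reasons[i] <- paste(r, collapse = "; ")
  }
  bad <- nzchar(reasons)
  if (anyDuplicated(parsed$id[!bad])) {
    stop("duplicate participant ids in cohort file", call. = FALSE)
  }
  out <- parsed[!bad, , drop = FALSE]
  rownames(out) <- NULL
  dropped <- data.frame(line = which(bad) + 1L, reason = reasons[bad])
  if (nrow(dropped)) {
    message("read_cohort: dropped ", nrow(dropped), " invalid row(s)")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Write a cohort CSV
#'
#' Plain comma-separated output, one row per participant, with the column
#' names of the cohort table; the exact inverse of [read_cohort()].
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write generator ground truth as a JSON sidecar
#'
#' @param ground_truth The `ground_truth` element of [generate_cohort()].
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
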