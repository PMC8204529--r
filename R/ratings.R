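#' Read a long-format ratings table
#'
#' Reads a CSV with columns `subject_id`, `rater_id`, `item_code`,
#' `rating` and validates it against an item catalogue. Empty strings and
#' `NA` in the rating column are treated as missing (an item the rater
#' declined to score); any other value must be an integer between 0 and
#' the catalogue's maximum rating.
#'
#' @param path Path to a CSV file (UTF-8, header required).
#' @param catalog An [item_catalog()]; defaults to the SOPS.
#' @return A validated data frame of class `sops_ratings` with columns
#'   `subject_id`, `rater_id`, `item_code` (character) and `rating`
#'   (integer, `NA` = missing).
#' @export
read_ratings <- function(path, catalog = sops_catalog()) {
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  validate_ratings(df, catalog)
}

#' Validate an in-memory ratings table
#'
#' @param records A data frame with columns `subject_id`, `rater_id`,
#'   `item_code`, `rating`.
#' @inheritParams read_ratings
#' @return The validated records, as for [read_ratings()].
#' @export
validate_ratings <- function(records, catalog = sops_catalog()) {
  need <- c("subject_id", "rater_id", "item_code", "rating")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("ratings table lacks column(s): ", paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  records$subject_id <- as.character(records$subject_id)
  records$rater_id <- as.character(records$rater_id)
  records$item_code <- as.character(records$item_code)

  bad_code <- !(records$item_code %in% catalog$item_code)
  if (any(bad_code)) {
    stop("unknown item code(s): ",
         paste(unique(records$item_code[bad_code]), collapse = ", "))
  }

  raw <- records$rating
  if (is.character(raw)) raw[!is.na(raw) & trimws(raw) == ""] <- NA
  num <- suppressWarnings(as.numeric(raw))
  unparsed <- which(!is.na(raw) & is.na(num))
  if (length(unparsed)) {
    stop(sprintf("unparseable rating '%s' at row %d",
                 raw[unparsed[1]], unparsed[1]))
  }
  mr <- .catalog_max_rating(catalog)
  bad <- which(!is.na(num) & (num < 0 | num > mr | num != round(num)))
  if (length(bad)) {
    stop(sprintf(
      "rating %s at row %d outside the integer range [0, %d]",
      format(num[bad[1]]), bad[1], mr
    ))
  }
  records$rating <- as.integer(round(num))

  key <- paste(records$subject_id, records$rater_id, records$item_code,
               sep = "\r")
  dup <- anyDuplicated(key)
  if (dup) {
    stop(sprintf(
      "duplicate rating for (subject %s, rater %s, item %s)",
      records$subject_id[dup], records$rater_id[dup], records$item_code[dup]
    ))
  }
  rownames(records) <- NULL
  class(records) <- c("sops_ratings", "data.frame")
  records
}

#' Write a ratings table
#'
#' Writes records in the same long CSV format read by [read_ratings()];
#' missing ratings become empty cells, so a write/read round trip
#' reproduces the records exactly.
#'
#' @param records Validated ratings (see [validate_ratings()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
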