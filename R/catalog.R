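#' The SOPS item catalogue
#'
#' The Scale of Prodromal Symptoms (SOPS) comprises 19 items in four
#' subscales: positive (P1--P5), negative (N1--N6), disorganization
#' (D1--D4) and general (G1--G4). Each item is rated on an ordinal
#' severity scale from 0 (absent) to 6 (severe and psychotic / extreme).
#' The general items are asked last in the SIPS interview, which is why
#' item-level missingness concentrates there when interviews are cut
#' short; `interview_order` records that ordering.
#'
#' @return A data frame of class `item_catalog` with one row per item and
#'   columns `item_code`, `label`, `subscale`
#'   (positive/negative/disorganization/general) and `interview_order`,
#'   plus an attribute `max_rating` (6).
#' @seealso [item_catalog()] to describe a different instrument with the
#'   same structure.
#' @examples
#' cat19 <- sops_catalog()
#' table(cat19$subscale)
#' @export
sops_catalog <- function() {
  item_catalog(
    item_code = c(
      "P1", "P2", "P3", "P4", "P5",
      "N1", "N2", "N3", "N4", "N5", "N6",
      "D1", "D2", "D3", "D4",
      "G1", "G2", "G3", "G4"
    ),
    subscale = rep(
      c("positive", "negative", "disorganization", "general"),
      c(5L, 6L, 4L, 4L)
    ),
    label = c(
      "Unusual thought content/delusional ideas",
      "Suspiciousness/persecutory ideas",
      "Grandiosity",
      "Perceptual abnormalities/hallucinations",
      "Disorganized communication",
      "Social anhedonia",
      "Avolition",
      "Expression of emotion",
      "Experience of emotions and self",
      "Ideational richness",
      "Occupational functioning",
      "Odd behavior or appearance",
      "Bizarre thinking",
      "Trouble with focus and attention",
      "Personal hygiene",
      "Sleep disturbance",
      "Dysphoric mood",
      "Motor disturbances",
      "Impaired tolerance to normal stress"
    ),
    interview_order = 1:19,
    max_rating = 6L
  )
}

#' Describe an ordinal rating instrument
#'
#' Constructs and validates an item catalogue for any instrument with the
#' same shape as the SOPS: a fixed set of items, each belonging to one
#' subscale and rated on an integer scale from 0 to `max_rating`.
#'
#' @param item_code Character vector of unique item codes.
#' @param subscale Character vector (same length) of subscale names.
#' @param label Optional character vector of item descriptions.
#' @param interview_order Integer vector; a permutation of
#'   `seq_along(item_code)` giving the order in which items are elicited.
#' @param max_rating Largest permissible rating (default 6).
#' @return A data frame of class `item_catalog`.
#' @export
item_catalog <- function(item_code, subscale, label = item_code,
                         interview_order = seq_along(item_code),
                         max_rating = 6L) {
  item_code <- as.character(item_code)
  subscale <- as.character(subscale)
  label <- as.character(label)
  interview_order <- as.integer(interview_order)
  n <- length(item_code)
  if (n < 1L) stop("catalog must contain at least one item")
  if (anyDuplicated(item_code)) stop("duplicate item codes in catalog")
  if (length(subscale) != n || length(label) != n ||
      length(interview_order) != n) {
    stop("item_code, subscale, label and interview_order lengths differ")
  }
  if (!setequal(interview_order, seq_len(n))) {
    stop("interview_order must be a permutation of 1..", n)
  }
  max_rating <- as.integer(max_rating)
  if (is.na(max_rating) || max_rating < 1L) stop("max_rating must be >= 1")
  out <- data.frame(
    item_code = item_code, label = label, subscale = subscale,
    interview_order = interview_order, stringsAsFactors = FALSE
  )
  attr(out, "max_rating") <- max_rating
  class(out) <- c("item_catalog", "data.frame")
  out
}

#' @keywords internal
.catalog_max_rating <- function(catalog) {
  mr <- attr(catalog, "max_rating")
  if (is.null(mr)) 6L else as.integer(mr)
}

#' @keywords internal
.catalog_codes <- function(catalog, subscales = NULL) {
  if (is.null(subscales)) return(catalog$item_code)
  catalog$item_code[catalog$subscale %in% subscales]
}
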