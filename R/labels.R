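# Class-label schemes and valence handling.
#
# Two schemes are supported:
#   POS_NEG      codes 0 = negative, 1 = positive
#   POS_NEU_NEG  codes 0 = negative, 1 = neutral, 2 = positive
# Both map bijectively onto the ordinal valence axis {-1, 0, +1}
# (negative < neutral < positive); the ordinal form is what dataset label
# vectors use on disk and what the categorical median filter orders by.

.schemes <- list(
  POS_NEG     = list(codes = c(0L, 1L), ordinals = c(-1L, 1L),
                     names = c("negative", "positive")),
  POS_NEU_NEG = list(codes = c(0L, 1L, 2L), ordinals = c(-1L, 0L, 1L),
                     names = c("negative", "neutral", "positive"))
)

#' Class-label schemes
#'
#' `scheme_codes()` returns the valid integer codes of a scheme,
#' `scheme_size()` the number of classes `z`, and `scheme_class_names()`
#' human-readable names in code order.
#'
#' @param scheme `"POS_NEG"` (negative/positive) or `"POS_NEU_NEG"`
#'   (negative/neutral/positive).
#' @return integer vector of codes / scalar count / character vector.
#' @export
scheme_codes <- function(scheme) .scheme_info(scheme)$codes

#' @rdname scheme_codes
#' @export
scheme_size <- function(scheme) length(.scheme_info(scheme)$codes)

#' @rdname scheme_codes
#' @export
scheme_class_names <- function(scheme) .scheme_info(scheme)$names

.scheme_info <- function(scheme) {
  if (!is.character(scheme) || length(scheme) != 1L || !scheme %in% names(.schemes))
    stopf("unknown class scheme '%s'; expected one of: %s",
          paste(scheme, collapse = ","), paste(names(.schemes), collapse = ", "))
  .schemes[[scheme]]
}

#' Convert between class codes and ordinal valence
#'
#' The ordinal form places classes on the valence axis: -1 negative, 0 neutral,
#' +1 positive. The mapping is bijective within a scheme, so
#' `ordinal_to_label(label_to_ordinal(x))` is the identity.
#'
#' @param code integer class code(s) valid for `scheme`.
#' @param ordinal integer ordinal(s) in \{-1, 0, 1\} valid for `scheme`.
#' @param scheme class scheme name.
#' @return integer vector of ordinals / codes.
#' @export
label_to_ordinal <- function(code, scheme) {
  info <- .scheme_info(scheme)
  idx <- match(as.integer(code), info$codes)
  if (anyNA(idx))
    stopf("label error: code(s) %s not valid for scheme %s",
          paste(unique(code[is.na(idx)]), collapse = ", "), scheme)
  info$ordinals[idx]
}

#' @rdname label_to_ordinal
#' @export
ordinal_to_label <- function(ordinal, scheme) {
  info <- .scheme_info(scheme)
  idx <- match(as.integer(ordinal), info$ordinals)
  if (anyNA(idx))
    stopf("label error: ordinal(s) %s not valid for scheme %s",
          paste(unique(ordinal[is.na(idx)]), collapse = ", "), scheme)
  info$codes[idx]
}

#' Binarize a continuous valence rating
#'
#' Ratings on the 1-9 self-assessment scale are thresholded at the midpoint
#' 4.5: ratings above the threshold are positive, ratings below are negative.
#' The boundary rating itself maps to the class given by `boundary`
#' ("negative" by default: a rating not strictly above the threshold is not
#' positive).
#'
#' @param rating numeric rating(s) in `[1, 9]`.
#' @param threshold decision threshold (default 4.5, the scale midpoint).
#' @param boundary class assigned to ratings exactly at the threshold.
#' @return integer POS_NEG code(s): 0 negative, 1 positive.
#' @export
#' @examples
#' binarize_valence(7.2)  # 1 (positive)
#' binarize_valence(3.1)  # 0 (negative)
#' binarize_valence(4.5)  # 0 (boundary is negative by default)
binarize_valence <- function(rating, threshold = 4.5,
                             boundary = c("negative", "positive")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(rating) || anyNA(rating))
    stopf("range error: rating must be numeric without NA")
  if (any(rating < 1 | rating > 9))
    stopf("range error: rating(s) outside [1, 9]: %s",
          paste(utils::head(rating[rating < 1 | rating > 9], 3), collapse = ", "))
  pos <- if (boundary == "negative") rating > threshold else rating >= threshold
  as.integer(pos)
}
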