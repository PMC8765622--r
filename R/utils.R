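# Small shared helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the printed area tables.
#' `base::round()` rounds half to even, which cannot reproduce tabulated
#' percentages such as 44.73 from 44.725.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny nudge guards against values like 44.725 stored as 44.72499999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Canonical predictor ordering: bio1..bio19 by number, anything else after,
# alphabetically. Used for deterministic tie-breaking in the collinearity
# filter and for stack layer ordering.
canonical_order <- function(names) {
  num <- suppressWarnings(as.integer(sub("^bio", "", names)))
  is_bio <- grepl("^bio[0-9]+$", names) & !is.na(num)
  key <- ifelse(is_bio, sprintf("A%05d", num), paste0("B", names))
  names[order(key)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
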