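#' Convert lengths between pre- and post-expansion units
#'
#' Expansion microscopy physically swells the specimen by an isotropic factor
#' `E` (about 4.2x for the protocol emulated here), so every length can be
#' stated either in pre-expansion (biological) or post-expansion (imaged)
#' micrometres. This helper keeps the bookkeeping explicit: a 60 um dendrite
#' segment images at 252 um, a 15 um dendron segment at 63 um.
#'
#' @param length_um Numeric vector of lengths in micrometres. Must be >= 0.
#' @param expansion_factor Isotropic linear expansion factor `E` (> 1).
#' @param direction `"pre_to_post"` multiplies by `E`; `"post_to_pre"` divides.
#' @return Numeric vector of converted lengths (micrometres).
#' @examples
#' convert_expansion(60, 4.2, "pre_to_post")  # 252
#' convert_expansion(63, 4.2, "post_to_pre")  # 15
#' @export
convert_expansion <- function(length_um, expansion_factor,
                              direction = c("pre_to_post", "post_to_pre")) {
  direction <- match.arg(direction)
  if (!is.numeric(length_um) || any(length_um < 0)) {
    stop("`length_um` must be non-negative")
  }
  if (!is.numeric(expansion_factor) || length(expansion_factor) != 1L ||
      expansion_factor <= 1) {
    stop("`expansion_factor` must be a single value > 1")
  }
  if (direction == "pre_to_post") length_um * expansion_factor
  else length_um / expansion_factor
}
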