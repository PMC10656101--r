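#' Signed color coherence from a blue-dot probability
#'
#' The color coherence is defined as \eqn{C^\pm = 2(p_{blue} - 0.5)}:
#' positive values denote blue-dominant stimuli, and the unsigned value
#' \eqn{C = |C^\pm|} is the color strength that sets the difficulty of a
#' color judgment.
#'
#' @param p_blue probability that a dot is colored blue, in \[0, 1\].
#' @return signed coherence in \[-1, 1\].
#' @examples
#' color_coherence(0.82)  # 0.64
#' @export
color_coherence <- function(p_blue) {
  if (!is.numeric(p_blue) || any(!is.finite(p_blue)) ||
      any(p_blue < 0) || any(p_blue > 1))
    stop("'p_blue' must be a probability in [0, 1]", call. = FALSE)
  2 * (p_blue - 0.5)
}

#' Experimental color-strength levels
#'
#' The six unsigned color strengths used by the two-patch designs.
#'
#' @return numeric vector of the six strengths.
#' @export
coherence_levels <- function() c(0, 0.128, 0.256, 0.384, 0.512, 0.64)

#' The 12-level signed coherence set
#'
#' The experimental set of signed coherences: each strength with both signs.
#' Zero appears twice because the designs carry an explicit plus/minus tag
#' on the 0 level (the tag decides which response is rewarded); the two
#' zeros are distinguished by the accompanying sign tag, not by value.
#'
#' @return data.frame with columns `value` (signed coherence) and
#'   `sign` (+1 or -1, the dominance tag).
#' @export
signed_coherence_set <- function() {
  lv <- coherence_levels()
  data.frame(value = c(-rev(lv), lv), sign = rep(c(-1, 1), each = length(lv)))
}
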