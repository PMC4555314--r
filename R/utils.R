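#' @importFrom rlang %||% .data
#' @importFrom stats setNames
NULL

# Round a mean qualifier to an integer: nearest integer, with exact halves
# rounded up, i.e. toward the worse (higher-severity) end of the scale.
# Clinically conservative; base round() would go to even instead.
round_toward_worse <- function(x) {
  as.integer(floor(x + 0.5))
}

# statistical mode; first-encountered value wins ties (deterministic given
# input order)
mode_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA)
  tab <- table(x)
  nm <- names(tab)[which.max(tab)]
  if (is.numeric(x)) as.numeric(nm) else nm
}
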