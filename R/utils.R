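# Internal helpers shared across modules.

#' The 25 COG/KOG one-letter functional categories
#'
#' The default category alphabet: the 25 functional classes of clusters of
#' orthologous groups (information storage and processing, cellular processes
#' and signaling, metabolism, and the two poorly characterized classes R/S).
#' The letter X is not part of the classical alphabet.
#'
#' @return Character vector of 25 single letters.
#' @export
#' @examples
#' cog_categories()
cog_categories <- function() {
  c("J", "A", "K", "L", "B",                     # information storage/processing
    "D", "Y", "V", "T", "M", "N", "Z", "W", "U", "O",  # cellular processes/signaling
    "C", "G", "E", "F", "H", "I", "P", "Q",      # metabolism
    "R", "S")                                    # poorly characterized
}

# Round half away from zero to `digits` decimals (commercial rounding, the
# rule that reproduces one-decimal percentage tables; base round() ties to
# even).
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stopifnot-style check with sprintf message
.check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

.msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

# Canonical unordered-pair key from two character ids.
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
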