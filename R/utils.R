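#' @importFrom stats quantile median pt ecdf setNames p.adjust cor dnorm
#' @importFrom utils head tail
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flip a strand symbol
#'
#' "+" becomes "-" and vice versa; "*" (unstranded) is left unchanged.
#'
#' @param s character vector of strand symbols ("+", "-", "*").
#' @return character vector of flipped symbols.
#' @export
flip_strand <- function(s) {
  out <- s
  out[s == "+"] <- "-"
  out[s == "-"] <- "+"
  out
}

# normalize "." (GTF unstranded) to "*" (GRanges unstranded)
norm_strand <- function(s) {
  s[s == "."] <- "*"
  s
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1
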