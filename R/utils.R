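#' @importFrom stats cor.test lm median p.adjust rbeta rlnorm rnorm
#'   rpois runif sd setNames coef residuals
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# fast char -> base index lookup (A=1 C=2 G=3 T=4, NA otherwise)
.base_lookup <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

.seq_index <- function(sequence) {
  .base_lookup[utf8ToInt(toupper(sequence))]
}

.comp_char <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string (A/C/G/T/N, case preserved as upper case).
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(.comp_char(toupper(x)), "")[[1L]]), collapse = "")
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# does `x` look like a path rather than an in-memory object?
.is_path <- function(x) .is_string(x) && file.exists(x)
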