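# Small internal helpers shared across modules.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                    a = "t", c = "g", g = "c", t = "a", n = "n")

#' Reverse complement of a DNA string
#'
#' Case-preserving reverse complement over the alphabet ACGTN.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1L]])
    out <- DNA_COMPLEMENT[ch]
    bad <- is.na(out)
    if (any(bad)) out[bad] <- ch[bad]
    paste(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# integer-safe modulo-based gcd/lcm for reading-frame period arithmetic
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a %/% gcd2(a, b) * b

# stop() with a line number prefix, used by all file readers
stop_line <- function(line, ...) {
  stop("line ", line, ": ", ..., call. = FALSE)
}

is_blank <- function(x) !nzchar(trimws(x))

# split one whitespace-delimited line into fields
split_ws <- function(x) strsplit(trimws(x), "[ \t]+")[[1L]]
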