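#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Complement DNA bases
#'
#' Vectorised complement over the internal alphabet {A,C,G,T,N,-}.
#' U is accepted and treated as T. Gaps and N map to themselves.
#'
#' @param x character vector of single bases or of sequences
#' @return character vector of the same shape, complemented
#' @examples
#' complement_base(c("A", "G", "-"))
#' @export
complement_base <- function(x) {
  chartr("ACGTUacgtu", "TGCAAtgcaa", x)
}

#' Reverse-complement a sequence string
#'
#' @param x character vector of sequence strings
#' @return reverse-complemented strings
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split sequence strings into a character matrix (rows = sequences)
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(0), nrow = 0, ncol = 0))
  n <- unique(nchar(seqs))
  stopifnot(length(n) == 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = length(seqs),
         ncol = n, byrow = TRUE)
}

# normalise a raw sequence string: uppercase, U->T, map residual
# characters outside {A,C,G,T,N,-} to N (with a warning upstream)
normalize_seq <- function(s) {
  s <- toupper(s)
  s <- chartr("U", "T", s)
  s
}

# positions (1-based) of characters outside the internal alphabet
nonstandard_chars <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  which(!chars %in% c(DNA_BASES, "N", "-"))
}

ungapped_length <- function(s) {
  nchar(gsub("-", "", s, fixed = TRUE))
}

count_char <- function(s, ch) {
  lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
}
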