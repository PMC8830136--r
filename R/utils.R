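#' @importFrom stats rbinom rpois runif median setNames
#' @importFrom data.table data.table rbindlist :=
NULL

.datatable.aware <- TRUE

DNA <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Vectorised over its input; ambiguity code N maps to N, the alignment gap
#' character `-` is preserved.
#'
#' @param x character vector of DNA strings over {A,C,G,T,N,-}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

## complement of a character vector of single bases
comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

## all kmers of a string (forward strand), dropping those with non-ACGT chars
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1), k:n)
  km[!grepl("[^ACGT]", km)]
}

## canonical kmer: lexicographic min of kmer and reverse complement
canonical_kmers <- function(km) {
  pmin(km, revcomp(km))
}

## split a string into single characters
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## interval helpers: 0-based half-open c(start, end); on a circle of size n an
## interval may have end > n, meaning it wraps past the origin
iv_len <- function(iv) iv[2] - iv[1]

## extract a circular substring, 0-based half-open coordinates
circ_substr <- function(seq, start, end, n = nchar(seq)) {
  stopifnot(end >= start, end - start <= n)
  if (end <= n) {
    substr(seq, start + 1, end)
  } else {
    paste0(substr(seq, start + 1, n), substr(seq, 1, end - n))
  }
}

## does circular interval [s1,e1) contain position p (both mod n)?
circ_contains <- function(iv, p, n) {
  rel <- (p - iv[1]) %% n
  rel < (iv[2] - iv[1])
}

## do two circular intervals overlap?
circ_overlap <- function(a, b, n) {
  if (iv_len(a) == 0 || iv_len(b) == 0) return(FALSE)
  circ_contains(a, b[1] %% n, n) || circ_contains(b, a[1] %% n, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
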