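# Internal sequence helpers. Sequences are plain upper-case character
# scalars/vectors; Biostrings objects are converted at the boundaries.

BASES <- c("A", "C", "G", "T")
DIMERS <- as.vector(outer(BASES, BASES, paste0)) # AA, CA, GA, TA, AC, ...
DIMERS <- sort(DIMERS)                           # alphabetical: AA, AC, ..., TT

# PWM-20 geometry: two decamers RRRCWWGYYY abutted (spacer removed).
# Mononucleotide columns, and the dinucleotide CWWG-core columns 5-6 / 15-16.
MONO_POS <- c(1:4, 7:14, 17:20)
DIMER_POS <- list(c(5L, 6L), c(15L, 16L))

.revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# A -> 1, C -> 2, G -> 3, T -> 4, anything else -> NA
.base_codes <- function(s) {
  m <- match(strsplit(s, "")[[1]], BASES)
  m
}

.codes_matrix <- function(x, width) {
  m <- matrix(NA_integer_, nrow = length(x), ncol = width)
  for (i in seq_along(x)) m[i, ] <- .base_codes(x[i])
  m
}

.dimer_index <- function(c1, c2) {
  # index into alphabetically sorted DIMERS: AA AC AG AT CA ... TT
  (c1 - 1L) * 4L + c2
}

.is_acgt <- function(x) !grepl("[^ACGT]", x)

.as_plain_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    out <- as.character(x)
  } else if (inherits(x, "DNAString")) {
    out <- as.character(x)
    names(out) <- "seq"
  } else if (is.character(x)) {
    out <- x
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  } else {
    stop("sequences must be a character vector, DNAString or DNAStringSet")
  }
  out
}
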