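# Global alignment and RE-vs-consensus substitution statistics.
#
# The aligner is a deterministic affine-gap Needleman-Wunsch (Gotoh). A gap
# of length k costs gap_open + k * gap_extend (the Biostrings convention).
# Traceback ties are resolved in a fixed order - diagonal, then gap in `a`,
# then gap in `b` - so the same input always yields the same alignment.

#' Global pairwise alignment of two DNA sequences
#'
#' @param a,b Non-empty DNA strings over ACGT(N); N matches nothing
#'   (scored as a mismatch against every base).
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Gap opening penalty, positive (default 5).
#' @param gap_extend Per-base gap extension penalty, positive (default 1).
#' @return Object of class `alu_alignment`: list with `a`, `b` (aligned
#'   strings with `-` gaps) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 1) {
  a <- toupper(.as_plain_seqs(a)[1])
  b <- toupper(.as_plain_seqs(b)[1])
  if (!nchar(a) || !nchar(b)) stop("global_align requires non-empty sequences")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  go <- gap_open; ge <- gap_extend
  # M: a[i] aligned to b[j]; X: gap in b (a[i] vs -); Y: gap in a (- vs b[j])
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -go - (i - 1) * ge
  for (j in 2:(m + 1)) Y[1, j] <- -go - (j - 1) * ge
  sub <- function(x, y) if (x == y && x != "N" && y != "N") match else mismatch
  for (i in 2:(n + 1)) {
    si <- av[i - 1]
    for (j in 2:(m + 1)) {
      s <- sub(si, bv[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  # traceback; tie preference: M (diagonal) > X (gap in b) > Y (gap in a)
  # per the documented convention "match/mismatch > gap-in-a > gap-in-b",
  # where gap-in-a means a gap character inserted in `a` (state Y).
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Y[i, j], X[i, j]))
  state <- c("M", "Y", "X")[state]
  ra <- character(0); rb <- character(0)
  score <- max(M[i, j], X[i, j], Y[i, j])
  while (i > 1 || j > 1) {
    if (state == "M") {
      s <- sub(av[i - 1], bv[j - 1])
      ra <- c(av[i - 1], ra); rb <- c(bv[j - 1], rb)
      prev <- c(M[i - 1, j - 1], Y[i - 1, j - 1], X[i - 1, j - 1])
      target <- M[i, j] - s
      state <- c("M", "Y", "X")[which(abs(prev - target) < 1e-9)[1]]
      i <- i - 1; j <- j - 1
    } else if (state == "Y") { # gap in a, consume b[j-1]
      ra <- c("-", ra); rb <- c(bv[j - 1], rb)
      if (abs(M[i, j - 1] - go - ge - Y[i, j]) < 1e-9) state <- "M"
      j <- j - 1
    } else { # X: gap in b, consume a[i-1]
      ra <- c(av[i - 1], ra); rb <- c("-", rb)
      if (abs(M[i - 1, j] - go - ge - X[i, j]) < 1e-9) state <- "M"
      i <- i - 1
    }
  }
  structure(list(a = paste(ra, collapse = ""),
                 b = paste(rb, collapse = ""),
                 score = score),
            class = "alu_alignment")
}

#' @export
print.alu_alignment <- function(x, width = 60, ...) {
  av <- strsplit(x$a, "")[[1]]
  bv <- strsplit(x$b, "")[[1]]
  marks <- ifelse(av == bv & av != "-", "|", " ")
  n <- length(av)
  cat(sprintf("global alignment, score %g, %d columns\n", x$score, n))
  for (o in seq(1, n, by = width)) {
    idx <- o:min(o + width - 1, n)
    cat("a: ", paste(av[idx], collapse = ""), "\n", sep = "")
    cat("   ", paste(marks[idx], collapse = ""), "\n", sep = "")
    cat("b: ", paste(bv[idx], collapse = ""), "\n\n", sep = "")
  }
  invisible(x)
}

.aln_cols <- function(aln) {
  list(a = strsplit(aln$a, "")[[1]], b = strsplit(aln$b, "")[[1]])
}

# columns of the alignment covering positions [from, to] of sequence `a`
.a_span_columns <- function(aln, from, to) {
  av <- .aln_cols(aln)$a
  apos <- cumsum(av != "-")
  which(av != "-" & apos >= from & apos <= to)
}

#' Percent divergence of an alignment
#'
#' 100 x (mismatched non-gap columns) / (non-gap columns). Gap columns are
#' excluded from both numerator and denominator; gap events are reported
#' separately.
#'
#' @param aln An `alu_alignment`.
#' @return list with `divergence_pct`, `n_substitutions`, `n_columns`
#'   (ungapped), `n_gap_events`.
#' @export
divergence_percent <- function(aln) {
  cols <- .aln_cols(aln)
  ungapped <- cols$a != "-" & cols$b != "-"
  nsub <- sum(ungapped & cols$a != cols$b)
  ncol <- sum(ungapped)
  gaps <- cols$a == "-" | cols$b == "-"
  n_gap_events <- sum(diff(c(FALSE, gaps)) == 1)
  list(divergence_pct = if (ncol) 100 * nsub / ncol else 0,
       n_substitutions = nsub, n_columns = ncol, n_gap_events = n_gap_events)
}

#' Substitution rate within the binding-site span
#'
#' Substitutions per base pair over the columns covering the 20+S site in
#' sequence `a` of the alignment.
#'
#' @param aln An `alu_alignment` (sequence `a` is the RE side).
#' @param site_start 1-based start of the site within the unaligned `a`.
#' @param site_len Site length, 20 + spacer.
#' @return Substitutions / site_len.
#' @export
site_substitution_rate <- function(aln, site_start, site_len) {
  cols <- .aln_cols(aln)
  idx <- .a_span_columns(aln, site_start, site_start + site_len - 1)
  if (!length(idx)) stop("site span lies outside the alignment")
  if (max(cumsum(cols$a != "-")) < site_start + site_len - 1)
    stop("site span lies outside the alignment")
  nsub <- sum(cols$a[idx] != cols$b[idx] & cols$b[idx] != "-")
  nsub / site_len
}

#' Count CpG dinucleotides in a sequence
#'
#' Overlapping occurrences of "CG".
#'
#' @param x DNA string (>= 2 bp).
#' @return Integer count.
#' @export
count_cg_dimers <- function(x) {
  x <- toupper(.as_plain_seqs(x)[1])
  if (nchar(x) < 2L) stop("need at least 2 bp")
  v <- strsplit(x, "")[[1]]
  sum(v[-length(v)] == "C" & v[-1] == "G")
}

#' Count CG to TG (CA) deamination transitions against a consensus
#'
#' Finds CG dinucleotides in the consensus side (`b`) of an alignment whose
#' aligned RE dinucleotide is TG (deamination of the methylated C on the
#' given strand) or CA (deamination on the complementary strand, seen as
#' CG to CA). `scope = "core"` restricts counting to the CNNG core columns
#' of the site (site positions 4-7 of each half-site, located from the RE's
#' own half-site registration); `scope = "full"` uses the whole 20+S site.
#'
#' @param aln An `alu_alignment`; `a` = RE, `b` = consensus.
#' @param scope `"core"` or `"full"`.
#' @param site_start 1-based start of the site within the unaligned RE.
#' @param spacer Spacer length S of the site.
#' @return Integer count of deamination-compatible CG substitutions.
#' @export
count_cg_to_tg <- function(aln, scope = c("full", "core"), site_start = 1L,
                           spacer = 0L) {
  scope <- match.arg(scope)
  cols <- .aln_cols(aln)
  if (scope == "full") {
    region <- .a_span_columns(aln, site_start, site_start + 19L + spacer)
  } else {
    # CNNG cores: site positions 4..7 and 14+S..17+S (1-based within site)
    region <- c(.a_span_columns(aln, site_start + 3L, site_start + 6L),
                .a_span_columns(aln, site_start + 13L + spacer, site_start + 16L + spacer))
  }
  region <- sort(region)
  count <- 0L
  n <- length(cols$b)
  for (j in seq_len(n - 1L)) {
    if (cols$b[j] == "C" && cols$b[j + 1L] == "G" &&
        cols$a[j] != "-" && cols$a[j + 1L] != "-") {
      if (!(j %in% region) || !((j + 1L) %in% region)) next
      d <- paste0(cols$a[j], cols$a[j + 1L])
      if (d == "TG" || d == "CA") count <- count + 1L
    }
  }
  count
}

#' Per-RE consensus comparison report
#'
#' Aligns a response element (plus flanks) to a repeat consensus and
#' collects divergence, site substitution rate, CpG statistics and the
#' hotspot-derived evolutionary group in one record.
#'
#' @param re_seq RE sequence with flanks.
#' @param consensus Subfamily consensus sequence.
#' @param site_start 1-based start of the 20+S site within `re_seq`.
#' @param spacer Spacer length S.
#' @param hotspot Hotspot label ("A", "A'" or "B") for group assignment;
#'   `NA` to skip.
#' @param ... Passed to [global_align()].
#' @return One-row data.frame: `divergence_pct`, `site_substitution_rate`,
#'   `cg_dimers_consensus`, `cg_to_tg_core`, `cg_to_tg_full`, `group`.
#' @export
re_consensus_report <- function(re_seq, consensus, site_start, spacer = 0L,
                                hotspot = NA_character_, ...) {
  aln <- global_align(re_seq, consensus, ...)
  div <- divergence_percent(aln)
  site_len <- 20L + spacer
  rate <- site_substitution_rate(aln, site_start, site_len)
  # consensus bases aligned under the site span
  cols <- .aln_cols(aln)
  idx <- .a_span_columns(aln, site_start, site_start + site_len - 1L)
  cons_region <- paste(cols$b[idx][cols$b[idx] != "-"], collapse = "")
  data.frame(
    divergence_pct = div$divergence_pct,
    site_substitution_rate = rate,
    cg_dimers_consensus = if (nchar(cons_region) >= 2) count_cg_dimers(cons_region) else 0L,
    cg_to_tg_core = count_cg_to_tg(aln, "core", site_start, spacer),
    cg_to_tg_full = count_cg_to_tg(aln, "full", site_start, spacer),
    group = if (is.na(hotspot)) NA_character_ else assign_group(hotspot),
    stringsAsFactors = FALSE)
}

#' Read a pre-computed pairwise alignment from aligned FASTA
#'
#' Accepts a two-record aligned FASTA (gap character `-`); the first record
#' is taken as the RE side (`a`), the second as the consensus (`b`). Use
#' this to bypass the package aligner with alignments produced elsewhere.
#'
#' @param path Path to an aligned FASTA file with exactly two records of
#'   equal length.
#' @return An `alu_alignment` (with `score = NA`).
#' @export
read_alignment_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L) stop("aligned FASTA must contain exactly two records")
  a <- toupper(as.character(recs[[1]]))
  b <- toupper(as.character(recs[[2]]))
  if (nchar(a) != nchar(b)) stop("aligned records differ in length")
  structure(list(a = a, b = b, score = NA_real_), class = "alu_alignment")
}
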