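# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's internal code paths.

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Naive O(L * S_max) scanner: enumerate every (start, S) window and score it
# through the public percent_score API one window at a time.
naive_scan <- function(pwm, seq, s_max, cutoff) {
  L <- nchar(seq)
  seq <- toupper(seq)
  out <- list()
  for (start in seq_len(L)) {
    for (S in 0:s_max) {
      if (start + 19 + S > L) next
      h1 <- substr(seq, start, start + 9)
      h2 <- substr(seq, start + 10 + S, start + 19 + S)
      w <- paste0(h1, h2)
      if (grepl("[^ACGT]", w)) next
      pct <- percent_score(pwm, w)
      if (!is.na(pct) && pct >= cutoff) {
        out[[length(out) + 1]] <- data.frame(start = start - 1L, spacer = S,
                                             percent = pct, half1 = h1, half2 = h2)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), spacer = integer(), percent = numeric(),
                      half1 = character(), half2 = character()))
  out <- do.call(rbind, out)
  out[order(out$start, out$spacer), , drop = FALSE]
}

# Exhaustive global-alignment score by recursive enumeration; gap of length
# k costs open + k * ext. Only feasible for short sequences.
brute_align_score <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  # state: (i, j, prev) with prev in {"M","X","Y"}; memoized
  memo <- new.env()
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) { # gap in b
      pen <- if (prev == "X") ext else open + ext
      best <- max(best, -pen + rec(i + 1, j, "X"))
    }
    if (j <= length(bv)) { # gap in a
      pen <- if (prev == "Y") ext else open + ext
      best <- max(best, -pen + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# Two-site toy training set used throughout (both sites palindromic).
toy_training <- function() c("AAACATGTTTAAACATGTTT", "GGGCATGCCCGGGCATGCCC")

# Implant the two half-sites of `site20` into a background at `start`
# (1-based) with spacer S; returns the modified sequence.
implant <- function(bg, site20, start, S) {
  v <- strsplit(bg, "")[[1]]
  v[start:(start + 9)] <- strsplit(substr(site20, 1, 10), "")[[1]]
  v[(start + 10 + S):(start + 19 + S)] <- strsplit(substr(site20, 11, 20), "")[[1]]
  paste(v, collapse = "")
}
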