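#' Scan sequences for candidate p53 binding sites
#'
#' Enumerates every window consisting of a 10-mer half-site, a spacer of S
#' bases (0 <= S <= `s_max`) and a second 10-mer half-site, scores the
#' concatenated 20-mer with the PWM-20 model and reports all windows at or
#' above the percent cutoff. Because the matrix is symmetric the score of a
#' window equals the score of its reverse complement, so only the forward
#' strand is scanned and each physical site is reported once. Windows that
#' touch an ambiguous base (N; or a lower-case base when `soft_mask = TRUE`)
#' are skipped. Overlapping hits and multiple spacers at the same start are
#' all reported.
#'
#' @param pwm A [p53_pwm()] model.
#' @param seqs Named character vector, `DNAString` or `DNAStringSet` (or path
#'   to a FASTA file).
#' @param s_max Maximum spacer length in bp (default 14).
#' @param cutoff Percent-score cutoff; defaults to the cutoff stored in the
#'   model (70 unless changed).
#' @param soft_mask If `TRUE`, lower-case (soft-masked) bases mask the
#'   windows that contain them; otherwise case is ignored.
#' @return data.frame of predicted sites with columns `chrom`, `start`
#'   (0-based), `end` (exclusive; `end - start == 20 + spacer`), `spacer`,
#'   `percent`, `half1`, `half2`, `strand` (always "+"), sorted by
#'   (chrom, start, spacer).
#' @export
scan_p53 <- function(pwm, seqs, s_max = 14L, cutoff = NULL, soft_mask = FALSE) {
  stopifnot(inherits(pwm, "p53_pwm"))
  if (s_max < 0) stop("s_max must be >= 0")
  if (is.character(seqs) && length(seqs) == 1L &&
      !grepl("^[ACGTNacgtn]+$", seqs) && file.exists(seqs)) {
    seqs <- Biostrings::readDNAStringSet(seqs)
  }
  if (length(seqs) == 0L) stop("empty FASTA input")
  seqs <- .as_plain_seqs(seqs)
  if (is.null(cutoff)) cutoff <- pwm$cutoff
  if (cutoff < 0 || cutoff > 100) stop("cutoff must be in [0, 100]")
  if (pwm$raw_max <= pwm$raw_min) stop("degenerate matrix: raw_min == raw_max")

  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    res[[i]] <- .scan_one(pwm, names(seqs)[i], seqs[i], as.integer(s_max),
                          cutoff, soft_mask)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.scan_one <- function(pwm, chrom, seq, s_max, cutoff, soft_mask) {
  raw <- seq
  if (soft_mask) raw <- gsub("[acgtn]", "N", raw)
  codes <- match(strsplit(toupper(raw), "")[[1]], BASES) # NA for N/masked
  L <- length(codes)
  span <- pwm$raw_max - pwm$raw_min
  hits <- list()
  # per-position offsets of the 20 columns for a spacer S:
  # columns 1..10 at offsets 0..9, columns 11..20 at offsets (10+S)..(19+S)
  for (S in 0:s_max) {
    n <- L - 20L - S + 1L
    if (n < 1L) next
    starts <- seq_len(n) # 1-based starts
    raw_sc <- numeric(n)
    # same symmetric pairwise accumulation as raw_score()
    for (p in c(1:4, 7:10)) {
      q <- 21L - p
      raw_sc <- raw_sc +
        (pwm$mono[cbind(codes[starts + (p - 1L)], p)] +
           pwm$mono[cbind(codes[starts + (q - 1L + S)], q)])
    }
    raw_sc <- raw_sc +
      (pwm$dimer[cbind(.dimer_index(codes[starts + 4L], codes[starts + 5L]), 1)] +
         pwm$dimer[cbind(.dimer_index(codes[starts + 14L + S],
                                      codes[starts + 15L + S]), 2)])
    pct <- 100 * (raw_sc - pwm$raw_min) / span
    keep <- which(!is.na(pct) & pct >= cutoff)
    if (length(keep)) {
      st <- keep # 1-based
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom,
        start = st - 1L,
        end = st - 1L + 20L + S,
        spacer = S,
        percent = pct[keep],
        half1 = substring(toupper(raw), st, st + 9L),
        half2 = substring(toupper(raw), st + 10L + S, st + 19L + S),
        strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      spacer = integer(), percent = numeric(),
                      half1 = character(), half2 = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$spacer), , drop = FALSE]
}

#' Spacer-length histogram of predicted sites
#'
#' @param sites data.frame from [scan_p53()] (needs a `spacer` column).
#' @param s_max Largest spacer bin; defaults to the scan maximum observed.
#' @return Named integer vector of counts for S = 0..`s_max`; the counts sum
#'   to `nrow(sites)`.
#' @export
spacer_histogram <- function(sites, s_max = NULL) {
  if (is.null(s_max)) s_max <- if (nrow(sites)) max(sites$spacer) else 0L
  counts <- integer(s_max + 1L)
  names(counts) <- 0:s_max
  if (nrow(sites)) {
    tab <- table(factor(sites$spacer, levels = 0:s_max))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Peak z-statistic of a spacer histogram
#'
#' Measures how far the mean occurrence at a set of "peak" spacer lengths
#' stands above the mean of the background spacer lengths, in units of the
#' background's population RMSD:
#' z = (mean(peaks) - mean(background)) / RMSD(background).
#'
#' Either supply a histogram plus the two spacer sets, or the pre-computed
#' triple (`peak_mean`, `bg_mean`, `bg_rmsd`).
#'
#' @param hist Named count vector from [spacer_histogram()] (names = spacer
#'   lengths). Ignored when the pre-computed triple is given.
#' @param peak_spacers,background_spacers Disjoint integer sets of spacer
#'   lengths; the background needs at least 2 elements.
#' @param peak_mean,bg_mean,bg_rmsd Optional pre-computed summary statistics.
#' @return The z value (scalar).
#' @export
peak_z <- function(hist = NULL, peak_spacers = NULL, background_spacers = NULL,
                   peak_mean = NULL, bg_mean = NULL, bg_rmsd = NULL) {
  if (is.null(peak_mean)) {
    stopifnot(!is.null(hist), !is.null(peak_spacers), !is.null(background_spacers))
    if (length(background_spacers) < 2L)
      stop("background needs at least 2 spacer lengths")
    if (length(intersect(peak_spacers, background_spacers)))
      stop("peak and background spacer sets must be disjoint")
    pk <- hist[as.character(peak_spacers)]
    bg <- hist[as.character(background_spacers)]
    if (anyNA(pk) || anyNA(bg)) stop("spacer length missing from histogram")
    peak_mean <- mean(pk)
    bg_mean <- mean(bg)
    bg_rmsd <- sqrt(mean((bg - bg_mean)^2)) # population SD
  }
  if (bg_rmsd <= 0) stop("background RMSD is zero; z undefined")
  (peak_mean - bg_mean) / bg_rmsd
}

#' Write predicted sites as BED6+2
#'
#' BED name is `S<spacer>`, score is percent x 10 rounded; the two extra
#' columns carry the half-site sequences.
#'
#' @param sites data.frame from [scan_p53()].
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(sites$chrom, sites$start, sites$end,
                   paste0("S", sites$spacer),
                   round(sites$percent * 10), sites$strand,
                   sites$half1, sites$half2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
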