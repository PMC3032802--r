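#' Build the PWM-20 p53 binding-site model
#'
#' Fits the symmetric 20-position weight model for p53 binding sites from a
#' set of experimentally validated response elements. A p53 site is two
#' RRRCWWGYYY decamers; the variable spacer between them is removed before
#' counting, so the model always sees a 20-mer. Positions 5-6 and 15-16 (the
#' central WW of each CWWG core) are modelled as dinucleotides, the other 16
#' positions as mononucleotides. Every training 20-mer is counted together
#' with its reverse complement, which makes the matrix exactly symmetric: any
#' sequence and its reverse complement score identically, as required by the
#' 2-fold symmetry of the DNA-bound p53 tetramer.
#'
#' Weights are log2 odds of pseudocounted frequencies against a uniform
#' background (1/4 per base, 1/16 per dinucleotide). The percent score is an
#' affine rescaling of the raw score, so any monotone weight transform leaves
#' the percent scale unchanged; log-odds is used because it is the field's
#' convention.
#'
#' @param sites Training sites: a data.frame with columns `half1`, `half2`
#'   (10-mers over ACGT) and optionally `spacer`, or a character vector of
#'   20-mers.
#' @param pseudocount Pseudocount added to each count cell (default 0.5).
#' @param cutoff Percent-score cutoff stored with the model (default 70).
#' @param source_label Free-text provenance label.
#' @return An object of class `p53_pwm` with components `mono` (4 x 20 weight
#'   matrix, `NA` at dinucleotide columns), `dimer` (16 x 2 matrix for columns
#'   5-6 and 15-16), `raw_min`, `raw_max`, `pseudocount`, `cutoff`,
#'   `n_sites`, `training`.
#' @examples
#' pwm <- p53_pwm(c("GGGCATGTACGTACATGCCC"))
#' percent_score(pwm, "GGGCATGTACGTACATGCCC") # 100
#' @export
p53_pwm <- function(sites, pseudocount = 0.5, cutoff = 70, source_label = "") {
  sites <- as_training_sites(sites)
  if (nrow(sites) == 0L) stop("training set is empty")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (cutoff < 0 || cutoff > 100) stop("cutoff must be in [0, 100]")

  twenty <- paste0(sites$half1, sites$half2)
  all20 <- c(twenty, .revcomp(twenty)) # enforced symmetrization
  n_tot <- length(all20)
  codes <- .codes_matrix(all20, 20L)

  mono_counts <- matrix(0, nrow = 4, ncol = 20, dimnames = list(BASES, NULL))
  for (p in MONO_POS) {
    tab <- tabulate(codes[, p], nbins = 4L)
    mono_counts[, p] <- tab
  }
  # Pseudocount is a background admixture: each accumulated sequence
  # contributes `pseudocount` uniform pseudo-observations spread over the
  # alphabet. This keeps the matrix invariant under duplicating the training
  # multiset (so symmetrization is exactly idempotent) and drives weights
  # monotonically to 0 as the pseudocount grows.
  pc_cell <- pseudocount * n_tot / 4
  mono <- log2(((mono_counts + pc_cell) / (n_tot * (1 + pseudocount))) / 0.25)
  mono[, c(5, 6, 15, 16)] <- NA_real_

  dimer <- matrix(NA_real_, nrow = 16, ncol = 2,
                  dimnames = list(DIMERS, c("5_6", "15_16")))
  for (k in seq_along(DIMER_POS)) {
    pp <- DIMER_POS[[k]]
    idx <- .dimer_index(codes[, pp[1]], codes[, pp[2]])
    tab <- tabulate(idx, nbins = 16L)
    dimer[, k] <- log2(((tab + pseudocount * n_tot / 16) /
                          (n_tot * (1 + pseudocount))) * 16)
  }

  raw_min <- sum(apply(mono[, MONO_POS], 2, min)) + sum(apply(dimer, 2, min))
  raw_max <- sum(apply(mono[, MONO_POS], 2, max)) + sum(apply(dimer, 2, max))

  structure(list(mono = mono, dimer = dimer,
                 raw_min = raw_min, raw_max = raw_max,
                 pseudocount = pseudocount, cutoff = cutoff,
                 n_sites = nrow(sites), source_label = source_label,
                 training = sites),
            class = "p53_pwm")
}

#' Coerce training input to a validated site table
#'
#' @param sites As in [p53_pwm()].
#' @return data.frame with columns `half1`, `half2`, `spacer`.
#' @export
as_training_sites <- function(sites) {
  if (length(sites) == 0L) stop("training set is empty")
  if (is.character(sites)) {
    bad <- nchar(sites) != 20L
    if (any(bad)) stop("training 20-mer of wrong length: ", sites[which(bad)[1]])
    sites <- data.frame(half1 = substr(sites, 1, 10),
                        half2 = substr(sites, 11, 20),
                        spacer = 0L)
  }
  if (!is.data.frame(sites) || !all(c("half1", "half2") %in% names(sites)))
    stop("training sites must be 20-mers or a data.frame with half1/half2")
  if (is.null(sites$spacer)) sites$spacer <- 0L
  sites$half1 <- toupper(sites$half1)
  sites$half2 <- toupper(sites$half2)
  for (col in c("half1", "half2")) {
    v <- sites[[col]]
    if (any(nchar(v) != 10L))
      stop("half-site is not a 10-mer: ", v[which(nchar(v) != 10L)[1]])
    ok <- .is_acgt(v)
    if (!all(ok))
      stop("non-ACGT character in training site: ", v[which(!ok)[1]])
  }
  if (any(sites$spacer < 0)) stop("negative spacer length")
  sites[, c("half1", "half2", "spacer")]
}

#' Raw PWM-20 score of a 20-mer
#'
#' Sum of 16 mononucleotide weights plus the two dinucleotide weights at
#' columns 5-6 and 15-16. Windows containing ambiguous bases (e.g. N) are
#' unscorable and return `NA`, which is distinct from a low score.
#'
#' @param pwm A [p53_pwm()] model.
#' @param x Character vector of 20-mers.
#' @return Numeric vector of raw scores (`NA` where unscorable).
#' @export
raw_score <- function(pwm, x) {
  stopifnot(inherits(pwm, "p53_pwm"))
  x <- toupper(.as_plain_seqs(x))
  if (any(nchar(x) != 20L)) stop("raw_score expects 20-mers")
  codes <- .codes_matrix(x, 20L)
  out <- numeric(length(x))
  # accumulate in symmetric pairs (p, 21-p) so that the floating-point sum
  # is bit-identical for a sequence and its reverse complement
  for (p in c(1:4, 7:10)) {
    q <- 21L - p
    out <- out + (pwm$mono[cbind(codes[, p], p)] + pwm$mono[cbind(codes[, q], q)])
  }
  out + (pwm$dimer[cbind(.dimer_index(codes[, 5], codes[, 6]), 1)] +
           pwm$dimer[cbind(.dimer_index(codes[, 15], codes[, 16]), 2)])
}

#' Percent PWM-20 score of a 20-mer
#'
#' Rescales the raw score so that 100 is the best possible site under the
#' matrix and 0 the worst possible one.
#'
#' @inheritParams raw_score
#' @return Numeric vector in \[0, 100\] (`NA` where unscorable).
#' @export
percent_score <- function(pwm, x) {
  stopifnot(inherits(pwm, "p53_pwm"))
  if (pwm$raw_max <= pwm$raw_min)
    stop("degenerate matrix: raw_min == raw_max")
  100 * (raw_score(pwm, x) - pwm$raw_min) / (pwm$raw_max - pwm$raw_min)
}

#' Best-scoring 20-mer under a PWM-20 model
#'
#' The column-wise argmax sequence; ties are broken alphabetically
#' (A < C < G < T). Always attains percent score 100.
#'
#' @inheritParams raw_score
#' @return A single 20-mer string.
#' @export
best_site <- function(pwm) {
  .extreme_site(pwm, which.max)
}

#' Worst-scoring 20-mer under a PWM-20 model
#'
#' @inheritParams raw_score
#' @return A single 20-mer attaining percent score 0.
#' @export
worst_site <- function(pwm) {
  .extreme_site(pwm, which.min)
}

.extreme_site <- function(pwm, pick) {
  stopifnot(inherits(pwm, "p53_pwm"))
  out <- character(20)
  for (p in MONO_POS) out[p] <- BASES[pick(pwm$mono[, p])]
  for (k in seq_along(DIMER_POS)) {
    pp <- DIMER_POS[[k]]
    d <- DIMERS[pick(pwm$dimer[, k])]
    out[pp[1]] <- substr(d, 1, 1)
    out[pp[2]] <- substr(d, 2, 2)
  }
  paste(out, collapse = "")
}

#' @export
print.p53_pwm <- function(x, ...) {
  cat("PWM-20 p53 binding-site model\n")
  cat(sprintf("  training sites : %d (+ reverse complements)\n", x$n_sites))
  if (nzchar(x$source_label)) cat(sprintf("  source         : %s\n", x$source_label))
  cat(sprintf("  pseudocount    : %g\n", x$pseudocount))
  cat(sprintf("  raw score range: [%.4f, %.4f]\n", x$raw_min, x$raw_max))
  cat(sprintf("  percent cutoff : %g%%\n", x$cutoff))
  cat(sprintf("  best site      : %s\n", best_site(x)))
  invisible(x)
}

#' @export
summary.p53_pwm <- function(object, ...) {
  # per-column information content (bits) of the pseudocounted frequencies
  freq <- 2^object$mono * 0.25
  ic <- apply(freq[, MONO_POS], 2, function(f) sum(f * log2(f / 0.25)))
  names(ic) <- MONO_POS
  dfreq <- 2^object$dimer / 16
  dic <- apply(dfreq, 2, function(f) sum(f * log2(f / (1 / 16))))
  out <- list(model = object, mono_ic = ic, dimer_ic = dic,
              consensus = best_site(object))
  class(out) <- "summary.p53_pwm"
  out
}

#' @export
print.summary.p53_pwm <- function(x, ...) {
  print(x$model)
  cat("  information content (bits) per mono column:\n")
  print(round(x$mono_ic, 3))
  cat("  dinucleotide columns 5-6 / 15-16:\n")
  print(round(x$dimer_ic, 3))
  invisible(x)
}

#' @export
coef.p53_pwm <- function(object, ...) {
  list(mono = object$mono, dimer = object$dimer)
}

#' Score sequences with a fitted PWM-20 model
#'
#' @param object A `p53_pwm` model.
#' @param newdata Character vector of 20-mers.
#' @param type `"percent"` (default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric scores.
#' @export
predict.p53_pwm <- function(object, newdata, type = c("percent", "raw"), ...) {
  type <- match.arg(type)
  switch(type,
         percent = percent_score(object, newdata),
         raw = raw_score(object, newdata))
}

#' Sample 20-mers from the PWM-20 probability model
#'
#' Draws each mononucleotide column and each dinucleotide column
#' independently from its pseudocounted frequency distribution.
#'
#' @param object A `p53_pwm` model.
#' @param nsim Number of 20-mers.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Character vector of 20-mers.
#' @export
simulate.p53_pwm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  freq <- 2^object$mono * 0.25
  dfreq <- 2^object$dimer / 16
  out <- matrix("", nrow = nsim, ncol = 20)
  for (p in MONO_POS)
    out[, p] <- sample(BASES, nsim, replace = TRUE, prob = freq[, p])
  for (k in seq_along(DIMER_POS)) {
    pp <- DIMER_POS[[k]]
    d <- sample(DIMERS, nsim, replace = TRUE, prob = dfreq[, k])
    out[, pp[1]] <- substr(d, 1, 1)
    out[, pp[2]] <- substr(d, 2, 2)
  }
  apply(out, 1, paste, collapse = "")
}

#' Read training binding sites from TSV or FASTA
#'
#' TSV input has 2 or 3 columns (half1, half2, optional spacer; header
#' optional, detected by non-ACGT content). FASTA input must contain 20-mers.
#'
#' @param path File path.
#' @return A validated training-site data.frame.
#' @export
read_training_sites <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    seqs <- as.character(Biostrings::readDNAStringSet(path))
    return(as_training_sites(unname(seqs)))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!.is_acgt(toupper(df[1, 1]))) { # header row
    df <- df[-1, , drop = FALSE]
  }
  names(df)[1:2] <- c("half1", "half2")
  if (ncol(df) >= 3) names(df)[3] <- "spacer"
  if (!is.null(df$spacer)) df$spacer <- as.integer(df$spacer)
  as_training_sites(df)
}

#' Serialize a PWM-20 model to TSV
#'
#' Header comment lines record pseudocount, raw range and cutoff; the body
#' has one row per (type, column, symbol, weight).
#'
#' @param pwm A `p53_pwm` model.
#' @param path Output path.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "p53_pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pseudocount=%.10g raw_min=%.10g raw_max=%.10g cutoff=%.10g n_sites=%d",
                     pwm$pseudocount, pwm$raw_min, pwm$raw_max, pwm$cutoff, pwm$n_sites), con)
  rows <- character(0)
  for (p in MONO_POS) for (b in BASES)
    rows <- c(rows, sprintf("mono\t%d\t%s\t%.12g", p, b, pwm$mono[b, p]))
  for (k in seq_along(DIMER_POS)) for (d in DIMERS)
    rows <- c(rows, sprintf("dimer\t%d\t%s\t%.12g", DIMER_POS[[k]][1], d, pwm$dimer[d, k]))
  writeLines(rows, con)
}

#' Read a serialized PWM-20 model
#'
#' @param path Path written by [write_pwm()].
#' @return A `p53_pwm` model (without its training table).
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  body <- utils::read.table(text = lines[-1], sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("type", "pos", "symbol", "weight"))
  mono <- matrix(NA_real_, 4, 20, dimnames = list(BASES, NULL))
  dimer <- matrix(NA_real_, 16, 2, dimnames = list(DIMERS, c("5_6", "15_16")))
  mrows <- body[body$type == "mono", ]
  mono[cbind(match(mrows$symbol, BASES), mrows$pos)] <- mrows$weight
  drows <- body[body$type == "dimer", ]
  dimer[cbind(match(drows$symbol, DIMERS),
              ifelse(drows$pos == 5L, 1L, 2L))] <- drows$weight
  structure(list(mono = mono, dimer = dimer,
                 raw_min = get_num("raw_min"), raw_max = get_num("raw_max"),
                 pseudocount = get_num("pseudocount"), cutoff = get_num("cutoff"),
                 n_sites = as.integer(get_num("n_sites")), source_label = "",
                 training = NULL),
            class = "p53_pwm")
}
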