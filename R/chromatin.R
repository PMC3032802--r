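# Rotational nucleosome positioning on the Alu consensus.
#
# The right Alu monomer carries a well-positioned nucleosome constrained
# between two long A-tracts; whether a p53 site wrapped in that nucleosome
# is accessible depends on its helical phase relative to the dyad. The
# scoring model is deliberately simple: AT-rich dinucleotides (AA, TT, AT,
# TA) favour bending into the minor groove, GC-rich ones (GG, CC, GC, CG)
# into the major groove, and a cosine kernel of period P translates the
# dinucleotide pattern into a rotational-positioning score.

AT_DIMERS <- c("AA", "TT", "AT", "TA")
GC_DIMERS <- c("GG", "CC", "GC", "CG")

#' Nucleosome model parameters
#'
#' @param period_P Helical period in bp/turn (default 10.36).
#' @param footprint_len Nucleosomal DNA length (147 bp; the dyad is
#'   `start + 73` of a footprint, 1-based).
#' @param exposure_tolerance Half-width, in fractional turns, of the
#'   "minor-groove-in" exposure window around phase 0.5 (default 0.15).
#' @param footprints data.frame with `start`, `end`, `dyad` (1-based
#'   consensus coordinates) or `NULL`.
#' @return list of class `nucleosome_model`.
#' @export
nucleosome_model <- function(period_P = 10.36, footprint_len = 147L,
                             exposure_tolerance = 0.15, footprints = NULL) {
  if (period_P <= 0) stop("period_P must be > 0")
  structure(list(period_P = period_P, footprint_len = footprint_len,
                 exposure_tolerance = exposure_tolerance,
                 footprints = footprints),
            class = "nucleosome_model")
}

#' Default Alu nucleosome footprints
#'
#' The left nucleosome is centered near the 5' end of the element
#' (footprint -72..74, dyad 1); the right nucleosome occupies `window`
#' (default the 147 bp between the two A-tracts, 134..280, dyad 207).
#'
#' @param seq Optional consensus sequence; when given and the right window
#'   is longer than 147 bp, the right dyad is optimized with
#'   [place_nucleosome()].
#' @param window Right-nucleosome search window (1-based inclusive).
#' @param model A [nucleosome_model()] for scoring/optimization.
#' @return The model with its `footprints` table populated.
#' @export
alu_nucleosome_model <- function(seq = NULL, window = c(134L, 280L),
                                 model = nucleosome_model()) {
  if (!is.null(seq) && diff(window) + 1L > model$footprint_len) {
    dy <- place_nucleosome(window[1], window[2], seq, model)
  } else {
    dy <- (window[1] + window[2]) / 2
  }
  half <- (model$footprint_len - 1L) / 2
  model$footprints <- data.frame(
    name = c("left", "right"),
    start = c(1L - half, as.integer(dy - half)),
    end = c(1L + half, as.integer(dy + half)),
    dyad = c(1L, as.integer(dy)),
    stringsAsFactors = FALSE)
  model
}

#' Find A-tracts in a sequence
#'
#' Maximal runs of consecutive A on the given strand of length at least
#' `min_len`.
#'
#' @param seq DNA string.
#' @param min_len Minimum run length (default 5).
#' @return data.frame with 1-based inclusive `start`, `end`, `length`.
#' @export
find_a_tracts <- function(seq, min_len = 5L) {
  seq <- toupper(.as_plain_seqs(seq)[1])
  r <- rle(strsplit(seq, "")[[1]] == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Rotational-positioning score of a 147-bp footprint
#'
#' Sum over dinucleotide positions i in the footprint of
#' w(dimer) * (-cos(2 * pi * (i + 0.5 - dyad) / P)) with w = +1 for AT-rich
#' and -1 for GC-rich dinucleotides (0 otherwise). The phase is evaluated at
#' the dinucleotide midpoint, which makes the score exactly invariant under
#' reverse complementation of the footprint about the dyad. An AT-rich
#' dinucleotide centered at offset (n + 1/2) * P from the dyad
#' (minor-groove-in) contributes +1.
#'
#' @param seq DNA string in consensus coordinates (position 1 = first base).
#' @param dyad 1-based dyad position; the footprint is `dyad - 73` to
#'   `dyad + 73`.
#' @param model A [nucleosome_model()].
#' @return Numeric score.
#' @export
rotational_score <- function(seq, dyad, model = nucleosome_model()) {
  seq <- toupper(.as_plain_seqs(seq)[1])
  half <- (model$footprint_len - 1L) / 2
  lo <- dyad - half
  hi <- dyad + half
  if (lo < 1L || hi > nchar(seq)) stop("footprint out of sequence range")
  v <- strsplit(substr(seq, lo, hi), "")[[1]]
  d <- paste0(v[-length(v)], v[-1])
  w <- ifelse(d %in% AT_DIMERS, 1, ifelse(d %in% GC_DIMERS, -1, 0))
  i <- lo:(hi - 1L) # dinucleotide start positions
  phase <- 2 * pi * (i + 0.5 - dyad) / model$period_P
  sum(w * (-cos(phase)))
}

#' Place a nucleosome in a window between A-tracts
#'
#' If the window is exactly 147 bp, the dyad is its arithmetic center. If
#' it is longer, every admissible dyad (keeping the 147-bp footprint inside
#' the window) is scored with [rotational_score()] and the argmax is
#' returned (ties go to the smallest dyad).
#'
#' @param window_start,window_end 1-based inclusive window bounds.
#' @param seq Sequence in consensus coordinates.
#' @param model A [nucleosome_model()].
#' @return Integer dyad position.
#' @export
place_nucleosome <- function(window_start, window_end, seq,
                             model = nucleosome_model()) {
  len <- window_end - window_start + 1L
  if (len < model$footprint_len)
    stop(sprintf("window too short for a %d-bp footprint (%d bp)",
                 model$footprint_len, len))
  half <- (model$footprint_len - 1L) / 2
  if (len == model$footprint_len) return(as.integer((window_start + window_end) / 2))
  dyads <- (window_start + half):(window_end - half)
  scores <- vapply(dyads, function(d) rotational_score(seq, d, model), numeric(1))
  as.integer(dyads[which.max(scores)])
}

#' Classify the accessibility of a p53 site center
#'
#' A site center outside every nucleosome footprint is in the linker. A
#' center inside a footprint is classified by its fractional-turn offset
#' from the dyad, f = ((center - dyad) / P) mod 1: minor-groove-in (exposed
#' on the nucleosome surface, accessible to p53) when
#' |f - 0.5| <= tolerance, occluded otherwise. The dyad itself has f = 0
#' and is occluded under this convention.
#'
#' @param center Integer vector of 1-based consensus positions (site
#'   centers).
#' @param model A [nucleosome_model()] with populated `footprints`.
#' @return data.frame with `center`, `footprint` (name or `NA`),
#'   `fractional_turn` (`NA` in linker) and `class` in
#'   `{"linker", "exposed", "occluded"}`.
#' @export
classify_exposure <- function(center, model) {
  if (is.null(model$footprints)) stop("model has no footprints")
  fp <- model$footprints
  out <- data.frame(center = center, footprint = NA_character_,
                    fractional_turn = NA_real_, class = "linker",
                    stringsAsFactors = FALSE)
  for (i in seq_along(center)) {
    hit <- which(fp$start <= center[i] & center[i] <= fp$end)
    if (!length(hit)) next
    hit <- hit[1]
    f <- ((center[i] - fp$dyad[hit]) / model$period_P) %% 1
    out$footprint[i] <- if (!is.null(fp$name)) fp$name[hit] else as.character(hit)
    out$fractional_turn[i] <- f
    out$class[i] <- if (abs(f - 0.5) <= model$exposure_tolerance) "exposed" else "occluded"
  }
  out
}
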