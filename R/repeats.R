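#' Parse a RepeatMasker .out annotation file
#'
#' Reads the standard whitespace-separated RepeatMasker `.out` layout: three
#' header lines, then one row per repeat with query coordinates (1-based
#' inclusive), strand ('+' or 'C' for complement), repeat name, class/family
#' and repeat-consensus coordinates. For '+' rows the consensus columns are
#' `begin end (left)`; for 'C' rows they appear as `(left) end begin`.
#' Parenthesized fields are parsed and discarded. Query coordinates are
#' converted to 0-based half-open; consensus begin/end are normalized so
#' begin <= end regardless of strand.
#'
#' @param path Path to a `.out` file (3 header lines expected; blank or
#'   missing headers tolerated).
#' @return data.frame of repeat annotations: `chrom`, `start`, `end`
#'   (0-based half-open), `strand` ('+'/'-'), `repeat_name`, `class_family`,
#'   `consensus_begin`, `consensus_end` (1-based inclusive),
#'   `divergence_pct`.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  # drop header block: lines starting with "SW"/"score" banners and blanks
  body <- lines[!grepl("^\\s*$", lines)]
  body <- body[!grepl("^\\s*(SW|score|bit)", body, ignore.case = TRUE)]
  if (!length(body)) return(.empty_annotations())
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 14L)
      stop(sprintf("malformed RepeatMasker row (need >= 14 fields, got %d) at line: %s",
                   length(f), body[i]))
    strand_raw <- f[9]
    strand <- if (strand_raw == "C") "-" else "+"
    unparen <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") {
      cb <- unparen(f[12]); ce <- unparen(f[13])
    } else {
      ce <- unparen(f[13]); cb <- unparen(f[14]) # (left) end begin
    }
    if (is.na(cb) || is.na(ce) || cb > ce)
      stop("malformed consensus coordinates at line: ", body[i])
    rows[[i]] <- data.frame(
      chrom = f[5],
      start = as.integer(f[6]) - 1L, # 1-based inclusive -> 0-based half-open
      end = as.integer(f[7]),
      strand = strand,
      repeat_name = f[10],
      class_family = f[11],
      consensus_begin = cb,
      consensus_end = ce,
      divergence_pct = as.numeric(f[2]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_annotations <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), repeat_name = character(),
             class_family = character(), consensus_begin = integer(),
             consensus_end = integer(), divergence_pct = numeric(),
             stringsAsFactors = FALSE)
}

#' Read repeat annotations from BED6+ format
#'
#' BED columns: chrom, start, end, name (= subfamily), score, strand, then
#' class/family, consensus begin, consensus end.
#'
#' @param path Path to a BED6+3 file.
#' @return Annotation data.frame as in [parse_repeatmasker_out()].
#' @export
read_repeat_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("BED6+3 requires 9 columns")
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]), end = as.integer(df[[3]]),
             strand = df[[6]], repeat_name = df[[4]], class_family = df[[7]],
             consensus_begin = as.integer(df[[8]]), consensus_end = as.integer(df[[9]]),
             divergence_pct = NA_real_, stringsAsFactors = FALSE)
}

#' Write annotations in RepeatMasker .out layout
#'
#' @param annotations Annotation data.frame.
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("   SW  perc perc perc  query     position in query   matching repeat        position in repeat",
               "score  div. del. ins.  sequence  begin end (left)    repeat  class/family   begin end (left)",
               ""), con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    div <- if (is.na(a$divergence_pct)) 0 else a$divergence_pct
    if (a$strand == "+") {
      rep_cols <- sprintf("%d %d (0)", a$consensus_begin, a$consensus_end)
      strand <- "+"
    } else {
      rep_cols <- sprintf("(0) %d %d", a$consensus_end, a$consensus_begin)
      strand <- "C"
    }
    writeLines(sprintf("  225 %5.1f  0.0  0.0  %s %d %d (0) %s %s %s %s %d",
                       div, a$chrom, a$start + 1L, a$end, strand,
                       a$repeat_name, a$class_family, rep_cols, i), con)
  }
}

#' Default hotspot windows on the Alu consensus
#'
#' Windows (1-based consensus coordinates) around the three positions where
#' p53 sites cluster: Box A (~10), Box B (~85) and Box A' (~150).
#'
#' @return Named list of `c(lo, hi)` integer windows.
#' @export
hotspot_windows <- function() {
  list(A = c(1L, 45L), B = c(60L, 115L), "A'" = c(125L, 175L))
}

#' Classify an Alu consensus position into a promoter-box hotspot
#'
#' @param center Integer vector of 1-based consensus positions.
#' @param windows Hotspot windows as produced by [hotspot_windows()].
#' @return Character vector in `{"A", "B", "A'", "none"}`.
#' @export
classify_hotspot <- function(center, windows = hotspot_windows()) {
  stopifnot(all(center >= 1))
  out <- rep("none", length(center))
  for (nm in names(windows)) {
    w <- windows[[nm]]
    out[center >= w[1] & center <= w[2]] <- nm
  }
  out
}

#' Map RE/BS hotspots to evolutionary groups A and B
#'
#' Sites near Boxes A and A' (generated largely by CpG deamination) form
#' group A; sites near Box B (largely ancestral) form group B.
#'
#' @param hotspot Character vector in `{"A", "A'", "B"}`.
#' @return Character vector in `{"A", "B"}`.
#' @export
assign_group <- function(hotspot) {
  if (any(hotspot == "none"))
    stop("cannot assign a group to a site outside all hotspots")
  bad <- !hotspot %in% c("A", "A'", "B")
  if (any(bad)) stop("unknown hotspot label: ", hotspot[which(bad)[1]])
  ifelse(hotspot == "B", "B", "A")
}

#' Assign predicted sites to repeat annotations
#'
#' Each site is assigned to the annotation with the largest genomic overlap,
#' provided the overlap is at least `min_overlap` bp (ties go to the
#' annotation with the smaller start). The site midpoint is projected into
#' repeat-consensus coordinates by linear interpolation between the
#' annotation's consensus begin/end (orientation flipped on the '-' strand;
#' the mapping assumes gapless proportionality within the annotated block
#' and is therefore approximate). The projected center is classified into a
#' hotspot.
#'
#' @param sites data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and any further columns (e.g. from [scan_p53()]).
#' @param annotations Annotation data.frame from
#'   [parse_repeatmasker_out()] / [read_repeat_bed()].
#' @param min_overlap Minimum overlap in bp (default 5).
#' @param windows Hotspot windows.
#' @return list with `mapped` (sites + `repeat_name`, `class_family`,
#'   `overlap_bp`, `consensus_center`, `hotspot`) and `unmapped` (the
#'   remaining site rows); the two partition the input.
#' @export
assign_sites <- function(sites, annotations, min_overlap = 5L,
                         windows = hotspot_windows()) {
  n <- nrow(sites)
  if (n == 0L) {
    mapped <- cbind(sites, data.frame(repeat_name = character(),
                                      class_family = character(),
                                      overlap_bp = integer(),
                                      consensus_center = integer(),
                                      hotspot = character()))
    return(list(mapped = mapped, unmapped = sites))
  }
  ann_idx <- rep(NA_integer_, n)
  ovl <- integer(n)
  if (nrow(annotations)) {
    q <- IRanges::IRanges(start = sites$start + 1L, end = sites$end)
    s <- IRanges::IRanges(start = annotations$start + 1L, end = annotations$end)
    ht <- IRanges::findOverlaps(q, s, minoverlap = as.integer(min_overlap))
    if (length(ht)) {
      qh <- S4Vectors::queryHits(ht)
      sh <- S4Vectors::subjectHits(ht)
      w <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      # max overlap, tie -> smaller annotation start
      ord <- order(qh, -w, annotations$start[sh])
      first <- !duplicated(qh[ord])
      ann_idx[qh[ord][first]] <- sh[ord][first]
      ovl[qh[ord][first]] <- w[ord][first]
    }
  }
  is_mapped <- !is.na(ann_idx)
  mapped <- sites[is_mapped, , drop = FALSE]
  if (nrow(mapped)) {
    a <- annotations[ann_idx[is_mapped], , drop = FALSE]
    mid_off <- (mapped$start + floor((mapped$end - mapped$start) / 2)) - a$start
    glen <- a$end - a$start
    cspan <- a$consensus_end - a$consensus_begin
    frac <- ifelse(glen > 1, mid_off / (glen - 1), 0)
    center <- ifelse(a$strand == "+",
                     a$consensus_begin + frac * cspan,
                     a$consensus_end - frac * cspan)
    mapped$repeat_name <- a$repeat_name
    mapped$class_family <- a$class_family
    mapped$overlap_bp <- ovl[is_mapped]
    mapped$consensus_center <- as.integer(round(center))
    mapped$hotspot <- classify_hotspot(pmax(1L, mapped$consensus_center), windows)
  } else {
    mapped$repeat_name <- character(0)
    mapped$class_family <- character(0)
    mapped$overlap_bp <- integer(0)
    mapped$consensus_center <- integer(0)
    mapped$hotspot <- character(0)
  }
  rownames(mapped) <- NULL
  unmapped <- sites[!is_mapped, , drop = FALSE]
  rownames(unmapped) <- NULL
  list(mapped = mapped, unmapped = unmapped)
}

#' Per-subfamily spacer count table
#'
#' Builds a table in the style of the per-subfamily motif summaries: one row
#' per repeat subfamily with the number of elements, the number of motifs
#' and the count of motifs for each spacer length, plus a Total row.
#'
#' @param mapped Mapped sites (need `repeat_name` and `spacer` columns).
#' @param element_counts Named integer vector: number of elements per
#'   subfamily; every subfamily present in `mapped` must be covered.
#' @param s_max Largest spacer column (default 14).
#' @return data.frame with columns `subfamily`, `n_elements`, `n_motifs`,
#'   `S0` ... `S<s_max>`; last row is `Total`. For every row
#'   `n_motifs == sum of the spacer columns`.
#' @export
build_spacer_table <- function(mapped, element_counts, s_max = 14L) {
  subs <- names(element_counts)
  missing_sub <- setdiff(unique(mapped$repeat_name), subs)
  if (length(missing_sub))
    stop("no element count for subfamily: ", paste(missing_sub, collapse = ", "))
  scols <- paste0("S", 0:s_max)
  mat <- matrix(0L, nrow = length(subs), ncol = s_max + 1L,
                dimnames = list(subs, scols))
  if (nrow(mapped)) {
    tab <- table(factor(mapped$repeat_name, levels = subs),
                 factor(mapped$spacer, levels = 0:s_max))
    mat[] <- as.integer(tab)
  }
  out <- data.frame(subfamily = subs,
                    n_elements = as.integer(element_counts),
                    n_motifs = as.integer(rowSums(mat)),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  total <- data.frame(subfamily = "Total",
                      n_elements = sum(out$n_elements),
                      n_motifs = sum(out$n_motifs),
                      as.list(colSums(mat)), check.names = FALSE)
  rbind(out, total)
}

#' Motif content ratio of a subfamily
#'
#' The number of sites with spacer in `spacers`, divided by the number of
#' elements of the subfamily, as a percentage. Used to compare subfamilies
#' on a relative scale (e.g. the S = 0 content, or the cumulative
#' S in {0, 8, 14} content of the CpG-derived Box B sites).
#'
#' @param table A spacer table ([build_spacer_table()] output, or any
#'   data.frame with `subfamily`, `n_elements` and `S<k>` columns).
#' @param subfamily Subfamily name.
#' @param spacers Integer set of spacer lengths.
#' @return list with `percent` (full precision) and `rounded`
#'   (nearest percent).
#' @export
content_ratio <- function(table, subfamily, spacers) {
  row <- table[table$subfamily == subfamily, , drop = FALSE]
  if (nrow(row) != 1L) stop("subfamily not in table: ", subfamily)
  if (row$n_elements <= 0) stop("subfamily has zero elements: ", subfamily)
  cols <- paste0("S", spacers)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("spacer column missing from table: ", paste(miss, collapse = ", "))
  pct <- 100 * sum(as.numeric(row[1, cols])) / row$n_elements
  list(percent = pct, rounded = round(pct))
}

#' Curate a response-element collection
#'
#' Applies removals and additions to a base collection of functional p53
#' response elements and reports the curated size. The defaults reproduce
#' the curation of the largest published RE collection: 156 sites, minus
#' the viral HBV site and one duplicated COL18A1 site, plus three further
#' experimentally supported CASP10 sites, giving 157.
#'
#' @param base_count Size of the base collection (default 156).
#' @param removals Character vector of removed entries.
#' @param additions Character vector of added entries.
#' @return list with `count` and `log` (data.frame of edits).
#' @export
curate_re_dataset <- function(base_count = 156L,
                              removals = c("HBV", "COL18A1_duplicate"),
                              additions = c("CASP10_RE2", "CASP10_RE3", "CASP10_RE4")) {
  if (base_count < 0) stop("base_count must be >= 0")
  if (length(removals) > base_count)
    stop("cannot remove more entries than the base collection holds")
  log <- data.frame(
    entry = c(removals, additions),
    action = c(rep("remove", length(removals)), rep("add", length(additions))),
    stringsAsFactors = FALSE)
  list(count = base_count - length(removals) + length(additions), log = log)
}
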