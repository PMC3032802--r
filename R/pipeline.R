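# End-to-end orchestration and packaged fixtures.

#' Packaged per-repeat RE and subfamily count tables
#'
#' Returns the two packaged reference tables: `table1`, the 24 functional
#' p53 response elements found in repeats (gene, half-sites, spacer, repeat
#' and class/family assignment), and `table2`, the per-Alu-subfamily counts
#' of predicted p53 motifs (number of elements, number of motifs, and the
#' counts for the prevalent spacers S = 0, 3, 8, 14). File integrity is
#' verified against recorded MD5 checksums.
#'
#' @return list with data.frames `table1` and `table2`.
#' @export
alu_fixtures <- function() {
  f1 <- system.file("extdata", "table1_repeat_REs.tsv", package = "alup53")
  f2 <- system.file("extdata", "table2_alu_subfamilies.tsv", package = "alup53")
  sums <- tools::md5sum(c(f1, f2))
  expected <- c("488702e094725708eaa36269b955e611",
                "3d8de383406f79f151e8b97adcb2ba32")
  if (!identical(unname(sums), expected))
    stop("packaged fixture checksum mismatch; reinstall the package")
  table1 <- utils::read.table(f1, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  table2 <- utils::read.table(f2, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
  list(table1 = table1, table2 = table2)
}

#' Pipeline configuration
#'
#' @param pwm A fitted [p53_pwm()] model (or `NULL` with `training` given).
#' @param training Training sites used to fit the model when `pwm` is NULL.
#' @param genome Sequences to scan (named character vector/`DNAStringSet`
#'   or FASTA path); `NULL` for tables-only runs.
#' @param annotations Repeat annotations (data.frame, or path to a
#'   RepeatMasker `.out` file); may be an empty data.frame.
#' @param element_counts Named vector of element counts per subfamily;
#'   defaults to the annotation tally.
#' @param s_max,cutoff,soft_mask Scan parameters.
#' @param hotspots Hotspot windows.
#' @param chromatin A [nucleosome_model()]; `NULL` disables exposure
#'   classification.
#' @param peak_spacers,background_spacers Spacer sets for the z statistic.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param seed Integer seed recorded in the summary.
#' @return list of class `alup53_config`.
#' @export
pipeline_config <- function(pwm = NULL, training = NULL, genome = NULL,
                            annotations = NULL, element_counts = NULL,
                            s_max = 14L, cutoff = 70, soft_mask = FALSE,
                            hotspots = hotspot_windows(),
                            chromatin = NULL,
                            peak_spacers = c(0L, 3L, 8L, 14L),
                            background_spacers = setdiff(1:13, c(3L, 8L)),
                            out_dir = NULL, seed = 1L) {
  structure(list(pwm = pwm, training = training, genome = genome,
                 annotations = annotations, element_counts = element_counts,
                 s_max = as.integer(s_max), cutoff = cutoff,
                 soft_mask = soft_mask, hotspots = hotspots,
                 chromatin = chromatin, peak_spacers = peak_spacers,
                 background_spacers = background_spacers,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "alup53_config")
}

#' Run the full analysis pipeline
#'
#' Stages: fit (or reuse) the PWM-20 model, scan the genome, map hits to
#' repeat annotations, tabulate per-subfamily spacer counts and content
#' ratios, compute the spacer histogram and its peak z statistic, and (when
#' a chromatin model is configured) classify the exposure of mapped site
#' centers. Any stage failure aborts with the stage name. When `out_dir`
#' is set, sites (BED), mapped sites (TSV), the spacer table (TSV) and a
#' JSON summary are written there.
#'
#' @param config An [pipeline_config()] object.
#' @return list with `pwm`, `sites`, `mapped`, `unmapped`, `spacer_table`,
#'   `histogram`, `summary` (list: seed, parameters, site counts, hotspot
#'   histogram, z statistic, exposure classes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "alup53_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  pwm <- config$pwm
  if (is.null(pwm) && !is.null(config$training))
    pwm <- stage("build-pwm", p53_pwm(config$training, cutoff = config$cutoff))

  ann <- config$annotations
  if (is.character(ann)) ann <- stage("annotations", parse_repeatmasker_out(ann))
  if (is.null(ann)) ann <- .empty_annotations()

  sites <- NULL; mapped <- NULL; unmapped <- NULL
  hist <- NULL; z <- NA_real_
  if (!is.null(config$genome)) {
    if (is.null(pwm)) stop("pipeline stage 'scan' failed: no PWM and no training sites")
    sites <- stage("scan", scan_p53(pwm, config$genome, s_max = config$s_max,
                                    cutoff = config$cutoff,
                                    soft_mask = config$soft_mask))
    hist <- spacer_histogram(sites, s_max = config$s_max)
    z <- tryCatch(peak_z(hist, config$peak_spacers, config$background_spacers),
                  error = function(e) NA_real_)
    asg <- stage("map", assign_sites(sites, ann, windows = config$hotspots))
    mapped <- asg$mapped
    unmapped <- asg$unmapped
  }

  el_counts <- config$element_counts
  if (is.null(el_counts) && nrow(ann))
    el_counts <- vapply(split(ann, ann$repeat_name), nrow, integer(1))
  spacer_table <- NULL
  if (!is.null(mapped) && !is.null(el_counts) && length(el_counts))
    spacer_table <- stage("table", build_spacer_table(mapped, el_counts,
                                                      s_max = config$s_max))

  exposure <- NULL
  if (!is.null(config$chromatin) && !is.null(mapped) && nrow(mapped))
    exposure <- stage("chromatin",
                      classify_exposure(mapped$consensus_center, config$chromatin))

  summary <- list(
    seed = config$seed,
    parameters = list(s_max = config$s_max, cutoff = config$cutoff,
                      soft_mask = config$soft_mask),
    n_sites = if (is.null(sites)) 0L else nrow(sites),
    n_mapped = if (is.null(mapped)) 0L else nrow(mapped),
    n_unmapped = if (is.null(unmapped)) 0L else nrow(unmapped),
    spacer_histogram = as.list(hist),
    peak_z = z,
    hotspot_histogram = if (!is.null(mapped) && nrow(mapped))
      as.list(table(mapped$hotspot)) else list(),
    exposure_classes = if (!is.null(exposure))
      as.list(table(exposure$class)) else list())

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(sites))
      write_sites_bed(sites, file.path(config$out_dir, "sites.bed"))
    if (!is.null(mapped))
      utils::write.table(mapped, file.path(config$out_dir, "mapped_sites.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(spacer_table))
      utils::write.table(spacer_table, file.path(config$out_dir, "spacer_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(pwm = pwm, sites = sites, mapped = mapped, unmapped = unmapped,
       spacer_table = spacer_table, histogram = hist, exposure = exposure,
       summary = summary)
}

#' Reference content ratios and totals from the packaged subfamily table
#'
#' Convenience wrapper used in tables-only analyses: computes the S = 0
#' content of AluSg1, the cumulative S in {0, 8, 14} contents of AluJo,
#' AluSc and AluY, and the motif-count column totals.
#'
#' @return list with `ratios` (named, rounded percents), `ratios_full`
#'   (full precision), `total_motifs`, `total_S0`.
#' @export
table2_reference_stats <- function() {
  t2 <- alu_fixtures()$table2
  r <- list(
    AluSg1_S0 = content_ratio(t2, "AluSg1", 0L),
    AluJo_cum = content_ratio(t2, "AluJo", c(0L, 8L, 14L)),
    AluSc_cum = content_ratio(t2, "AluSc", c(0L, 8L, 14L)),
    AluY_cum = content_ratio(t2, "AluY", c(0L, 8L, 14L)))
  list(ratios = vapply(r, function(x) x$rounded, numeric(1)),
       ratios_full = vapply(r, function(x) x$percent, numeric(1)),
       total_motifs = sum(t2$n_motifs),
       total_S0 = sum(t2$S0))
}
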