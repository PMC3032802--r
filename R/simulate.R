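# Synthetic Alu-decay generator. Produces Alu-like elements decayed from a
# consensus under a CpG-transition-biased substitution process, places them
# in random background sequence, and emits annotations plus a truth table so
# scanner, mapper and evolution statistics can be validated end to end.

#' Packaged synthetic Alu-like consensus (290 bp)
#'
#' A hand-designed toy consensus, explicitly synthetic (not a Repbase
#' sequence), that reproduces the coarse architecture the analysis relies
#' on: CG-bearing CNNG...CNNG arrangements near positions 10 (Box A like)
#' and 150 (Box A' like), a CG-poor p53-like arrangement near position 85
#' (Box B like), an A-tract at positions 121-133, and a 3' A-tail from
#' position 281, leaving the 147-bp window 134..280 between the two
#' A-tracts for the "right" nucleosome.
#'
#' @return A 290-bp DNA string.
#' @export
synthetic_alu_consensus <- function() {
  paste0(
    #   1-30: Box-A-like, CG-rich CNNG cores (CACG -> CATG on deamination)
    "GGCC", "GGGCACGCCCGGGCACGCCC", "TGGCTC",
    #  31-78: left-monomer body
    "ACGCCTGTAATCCCAGCACTTTGGGAGGCTGAGGCAGGTGGATCACCT",
    #  79-101: Box-B-like, CG-poor site with spacer 3 already close to
    #  consensus (GGTCATGTTG ACT GGACATGGTG)
    "GGTCATGTTGACTGGACATGGTG",
    # 102-120: inter-monomer
    "AGTTTGAGACCAGCCTGGC",
    # 121-133: A-tract (left boundary of the right nucleosome)
    "AAAAAAAAAAAAA",
    # 134-170: Box-A'-like, CG-rich CNNG cores
    "TAGCCGGGCACGCCCGGGCACGCCCTGGTGGCGGGCG",
    # 171-280: right-monomer body
    "CCTGTAGTCCCAGCTACTCGGGAGGCTGAGGCAGGAGAATGGCGTGAACCCGGGAGGCGG",
    "AGCTTGCAGTGAGCCGAGATCGCGCCACTGCACTCCAGCCTGGGCGACAG",
    # 281-290: 3' A-tail
    "AAAAAAAAAA")
}

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: substitution
#' rate 0.10/bp (typical Alu divergence from its subfamily consensus is
#' around 10%), CpG transition multiplier 8 (CpG transitions run about an
#' order of magnitude above the background substitution rate), background
#' GC 0.41 (human genome), no indels.
#'
#' @param consensus Consensus DNA string (default
#'   [synthetic_alu_consensus()]).
#' @param n_elements Number of decayed elements to place (default 50).
#' @param substitution_rate Per-bp substitution probability r (default 0.10).
#' @param cpg_multiplier m >= 1: the C of a CpG undergoes the C->T
#'   transition with total probability m * r (and symmetrically G->A on the
#'   other strand).
#' @param indel_rate Reserved; must be 0 (substitution-only model).
#' @param background_length Background genome length (default 60000).
#' @param background_gc Background GC fraction (default 0.41).
#' @param implant_spec List of implants, each
#'   `list(site = <20-mer or half-sites>, spacer = S, offset = 1-based
#'   consensus offset)`; implanted into the consensus copy of every element
#'   before decay.
#' @param subfamily Label used in annotations (default "AluSyn").
#' @param seed Integer seed recorded in all outputs.
#' @return list of class `alu_sim_config`.
#' @export
synthetic_config <- function(consensus = synthetic_alu_consensus(),
                             n_elements = 50L,
                             substitution_rate = 0.10,
                             cpg_multiplier = 8,
                             indel_rate = 0,
                             background_length = 60000L,
                             background_gc = 0.41,
                             implant_spec = list(),
                             subfamily = "AluSyn",
                             seed = 1L) {
  if (substitution_rate < 0 || substitution_rate > 1) stop("substitution_rate must be in [0,1]")
  if (cpg_multiplier < 1) stop("cpg_multiplier must be >= 1")
  if (indel_rate != 0) stop("indel model not implemented; indel_rate must be 0")
  if (background_gc < 0 || background_gc > 1) stop("background_gc must be in [0,1]")
  structure(list(consensus = toupper(.as_plain_seqs(consensus)[1]),
                 n_elements = as.integer(n_elements),
                 substitution_rate = substitution_rate,
                 cpg_multiplier = cpg_multiplier,
                 indel_rate = indel_rate,
                 background_length = as.integer(background_length),
                 background_gc = background_gc,
                 implant_spec = implant_spec,
                 subfamily = subfamily,
                 seed = as.integer(seed)),
            class = "alu_sim_config")
}

#' Decay a consensus under a CpG-biased substitution process
#'
#' Every base substitutes with probability r, uniformly to the three
#' alternatives. Additionally, the C of each consensus CpG mutates to T
#' with total probability m * r (and the G to A with the same probability,
#' the complementary-strand deamination), so the CpG transition rate is m
#' times the overall background substitution rate. Requires
#' m * r + 2r/3 <= 1.
#'
#' @param consensus DNA string.
#' @param rate Substitution rate r per bp.
#' @param cpg_multiplier Multiplier m.
#' @param seed Optional integer seed (set for reproducibility).
#' @return list with `seq` (mutated string) and `log` (data.frame `pos`,
#'   `ref`, `alt`, `cpg`).
#' @export
mutate_consensus <- function(consensus, rate, cpg_multiplier = 1, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0,1]")
  if (cpg_multiplier < 1) stop("cpg_multiplier must be >= 1")
  if (cpg_multiplier * rate + 2 * rate / 3 > 1)
    stop("cpg_multiplier * rate too large; total mutation probability exceeds 1")
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(toupper(.as_plain_seqs(consensus)[1]), "")[[1]]
  L <- length(v)
  if (rate == 0 || L == 0) {
    return(list(seq = paste(v, collapse = ""),
                log = data.frame(pos = integer(), ref = character(),
                                 alt = character(), cpg = logical())))
  }
  is_cpg_c <- v == "C" & c(v[-1], "") == "G"
  is_cpg_g <- v == "G" & c("", v[-L]) == "C"
  cpg <- is_cpg_c | is_cpg_g
  m <- cpg_multiplier
  alt <- v
  u <- stats::runif(L)
  pick <- stats::runif(L)
  for (i in which(v %in% BASES)) {
    others <- setdiff(BASES, v[i])
    if (cpg[i]) {
      # transition target: C->T for the CpG C, G->A for the CpG G
      ts <- if (is_cpg_c[i]) "T" else "A"
      tv <- setdiff(others, ts)
      p_ts <- m * rate
      p_tv <- rate / 3
      if (u[i] < p_ts) alt[i] <- ts
      else if (u[i] < p_ts + 2 * p_tv) alt[i] <- tv[1 + (pick[i] < 0.5)]
    } else {
      if (u[i] < rate) alt[i] <- others[1 + findInterval(pick[i], c(1 / 3, 2 / 3))]
    }
  }
  changed <- which(alt != v)
  list(seq = paste(alt, collapse = ""),
       log = data.frame(pos = changed, ref = v[changed], alt = alt[changed],
                        cpg = cpg[changed]))
}

.random_background <- function(length, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = probs), collapse = "")
}

.implant_into <- function(seq, implant_spec) {
  v <- strsplit(seq, "")[[1]]
  truth <- list()
  for (sp in implant_spec) {
    site <- toupper(sp$site)
    S <- if (is.null(sp$spacer)) 0L else as.integer(sp$spacer)
    off <- as.integer(sp$offset) # 1-based position of the site's first base
    if (nchar(site) != 20L) stop("implant site must be a 20-mer")
    h1 <- substr(site, 1, 10); h2 <- substr(site, 11, 20)
    if (off + 19L + S > length(v)) stop("implant does not fit in the consensus")
    v[off:(off + 9L)] <- strsplit(h1, "")[[1]]
    v[(off + 10L + S):(off + 19L + S)] <- strsplit(h2, "")[[1]]
    truth[[length(truth) + 1L]] <- data.frame(offset = off, spacer = S)
  }
  list(seq = paste(v, collapse = ""),
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(offset = integer(), spacer = integer()))
}

#' Generate a synthetic genome with decayed Alu-like elements
#'
#' Implants sites into the consensus (if requested), decays an independent
#' copy per element, and places the copies non-overlapping on random
#' strands in i.i.d. background sequence. Consensus coordinates of each
#' annotation cover the full element (1..L).
#'
#' @param config An [synthetic_config()] object.
#' @return list with `genome` (named character vector of one sequence,
#'   "chrSyn"), `annotations` (annotation data.frame as in
#'   [parse_repeatmasker_out()]), `truth` (data.frame: `element`, `start`,
#'   `end` (0-based half-open element interval), `strand`, `subfamily`,
#'   `site_start` (0-based genomic start of implanted site or `NA`),
#'   `spacer`), and `config`.
#' @export
build_synthetic_genome <- function(config) {
  stopifnot(inherits(config, "alu_sim_config"))
  set.seed(config$seed)
  imp <- .implant_into(config$consensus, config$implant_spec)
  Le <- nchar(imp$seq)
  n <- config$n_elements
  Lb <- config$background_length
  if (n * Le > Lb) stop("elements do not fit in the background")
  genome <- .random_background(Lb, config$background_gc)

  # non-overlapping placement: draw starts in the gap-partition layout
  free <- Lb - n * Le
  if (n > 0L) {
    cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
    starts0 <- cuts + (seq_len(n) - 1L) * Le # 0-based
  } else {
    starts0 <- integer(0)
  }
  strands <- if (n > 0L) sample(c("+", "-"), n, replace = TRUE) else character(0)

  gvec <- strsplit(genome, "")[[1]]
  ann <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    mut <- mutate_consensus(imp$seq, config$substitution_rate,
                            config$cpg_multiplier)
    eseq <- mut$seq
    if (strands[i] == "-") eseq <- .revcomp(eseq)
    st <- starts0[i]
    gvec[(st + 1L):(st + Le)] <- strsplit(eseq, "")[[1]]
    ann[[i]] <- data.frame(chrom = "chrSyn", start = st, end = st + Le,
                           strand = strands[i],
                           repeat_name = config$subfamily,
                           class_family = "SINE/Alu",
                           consensus_begin = 1L, consensus_end = Le,
                           divergence_pct = 100 * config$substitution_rate,
                           stringsAsFactors = FALSE)
    if (nrow(imp$truth)) {
      site_len <- 20L + imp$truth$spacer
      if (strands[i] == "+") {
        s0 <- st + imp$truth$offset - 1L
      } else {
        s0 <- st + Le - (imp$truth$offset - 1L) - site_len
      }
      truth[[i]] <- data.frame(element = i, start = st, end = st + Le,
                               strand = strands[i], subfamily = config$subfamily,
                               site_start = s0, spacer = imp$truth$spacer,
                               stringsAsFactors = FALSE)
    } else {
      truth[[i]] <- data.frame(element = i, start = st, end = st + Le,
                               strand = strands[i], subfamily = config$subfamily,
                               site_start = NA_integer_, spacer = NA_integer_,
                               stringsAsFactors = FALSE)
    }
  }
  genome <- paste(gvec, collapse = "")
  names(genome) <- "chrSyn"
  annotations <- if (n > 0L) do.call(rbind, ann) else .empty_annotations()
  truth <- if (n > 0L) do.call(rbind, truth) else
    data.frame(element = integer(), start = integer(), end = integer(),
               strand = character(), subfamily = character(),
               site_start = integer(), spacer = integer())
  list(genome = genome, annotations = annotations, truth = truth,
       config = config)
}

#' Precision and recall of predicted sites against simulation truth
#'
#' A predicted site matches a truth site when its genomic start is within
#' `tol` bp of the truth start and the spacer agrees. Reports overall and
#' per-spacer precision/recall.
#'
#' @param predicted data.frame from [scan_p53()].
#' @param truth Truth table from [build_synthetic_genome()].
#' @param tol Start-position tolerance in bp (default 2).
#' @return list with `precision`, `recall`, `per_spacer` (data.frame).
#' @export
recovery_metrics <- function(predicted, truth, tol = 2L) {
  tr <- truth[!is.na(truth$site_start), , drop = FALSE]
  n_true <- nrow(tr)
  n_pred <- nrow(predicted)
  match_true <- logical(n_true)
  match_pred <- logical(n_pred)
  for (i in seq_len(n_true)) {
    hit <- which(!match_pred &
                   abs(predicted$start - tr$site_start[i]) <= tol &
                   predicted$spacer == tr$spacer[i])
    if (length(hit)) {
      match_true[i] <- TRUE
      match_pred[hit[1]] <- TRUE
    }
  }
  per_spacer <- do.call(rbind, lapply(sort(unique(tr$spacer)), function(S) {
    ti <- tr$spacer == S
    pi <- predicted$spacer == S
    data.frame(spacer = S,
               recall = if (any(ti)) mean(match_true[ti]) else NA_real_,
               precision = if (any(pi)) mean(match_pred[pi]) else NA_real_)
  }))
  list(precision = if (n_pred) mean(match_pred) else NA_real_,
       recall = if (n_true) mean(match_true) else NA_real_,
       per_spacer = per_spacer)
}

#' Estimate the CpG transition multiplier from decayed elements
#'
#' Compares each decayed element with the consensus position-wise (the
#' generator is substitution-only, so no alignment is needed): the fraction
#' of consensus CpG C/G bases showing the deamination transition (C->T, or
#' G->A on the other strand) estimates m * r, and the fraction of non-CpG
#' bases substituted in any way estimates r. Their ratio estimates m, with
#' a 95% binomial (Wald) interval propagated from the CpG transition count.
#'
#' @param elements Character vector of decayed element sequences (consensus
#'   orientation).
#' @param consensus The consensus they decayed from.
#' @return list with `m_hat`, `ci` (length-2), `cpg_rate`, `background_rate`.
#' @export
estimate_cpg_multiplier <- function(elements, consensus) {
  cv <- strsplit(toupper(consensus), "")[[1]]
  L <- length(cv)
  is_cpg_c <- cv == "C" & c(cv[-1], "") == "G"
  is_cpg_g <- cv == "G" & c("", cv[-L]) == "C"
  cpg <- is_cpg_c | is_cpg_g
  n_ts <- 0L; n_cpg <- 0L
  n_bg_mut <- 0L; n_bg <- 0L
  for (e in elements) {
    ev <- strsplit(toupper(e), "")[[1]]
    stopifnot(length(ev) == L)
    ts_target <- ifelse(is_cpg_c, "T", ifelse(is_cpg_g, "A", NA))
    n_ts <- n_ts + sum(cpg & ev == ts_target, na.rm = TRUE)
    n_cpg <- n_cpg + sum(cpg)
    n_bg_mut <- n_bg_mut + sum(!cpg & ev != cv)
    n_bg <- n_bg + sum(!cpg)
  }
  p_cpg <- n_ts / n_cpg
  p_bg <- n_bg_mut / n_bg
  m_hat <- p_cpg / p_bg
  se <- sqrt(p_cpg * (1 - p_cpg) / n_cpg)
  ci <- (p_cpg + c(-1.96, 1.96) * se) / p_bg
  list(m_hat = m_hat, ci = ci, cpg_rate = p_cpg, background_rate = p_bg)
}

#' Serialize / restore a simulation configuration
#'
#' JSON round-trip for [synthetic_config()] objects, so simulation runs can
#' be reproduced from a recorded file.
#'
#' @param config An `alu_sim_config`.
#' @param path File path.
#' @return `read_synthetic_config()` returns an `alu_sim_config` identical
#'   to the one written.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "alu_sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$implant_spec <- if (is.null(x$implant_spec) || !length(x$implant_spec))
    list() else lapply(seq_len(nrow(x$implant_spec)), function(i)
      as.list(x$implant_spec[i, ]))
  do.call(synthetic_config, x)
}
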