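rm_header <- c(
  "   SW  perc perc perc  query     position in query   matching repeat        position in repeat",
  "score  div. del. ins.  sequence  begin end (left)    repeat  class/family   begin end (left)",
  "")

test_that("RepeatMasker rows parse with strand-dependent consensus columns", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c(rm_header,
    "  463 11.2  0.0  0.0  chr1 1001 1300 (5000) + AluSx SINE/Alu 1 300 (12) 1",
    "  463 13.1  0.0  0.0  chr1 2001 2296 (4000) C AluJo SINE/Alu (12) 310 15 2"),
    path)
  ann <- parse_repeatmasker_out(path)
  expect_equal(nrow(ann), 2)
  # '+' row: 1-based 1001-1300 -> 0-based half-open 1000-1300, consensus 1..300
  expect_equal(ann$start[1], 1000L)
  expect_equal(ann$end[1], 1300L)
  expect_equal(ann$strand[1], "+")
  expect_equal(ann$consensus_begin[1], 1L)
  expect_equal(ann$consensus_end[1], 300L)
  # 'C' row: repeat columns "(12) 310 15" -> begin 15, end 310, strand '-'
  expect_equal(ann$strand[2], "-")
  expect_equal(ann$consensus_begin[2], 15L)
  expect_equal(ann$consensus_end[2], 310L)
  expect_equal(ann$divergence_pct[2], 13.1)
})

test_that("header-only and malformed .out files are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(rm_header, path)
  expect_equal(nrow(parse_repeatmasker_out(path)), 0)
  writeLines(c(rm_header, "  463 11.2 chr1 1001"), path)
  expect_error(parse_repeatmasker_out(path), "malformed")
})

test_that(".out writer round-trips through the parser", {
  ann <- data.frame(chrom = "chrSyn", start = c(100L, 900L), end = c(400L, 1190L),
                    strand = c("+", "-"), repeat_name = "AluSyn",
                    class_family = "SINE/Alu", consensus_begin = 1L,
                    consensus_end = 290L, divergence_pct = c(10, 12),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ann, path)
  back <- parse_repeatmasker_out(path)
  expect_equal(back[names(ann)], ann)
})

test_that("sites map to the max-overlap annotation with interpolated centers", {
  ann <- data.frame(chrom = "chr1", start = c(1000L, 2000L), end = c(1300L, 2300L),
                    strand = c("+", "-"), repeat_name = c("AluSx", "AluJo"),
                    class_family = "SINE/Alu", consensus_begin = 1L,
                    consensus_end = 300L, divergence_pct = NA_real_,
                    stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "chr1",
                      start = c(1010L, 2010L, 500L, 1297L),
                      end = c(1030L, 2030L, 520L, 1317L),
                      spacer = 0L)
  out <- assign_sites(sites, ann, min_overlap = 5)
  expect_equal(nrow(out$mapped) + nrow(out$unmapped), nrow(sites))
  # 20-bp site 10 bp into a '+' annotation: center = 1 + 10 + 10 = 21
  expect_equal(out$mapped$consensus_center[out$mapped$start == 1010], 21L)
  expect_equal(out$mapped$hotspot[out$mapped$start == 1010], "A")
  # same geometry on the '-' strand mirrors about the consensus interval
  minus_center <- out$mapped$consensus_center[out$mapped$start == 2010]
  expect_equal(minus_center, 300L + 1L - 21L)
  # outside everything -> unmapped; 3-bp overlap -> unmapped under min 5
  expect_true(500 %in% out$unmapped$start)
  expect_true(1297 %in% out$unmapped$start)
})

test_that("overlap ties go to the annotation with the smaller start", {
  ann <- data.frame(chrom = "c", start = c(100L, 110L), end = c(130L, 140L),
                    strand = "+", repeat_name = c("first", "second"),
                    class_family = "SINE/Alu", consensus_begin = 1L,
                    consensus_end = 31L, divergence_pct = NA_real_,
                    stringsAsFactors = FALSE)
  # site 110..130 overlaps both by 20
  site <- data.frame(chrom = "c", start = 110L, end = 130L, spacer = 0L)
  out <- assign_sites(site, ann)
  expect_equal(out$mapped$repeat_name, "first")
})

test_that("hotspot classification follows the configured windows", {
  expect_equal(classify_hotspot(c(10, 85, 150, 250, 46, 59, 116, 124, 176)),
               c("A", "B", "A'", "none", "none", "none", "none", "none", "none"))
  expect_equal(classify_hotspot(c(1, 45, 60, 115, 125, 175)),
               c("A", "A", "B", "B", "A'", "A'"))
  expect_error(classify_hotspot(0))
  # windows are disjoint
  w <- hotspot_windows()
  covers <- unlist(lapply(w, function(x) x[1]:x[2]))
  expect_equal(anyDuplicated(covers), 0)
})

test_that("hotspots map to evolutionary groups A and B", {
  expect_equal(assign_group(c("A", "A'", "B")), c("A", "A", "B"))
  expect_error(assign_group("none"), "outside")
})

test_that("the packaged RE table has 24 rows, 13 of them in SINE/Alu", {
  t1 <- alu_fixtures()$table1
  expect_equal(nrow(t1), 24)
  expect_equal(sum(t1$class_family == "SINE/Alu"), 13)
  expect_true(all(nchar(t1$half1) == 10 & nchar(t1$half2) == 10))
  expect_true(all(t1$spacer >= 0))
})

test_that("spacer tables conserve counts and match a simulation truth table", {
  mapped <- data.frame(
    repeat_name = c("AluSg", "AluSg", "AluJo", "AluJo", "AluJo"),
    spacer = c(0L, 0L, 8L, 8L, 14L))
  tab <- build_spacer_table(mapped, c(AluSg = 10L, AluJo = 20L), s_max = 14)
  expect_equal(tab$n_motifs[tab$subfamily == "AluSg"], 2L)
  expect_equal(tab$S8[tab$subfamily == "AluJo"], 2L)
  scols <- paste0("S", 0:14)
  expect_equal(tab$n_motifs, unname(rowSums(tab[, scols])))
  expect_equal(unname(unlist(tab[tab$subfamily == "Total", scols])),
               unname(colSums(tab[tab$subfamily != "Total", scols])))
  empty <- build_spacer_table(mapped[0, ], c(AluSg = 10L), s_max = 14)
  expect_true(all(empty$n_motifs == 0))
  expect_error(build_spacer_table(mapped, c(AluSg = 10L)), "AluJo")
})

test_that("content ratios reproduce the published subfamily percentages", {
  t2 <- alu_fixtures()$table2
  expect_equal(content_ratio(t2, "AluSg1", 0)$rounded, 58)
  expect_equal(content_ratio(t2, "AluSg1", 0)$percent, 100 * 3570 / 6130)
  expect_equal(content_ratio(t2, "AluJo", c(0, 8, 14))$rounded, 35)
  expect_equal(content_ratio(t2, "AluSc", c(0, 8, 14))$rounded, 8)
  expect_equal(content_ratio(t2, "AluY", c(0, 8, 14))$rounded, 3)
  expect_error(content_ratio(t2, "AluZz", 0), "not in table")
})

test_that("published subfamily motif totals are conserved", {
  t2 <- alu_fixtures()$table2
  expect_equal(nrow(t2), 11)
  expect_equal(sum(t2$n_motifs), 393947)
  expect_equal(sum(t2$S0), 99521)
})

test_that("RE collection curation arithmetic", {
  cur <- curate_re_dataset()
  expect_equal(cur$count, 157)
  expect_equal(sum(cur$log$action == "remove"), 2)
  expect_equal(curate_re_dataset(0, character(0), character(0))$count, 0)
  expect_error(curate_re_dataset(1, c("a", "b"), character(0)), "remove")
})
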