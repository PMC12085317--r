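test_that("pileup counts bases, skipping deletions and low-quality calls", {
  reads <- c(
    vapply(1:10, function(i)
      sam_read(paste0("m", i), 1, "20M", strrep("A", 20)), ""),
    sam_read("del1", 1, "5M10D5M", strrep("A", 10)),       # deletion over 6-15
    sam_read("lowq", 1, "20M", strrep("G", 20),
             qual = strrep("!", 20)),                      # base qual 0
    sam_read("lowmapq", 1, "20M", strrep("G", 20), mapq = 5))
  sam <- write_toy_sam(reads)
  pc <- pileup_base_counts(sam, genomic_sites("amp", c(3, 10)),
                           min_base_qual = 20, min_map_qual = 20)
  # pos 3: 10 matched A + del-read A + lowq skipped; lowmapq never counted
  expect_identical(pc$A[1], 11L)
  expect_identical(pc$n_low_qual_skipped[1], 1L)
  expect_identical(pc$n_del_skipped[1], 0L)
  # pos 10: deletion-spanning read excluded and tallied
  expect_identical(pc$A[2], 10L)
  expect_identical(pc$n_del_skipped[2], 1L)
  # conservation: depth + skipped tallies = quality-mapped reads over pos
  expect_identical(pc$depth + pc$n_del_skipped + pc$n_low_qual_skipped,
                   c(12L, 12L))
  # uncovered position: zero counts, not an error
  pc0 <- pileup_base_counts(sam, genomic_sites("amp", 40))
  expect_identical(pc0$depth, 0L)
})

test_that("pileup is invariant to read order in the SAM", {
  set.seed(19)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  spec <- amplicon_sim_spec(ref, rates = setNames(
    0.4, as.character(a_positions(ref)[1])), depth = 40, seed = 20)
  r <- simulate_amplicon_reads(spec, "cdna")
  lines <- readLines(r$sam)
  hdr <- grepl("^@", lines)
  shuf <- write_toy_sam(character(0))  # placeholder path
  writeLines(c(lines[hdr], sample(lines[!hdr])), shuf)
  sites <- genomic_sites("amplicon", a_positions(ref))
  sites2 <- genomic_sites("amplicon", a_positions(ref))
  p1 <- pileup_base_counts(r$sam, sites)
  p2 <- pileup_base_counts(shuf, sites2)
  expect_identical(p1[c("A", "C", "G", "T", "depth")],
                   p2[c("A", "C", "G", "T", "depth")])
})

test_that("editing percent uses the documented denominator", {
  cnt <- data.frame(A = c(70L, 100L, 50L), C = c(0L, 0L, 1L),
                    G = c(30L, 0L, 49L), T = c(0L, 0L, 0L))
  expect_equal(editing_percent(cnt), c(30, 0, 49))
  # A+G denominator mode ignores the stray C call
  expect_equal(editing_percent(cnt, denominator = "ag")[3], 49.49495,
               tolerance = 1e-6)
  cnt0 <- data.frame(A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L)
  expect_true(is.na(editing_percent(cnt0)))
})

test_that("genotype check demands adequate depth and a clean A genotype", {
  g <- data.frame(A = c(500L, 250L, 45L), C = 0L, G = c(2L, 250L, 5L),
                  T = 0L)
  g$depth <- g$A + g$C + g$G + g$T
  ok <- genotype_check(g, max_g_percent = 1, min_depth = 100)
  expect_identical(as.logical(ok), c(TRUE, FALSE, FALSE))
  expect_identical(attr(ok, "reason"),
                   c("ok", "gdna_not_A", "low_coverage"))
})

test_that("discovery scans all A positions and labels predicted vs novel", {
  set.seed(21)
  ref <- paste(rep("ACGTA", 40), collapse = "")  # 200 bp, 80 A positions
  apos <- a_positions(ref)
  edited <- apos[c(5, 20, 40)]
  rates <- setNames(c(0.2, 0.3, 0.5), edited)
  spec <- amplicon_sim_spec(ref, rates = rates, depth = 2000,
                            error_rate = 0, seed = 22)
  cd <- simulate_amplicon_reads(spec, "cdna")
  gd <- simulate_amplicon_reads(spec, "gdna")
  sites <- genomic_sites("amplicon", apos)
  predicted <- format_site_id("amplicon", edited[1:2])  # third is "novel"
  calls <- discover_and_quantify(gd$sam, cd$sam, sites,
                                 predicted_sites = predicted)
  expect_identical(nrow(calls), length(apos))
  expect_identical(calls$site_id[calls$status == "edited"],
                   format_site_id("amplicon", edited))
  expect_identical(calls$predicted[match(format_site_id("amplicon", edited),
                                         calls$site_id)],
                   c(TRUE, TRUE, FALSE))
  # recovered G% within 3 binomial SDs of the injected rates
  got <- calls$g_percent_cdna[match(format_site_id("amplicon", edited),
                                    calls$site_id)]
  tol <- 300 * sqrt(c(0.2, 0.3, 0.5) * c(0.8, 0.7, 0.5) / 2000)
  expect_true(all(abs(got - c(20, 30, 50)) <= tol))
  # gDNA is clean everywhere
  expect_true(all(calls$g_percent_gdna == 0))
  expect_true(all(calls$genotype_ok))
})

test_that("SNP-listed and sub-threshold sites are reported, not dropped", {
  ref <- paste(rep("ACGTA", 20), collapse = "")
  apos <- a_positions(ref)
  rates <- setNames(c(0.3, 0.03, 0.4), apos[c(2, 4, 6)])
  spec <- amplicon_sim_spec(ref, rates = rates, depth = 1000,
                            error_rate = 0, seed = 23)
  cd <- simulate_amplicon_reads(spec, "cdna")
  gd <- simulate_amplicon_reads(spec, "gdna")
  sites <- genomic_sites("amplicon", apos)
  snps <- snp_table("amplicon", apos[6], ref = "A", alt = "G")
  calls <- discover_and_quantify(gd$sam, cd$sam, sites, snps = snps)
  get <- function(p) calls[calls$pos == p, ]
  expect_identical(get(apos[2])$status, "edited")
  # a predicted site editing at 3% (< 5% floor): reported as not_edited
  low <- get(apos[4])
  expect_identical(low$status, "not_edited")
  expect_gt(low$g_percent_cdna, 0)
  # the known A->G SNP is excluded despite strong cDNA G%
  expect_identical(get(apos[6])$status, "excluded_snp")
  expect_true(get(apos[6])$snp_flagged)
  # error-free gDNA-vs-gDNA comparison yields zero edited calls
  gd2 <- simulate_amplicon_reads(
    amplicon_sim_spec(ref, rates = rates, depth = 1000, error_rate = 0,
                      seed = 24), "gdna")
  calls_null <- discover_and_quantify(gd$sam, gd2$sam, sites)
  expect_false(any(calls_null$status == "edited"))
})

test_that("coverage and genotype failures carry explanatory statuses", {
  ref <- strrep("CA", 30)
  apos <- a_positions(ref)
  spec <- amplicon_sim_spec(ref, depth = 50, error_rate = 0, seed = 25)
  cd <- simulate_amplicon_reads(spec, "cdna")
  gd <- simulate_amplicon_reads(spec, "gdna")
  sites <- genomic_sites("amplicon", apos[1:3])
  # depth 50 < default min_depth 100
  calls <- discover_and_quantify(gd$sam, cd$sam, sites)
  expect_true(all(calls$status == "low_coverage"))
  # heterozygous gDNA (half reads G at one site) fails the genotype check
  het_lines <- readLines(gd$sam)
  body <- !grepl("^@", het_lines)
  flip <- which(body)[1:25]
  het_lines[flip] <- vapply(het_lines[flip], function(l) {
    f <- strsplit(l, "\t")[[1]]
    substr(f[10], apos[1], apos[1]) <- "G"
    paste(f, collapse = "\t")
  }, "", USE.NAMES = FALSE)
  het <- write_toy_sam(character(0)); writeLines(het_lines, het)
  calls2 <- discover_and_quantify(het, cd$sam, sites, min_depth = 40)
  expect_identical(calls2$status[1], "excluded_genotype")
  expect_false(calls2$genotype_ok[1])
  # mismatched references refuse to run
  other <- write_toy_sam(sam_read("x", 1, "5M", "ACGTA", ref = "other"),
                         ref_name = "other", ref_len = 60)
  expect_error(discover_and_quantify(other, cd$sam, sites),
               "different references")
})

test_that("condition comparison reports delta always, fold when defined", {
  mk <- function(gp) {
    df <- genomic_sites("amp", c(10, 20, 30))
    df$g_percent_cdna <- gp
    df
  }
  cmp <- compare_editing(mk(c(30, 0, 12)), mk(c(10, 5, 0)))
  expect_equal(cmp$delta, c(20, -5, 12))
  expect_equal(cmp$fold[1], 3)
  expect_identical(cmp$fold[3], Inf)      # zero denominator flagged
  expect_false(cmp$fold_defined[3])
  expect_equal(cmp$delta[3], 12)          # delta still reported
  b <- mk(c(1, 2, 3)); b$site_id[1] <- "amp:99"; b$pos[1] <- 99L
  expect_error(compare_editing(mk(c(1, 2, 3)), b), "amp:99")
})

test_that("knockdown simulation halves editing: deltas negative at true sites", {
  ref <- paste(rep("AACGT", 30), collapse = "")
  apos <- a_positions(ref)
  tgt <- apos[c(10, 25, 40)]
  hi <- setNames(c(0.4, 0.5, 0.6), tgt)
  ctrl <- simulate_amplicon_reads(
    amplicon_sim_spec(ref, rates = hi, depth = 1500, seed = 26), "cdna")
  kd <- simulate_amplicon_reads(
    amplicon_sim_spec(ref, rates = hi / 2, depth = 1500, seed = 27), "cdna")
  gd <- simulate_amplicon_reads(
    amplicon_sim_spec(ref, rates = hi, depth = 1500, seed = 28), "gdna")
  sites <- genomic_sites("amplicon", apos)
  calls_kd <- discover_and_quantify(gd$sam, kd$sam, sites, min_depth = 100)
  calls_ctrl <- discover_and_quantify(gd$sam, ctrl$sam, sites,
                                      min_depth = 100)
  cmp <- compare_editing(calls_kd, calls_ctrl)
  at_tgt <- cmp[match(format_site_id("amplicon", tgt), cmp$site_id), ]
  expect_true(all(at_tgt$delta < 0))
  expect_true(all(at_tgt$fold < 1))
})
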