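# Extent arithmetic, SAM pileup at annotated C targets, matrix assembly.

test_that("editing_extent is the informative-read fraction", {
  expect_equal(editing_extent(900, 100), 0.9)
  expect_equal(editing_extent(83, 17), 0.83)
  expect_true(is.na(editing_extent(0, 0)))
  expect_error(editing_extent(-1, 5), "non-negative")
  # scale-free: multiplying all counts by k leaves the extent unchanged
  expect_equal(editing_extent(12, 30), editing_extent(12 * 7, 30 * 7))
})

test_that("pileup on spaced sites reproduces generated totals exactly", {
  sites <- spaced_sites(8)
  truth <- gen_truth(sites, seed = 12, mutants = "mutA")
  design <- design_from_truth(truth)
  rr <- gen_reads(truth, design, reads_per_site = 250, seed = 13,
                  dir = withr::local_tempdir())
  counts <- pileup_counts(rr$sam, sites)
  # error rate 0, guaranteed anchors, no cross-site read overlap:
  # every site's informative depth is exactly the reads generated for it
  expect_true(all(counts$edited + counts$unedited == 250))
  expect_true(all(counts$other == 0))
  em <- assemble_matrix(counts, design, sites)
  obs <- extents(em)
  tru <- truth$extents[, design$genotype]
  # within 3 binomial standard errors of the truth at every cell
  se3 <- 3 * sqrt(tru * (1 - tru) / 250)
  expect_true(all(abs(obs - tru) <= pmax(se3, 1e-9)))
})

test_that("pileup extents stay unbiased when reads span several sites", {
  # crowded annotation: reads drawn for one site also cover neighbours
  # and must show a correctly sampled editing state there
  sites <- gen_sites(8, 2, 3, seed = 11)
  truth <- gen_truth(sites, seed = 12, mutants = "mutA")
  design <- design_from_truth(truth)
  rr <- gen_reads(truth, design, reads_per_site = 250, seed = 13,
                  dir = withr::local_tempdir())
  counts <- pileup_counts(rr$sam, sites)
  # depth can exceed the per-site read count (neighbouring reads), and
  # the observed extent still tracks the truth
  expect_true(all(counts$edited + counts$unedited >= 250))
  em <- assemble_matrix(counts, design, sites)
  obs <- extents(em)
  tru <- truth$extents[, design$genotype]
  depth <- em$edited + em$unedited
  se3 <- 3.5 * sqrt(tru * (1 - tru) / depth)
  expect_true(all(abs(obs - tru) <= pmax(se3, 1e-9)))
})

test_that("antisense alignments of a strand-specific library are excluded", {
  sites <- gen_sites(5, 0, 2, seed = 21)
  truth <- gen_truth(sites, frac_increased = 0, frac_decreased = 0,
                     seed = 22)
  design <- data.frame(sample_id = "WT_1", genotype = "WT", replicate = 1,
                       role = "wildtype", background = NA_character_)
  rr <- gen_reads(truth, design, reads_per_site = 100, seed = 23,
                  antisense_fraction = 1, dir = withr::local_tempdir())
  counts <- pileup_counts(rr$sam, sites)
  expect_true(all(counts$edited == 0 & counts$unedited == 0 &
                    counts$other == 0))
})

test_that("non-C/T sense bases count as other, outside the denominator", {
  sites <- spaced_sites(10)
  truth <- gen_truth(sites, frac_increased = 0, frac_decreased = 0,
                     seed = 32)
  design <- data.frame(sample_id = "WT_1", genotype = "WT", replicate = 1,
                       role = "wildtype", background = NA_character_)
  rr <- gen_reads(truth, design, reads_per_site = 200, seed = 33,
                  error_rate = 0.2, dir = withr::local_tempdir())
  counts <- pileup_counts(rr$sam, sites)
  expect_true(all(counts$edited + counts$unedited + counts$other == 200))
  expect_gt(sum(counts$other), 0)
})

test_that("reads with a deletion over the site carry no base evidence", {
  sites <- data.frame(
    site_id = "tx1_C50", transcript = "tx1", organelle = "mito",
    complex_group = "complex I", strand = "+", tx_position = 50L,
    genome_position = 50L, stringsAsFactors = FALSE
  )
  recs <- data.frame(
    qname = c("covering", "deleted", "short_anchor"),
    flag = 0L,
    rname = "tx1",
    pos = c(30L, 45L, 49L),
    cigar = c("41M", "4M2D10M", "10M"),
    # covering read has T at offset 21 (position 50)
    seq = c(paste0(strrep("A", 20), "T", strrep("A", 20)),
            strrep("A", 14), strrep("T", 10)),
    stringsAsFactors = FALSE
  )
  sam <- withr::local_tempfile(fileext = ".sam")
  orgedit:::write_sam(recs, c(tx1 = 100L), sam)
  counts <- pileup_counts(setNames(sam, "s1"), sites, min_base_anchor = 3)
  # deleted read: D spans 49-50; short_anchor read starts at 49 (< 3
  # bases left of the site); only the covering read counts
  expect_equal(counts$edited, 1L)
  expect_equal(counts$unedited, 0L)
  expect_equal(counts$other, 0L)
})

test_that("assemble_matrix builds a complete rectangle and flags gaps", {
  study <- toy_study(n_mito = 10, n_plastid = 2, depth = 300, seed = 41)
  long <- as.data.frame(study$matrix)
  em <- assemble_matrix(long, study$design, study$sites)
  expect_equal(dim(em$edited), c(12L, nrow(study$design)))
  expect_identical(em$edited, study$matrix$edited)

  # a missing cell is recorded as zero depth, not dropped
  expect_message(
    em2 <- assemble_matrix(long[-1, ], study$design, study$sites),
    "absent from input")
  missing_site <- long$site_id[1]
  missing_sample <- long$sample_id[1]
  expect_equal(em2$edited[missing_site, missing_sample], 0L)
  expect_equal(attr(em2, "incomplete_cells"), 1L)

  expect_error(assemble_matrix(rbind(long, long[1, ]), study$design),
               "duplicate")
})

test_that("count tables round-trip through TSV exactly", {
  study <- toy_study(n_mito = 6, n_plastid = 0, depth = 150, seed = 51)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(study$matrix, tsv)
  back <- assemble_matrix(read_count_table(tsv), study$design, study$sites)
  expect_identical(back$edited, study$matrix$edited)
  expect_identical(back$unedited, study$matrix$unedited)
})

test_that("wide-format count tables load through a column mapping", {
  wide <- data.frame(
    site_id = c("nad7_C789", "ccmB_C576"),
    WT1_T = c(90L, 10L), WT1_C = c(10L, 190L),
    mut1_T = c(50L, 60L), mut1_C = c(50L, 140L),
    check.names = FALSE
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  long <- read_count_table_wide(
    path,
    mapping = list(WT_1 = c("WT1_T", "WT1_C"),
                   mut_1 = c("mut1_T", "mut1_C")))
  expect_equal(nrow(long), 4L)
  expect_equal(long$edited[long$site_id == "nad7_C789" &
                             long$sample_id == "WT_1"], 90L)
  expect_error(
    read_count_table_wide(path, mapping = list(WT_1 = c("nope", "WT1_C"))),
    "absent")
})
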