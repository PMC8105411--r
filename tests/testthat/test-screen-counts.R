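test_that("guide library validation rejects malformed input", {
  expect_error(guide_library(c("a", "a"), c("G1", "G1"),
                             c("ACGTACGTACGTACGTACGT",
                               "ACGTACGTACGTACGTACGA")),
               "duplicate sgRNA")
  expect_error(guide_library("a", "G1", "ACGTN"), "non-ACGT")
  expect_error(guide_library(c("a", "b"), c("G1", "G1"),
                             c("ACGT", "ACGTA")), "identical length")
})

test_that("library TSV round-trips, including a full-size generated library", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  small <- guide_library(c("a", "b", "c"), c("G1", "G1", "NT"),
                         c("AAAA", "CCCC", "GGGG"),
                         is_nt = c(FALSE, FALSE, TRUE))
  write_guide_library(small, tf)
  expect_equal(nrow(read_guide_library(tf)), 3)
  expect_identical(read_guide_library(tf), small)

  lib <- simulate_guide_library(seed = 4)   # 2930 entries
  write_guide_library(lib, tf)
  expect_identical(read_guide_library(tf), lib)
})

test_that("spacer extraction counts exact matches at any stagger and nothing else", {
  lib <- guide_library(c("g1", "g2"), c("GA", "GB"),
                       c("ACGTACGTACGTACGTACGT", "TTTTCCCCGGGGAAAATTTT"))
  anchor <- "CACCG"
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- c(paste0(anchor, lib$spacer[1], "GGAT"),                 # stagger 0
             paste0("AAA", anchor, lib$spacer[1], "G"),             # stagger 3
             paste0("ACGTAA", anchor, lib$spacer[2], "CT"))         # stagger 6
  writeLines(as.vector(rbind(paste0("@r", 1:3), reads, "+",
                             strrep("I", nchar(reads)))), fq)
  cm <- extract_counts(fq, lib, anchor)
  # brute-force scan oracle: count anchor+spacer substring occurrences
  oracle <- vapply(lib$spacer, function(sp)
    sum(grepl(paste0(anchor, sp), reads, fixed = TRUE)), numeric(1))
  expect_equal(unname(cm$counts[, 1]), unname(oracle))
  expect_equal(unname(cm$counts[, 1]), c(2, 1))
  expect_equal(unname(cm$unmapped), 0)

  # a single mismatch in the spacer sends the read to unmapped
  bad <- sub("^ACGT", "TCGT", lib$spacer[1])
  writeLines(c("@r1", paste0(anchor, bad, "AAAA"), "+", strrep("I", 29)), fq)
  cm2 <- extract_counts(fq, lib, anchor)
  expect_equal(sum(cm2$counts), 0)
  expect_equal(unname(cm2$unmapped), 1)
})

test_that("extraction handles empty files and conserves reads", {
  lib <- tiny_library()
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  cm <- extract_counts(fq, lib)
  expect_true(all(cm$counts == 0))
  expect_equal(unname(cm$unmapped), 0)
  expect_error(extract_counts("no/such/file.fastq", lib), "cannot read")

  # generated FASTQ plus junk reads: mapped + unmapped == total reads
  write_screen_fastq(fq, lib, reads_per_guide = 3L, seed = 2)
  junk <- c("@junk", strrep("A", 40), "+", strrep("I", 40))
  cat(paste(junk, collapse = "\n"), "\n", sep = "", file = fq, append = TRUE)
  cm <- extract_counts(fq, lib)
  expect_equal(sum(cm$counts) + unname(cm$unmapped), 3 * nrow(lib) + 1)
  expect_true(all(cm$counts == 3L))
})

test_that("median-ratio size factors match hand computation and preserve ranks", {
  a <- c(10, 20, 40, 80, 100)
  mat <- cbind(s1 = a, s2 = a)
  rownames(mat) <- paste0("g", 1:5)
  cm <- count_matrix(mat, rep("G1", 5))
  nm <- median_ratio_normalize(cm, min_guides = 1)
  expect_equal(unname(nm$size_factors), c(1, 1))

  # sample B = 2 x sample A: hand oracle via the defining formula
  mat2 <- cbind(s1 = a, s2 = 2 * a)
  cm2 <- count_matrix(`rownames<-`(mat2, paste0("g", 1:5)), rep("G1", 5))
  nm2 <- median_ratio_normalize(cm2, min_guides = 1)
  geo <- sqrt(a * 2 * a)
  oracle <- c(median(a / geo), median(2 * a / geo))
  expect_equal(unname(nm2$size_factors), oracle)
  expect_equal(nm2$size_factors[[2]] / nm2$size_factors[[1]], 2)
  expect_equal(nm2$normalized[, "s1"], nm2$normalized[, "s2"])

  # rank preservation within sample
  cfg <- screen_sim_config(n_genes = 30, seed = 2)
  scr <- simulate_screen(cfg)
  nm3 <- median_ratio_normalize(scr)
  for (j in 1:2)
    expect_equal(order(nm3$normalized[, j]), order(scr$counts[, j]))

  expect_error(median_ratio_normalize(
    count_matrix(mat[, 1, drop = FALSE], rep("G1", 5))), "2 samples")
  matz <- cbind(s1 = a, s2 = rep(0, 5))
  expect_error(median_ratio_normalize(
    count_matrix(`rownames<-`(matz, paste0("g", 1:5)), rep("G1", 5))),
    "all-zero")
})

test_that("library QC reports detection and central fold difference", {
  mk <- function(x) count_matrix(matrix(x, ncol = 1,
                                        dimnames = list(paste0("g",
                                                               seq_along(x)),
                                                        "pool")),
                                 rep("G1", length(x)))
  qc <- library_qc(mk(rep(10, 50)))
  expect_equal(qc$percent_detected, 100)
  expect_equal(qc$quantile_fold_difference, 1)

  x <- 1:100
  qc2 <- library_qc(mk(x))
  q <- quantile(x, c(0.1, 0.9), names = FALSE)   # direct quantile oracle
  expect_equal(qc2$quantile_fold_difference, q[2] / q[1])

  x3 <- rep(10, 2930); x3[7] <- 0
  qc3 <- library_qc(mk(x3))
  expect_equal(qc3$percent_detected, 100 * 2929 / 2930)
  expect_equal(qc3$zero_count_guides, "g7")

  # generator property: fold difference tends to 1 as dispersion grows
  qc_tight <- library_qc(count_matrix(
    simulate_screen(screen_sim_config(n_genes = 100, dispersion = 1e4,
                                      abundance_sdlog = 0.01,
                                      seed = 5))$counts[, 1, drop = FALSE],
    rep("G", 650)))
  qc_loose <- library_qc(count_matrix(
    simulate_screen(screen_sim_config(n_genes = 100, dispersion = 2,
                                      abundance_sdlog = 0.01,
                                      seed = 5))$counts[, 1, drop = FALSE],
    rep("G", 650)))
  expect_lt(qc_tight$quantile_fold_difference,
            qc_loose$quantile_fold_difference)
  expect_lt(qc_tight$quantile_fold_difference, 1.2)
})

test_that("coverage and titer arithmetic follow their defining formulas", {
  expect_lt(abs(coverage_per_guide(10, 7.5, 2930) - 455), 1)
  expect_equal(coverage_per_guide(20, 7.5, 2930),
               2 * coverage_per_guide(10, 7.5, 2930))
  expect_error(coverage_per_guide(0, 7.5, 2930), "positive")

  expect_equal(viral_titer(0.5, 1e6, 50), 1e7)
  expect_equal(viral_titer(0, 1e6, 50), 0)
  expect_equal(viral_titer(0.5, 1e6, 25), 2 * viral_titer(0.5, 1e6, 50))
  expect_error(viral_titer(0.5, 1e6, 0), "positive")
})

test_that("count matrices round-trip through TSV with sample metadata", {
  scr <- simulate_screen(screen_sim_config(n_genes = 10, seed = 6))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(scr, tf)
  back <- read_count_matrix(tf)
  expect_equal(back$counts, scr$counts)
  expect_equal(back$samples$condition, scr$samples$condition)
  expect_equal(back$samples$day, as.numeric(scr$samples$day))
})
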