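# Spacer extraction, counting, replicate pooling, median-ratio normalization.

SCHEMA <- amplicon_schema("ACGTTGGATCCA", "TTCAGACGTGTA")

test_that("spacer extraction handles the elementary cases", {
  sp <- strrep("ACGT", 5)
  read <- paste0(SCHEMA$upstream, sp, SCHEMA$downstream)
  expect_identical(extract_spacers(read, SCHEMA), sp)
  # reverse-complemented read recovers the same spacer
  expect_identical(extract_spacers(rc_string(read), SCHEMA), sp)
  # missing upstream anchor -> NA
  expect_true(is.na(extract_spacers(paste0(sp, SCHEMA$downstream), SCHEMA)))
  # anchors not 20 nt apart -> NA
  bad <- paste0(SCHEMA$upstream, substr(sp, 1, 19), SCHEMA$downstream)
  expect_true(is.na(extract_spacers(bad, SCHEMA)))
  # one mismatch in the upstream anchor fails at 0 but passes at 1
  up1 <- paste0("T", substr(SCHEMA$upstream, 2, 12))
  r1 <- paste0(up1, sp, SCHEMA$downstream)
  expect_true(is.na(extract_spacers(r1, SCHEMA)))
  expect_identical(extract_spacers(r1, SCHEMA, max_mismatch = 1L), sp)
})

test_that("simulated error-free reads are recovered 100% with exact composition", {
  set.seed(31)
  spacers <- vapply(1:50, function(i) random_dna(20, gc = 0.5), "")
  counts <- sample(50:400, 50, replace = TRUE)
  cm <- count_matrix(matrix(as.integer(counts), ncol = 1,
                            dimnames = list(spacers, "s1")),
                     data.frame(sample = "s1", condition = "mock", replicate = "1"))
  sheet <- simulate_fastq(cm, SCHEMA, tempfile("fq"), seed = 2)
  got <- count_reads(sheet, spacers, SCHEMA)
  expect_equal(unname(got$counts[spacers, 1]), counts)
  expect_equal(unname(got$unassigned), 0L)
  expect_equal(sum(got$counts) + sum(got$unassigned), sum(counts))
})

test_that("counting conserves reads and ignores read order", {
  set.seed(32)
  spacers <- vapply(1:20, function(i) random_dna(20, gc = 0.5), "")
  lib_spacers <- spacers[1:15]  # 5 spacers are not in the library
  counts <- sample(10:50, 20, replace = TRUE)
  cm <- count_matrix(matrix(as.integer(counts), ncol = 1,
                            dimnames = list(spacers, "s1")),
                     data.frame(sample = "s1", condition = "mock", replicate = "1"))
  dir1 <- tempfile("fq")
  sheet <- simulate_fastq(cm, SCHEMA, dir1, seed = 5)
  got <- count_reads(sheet, lib_spacers, SCHEMA)
  expect_equal(sum(got$counts) + sum(got$unassigned), sum(counts))
  expect_equal(unname(got$unassigned), sum(counts[16:20]))
  # shuffle the FASTQ and recount: identical matrix
  reads <- readLines(sheet$fastq[1])
  rec <- matrix(reads, nrow = 4)
  set.seed(99)
  rec <- rec[, sample(ncol(rec))]
  writeLines(as.vector(rec), sheet$fastq[1])
  got2 <- count_reads(sheet, lib_spacers, SCHEMA)
  expect_identical(got2$counts, got$counts)
  expect_identical(got2$unassigned, got$unassigned)
})

test_that("empty samples give an all-zero column with a warning", {
  fq <- tempfile(fileext = ".fastq")
  file.create(fq)
  sheet <- data.frame(sample = "e", condition = "mock", replicate = "1", fastq = fq)
  expect_warning(got <- count_reads(sheet, c("ACGTACGTACGTACGTACGT"), SCHEMA),
                 "no reads")
  expect_equal(sum(got$counts), 0L)
  expect_equal(unname(got$unassigned), 0L)
})

test_that("replicate pooling sums raw counts per condition", {
  m <- matrix(1:12, nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  cm <- count_matrix(m, data.frame(sample = paste0("s", 1:4),
                                   condition = c("x", "x", "y", "y"),
                                   replicate = c("1", "2", "1", "2")),
                     unassigned = stats::setNames(c(1L, 2L, 3L, 4L), paste0("s", 1:4)))
  p <- pool_replicates(cm)
  expect_equal(unname(p$counts[, "x"]), unname(rowSums(m[, 1:2])))
  expect_equal(unname(p$counts[, "y"]), unname(rowSums(m[, 3:4])))
  expect_equal(unname(p$unassigned), c(3, 7))
  # one replicate -> identity; duplicated replicate -> doubled column
  one <- count_matrix(m[, 1, drop = FALSE],
                      data.frame(sample = "s1", condition = "x", replicate = "1"))
  expect_equal(pool_replicates(one)$counts[, "x"], m[, 1])
  two <- count_matrix(cbind(s1 = m[, 1], s2 = m[, 1]),
                      data.frame(sample = c("s1", "s2"), condition = "x",
                                 replicate = c("1", "2")))
  expect_equal(unname(pool_replicates(two)$counts[, "x"]), unname(2L * m[, 1]))
})

test_that("median-ratio size factors follow the definition", {
  # identical columns -> both size factors 1
  m <- matrix(c(5L, 10L, 20L, 5L, 10L, 20L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cm <- count_matrix(m, data.frame(sample = c("s1", "s2"),
                                   condition = c("x", "y"), replicate = "1"))
  nn <- median_ratio_normalize(cm)
  expect_equal(unname(nn$size_factors), c(1, 1))
  # tripling one column triples its size factor relative to the other
  m3 <- m; m3[, 2] <- 3L * m3[, 2]
  cm3 <- count_matrix(m3, cm$samples)
  sf <- median_ratio_normalize(cm3)$size_factors
  expect_equal(unname(sf[2] / sf[1]), 3)
  # depth removal: scaling one of m samples by k rescales every normalized
  # column by the common factor k^(1/m) (the geometric-mean reference moves),
  # so all between-sample ratios — the quantities the contrasts consume —
  # are exactly unchanged
  n1 <- median_ratio_normalize(cm)$matrix
  n3 <- median_ratio_normalize(cm3)$matrix
  expect_equal(n3 / n3[1, 1], n1 / n1[1, 1], tolerance = 1e-9)
  expect_equal(unname(n3[1, 1] / n1[1, 1]), sqrt(3), tolerance = 1e-9)
})

test_that("size factors match a hand computation on a 5x3 matrix", {
  m <- matrix(c(10L, 20L, 40L, 5L, 100L,
                20L, 40L, 80L, 10L, 200L,
                10L, 10L, 40L, 20L, 100L), ncol = 3,
              dimnames = list(letters[1:5], c("s1", "s2", "s3")))
  # hand computation of the definition, row by row
  g <- apply(m, 1, function(r) prod(r)^(1 / 3))
  sf_hand <- apply(m, 2, function(col) median(col / g))
  cm <- count_matrix(m, data.frame(sample = colnames(m), condition = colnames(m),
                                   replicate = "1"))
  nn <- median_ratio_normalize(cm)
  expect_equal(unname(nn$size_factors), unname(sf_hand), tolerance = 1e-12)
  expect_equal(nn$matrix, sweep(m, 2, sf_hand, "/"), tolerance = 1e-12)
})

test_that("size factors agree with the DESeq reference implementation", {
  set.seed(12)
  # odd guide count: the median is a single element, so the value-scale and
  # log-scale medians coincide exactly
  m <- matrix(rpois(303, 60) + 1L, ncol = 3,
              dimnames = list(sprintf("g%03d", 1:101), c("s1", "s2", "s3")))
  cm <- count_matrix(m, data.frame(sample = colnames(m), condition = colnames(m),
                                   replicate = "1"))
  sf <- median_ratio_normalize(cm)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("normalization refuses a matrix with no all-nonzero guide", {
  m <- matrix(c(0L, 5L, 5L, 0L), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(m, data.frame(sample = c("s1", "s2"), condition = c("x", "y"),
                                   replicate = "1"))
  expect_error(median_ratio_normalize(cm), "filter")
})

test_that("count matrices round-trip through TSV", {
  set.seed(3)
  m <- matrix(rpois(40, 30), ncol = 4,
              dimnames = list(sprintf("sp%02d", 1:10), paste0("s", 1:4)))
  storage.mode(m) <- "integer"
  cm <- count_matrix(m, data.frame(sample = paste0("s", 1:4),
                                   condition = c("mock", "mock", "Ci", "Ci"),
                                   replicate = c("1", "2", "1", "2")),
                     stats::setNames(11:14, paste0("s", 1:4)))
  fp <- tempfile(fileext = ".tsv")
  write_counts(cm, fp)
  back <- read_counts(fp)
  expect_identical(back$counts, cm$counts)
  expect_equal(back$samples, cm$samples)
  expect_equal(back$unassigned, stats::setNames(as.integer(cm$unassigned),
                                                names(cm$unassigned)))
})
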