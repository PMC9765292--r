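# PAM scanning, strand-retention rules, library statistics and I/O.

test_that("enumeration finds nothing where no candidate can exist", {
  polyA <- annotated_genome("a", strrep("A", 200), FALSE, NULL)
  expect_equal(nrow(enumerate_candidates(polyA)), 0L)
  short <- annotated_genome("s", strrep("ACG", 7), FALSE, NULL)  # 21 nt
  expect_equal(nrow(enumerate_candidates(short)), 0L)
  short22 <- annotated_genome("s", paste0(strrep("A", 19), "TGG"), FALSE, NULL)
  expect_equal(nrow(enumerate_candidates(short22)), 0L)  # window cannot fit
})

test_that("a 23-nt linear genome with a terminal NGG yields exactly one + candidate", {
  s <- paste0(strrep("A", 20), "TGG")
  g <- annotated_genome("g", s, FALSE, NULL)
  cand <- enumerate_candidates(g)
  plus <- cand[cand$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 0L)
  expect_equal(plus$spacer, strrep("A", 20))
  expect_equal(plus$pam, "TGG")
})

test_that("windows containing N are skipped", {
  s <- paste0(strrep("A", 9), "N", strrep("A", 10), "TGG")
  g <- annotated_genome("g", s, FALSE, NULL)
  expect_equal(nrow(enumerate_candidates(g)), 0L)
})

test_that("candidate enumeration equals the sliding-window oracle", {
  set.seed(101)
  for (i in 1:25) {
    g <- random_annotated_genome(L = sample(150:600, 1),
                                 n_frac = sample(c(0, 0.01), 1))
    cand <- enumerate_candidates(g)
    orc <- oracle_design(g)  # all windows, including ones later rejected
    key <- function(df) sort(paste(df$strand, df$start, df$spacer, df$pam))
    expect_identical(key(cand), key(orc))
  }
})

test_that("circular genomes include origin-spanning candidates", {
  # place a PAM so the spacer wraps the origin
  s <- paste0("GG", strrep("A", 75), strrep("C", 23))
  L <- nchar(s)
  circ <- annotated_genome("c", s, TRUE, NULL)
  lin <- annotated_genome("c", s, FALSE, NULL)
  cand_c <- enumerate_candidates(circ)
  cand_l <- enumerate_candidates(lin)
  expect_gt(nrow(cand_c), nrow(cand_l))
  wrapping <- cand_c[cand_c$strand == "+" & cand_c$start > L - 23, ]
  expect_gt(nrow(wrapping), 0L)
  # each re-extracts correctly across the origin
  got <- extract_protospacer(circ, wrapping$strand, wrapping$start)
  expect_identical(got, paste0(wrapping$spacer, wrapping$pam))
})

test_that("CDS strand rule follows base-pairing with the coding strand", {
  # 100-bp + strand CDS covering the whole toy genome except margins
  set.seed(5)
  core <- random_dna(100, gc = 0.5)
  s <- paste0(strrep("A", 25), core, strrep("A", 25))
  feats <- data.frame(locus_tag = "cds1", gene_name = NA, kind = "CDS",
                      strand = "+", start = 25L, end = 125L)
  g <- annotated_genome("t", s, FALSE, feats)
  lib <- design_guides(g)
  inside <- vapply(seq_len(nrow(lib$guides)), function(i) {
    fp <- if (lib$guides$strand[i] == "+") lib$guides$start[i] + 0:19
          else lib$guides$start[i] - 0:19
    any(fp >= 25 & fp < 125)
  }, logical(1))
  hit <- lib$guides[inside & lib$guides$target_class == "cds_rule_pass", ]
  expect_gt(nrow(hit), 0L)
  # all retained guides inside a + strand CDS have - strand protospacers
  expect_true(all(hit$strand == "-"))
  # and each spacer is the reverse complement of the coding-strand segment,
  # i.e. base-pairs with the coding (nontemplate) strand
  for (i in seq_len(nrow(hit))) {
    seg <- substr(s, hit$start[i] - 19 + 1, hit$start[i] + 1)  # + strand segment
    expect_identical(hit$spacer[i], rc_string(seg))
  }
  # flipping the CDS to the - strand flips which protospacers pass
  feats$strand <- "-"
  g2 <- annotated_genome("t", s, FALSE, feats)
  lib2 <- design_guides(g2)
  inside2 <- vapply(seq_len(nrow(lib2$guides)), function(i) {
    fp <- if (lib2$guides$strand[i] == "+") lib2$guides$start[i] + 0:19
          else lib2$guides$start[i] - 0:19
    any(fp >= 25 & fp < 125)
  }, logical(1))
  hit2 <- lib2$guides[inside2 & lib2$guides$target_class == "cds_rule_pass", ]
  expect_true(all(hit2$strand == "+"))
})

test_that("wholly intergenic candidates are retained on either strand", {
  set.seed(9)
  s <- random_dna(300, gc = 0.5)
  feats <- data.frame(locus_tag = "c1", gene_name = NA, kind = "CDS",
                      strand = "+", start = 0L, end = 50L)
  g <- annotated_genome("t", s, FALSE, feats)
  lib <- design_guides(g)
  ig <- lib$guides[lib$guides$target_class == "intergenic", ]
  expect_setequal(unique(ig$strand), c("+", "-"))
  expect_true(all(ig$targets == "."))
})

test_that("rRNA/tRNA loci follow the configured rule", {
  set.seed(11)
  s <- random_dna(200, gc = 0.5)
  feats <- data.frame(locus_tag = "r1", gene_name = NA, kind = "rRNA",
                      strand = "+", start = 0L, end = 200L)
  g <- annotated_genome("t", s, FALSE, feats)
  cds_like <- design_guides(g, rna_rule = "cds")
  dual <- design_guides(g, rna_rule = "both_strands")
  expect_true(all(cds_like$guides$strand == "-"))
  expect_setequal(unique(dual$guides$strand), c("+", "-"))
  expect_gt(nrow(dual$guides), nrow(cds_like$guides))
})

test_that("retained libraries equal the brute-force rule oracle", {
  set.seed(202)
  for (i in 1:40) {
    g <- random_annotated_genome()
    lib <- design_guides(g)
    orc <- oracle_design(g)
    orc <- orc[orc$target_class != "rejected", , drop = FALSE]
    expect_identical(
      guide_key(lib$guides[c("strand", "start", "spacer", "pam",
                             "target_class", "targets")]),
      guide_key(orc))
  }
})

test_that("every retained guide re-extracts from its recorded locus", {
  set.seed(77)
  g <- random_annotated_genome(L = 800, n_feat = 4, circular = TRUE)
  lib <- design_guides(g)
  got <- extract_protospacer(g, lib$guides$strand, lib$guides$start)
  expect_identical(got, paste0(lib$guides$spacer, lib$guides$pam))
})

test_that("reverse-complement symmetry holds up to coordinate reflection", {
  set.seed(303)
  for (i in 1:5) {
    g <- random_annotated_genome(L = 600, n_feat = 4)
    lib <- design_guides(g)
    f <- g$features
    rcf <- data.frame(locus_tag = f$locus_tag, gene_name = f$gene_name,
                      kind = f$kind,
                      strand = ifelse(f$strand == "+", "-", "+"),
                      start = g$length - f$end, end = g$length - f$start)
    grc <- annotated_genome(g$id, rc_string(g$sequence), g$circular, rcf)
    librc <- design_guides(grc)
    reflected <- data.frame(
      strand = ifelse(lib$guides$strand == "+", "-", "+"),
      start = g$length - 1L - lib$guides$start,
      spacer = lib$guides$spacer, pam = lib$guides$pam,
      target_class = lib$guides$target_class, targets = lib$guides$targets)
    expect_identical(
      guide_key(librc$guides[names(reflected)]), guide_key(reflected))
  }
})

test_that("duplicate spacers are flagged multi_target with copy counts", {
  # two identical 60-bp repeats guarantee duplicated spacers
  set.seed(4)
  unit <- random_dna(60, gc = 0.6)
  s <- paste0(unit, random_dna(50, gc = 0.5), unit)
  g <- annotated_genome("rep", s, FALSE, NULL)
  lib <- design_guides(g)
  dup <- lib$guides[lib$guides$multi_target, ]
  expect_gt(nrow(dup), 0L)
  expect_true(all(dup$copies > 1L))
  tb <- table(lib$guides$spacer)
  expect_equal(unname(lib$guides$copies), as.integer(tb[lib$guides$spacer]))
  expect_identical(lib$guides$multi_target, lib$guides$copies > 1L)
})

test_that("library statistics follow their definitions", {
  genes <- sprintf("g%02d", 1:10)
  lib <- simulate_library(genes, guides_per_gene = 5, fixed_guides = TRUE, seed = 1)
  # 1 guide on a 100-bp genome: spacing 100
  one <- lib
  one$guides <- one$guides[1, , drop = FALSE]
  gfake <- annotated_genome("f", random_dna(100), FALSE, NULL)
  expect_equal(library_stats(one, gfake)$mean_spacing_bp, 100)
  # empty library errors explicitly
  none <- lib
  none$guides <- none$guides[0, , drop = FALSE]
  expect_error(library_stats(none, gfake), "empty")
  # per-CDS counts {0..9} -> median 4.5 (midpoint convention, zeros included)
  set.seed(8)
  counts <- 0:9
  feats <- data.frame(locus_tag = genes, gene_name = NA, kind = "CDS",
                      strand = "+", start = (0:9) * 10L, end = (0:9) * 10L + 9L)
  g10 <- annotated_genome("m", random_dna(200), FALSE, feats)
  lib2 <- simulate_library(genes, guides_per_gene = 1, fixed_guides = TRUE, seed = 2)
  keep <- unlist(lapply(seq_along(genes), function(i) rep(i, counts[i])))
  lib2$guides <- do.call(rbind, lapply(seq_along(genes), function(i) {
    rows <- lib2$guides[lib2$guides$targets == paste0(genes[i], ":20"), , drop = FALSE]
    rows[rep(1, counts[i]), , drop = FALSE]
  }))
  lib2$guides$spacer <- vapply(seq_len(nrow(lib2$guides)), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), "")
  st <- library_stats(lib2, g10)
  expect_equal(st$median_guides_per_cds, 4.5)
  expect_equal(st$n_guides, sum(counts))
})

test_that("library TSV and BED round-trip losslessly", {
  g <- simulate_genome(n_genes = 5, seed = 21)
  lib <- design_guides(g)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_library(lib, tsv, bed)
  back <- read_library(tsv)
  expect_equal(back$guides, lib$guides)
  expect_equal(back$genome_length, lib$genome_length)
  expect_equal(back$rna_rule, lib$rna_rule)
  # BED intervals are the 0-based half-open protospacer footprints
  bd <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_true(all(bd$V3 > bd$V2))
  expect_true(all(bd$V2 >= 0 & bd$V3 <= g$length))
  one <- lib$guides[match(bd$V4[1], lib$guides$spacer), ]
  lo <- if (one$strand == "+") one$start else one$start - 19L
  expect_true(any(bd$V2[bd$V4 == bd$V4[1]] == lo %% g$length))
  # empty library -> header-only TSV
  empty <- lib; empty$guides <- lib$guides[0, , drop = FALSE]
  tsv2 <- tempfile(fileext = ".tsv")
  write_library(empty, tsv2)
  expect_equal(nrow(read_library(tsv2)$guides), 0L)
})
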