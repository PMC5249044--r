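test_that("coordinates follow the 1-based-in, 0-based-internal convention", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "g.fasta"); tb <- file.path(tmp, "g.tsv")
  set.seed(1)
  s <- random_dna(100)
  writeLines(c(">G1", s), fa)
  writeLines(c("label\tkind\tstart\tend\tstrand",
               "cox1\tPCG\t1\t30\t+"), tb)
  g <- read_feature_table(fa, tb)
  expect_equal(g$features$start, 0L)
  expect_equal(g$features$end, 30L)
  expect_identical(gene_sequence(g, "cox1"), substr(s, 1, 30))

  # out-of-range coordinate is rejected
  writeLines(c("label\tkind\tstart\tend\tstrand",
               "cox1\tPCG\t1\t110\t+"), tb)
  expect_error(read_feature_table(fa, tb), "outside")

  # duplicate (label, copy_index) is rejected
  writeLines(c("label\tkind\tstart\tend\tstrand",
               "cox1\tPCG\t1\t30\t+", "cox1\tPCG\t31\t60\t+"), tb)
  expect_error(read_feature_table(fa, tb), "duplicate")
})

test_that("origin-spanning features extract suffix+prefix on circular genomes", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "g.fasta"); tb <- file.path(tmp, "g.tsv")
  set.seed(2)
  s <- random_dna(100)
  writeLines(c(">G1", s), fa)
  writeLines(c("label\tkind\tstart\tend\tstrand",
               "CR\tCR\t95\t10\t+"), tb)
  g <- read_feature_table(fa, tb)
  # 1-based inclusive 95..100 plus 1..10 = 16 b.p.
  expect_identical(gene_sequence(g, "CR"),
                   paste0(substr(s, 95, 100), substr(s, 1, 10)))
  expect_equal(nchar(gene_sequence(g, "CR")), 16L)

  # rotated-genome oracle: rotate so the feature becomes contiguous
  rot <- paste0(substr(s, 51, 100), substr(s, 1, 50))
  g_rot <- mito_genome("G1r", rot, data.frame(
    label = "CR", kind = "CR", start = 44L, end = 60L, strand = "+",
    stringsAsFactors = FALSE))
  expect_identical(gene_sequence(g_rot, "CR"), gene_sequence(g, "CR"))

  # wrap-around is an error on a linear molecule
  expect_error(read_feature_table(fa, tb, circular = FALSE), "linear")
})

test_that("minus-strand extraction reverse complements", {
  g <- mito_genome("M", "ATGCATGCAT", data.frame(
    label = "trnK", kind = "tRNA", start = 0L, end = 4L, strand = "-",
    stringsAsFactors = FALSE))
  expect_identical(gene_sequence(g, "trnK"), "GCAT")
})

test_that("GenBank and feature-table round trips preserve all feature tuples", {
  spec <- synthetic_spec(seed = 11,
    trna_duplications = list(list(label = "trnP", identity = 78.7,
                                  donor = "trnL1")),
    spacers = c(nad5 = 120L))
  g <- generate_genome(spec)$genome
  tmp <- withr::local_tempdir()
  gb <- file.path(tmp, "g.gb")
  write_genbank(g, gb)
  g2 <- read_genbank(gb)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$features, g$features)
  expect_true(g2$circular)
  expect_identical(g2$id, g$id)

  fa <- file.path(tmp, "g.fasta"); tb <- file.path(tmp, "g.tsv")
  write_feature_table(g, fa, tb)
  g3 <- read_feature_table(fa, tb)
  expect_identical(g3$sequence, g$sequence)
  expect_identical(g3$features, g$features)
})

test_that("malformed GenBank input is reported with a location", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.gb")
  writeLines(c("LOCUS       X 10 bp DNA circular",
               "FEATURES             Location/Qualifiers",
               "     CDS             3..x7",
               '                     /gene="cox1"',
               "ORIGIN", "        1 acgtacgtac", "//"), p)
  expect_error(read_genbank(p), "line 3")
  writeLines("not genbank at all", p)
  expect_error(read_genbank(p), "LOCUS")
})

test_that("extraction is invariant under genome reflection", {
  spec <- synthetic_spec(seed = 12)
  g <- generate_genome(spec)$genome
  L <- g$length
  fe <- g$features
  refl <- fe
  refl$start <- (L - fe$end) %% L
  refl$end <- L - fe$start
  refl$end[refl$end == 0L] <- L
  refl$strand <- ifelse(fe$strand == "+", "-", "+")
  g_ref <- mito_genome(g$id, revcomp_chr(g$sequence), refl, circular = TRUE)
  for (lab in c("cox1", "nad5", "rrnS", "trnQ", "CR")) {
    expect_identical(gene_sequence(g_ref, lab), gene_sequence(g, lab),
                     label = lab)
  }
  # wrap-around case via the toy genome
  tg <- toy_genome()
  refl2 <- tg$features
  refl2$start <- (tg$length - tg$features$end) %% tg$length
  refl2$end <- tg$length - tg$features$start
  refl2$end[refl2$end == 0L] <- tg$length
  refl2$strand <- ifelse(tg$features$strand == "+", "-", "+")
  tg_ref <- mito_genome("TOYr", revcomp_chr(tg$sequence), refl2,
                        circular = TRUE)
  expect_identical(gene_sequence(tg_ref, "CR"), gene_sequence(tg, "CR"))
})

test_that("overlap-free annotation tiles the genome", {
  g <- generate_genome(synthetic_spec(seed = 13))$genome
  spans <- ifelse(g$features$start < g$features$end,
                  g$features$end - g$features$start,
                  g$length - g$features$start + g$features$end)
  expect_equal(sum(spans), g$length)

  g2 <- generate_genome(synthetic_spec(seed = 13,
                                       spacers = c(cox1 = 50L,
                                                   nad4 = 75L)))$genome
  spans2 <- g2$features$end - g2$features$start
  nc <- noncoding_regions(g2)
  expect_equal(sum(spans2) + sum(nc$length), g2$length)
})

test_that("gene labels canonicalize across deposited-record synonyms", {
  expect_identical(
    canonical_label(c("COI", "ND4L", "12S rRNA", "tRNA-Leu(UUR)", "CYTB",
                      "D-loop", "tRNA-Ser(AGN)")),
    c("cox1", "nad4l", "rrnS", "trnL2", "cytB", "CR", "trnS1"))
  expect_warning(out <- canonical_label("mystery9"), "unrecognized")
  expect_identical(out, "mystery9")
})
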