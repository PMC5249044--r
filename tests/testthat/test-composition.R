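test_that("skew and AT% formulas give exact hand-computable values", {
  expect_equal(composition_stats("AATT")$at_skew, 0)
  set.seed(5)
  s <- paste(sample(c(rep("A", 60), rep("T", 40), rep("G", 25),
                      rep("C", 75))), collapse = "")
  cs <- composition_stats(s)
  expect_equal(cs$at_skew, 0.2)
  expect_equal(cs$gc_skew, -0.5)
  expect_equal(cs$at_percent, 50)
  expect_error(composition_stats("NNNN"), "all-N")
  expect_error(composition_stats(""), "all-N|empty")
  # skew undefined when its denominator is empty
  expect_true(is.na(composition_stats("AATT")$gc_skew))
})

test_that("skews are antisymmetric under reverse complement and bounded", {
  set.seed(42)
  for (i in 1:30) {
    s <- random_dna(sample(50:400, 1), at = runif(1, 0.2, 0.8),
                    with_n = if (i %% 5 == 0) 0.05 else 0)
    a <- composition_stats(s)
    b <- composition_stats(revcomp_chr(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
    expect_true(abs(a$at_skew) <= 1 && abs(a$gc_skew) <= 1)
    expect_true(a$at_percent >= 0 && a$at_percent <= 100)
    # AT% + GC% == 100 over counted bases
    gc_pct <- 100 * (a$n_G + a$n_C) / a$length
    expect_equal(a$at_percent + gc_pct, 100)
  }
})

test_that("sliding windows cover the sequence as specified", {
  p <- sliding_window_profile(strrep("A", 200), 100, 10, "at_skew")
  expect_true(all(p$values == 1))
  expect_length(p$values, (200 - 100) / 10 + 1)
  set.seed(7)
  s <- random_dna(537)
  p2 <- sliding_window_profile(s, 100, 13, "at_percent")
  expect_length(p2$values, floor((537 - 100) / 13) + 1)
  expect_true(all(diff(p2$positions) == 13))
  # circular: every start below L is used, windows wrap the origin
  p3 <- sliding_window_profile(s, 100, 13, "at_percent", circular = TRUE)
  expect_length(p3$values, length(seq.int(0, 536, by = 13)))
  wrapped <- paste0(substr(s, 521, 537), substr(s, 1, 83))
  expect_equal(p3$values[41], composition_stats(wrapped)$at_percent)
  expect_error(sliding_window_profile("ACGT", 10, 1), "window")
})

test_that("window AT% averages back to the global AT%", {
  set.seed(8)
  s <- random_dna(600, at = 0.63)
  p <- sliding_window_profile(s, 100, 100, "at_percent")  # non-overlapping
  expect_equal(mean(p$values), composition_stats(s)$at_percent)
})

test_that("codon-position AT pools positions correctly", {
  expect_equal(unname(at_by_codon_position("ATGGCCTAA")["pos1"]),
               100 * 2 / 3)  # A, G, T at first positions
  # length-weighted mean over positions equals the overall CDS AT%
  set.seed(9)
  cds <- vapply(1:5, function(i) random_dna(3 * sample(40:80, 1)),
                character(1))
  at3 <- at_by_codon_position(cds, warn_internal_stops = FALSE)
  expect_equal(mean(at3),
               composition_stats(paste(cds, collapse = ""))$at_percent)
  # trailing partial codon excluded
  expect_equal(at_by_codon_position("ATGGCCTAATT", warn_internal_stops = FALSE),
               at_by_codon_position("ATGGCCTAA", warn_internal_stops = FALSE))
  expect_warning(at_by_codon_position("ATGTAACCCTAA"), "internal stop")
})

test_that("generator codon-position AT targets are recovered at genome scale", {
  spec <- synthetic_spec(seed = 21, at_codon = c(40, 50, 80))
  g <- generate_genome(spec)$genome
  at3 <- at_by_codon_position(unname(gene_sequences(g, "PCG")),
                              warn_internal_stops = FALSE)
  expect_equal(unname(at3), c(40, 50, 80), tolerance = 2 / 50)
})

test_that("partition statistics pool categories on coding sense", {
  # genome tiled by a single PCG: PCG AT% equals whole-genome AT%
  set.seed(10)
  s <- random_dna(300, at = 0.66)
  g1 <- mito_genome("ONE", s, data.frame(
    label = "cox1", kind = "PCG", start = 0L, end = 300L, strand = "+",
    stringsAsFactors = FALSE))
  ps <- genome_partition_stats(g1)
  expect_equal(ps$at_percent[ps$category == "PCGs"],
               ps$at_percent[ps$category == "whole"])
  expect_equal(ps$length[ps$category == "PCGs"], 300L)
  expect_true(is.na(ps$at_percent[ps$category == "tRNAs"]))
  expect_equal(ps$length[ps$category == "tRNAs"], 0L)

  # category totals equal hand-summed per-feature counts on the toy genome
  tg <- toy_genome()
  pst <- genome_partition_stats(tg)
  expect_equal(pst$length[pst$category == "PCGs"], 30L)
  expect_equal(pst$length[pst$category == "rRNAs"], 30L)
  expect_equal(pst$length[pst$category == "CRs"], 15L)
  expect_equal(pst$length[pst$category == "spacers"], 15L)  # 80..95 gap
  expect_equal(sum(pst$length[pst$category != "whole"]), tg$length)
  crseq <- gene_sequence(tg, "CR")
  expect_equal(pst$at_percent[pst$category == "CRs"],
               composition_stats(crseq)$at_percent)
})

test_that("minus-strand genes flip skew sign on coding sense", {
  g <- generate_genome(synthetic_spec(seed = 22, gc_skew = -0.25))$genome
  tab <- gene_composition_table(g, kinds = "PCG")
  plus <- tab$gc_skew[tab$strand == "+"]
  minus <- tab$gc_skew[tab$strand == "-"]
  expect_true(mean(plus) < 0)
  expect_true(mean(minus) > 0)
  # whole-genome (+)-strand skew is negative while (-)-strand genes read +
  expect_true(composition_stats(g$sequence)$gc_skew < 0)
})
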