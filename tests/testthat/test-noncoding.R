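test_that("unannotated regions are recovered exactly", {
  g0 <- generate_genome(synthetic_spec(seed = 81))$genome
  expect_equal(nrow(noncoding_regions(g0)), 0L)  # fully tiled

  sim <- generate_genome(synthetic_spec(seed = 82,
    spacers = c(cox1 = 40L, nad4 = 90L, rrnS = 130L)))
  nc <- noncoding_regions(sim$genome)
  expect_equal(nrow(nc), 3L)
  tr <- sim$truth$spacers
  expect_setequal(nc$length, tr$length)
  expect_setequal(nc$start, tr$start)
  # flanks name the upstream feature the spacer was planted after
  expect_setequal(nc$upstream[order(nc$start)],
                  tr$after[order(tr$start)])

  # gap between the last feature end (80) and the wrap CR start (95)
  tg <- toy_genome()
  nct <- noncoding_regions(tg)
  expect_equal(nct$start, 80L)
  expect_equal(nct$end, 95L)
  expect_equal(nct$length, 15L)
})

test_that("poly-T runs are found on both strands", {
  r <- poly_t_runs("AATTTTTTTTTTTTTG", min_len = 10)
  expect_equal(nrow(r), 1L)
  expect_equal(r$length, 13L)
  expect_equal(r$position, 3L)
  expect_equal(r$strand, "+")
  # an A run is a T run on the (-) strand
  r2 <- poly_t_runs(paste0(strrep("A", 11), "CGCG"), min_len = 10)
  expect_equal(r2$strand, "-")
  expect_equal(r2$length, 11L)
  expect_equal(nrow(poly_t_runs("ACGT", min_len = 2)), 0L)
  # N breaks a run
  expect_equal(max(poly_t_runs(paste0(strrep("T", 5), "N", strrep("T", 6)),
                               min_len = 3)$length), 6L)
})

test_that("tandem repeats are detected at the planted period", {
  r <- tandem_repeats("ACGTACGTACGT", min_period = 2, seed = 4)
  expect_equal(r$period, 4L)
  expect_equal(r$copies, 3)

  set.seed(83)
  for (i in 1:5) {
    period <- sample(15:60, 1)
    copies <- sample(3:5, 1)
    unit <- random_dna(period, at = 0.6)
    arr <- strrep(unit, copies)
    v <- strsplit(arr, "", fixed = TRUE)[[1]]
    hit <- sample(length(v), round(0.05 * length(v)))
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    seqn <- paste0(random_dna(80, 0.5), paste(v, collapse = ""),
                   random_dna(80, 0.5))
    det <- tandem_repeats(seqn)
    expect_gte(nrow(det), 1L)
    expect_lte(abs(det$period[which.max(det$span)] - period), 1L)
    # autocorrelation oracle agrees on the fundamental period
    expect_equal(oracle_best_period(paste(v, collapse = "")), period)
  }
  # quiet on balanced random sequence
  set.seed(84)
  expect_equal(nrow(tandem_repeats(random_dna(400, at = 0.5))), 0L)
})

test_that("hairpins match the exhaustive triple-enumeration oracle", {
  h <- find_hairpins("GGGGGGAAAACCCCCC")
  expect_equal(h$stem, 6L)
  expect_equal(h$loop, 4L)
  expect_equal(h$position, 1L)
  expect_equal(nrow(find_hairpins("ACACACACACACACAC")), 0L)
  set.seed(85)
  for (i in 1:4) {
    s <- random_dna(100, at = 0.6)
    det <- find_hairpins(s)
    ora <- oracle_hairpins(s)
    expect_equal(nrow(det), nrow(ora))
    if (nrow(det)) {
      expect_equal(det$position, ora$position)
      expect_equal(det$stem, ora$stem)
      expect_equal(det$loop, ora$loop)
    }
  }
})

test_that("detectors mirror under reverse complement", {
  set.seed(86)
  s <- paste0(random_dna(60, 0.6), strrep("T", 12),
              strrep("ACGGATTACGGA", 3), random_dna(60, 0.6))
  rc <- revcomp_chr(s)
  L <- nchar(s)
  pt <- poly_t_runs(s, 10); pt_rc <- poly_t_runs(rc, 10)
  expect_equal(nrow(pt), nrow(pt_rc))
  expect_setequal(pt$length, pt_rc$length)
  # positions mirror: start' = L - (start + len - 1) + 1
  expect_setequal(L - (pt$position + pt$length - 1) + 1, pt_rc$position)
  expect_setequal(ifelse(pt$strand == "+", "-", "+"), pt_rc$strand)
  tr <- tandem_repeats(s, min_period = 5, seed = 8)
  tr_rc <- tandem_repeats(rc, min_period = 5, seed = 8)
  expect_setequal(tr$period, tr_rc$period)
  hp <- find_hairpins(s); hp_rc <- find_hairpins(rc)
  expect_equal(nrow(hp), nrow(hp_rc))
  expect_setequal(paste(hp$stem, hp$loop), paste(hp_rc$stem, hp_rc$loop))
})

test_that("the planted control region outranks featureless spacers", {
  sim <- generate_genome(synthetic_spec(seed = 87,
                                        spacers = c(nad4 = 150L)))
  rc <- rank_cr_candidates(sim$genome)
  expect_true(rc$annotated_cr[1])
  expect_equal(rc$score[1], 4L)
  expect_gte(rc$poly_t[1], sim$truth$cr$poly_t)
  expect_gte(rc$at_excess[1], 5)

  # candidates shorter than the length floor are excluded, with a warning
  # when nothing qualifies
  set.seed(88)
  s <- random_dna(100)
  g2 <- mito_genome("GAPPY", s, data.frame(
    label = c("cox1", "nad2"), kind = "PCG", start = c(0L, 60L),
    end = c(60L, 70L), strand = "+", stringsAsFactors = FALSE),
    circular = TRUE)
  expect_warning(out <- rank_cr_candidates(g2, min_length = 50),
                 "no candidate")
  expect_equal(nrow(out), 0L)
})

test_that("featureless spacers all score zero and rank by length", {
  # spacers verified to lack every feature class (no poly-T run, tandem
  # repeat, or stem-6 hairpin; genome-typical AT)
  calm1 <- paste0("GAGAACTATGAGTTCACCGAATTATTTTGCAATACGACGCCGGGCCCGGA",
                  "CGACTCCAAGTCGGAGAAAGATTCGCGTGCCTGACGAAACCTGTGCACGT")
  calm2 <- paste0("TGGAGAATGCAGCATCTATGTGGCGACCCTTATTTTAAAGGGCCACCCCT",
                  "AGGCCGTCGCTGTGGTTCGGTCATTTGTATAGTGTGGTAAGGATAGGTCT")
  set.seed(89)
  base <- random_dna(2800, at = 0.5)
  s <- paste0(substr(base, 1, 1500), calm1,
              substr(base, 1501, 2800), substr(calm2, 1, 80))
  feats <- data.frame(label = c("cox1", "nad2"), kind = "PCG",
                      start = c(0L, 1600L), end = c(1500L, 2900L),
                      strand = "+", stringsAsFactors = FALSE)
  g <- mito_genome("CALM", s, feats, circular = TRUE)
  rc <- rank_cr_candidates(g)
  expect_equal(nrow(rc), 2L)
  expect_true(all(rc$score == 0))
  expect_equal(rc$length, sort(rc$length, decreasing = TRUE))
})

test_that("region identity reproduces hand-counted values", {
  expect_equal(region_identity("ACGTACGT", "ACGTACGT")$percent_identity, 100)
  set.seed(90)
  s <- random_dna(102)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(102, 2)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  expect_equal(region_identity(s, paste(v, collapse = ""))$percent_identity,
               98.04)  # 100/102 to 2 d.p.
  # unrelated regions sit near the random-alignment baseline
  ids <- vapply(1:10, function(i)
    region_identity(random_dna(100), random_dna(100))$percent_identity,
    numeric(1))
  expect_lt(max(ids), 75)
  expect_gt(min(ids), 30)
})
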