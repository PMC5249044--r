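test_that("the ground-pattern PCG signature is the canonical arrangement", {
  sig <- gene_order_signature(ground_pattern(), "PCG")
  expect_equal(sig$elements$label,
               c("cox1", "cox2", "atp8", "atp6", "cox3", "nad3", "nad5",
                 "nad4", "nad4l", "nad6", "cytB", "nad1", "nad2"))
  expect_equal(sig$elements$sign,
               c(1, 1, 1, 1, 1, 1, -1, -1, -1, 1, 1, -1, 1))
  expect_error(gene_order_signature(ground_pattern("PCG"), "PCG",
                                    anchor = "trnX"), "anchor")
})

test_that("signatures are invariant under rotation and reflection", {
  g <- generate_genome(synthetic_spec(seed = 61))$genome
  sig0 <- gene_order_signature(g, "all")
  # rotate the circular genome by an arbitrary offset
  k <- 4321L
  rot_seq <- paste0(substr(g$sequence, k + 1, g$length),
                    substr(g$sequence, 1, k))
  fe <- g$features
  fe$start <- (fe$start - k) %% g$length
  fe$end <- fe$end - k
  fe$end <- ifelse(fe$end <= 0L, fe$end + g$length, fe$end)
  g_rot <- mito_genome(g$id, rot_seq, fe, circular = TRUE)
  expect_equal(gene_order_signature(g_rot, "all")$elements, sig0$elements)
  # full reflection (reverse complement of the record)
  fe2 <- g$features
  fe2$start <- (g$length - g$features$end) %% g$length
  fe2$end <- g$length - g$features$start
  fe2$end[fe2$end == 0L] <- g$length
  fe2$strand <- ifelse(g$features$strand == "+", "-", "+")
  g_ref <- mito_genome(g$id, revcomp_chr(g$sequence), fe2, circular = TRUE)
  expect_equal(gene_order_signature(g_ref, "all")$elements, sig0$elements)
})

test_that("identical orders give zero breakpoints", {
  sig <- gene_order_signature(ground_pattern(), "PCG")
  r <- compare_orders(sig, sig)
  expect_equal(r$breakpoints, 0)
  expect_true(r$identical)
  expect_length(r$translocated, 0)
})

test_that("single translocations and inversions are localized", {
  ref <- gene_order_signature(ground_pattern(), "PCG")
  g <- generate_genome(synthetic_spec(seed = 62, rearrangements = list(
    list(type = "translocate", label = "nad1", after = "cox3"))))$genome
  r <- compare_orders(gene_order_signature(g, "PCG"), ref)
  expect_true("nad1" %in% r$translocated)
  expect_equal(r$breakpoints, 3)
  expect_false(r$identical)

  g2 <- generate_genome(synthetic_spec(seed = 63, rearrangements = list(
    list(type = "invert", label = "cytB"))))$genome
  r2 <- compare_orders(gene_order_signature(g2, "PCG"), ref)
  expect_equal(r2$inverted, "cytB")
  expect_equal(r2$breakpoints, 2)

  # a six-gene shuffle reports (at least) all moved genes
  moved <- c("nad1", "nad5", "nad4", "nad4l", "nad6", "cytB")
  g3 <- generate_genome(synthetic_spec(seed = 64, rearrangements = list(
    list(type = "translocate", label = "nad1", after = "cox1"),
    list(type = "translocate", label = "nad5", after = "nad1"),
    list(type = "translocate", label = "nad4", after = "cox2"),
    list(type = "translocate", label = "nad4l", after = "atp6"),
    list(type = "translocate", label = "nad6", after = "rrnS"),
    list(type = "translocate", label = "cytB", after = "trnI"))))$genome
  r3 <- compare_orders(gene_order_signature(g3, "PCG"), ref)
  expect_true(all(moved %in% r3$translocated))
})

test_that("breakpoint counts match exhaustive adjacency enumeration", {
  set.seed(65)
  for (i in 1:40) {
    k <- sample(4:12, 1)
    t1 <- random_signature(k, seed = 1000 + i)
    t2 <- t1[sample(k), , drop = FALSE]          # permuted order
    flip <- runif(k) < 0.3
    t2$strand[flip] <- ifelse(t2$strand[flip] == "+", "-", "+")
    s1 <- sig_from_table(t1, anchor = "g1")
    s2 <- sig_from_table(t2, anchor = "g1")
    bp <- compare_orders(s1, s2)$breakpoints
    ora <- oracle_breakpoints(
      s1$elements$label, s1$elements$sign,
      s2$elements$label, s2$elements$sign)
    expect_equal(bp, ora, label = paste("case", i))
  }
})

test_that("breakpoint distance is a symmetric pseudo-metric", {
  set.seed(66)
  for (i in 1:15) {
    k <- sample(5:10, 1)
    tabs <- lapply(1:3, function(j) {
      t0 <- random_signature(k, seed = 2000 + 10 * i + j)
      t0[sample(k), , drop = FALSE]
    })
    sigs <- lapply(tabs, sig_from_table, anchor = "g1")
    d <- function(x, y) compare_orders(x, y)$breakpoints
    expect_equal(d(sigs[[1]], sigs[[1]]), 0)
    d12 <- d(sigs[[1]], sigs[[2]]); d21 <- d(sigs[[2]], sigs[[1]])
    d13 <- d(sigs[[1]], sigs[[3]]); d23 <- d(sigs[[2]], sigs[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
  }
})

test_that("batch comparison yields a symmetric distance matrix", {
  genomes <- lapply(c(67, 68), function(s)
    generate_genome(synthetic_spec(seed = s, rearrangements = if (s == 68)
      list(list(type = "translocate", label = "nad1", after = "cox3"))
      else list()))$genome)
  res <- batch_compare(genomes, scope = "PCG")
  expect_equal(res$distance, t(res$distance))
  expect_true(all(diag(res$distance) == 0))
  expect_true(res$reports[[1]]$identical)
  expect_false(res$reports[[2]]$identical)
  expect_error(compare_orders(
    sig_from_table(random_signature(5, 1), anchor = "g1"),
    gene_order_signature(ground_pattern(), "PCG")), "disjoint")
})
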