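# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive reimplementation (enumeration, direct
# formula) kept independent of the code paths it checks.

random_dna <- function(n, at = 0.5, with_n = 0) {
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  s <- sample(names(p), n, replace = TRUE, prob = p)
  if (with_n > 0) s[sample.int(n, ceiling(with_n * n))] <- "N"
  paste(s, collapse = "")
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# brute-force nucleotide diversity: explicit loops over pairs and sites,
# complete deletion
oracle_pi <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  use <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, use, drop = FALSE]
  n <- nrow(m)
  total <- 0; npair <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    diffs <- 0
    for (k in seq_len(ncol(m))) if (m[i, k] != m[j, k]) diffs <- diffs + 1
    total <- total + diffs / ncol(m)
    npair <- npair + 1
  }
  total / npair
}

# direct-formula ("spreadsheet-style") Wright Nc from a codon count vector
# named by codon, using the genetic code straight from Biostrings
oracle_enc <- function(counts, split_families = FALSE) {
  gc5 <- Biostrings::getGeneticCode("5")
  fam_of <- as.character(gc5)
  names(fam_of) <- names(gc5)
  if (split_families) {
    fam_of[c("TTA", "TTG")] <- "L2f"
    fam_of[c("CTT", "CTC", "CTA", "CTG")] <- "L4f"
    fam_of[c("TCT", "TCC", "TCA", "TCG")] <- "S4a"
    fam_of[c("AGT", "AGC", "AGA", "AGG")] <- "S4b"
  }
  fam_of <- fam_of[fam_of != "*"]
  fams <- unique(fam_of)
  deg <- sapply(fams, function(f) sum(fam_of == f))
  f_hat <- sapply(fams, function(f) {
    cods <- names(fam_of)[fam_of == f]
    ni <- sapply(cods, function(cd) if (cd %in% names(counts))
      counts[[cd]] else 0)
    n <- sum(ni)
    if (n < 2) return(NA_real_)
    fh <- (n * sum((ni / n)^2) - 1) / (n - 1)
    if (fh <= 0) NA_real_ else fh
  })
  nc <- 0
  for (k in sort(unique(deg))) {
    fk <- f_hat[deg == k]
    fbar <- if (all(is.na(fk))) 1 / k else mean(fk, na.rm = TRUE)
    nc <- nc + sum(deg == k) / fbar
  }
  min(nc, length(fam_of))
}

codon_count_vector <- function(cds) {
  n <- nchar(cds) %/% 3
  cods <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  tab <- table(cods)
  setNames(as.integer(tab), names(tab))
}

# exhaustive breakpoint count: every adjacency of (lab1, sgn1) checked
# against every adjacency of (lab2, sgn2) in both reading directions
oracle_breakpoints <- function(lab1, sgn1, lab2, sgn2) {
  n1 <- length(lab1); n2 <- length(lab2)
  bp <- 0
  for (i in seq_len(n1)) {
    a <- lab1[i]; b <- lab1[if (i == n1) 1 else i + 1]
    sa <- sgn1[i]; sb <- sgn1[if (i == n1) 1 else i + 1]
    found <- FALSE
    for (j in seq_len(n2)) {
      x <- lab2[j]; y <- lab2[if (j == n2) 1 else j + 1]
      sx <- sgn2[j]; sy <- sgn2[if (j == n2) 1 else j + 1]
      if (x == a && y == b && sx == sa && sy == sb) found <- TRUE
      if (x == b && y == a && sx == -sb && sy == -sa) found <- TRUE
    }
    if (!found) bp <- bp + 1
  }
  bp
}

# exhaustive global-alignment score by recursive enumeration of every
# alignment (exponential; sequences must stay tiny)
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      s <- if (va[i] == vb[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(va)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(vb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# exhaustive hairpin enumeration over all (position, stem, loop) triples,
# with the same maximality convention as the detector: stems not extendable
# outward, innermost pair not tightenable while the loop stays allowed
oracle_hairpins <- function(seq, min_stem = 6, loop_range = 3:30) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- function(i, j) i >= 1 && j <= L && !is.na(comp[v[i]]) &&
    comp[[v[i]]] == v[j]
  out <- list()
  for (p in seq_len(L)) for (s in min_stem:floor((L - min(loop_range)) / 2)) {
    for (l in loop_range) {
      q <- p + 2 * s + l - 1
      if (q > L) next
      arm_ok <- all(vapply(seq_len(s), function(k)
        wc(p + k - 1, q - k + 1), logical(1)))
      if (!arm_ok) next
      if (wc(p - 1, q + 1)) next                 # outward extendable
      if (l - 2 >= min(loop_range) &&
          wc(p + s, q - s)) next                 # tighter center allowed
      out[[length(out) + 1]] <- c(stem = s, loop = l, position = p)
    }
  }
  if (!length(out)) return(data.frame(stem = integer(), loop = integer(),
                                      position = integer()))
  df <- unique(as.data.frame(do.call(rbind, out)))
  df[order(df$position, df$loop), , drop = FALSE]
}

# autocorrelation oracle: fundamental period = smallest lag whose match
# fraction clears the identity threshold (all multiples of the true period
# share the same expected identity under i.i.d. copy noise)
oracle_best_period <- function(seq, min_period = 10, max_period = 200,
                               min_identity = 0.8) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  periods <- min_period:min(max_period, L %/% 2)
  frac <- vapply(periods, function(P)
    mean(v[seq_len(L - P)] == v[seq.int(P + 1, L)]), numeric(1))
  periods[frac >= min_identity][1]
}

# small deterministic hand-built genome with an origin-spanning CR
# (features tile 95..10, 10..40, 40..50, 50..80; unannotated gap 80..95)
toy_genome <- function() {
  set.seed(4711)
  seq <- random_dna(100, at = 0.6)
  feats <- data.frame(
    label = c("cox1", "trnK", "rrnS", "CR"),
    kind = c("PCG", "tRNA", "rRNA", "CR"),
    start = c(10L, 40L, 50L, 95L),
    end = c(40L, 50L, 80L, 10L),
    strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE)
  mito_genome("TOY1", seq, feats, circular = TRUE)
}

# random signed signature over k labels (for gene-order property tests)
random_signature <- function(k, seed) {
  set.seed(seed)
  labs <- paste0("g", sample(seq_len(k)))
  data.frame(label = labs, kind = "PCG",
             strand = sample(c("+", "-"), k, replace = TRUE),
             stringsAsFactors = FALSE)
}

sig_from_table <- function(tab, anchor = tab$label[1]) {
  gene_order_signature(tab, scope = "PCG", anchor = anchor)
}
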