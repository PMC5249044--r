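# Intergenic spacers and control-region feature scanning.
#
# A putative control region (CR) is recognized by the features typical of
# invertebrate mitochondrial CRs: a poly-T stretch, tandemly repeated
# sequence, hairpin-forming inverted repeats, and AT richness relative to
# the whole genome. The candidate score simply counts which of the four
# feature classes are present (unweighted: the literature gives no basis
# for weighting).

#' Maximal unannotated regions of a genome
#'
#' Complements the annotated features on the (+) strand, including the
#' circular closure, and reports every maximal unannotated interval.
#' Regions annotated as CR or spacer are features, not gaps, and so are not
#' returned here.
#'
#' @param genome a [mito_genome()].
#' @return data.frame with columns `start`, `end` (0-based half-open;
#'   `start > end` for an origin-spanning region), `length`, `upstream`,
#'   `downstream` (flanking feature labels).
#' @export
noncoding_regions <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  L <- genome$length
  fe <- genome$features
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      upstream = character(), downstream = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(fe)) {
    return(data.frame(start = 0L, end = L, length = L,
                      upstream = NA_character_, downstream = NA_character_,
                      stringsAsFactors = FALSE))
  }
  # mark covered positions (0-based); wrap features cover suffix + prefix
  cov <- logical(L)
  for (i in seq_len(nrow(fe))) {
    s <- fe$start[i]; e <- fe$end[i]
    if (s < e) cov[(s + 1L):e] <- TRUE
    else { if (s < L) cov[(s + 1L):L] <- TRUE; cov[seq_len(e)] <- TRUE }
  }
  if (all(cov)) return(empty)
  gap <- !cov
  # runs of TRUE in gap, treating the sequence as circular
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based starts
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (genome$circular && nrow(runs) > 1L &&
      runs$start[1] == 0L && runs$end[nrow(runs)] == L) {
    runs$start[1] <- runs$start[nrow(runs)]  # merge across origin
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  flank <- function(pos, side) {
    # nearest feature boundary before/after pos on the circle
    if (side == "up") {
      d <- (pos - fe$end) %% L
      fe$label[which.min(d)]
    } else {
      d <- (fe$start - pos) %% L
      fe$label[which.min(d)]
    }
  }
  runs$length <- as.integer(span_length(runs$start, runs$end, L))
  runs$upstream <- vapply(runs$start, flank, character(1), side = "up")
  runs$downstream <- vapply(runs$end, flank, character(1), side = "down")
  rownames(runs) <- NULL
  runs
}

#' Poly-T homopolymer runs on either strand
#'
#' Maximal runs of T (and of A, reported as T-runs on the (-) strand) of at
#' least `min_len` bases. N breaks a run.
#'
#' @param seq DNA string.
#' @param min_len minimal run length (default 10, the shortest poly-T
#'   stretch bounding a CR in amphipod mitogenomes).
#' @return data.frame with columns `position` (1-based start on the given
#'   strand), `length`, `strand`.
#' @export
#' @examples
#' poly_t_runs("AATTTTTTTTTTTTTG", min_len = 10)  # one 13-T run
poly_t_runs <- function(seq, min_len = 10L) {
  seq <- toupper(seq)
  find_runs <- function(base, strand) {
    v <- strsplit(seq, "", fixed = TRUE)[[1]] == base
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    data.frame(position = starts[keep], length = r$lengths[keep],
               strand = rep(strand, sum(keep)), stringsAsFactors = FALSE)
  }
  out <- rbind(find_runs("T", "+"), find_runs("A", "-"))
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Tandem repeat detection (seed and extend)
#'
#' For each candidate period the sequence is compared against itself shifted
#' by the period; a seed of `seed` consecutive matches is extended outward
#' while cumulative adjacent-copy identity stays at or above
#' `min_identity`. Overlapping calls are merged, keeping the fundamental
#' call (most copies, then longest span; harmonic periods tie on span but
#' halve the copy count). The defaults (period 10-200, 12-match seed)
#' target the repeat scales seen in invertebrate control regions while
#' staying quiet on random sequence; lower `min_period` and `seed` together
#' to detect microsatellite-scale repeats (e.g. period 4 in
#' `"ACGTACGTACGT"` needs `min_period = 2, seed = 4`).
#'
#' @param seq DNA string.
#' @param min_period,max_period period range searched (defaults 10-200).
#' @param min_copies minimal copy number (default 2.0).
#' @param min_identity minimal adjacent-copy identity (default 0.8).
#' @param seed seed length: required consecutive matches (default 12).
#' @return data.frame with columns `period`, `copies`, `start` (1-based),
#'   `span`.
#' @export
#' @examples
#' tandem_repeats("ACGTACGTACGT", min_period = 2, seed = 4)  # period 4
tandem_repeats <- function(seq, min_period = 10L, max_period = 200L,
                           min_copies = 2, min_identity = 0.8, seed = 12L) {
  seq <- toupper(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  calls <- list()
  for (P in seq.int(min_period, min(max_period, L %/% 2L))) {
    m <- v[seq_len(L - P)] == v[seq.int(P + 1L, L)] &
      v[seq_len(L - P)] %in% .BASES
    if (!any(m)) next
    need <- seed
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seeds <- which(r$values & r$lengths >= need)
    used_until <- 0L
    for (si in seeds) {
      a <- starts[si]; b <- ends[si]
      if (a <= used_until) next
      # greedy extension keeping cumulative identity >= min_identity
      match_n <- b - a + 1L; tot <- match_n
      bb <- b
      while (bb < length(m) &&
             (match_n + m[bb + 1L]) / (tot + 1L) >= min_identity) {
        bb <- bb + 1L; tot <- tot + 1L; match_n <- match_n + m[bb]
      }
      aa <- a
      while (aa > 1L &&
             (match_n + m[aa - 1L]) / (tot + 1L) >= min_identity) {
        aa <- aa - 1L; tot <- tot + 1L; match_n <- match_n + m[aa]
      }
      span <- bb - aa + 1L + P
      copies <- span / P
      if (copies >= min_copies && match_n / tot >= min_identity)
        calls[[length(calls) + 1L]] <-
          data.frame(period = P, copies = round(copies, 2),
                     start = aa, span = span)
      used_until <- bb
    }
  }
  if (!length(calls))
    return(data.frame(period = integer(), copies = numeric(),
                      start = integer(), span = integer()))
  calls <- do.call(rbind, calls)
  # merge overlapping calls: keep the fundamental (most copies, then
  # longest span) -- harmonic periods tie on span but halve the copy count
  calls <- calls[order(-calls$copies, -calls$span, calls$period), ,
                 drop = FALSE]
  kept <- calls[0, ]
  for (i in seq_len(nrow(calls))) {
    ci <- calls[i, ]
    overlaps <- any(ci$start <= kept$start + kept$span - 1L &
                    kept$start <= ci$start + ci$span - 1L)
    if (!overlaps) kept <- rbind(kept, ci)
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Hairpin (inverted repeat) detection
#'
#' Perfect Watson-Crick inverted repeats with stem at least `min_stem` base
#' pairs and a loop of `loop_range` nucleotides. Only maximal stems (not
#' extendable on either side) are reported.
#'
#' @param seq DNA string.
#' @param min_stem minimal stem length in b.p. (default 6).
#' @param loop_range allowed loop lengths (default 3:30).
#' @return data.frame with columns `stem`, `loop`, `position` (1-based
#'   start of the 5' stem arm).
#' @export
#' @examples
#' find_hairpins("GGGGGGAAAACCCCCC")  # stem 6, loop 4
find_hairpins <- function(seq, min_stem = 6L, loop_range = 3:30) {
  seq <- toupper(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs_ok <- function(i, j) {
    vi <- v[i]; vj <- v[j]
    !is.na(comp[vi]) & comp[vi] == vj
  }
  out <- list()
  for (loop in loop_range) {
    if (L - loop - 1L < 1L) next
    # center c: stem arms end at c and start at c + loop + 1
    for (cpos in seq_len(L - loop - 1L)) {
      i <- cpos; j <- cpos + loop + 1L
      if (j > L) break
      if (!pairs_ok(i, j)) next
      # maximality: (i, j) must be the innermost usable pair -- skip when a
      # tighter pairing exists whose loop is still allowed
      if (loop - 2L >= min(loop_range) && pairs_ok(i + 1L, j - 1L)) next
      s <- 1L
      while (i - s >= 1L && j + s <= L && pairs_ok(i - s, j + s)) s <- s + 1L
      if (s >= min_stem) {
        out[[length(out) + 1L]] <-
          data.frame(stem = s, loop = loop, position = i - s + 1L)
      }
    }
  }
  if (!length(out))
    return(data.frame(stem = integer(), loop = integer(),
                      position = integer()))
  res <- unique(do.call(rbind, out))
  res <- res[order(res$position, res$loop), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank control-region candidates
#'
#' Candidates are the unannotated regions of at least `min_length` b.p.
#' plus (by default) regions annotated as CR. Each candidate is scanned for
#' the four invertebrate CR feature classes; the score counts classes
#' present: longest poly-T run >= `poly_t_min`, >= 1 tandem repeat, >= 1
#' hairpin, AT% exceeding the whole-genome AT% by >= `at_excess_min`
#' points. Candidates are ordered by score (descending), then length.
#'
#' @param genome a [mito_genome()].
#' @param min_length minimal candidate length (default 50).
#' @param poly_t_min poly-T threshold (default 10).
#' @param at_excess_min AT-excess threshold in percentage points (default 5).
#' @param include_annotated_cr include annotated CR features as candidates?
#' @return an object of class `cr_candidates`: data.frame with columns
#'   `start`, `end`, `length`, `annotated_cr`, `upstream`, `downstream`,
#'   `at_percent`, `at_excess`, `poly_t`, `n_repeats`, `n_hairpins`,
#'   `score`; detector details in `attr(, "detail")`.
#' @export
rank_cr_candidates <- function(genome, min_length = 50L, poly_t_min = 10L,
                               at_excess_min = 5, include_annotated_cr = TRUE) {
  stopifnot(inherits(genome, "mito_genome"))
  genome_at <- composition_stats(genome$sequence)$at_percent
  nc <- noncoding_regions(genome)
  cand <- if (nrow(nc))
    data.frame(nc[, c("start", "end", "length", "upstream", "downstream")],
               annotated_cr = FALSE, stringsAsFactors = FALSE)
  else data.frame(start = integer(), end = integer(), length = integer(),
                  upstream = character(), downstream = character(),
                  annotated_cr = logical())
  if (include_annotated_cr) {
    crf <- genome$features[genome$features$kind == "CR", , drop = FALSE]
    if (nrow(crf)) {
      cand <- rbind(cand, data.frame(
        start = crf$start, end = crf$end,
        length = as.integer(span_length(crf$start, crf$end, genome$length)),
        upstream = NA_character_, downstream = NA_character_,
        annotated_cr = TRUE, stringsAsFactors = FALSE))
    }
  }
  cand <- cand[cand$length >= min_length, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no candidate region of length >= ", min_length, call. = FALSE)
    out <- data.frame()
    class(out) <- c("cr_candidates", "data.frame")
    return(out)
  }
  detail <- vector("list", nrow(cand))
  stats <- lapply(seq_len(nrow(cand)), function(i) {
    s <- extract_span(genome$sequence, cand$start[i], cand$end[i],
                      genome$circular)
    pt <- poly_t_runs(s, min_len = 1L)
    longest_t <- if (nrow(pt)) max(pt$length) else 0L
    tr <- tandem_repeats(s)
    hp <- find_hairpins(s)
    at <- if (nchar(gsub("N", "", s))) composition_stats(s)$at_percent
          else NA_real_
    detail[[i]] <<- list(poly_t = pt, repeats = tr, hairpins = hp)
    data.frame(at_percent = at,
               at_excess = at - genome_at,
               poly_t = longest_t, n_repeats = nrow(tr),
               n_hairpins = nrow(hp))
  })
  out <- cbind(cand, do.call(rbind, stats))
  out$score <- (out$poly_t >= poly_t_min) + (out$n_repeats >= 1L) +
    (out$n_hairpins >= 1L) +
    (!is.na(out$at_excess) & out$at_excess >= at_excess_min)
  ord <- order(-out$score, -out$length)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "detail") <- detail[ord]
  class(out) <- c("cr_candidates", "data.frame")
  out
}
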