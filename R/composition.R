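# Base-composition statistics: AT/GC skew, AT content, codon-position AT,
# sliding-window profiles. N and ambiguity codes are excluded from every
# count (deposited mitogenomes may contain unsequenced N runs).

base_counts <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(n_A = sum(v == "A"), n_C = sum(v == "C"),
    n_G = sum(v == "G"), n_T = sum(v == "T"))
}

#' Base composition and strand-skew statistics
#'
#' Computes exact base counts and the strand-asymmetry statistics
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), together with
#' AT% = 100 (A + T)/(A + C + G + T). A skew is reported as `NA` when its
#' denominator is zero. `N` bases are ignored.
#'
#' @param seq DNA string.
#' @return an object of class `composition_stats`: a list with `n_A`, `n_C`,
#'   `n_G`, `n_T`, `length` (counted bases), `at_percent`, `at_skew`,
#'   `gc_skew`.
#' @export
#' @examples
#' composition_stats("AATT")$at_skew        # 0
#' composition_stats("AAATTGC")$gc_skew     # 0
composition_stats <- function(seq) {
  seq <- toupper(seq)
  cn <- base_counts(seq)
  tot <- sum(cn)
  if (tot == 0L)
    stop("empty or all-N sequence: no countable bases", call. = FALSE)
  at <- cn[["n_A"]] + cn[["n_T"]]
  gc <- cn[["n_G"]] + cn[["n_C"]]
  structure(list(
    n_A = cn[["n_A"]], n_C = cn[["n_C"]], n_G = cn[["n_G"]],
    n_T = cn[["n_T"]], length = tot,
    at_percent = 100 * at / tot,
    at_skew = if (at > 0) (cn[["n_A"]] - cn[["n_T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (cn[["n_G"]] - cn[["n_C"]]) / gc else NA_real_),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "composition: %d b.p. | AT%% %.2f | AT-skew %s | GC-skew %s\n",
    x$length, x$at_percent,
    ifelse(is.na(x$at_skew), "NA", sprintf("%.3f", x$at_skew)),
    ifelse(is.na(x$gc_skew), "NA", sprintf("%.3f", x$gc_skew))))
  invisible(x)
}

#' Composition statistics per annotation category
#'
#' One row per category (`whole`, `PCGs`, `rRNAs`, `tRNAs`, `CRs`,
#' `spacers`), pooling the member features of each. Gene categories (PCG,
#' rRNA, tRNA) are measured on coding-sense sequences, so strand bias shows
#' as a sign flip between (+)- and (-)-strand genes; the `whole` row and
#' non-coding categories use the (+) strand. The `spacers` category pools
#' annotated spacer features with unannotated intergenic gaps. Empty
#' categories get zero length and `NA` statistics.
#'
#' @param genome a [mito_genome()].
#' @return data.frame with columns `category`, `n_features`, `length`,
#'   `at_percent`, `at_skew`, `gc_skew`.
#' @export
genome_partition_stats <- function(genome) {
  stopifnot(inherits(genome, "mito_genome"))
  cats <- list(PCGs = "PCG", rRNAs = "rRNA", tRNAs = "tRNA", CRs = "CR")
  rows <- list()
  add_row <- function(category, seqs) {
    pooled <- paste(seqs, collapse = "")
    if (nchar(gsub("N", "", pooled)) == 0L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        category = category, n_features = length(seqs),
        length = sum(nchar(seqs)), at_percent = NA_real_,
        at_skew = NA_real_, gc_skew = NA_real_, stringsAsFactors = FALSE)
    } else {
      cs <- composition_stats(pooled)
      rows[[length(rows) + 1L]] <<- data.frame(
        category = category, n_features = length(seqs),
        length = sum(nchar(seqs)), at_percent = cs$at_percent,
        at_skew = cs$at_skew, gc_skew = cs$gc_skew, stringsAsFactors = FALSE)
    }
  }
  add_row("whole", genome$sequence)
  rows[[1]]$n_features <- nrow(genome$features)
  for (nm in names(cats)) add_row(nm, unname(gene_sequences(genome, cats[[nm]])))
  gaps <- noncoding_regions(genome)
  spacer_seqs <- c(unname(gene_sequences(genome, "spacer")),
                   if (nrow(gaps)) vapply(seq_len(nrow(gaps)), function(i)
                     extract_span(genome$sequence, gaps$start[i], gaps$end[i],
                                  genome$circular), character(1)))
  add_row("spacers", spacer_seqs %||% character(0))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene composition table
#'
#' Coding-sense composition statistics for every annotated gene feature,
#' the data behind per-gene skew comparisons across genomes.
#'
#' @param genome a [mito_genome()].
#' @param kinds feature kinds to include.
#' @return data.frame with one row per feature.
#' @export
gene_composition_table <- function(genome, kinds = c("PCG", "rRNA")) {
  fe <- genome$features[genome$features$kind %in% kinds, , drop = FALSE]
  if (!nrow(fe)) return(data.frame())
  rows <- lapply(seq_len(nrow(fe)), function(i) {
    s <- gene_sequence(genome, fe[i, , drop = FALSE])
    cs <- composition_stats(s)
    data.frame(genome = genome$id, label = fe$label[i], kind = fe$kind[i],
               strand = fe$strand[i], copy_index = fe$copy_index[i],
               length = nchar(s), at_percent = cs$at_percent,
               at_skew = cs$at_skew, gc_skew = cs$gc_skew,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window composition profile
#'
#' Windows start at 0, `step`, 2 `step`, ...; for linear sequences the last
#' partial window is dropped (`floor((L - window)/step) + 1` windows); for
#' circular sequences windows wrap the origin so every window start below the
#' sequence length is used and every position is covered.
#'
#' @param seq DNA string.
#' @param window window size in b.p. (default 100).
#' @param step step in b.p. (default 10).
#' @param metric one of `"at_skew"`, `"gc_skew"`, `"at_percent"`.
#' @param circular wrap windows around the origin?
#' @return an object of class `skew_profile`: list with `window`, `step`,
#'   `metric`, `positions` (window midpoints, `start + window/2`), `values`.
#' @export
sliding_window_profile <- function(seq, window = 100L, step = 10L,
                                   metric = c("at_skew", "gc_skew",
                                              "at_percent"),
                                   circular = FALSE) {
  metric <- match.arg(metric)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (window > L) stop("window larger than sequence", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  starts <- if (circular) seq.int(0L, L - 1L, by = step)
            else seq.int(0L, L - window, by = step)
  ext <- if (circular) paste0(seq, substr(seq, 1L, window)) else seq
  vals <- vapply(starts, function(s0) {
    w <- substr(ext, s0 + 1L, s0 + window)
    cn <- base_counts(w)
    switch(metric,
      at_skew = {
        at <- cn[["n_A"]] + cn[["n_T"]]
        if (at > 0) (cn[["n_A"]] - cn[["n_T"]]) / at else NA_real_
      },
      gc_skew = {
        gc <- cn[["n_G"]] + cn[["n_C"]]
        if (gc > 0) (cn[["n_G"]] - cn[["n_C"]]) / gc else NA_real_
      },
      at_percent = {
        tot <- sum(cn)
        if (tot > 0) 100 * (cn[["n_A"]] + cn[["n_T"]]) / tot else NA_real_
      })
  }, numeric(1))
  structure(list(window = window, step = step, metric = metric,
                 positions = starts + window / 2, values = vals),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("skew_profile: %s, window %d, step %d, %d windows\n",
              x$metric, x$window, x$step, length(x$values)))
  invisible(x)
}

#' @export
plot.skew_profile <- function(x, ...) {
  plot(x$positions, x$values, type = "l", xlab = "position (b.p.)",
       ylab = x$metric, ...)
  if (x$metric != "at_percent") graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' AT content by codon position
#'
#' Pools the position-1, -2 and -3 bases over all codons of a set of
#' coding-sense CDS and reports AT% for each position. Each CDS is framed
#' from its first base; a trailing 1-2 nt partial codon (a truncated stop
#' completed by polyadenylation) is excluded. An internal stop codon
#' triggers a warning but the sequence is still counted.
#'
#' @param cds_set character vector of coding-sense CDS.
#' @param warn_internal_stops warn on internal stops (invertebrate
#'   mitochondrial code)?
#' @return named numeric vector `c(pos1 =, pos2 =, pos3 =)` of AT percents.
#' @export
at_by_codon_position <- function(cds_set, warn_internal_stops = TRUE) {
  cds_set <- toupper(cds_set)
  if (!length(cds_set) || any(nchar(cds_set) < 3L))
    stop("each CDS must be at least one codon long", call. = FALSE)
  pooled <- lapply(cds_set, function(s) {
    n_cod <- nchar(s) %/% 3L
    v <- strsplit(substr(s, 1L, 3L * n_cod), "", fixed = TRUE)[[1]]
    matrix(v, nrow = 3L)
  })
  if (warn_internal_stops) {
    n_int <- sum(vapply(pooled, function(m) {
      cod <- apply(m[, -ncol(m), drop = FALSE], 2, paste, collapse = "")
      sum(cod %in% c("TAA", "TAG"))
    }, numeric(1)))
    if (n_int > 0)
      warning(n_int, " internal stop codon(s) in CDS set; sequences counted",
              call. = FALSE)
  }
  m <- do.call(cbind, pooled)
  at_pct <- function(v) {
    v <- v[v %in% .BASES]
    100 * mean(v %in% c("A", "T"))
  }
  c(pos1 = at_pct(m[1, ]), pos2 = at_pct(m[2, ]), pos3 = at_pct(m[3, ]))
}
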