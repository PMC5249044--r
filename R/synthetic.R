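# Synthetic annotated mitogenomes with recorded ground truth.
#
# The generator emulates the statistical structure of small circular
# mitogenomes: the 37-gene pancrustacean arrangement plus control region,
# configurable strand-composition bias, codon-position AT structure in
# PCGs, planted rearrangements, duplicated (optionally remolded) tRNAs,
# CR feature classes, and star-tree gene alignments at a target pairwise
# diversity. Skew targets are applied to the (+) strand of every region
# (a replication-strand model), so genome-wide skews meet the targets and
# (-)-strand genes show the sign-flipped coding-sense skew typical of real
# mitogenomes. Synthetic PCGs are statistical emulations, not translatable
# ORFs: codons are drawn i.i.d. per position (so composition targets hold
# exactly in expectation) and only the start/stop codons are planted.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

base_freqs <- function(at_percent, at_skew, gc_skew) {
  f <- at_percent / 100
  p <- c(A = f * (1 + at_skew) / 2, C = (1 - f) * (1 - gc_skew) / 2,
         G = (1 - f) * (1 + gc_skew) / 2, T = f * (1 - at_skew) / 2)
  if (any(p < 0))
    stop("infeasible composition targets (negative base frequency)",
         call. = FALSE)
  p
}

sample_seq <- function(n, freqs) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
        collapse = "")
}

.DEFAULT_GENE_LENGTHS <- c(
  cox1 = 1536L, cox2 = 684L, cox3 = 786L, atp6 = 672L, atp8 = 159L,
  nad1 = 939L, nad2 = 1002L, nad3 = 351L, nad4 = 1329L, nad4l = 297L,
  nad5 = 1716L, nad6 = 501L, cytB = 1137L, rrnL = 980L, rrnS = 624L)
.DEFAULT_TRNA_LENGTH <- 62L

#' Specification of a synthetic mitogenome
#'
#' The defaults emulate a typical Baikal-amphipod-like mitogenome: ~15 kb,
#' AT 65%, AT-skew ~0, GC-skew -0.25 on the (+) strand, PCG codon-position
#' AT increasing from position 1 to position 3, rRNA lengths 980/624 b.p.,
#' 62 b.p. tRNAs, and a control region carrying all four CR feature
#' classes.
#'
#' @param seed RNG seed (drives every random choice in
#'   [generate_genome()]).
#' @param id genome identifier.
#' @param at_percent target whole-genome AT content (percent).
#' @param at_skew,gc_skew target (+)-strand skews, each in `[-1, 1]`.
#' @param at_codon length-3 vector of AT percents for PCG codon positions
#'   1-3; default `at_percent + c(-10, -2, +12)`.
#' @param rearrangements list of edits to the ground pattern, each
#'   `list(type = "translocate", label =, after =)` or
#'   `list(type = "invert", label =)`.
#' @param trna_duplications list of planted tRNA duplications, each
#'   `list(label =, identity =, donor = NULL)` with `identity` the target
#'   percent identity; a non-`NULL` `donor` builds the extra copy from the
#'   donor tRNA (a remolding scenario).
#' @param cr control-region recipe: `length`, `poly_t`, `repeat_period`,
#'   `repeat_copies`, `repeat_noise`, `hairpin_stem`, `hairpin_loop`,
#'   `at_excess` (percentage points above `at_percent`). Any element set
#'   to 0 (or `at_excess` 0) omits that feature class.
#' @param spacers named integer vector: unannotated spacer lengths planted
#'   after the named genes.
#' @param gene_lengths named integer overrides of per-gene lengths
#'   (PCG lengths are rounded to codon multiples).
#' @return an object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L, id = sprintf("SYN%05d", seed),
                           at_percent = 65, at_skew = 0, gc_skew = -0.25,
                           at_codon = NULL, rearrangements = list(),
                           trna_duplications = list(),
                           cr = list(), spacers = integer(),
                           gene_lengths = integer()) {
  if (abs(at_skew) > 1 || abs(gc_skew) > 1)
    stop("skew targets must lie in [-1, 1]", call. = FALSE)
  if (at_percent < 0 || at_percent > 100)
    stop("at_percent must lie in [0, 100]", call. = FALSE)
  if (is.null(at_codon)) at_codon <- at_percent + c(-10, -2, 12)
  at_codon <- pmin(pmax(at_codon, 0), 100)
  cr_def <- list(length = 437L, poly_t = 13L, repeat_period = 51L,
                 repeat_copies = 4L, repeat_noise = 0.05,
                 hairpin_stem = 8L, hairpin_loop = 6L, at_excess = 10)
  unknown <- setdiff(names(cr), names(cr_def))
  if (length(unknown))
    stop("unknown cr element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cr_def[names(cr)] <- cr
  need <- cr_def$poly_t +
    cr_def$repeat_period * cr_def$repeat_copies +
    2L * cr_def$hairpin_stem + cr_def$hairpin_loop
  if (cr_def$length < need)
    stop("cr length ", cr_def$length, " too short for requested features (",
         need, " b.p.)", call. = FALSE)
  base_labels <- ground_pattern("all")$label
  for (e in rearrangements) {
    if (!(e$type %in% c("translocate", "invert")))
      stop("unknown rearrangement type: ", e$type, call. = FALSE)
    if (!(e$label %in% base_labels))
      stop("rearrangement references unknown label: ", e$label,
           call. = FALSE)
    if (e$type == "translocate" && !(e$after %in% base_labels))
      stop("translocation target label unknown: ", e$after, call. = FALSE)
  }
  for (d in trna_duplications) {
    if (!(d$label %in% base_labels) ||
        (!is.null(d$donor) && !(d$donor %in% base_labels)))
      stop("tRNA duplication references unknown label", call. = FALSE)
    if (d$identity <= 0 || d$identity > 100)
      stop("duplication identity must lie in (0, 100]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), id = id, at_percent = at_percent,
                 at_skew = at_skew, gc_skew = gc_skew, at_codon = at_codon,
                 rearrangements = rearrangements,
                 trna_duplications = trna_duplications, cr = cr_def,
                 spacers = spacers, gene_lengths = gene_lengths),
            class = "synthetic_spec")
}

# plant k substitutions to hit a target identity; returns the mutated
# string and the realized identity
mutate_to_identity <- function(seq, identity) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(v)
  k <- min(round(L * (1 - identity / 100)), L)
  if (k > 0) {
    pos <- sample.int(L, k)
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
  }
  list(seq = paste(v, collapse = ""), realized = 100 * (L - k) / L,
       n_mut = k)
}

build_cr <- function(cr, at_percent, at_skew, gc_skew) {
  at_cr <- min(at_percent + cr$at_excess, 100)
  fr <- base_freqs(at_cr, at_skew, gc_skew)
  parts <- list()
  truth <- list(at_target = at_cr)
  if (cr$poly_t > 0) {
    parts$poly_t <- strrep("T", cr$poly_t)
    truth$poly_t <- cr$poly_t
  }
  if (cr$repeat_period > 0 && cr$repeat_copies >= 2) {
    # the unit is copied, so its composition dominates the repeat tract;
    # constrain it near the CR target or the planted AT excess washes out
    unit <- sample_seq(cr$repeat_period, fr)
    for (try in 1:200) {
      if (abs(composition_stats(unit)$at_percent - at_cr) <= 3) break
      unit <- sample_seq(cr$repeat_period, fr)
    }
    rep_seq <- strrep(unit, cr$repeat_copies)
    if (cr$repeat_noise > 0) {
      # exact mutation count: the planted adjacent-copy identity must hold,
      # not just its expectation
      v <- strsplit(rep_seq, "", fixed = TRUE)[[1]]
      hit <- sample.int(length(v), round(length(v) * cr$repeat_noise))
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(.BASES, b), 1L), character(1))
      rep_seq <- paste(v, collapse = "")
    }
    parts$repeats <- rep_seq
    truth$repeat_period <- cr$repeat_period
    truth$repeat_copies <- cr$repeat_copies
  }
  if (cr$hairpin_stem > 0) {
    arm <- sample_seq(cr$hairpin_stem, fr)
    loop <- sample_seq(cr$hairpin_loop, fr)
    parts$hairpin <- paste0(arm, loop, revcomp(arm))
    truth$hairpin_stem <- cr$hairpin_stem
    truth$hairpin_loop <- cr$hairpin_loop
  }
  used <- sum(nchar(unlist(parts)))
  fill_total <- cr$length - used
  n_slots <- length(parts) + 1L
  fill_len <- diff(round(seq(0, fill_total, length.out = n_slots + 1L)))
  pieces <- character(0)
  for (i in seq_along(parts)) {
    pieces <- c(pieces, sample_seq(fill_len[i], fr), parts[[i]])
  }
  pieces <- c(pieces, sample_seq(fill_len[n_slots], fr))
  seq <- paste(pieces, collapse = "")
  # positions of planted features within the CR (1-based)
  off <- cumsum(c(0L, nchar(pieces)))
  names(off) <- NULL
  plant_pos <- off[seq(2L, by = 2L, length.out = length(parts))] + 1L
  truth$positions <- setNames(plant_pos, names(parts))
  list(seq = seq, truth = truth)
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds the genome described by a [synthetic_spec()] and returns both the
#' genome and a ground-truth record of every planted fact, so analysis
#' results can be checked against what was actually simulated. Identical
#' specs yield byte-identical genomes.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `genome` (a [mito_genome()]) and `truth`
#'   (list: `spec`, per-feature `layout`, `duplications`, `cr`, `spacers`,
#'   `order` -- the rearranged label/strand table).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    ord <- ground_pattern("all")
    for (e in spec$rearrangements) {
      i <- which(ord$label == e$label)
      if (e$type == "invert") {
        ord$strand[i] <- ifelse(ord$strand[i] == "+", "-", "+")
      } else {
        row <- ord[i, , drop = FALSE]
        ord <- ord[-i, , drop = FALSE]
        j <- which(ord$label == e$after)
        ord <- rbind(ord[seq_len(j), , drop = FALSE], row,
                     if (j < nrow(ord)) ord[seq.int(j + 1L, nrow(ord)), ,
                                            drop = FALSE])
      }
    }
    rownames(ord) <- NULL

    glen <- .DEFAULT_GENE_LENGTHS
    glen[names(spec$gene_lengths)] <- unlist(spec$gene_lengths)
    gene_len <- function(lab, kind) {
      if (lab %in% names(glen)) {
        L <- glen[[lab]]
        if (kind == "PCG") L <- 3L * (L %/% 3L)
        L
      } else if (kind == "tRNA") .DEFAULT_TRNA_LENGTH
      else if (kind == "CR") spec$cr$length
      else stop("no length for ", lab, call. = FALSE)
    }

    sample_pcg <- function(n_nt, strand_sign) {
      n_cod <- n_nt %/% 3L
      pos_freqs <- lapply(spec$at_codon, function(at)
        base_freqs(at, spec$at_skew * strand_sign,
                   spec$gc_skew * strand_sign))
      m <- vapply(pos_freqs, function(fr)
        sample(names(fr), n_cod, replace = TRUE, prob = fr),
        character(n_cod))
      cod <- apply(m, 1, paste, collapse = "")
      cod[1] <- sample(c("ATA", "ATG", "ATT", "ATC", "TTG", "GTG"), 1L,
                       prob = c(.35, .35, .1, .1, .05, .05))
      cod[n_cod] <- sample(c("TAA", "TAG"), 1L, prob = c(.8, .2))
      paste(cod, collapse = "")
    }

    cr_truth <- NULL
    seqs <- character(nrow(ord))
    for (i in seq_len(nrow(ord))) {
      lab <- ord$label[i]; kind <- ord$kind[i]
      ssign <- if (ord$strand[i] == "+") 1 else -1
      L <- gene_len(lab, kind)
      seqs[i] <- if (kind == "PCG") {
        sample_pcg(L, ssign)
      } else if (kind == "CR") {
        cr_b <- build_cr(spec$cr, spec$at_percent, spec$at_skew,
                         spec$gc_skew)
        cr_truth <- cr_b$truth
        cr_b$seq
      } else {
        sample_seq(L, base_freqs(spec$at_percent, spec$at_skew * ssign,
                                 spec$gc_skew * ssign))
      }
    }

    # planted tRNA duplications: copy-and-mutate, insert after a random
    # feature (never splitting the source from its own annotation)
    feat <- data.frame(label = ord$label, kind = ord$kind,
                       strand = ord$strand, seq = seqs,
                       copy_index = 1L, stringsAsFactors = FALSE)
    dup_truth <- list()
    for (d in spec$trna_duplications) {
      source_lab <- if (is.null(d$donor)) d$label else d$donor
      src <- feat$seq[feat$label == source_lab & feat$copy_index == 1L][1]
      mt <- mutate_to_identity(src, d$identity)
      at_pos <- sample.int(nrow(feat), 1L)
      newrow <- data.frame(label = d$label, kind = "tRNA",
                           strand = feat$strand[feat$label == source_lab][1],
                           seq = mt$seq,
                           copy_index = sum(feat$label == d$label) + 1L,
                           stringsAsFactors = FALSE)
      feat <- rbind(feat[seq_len(at_pos), , drop = FALSE], newrow,
                    if (at_pos < nrow(feat))
                      feat[seq.int(at_pos + 1L, nrow(feat)), , drop = FALSE])
      dup_truth[[length(dup_truth) + 1L]] <-
        data.frame(label = d$label, source = source_lab,
                   remolded = !is.null(d$donor),
                   target_identity = d$identity,
                   realized_identity = mt$realized, n_mut = mt$n_mut,
                   stringsAsFactors = FALSE)
    }

    # assemble the (+) strand, planting unannotated spacers where requested
    pieces <- character(0)
    rows <- list()
    spacer_truth <- list()
    pos <- 0L
    for (i in seq_len(nrow(feat))) {
      s_plus <- if (feat$strand[i] == "+") feat$seq[i] else revcomp(feat$seq[i])
      rows[[length(rows) + 1L]] <-
        data.frame(label = feat$label[i], kind = feat$kind[i],
                   start = pos, end = pos + nchar(s_plus),
                   strand = feat$strand[i], copy_index = feat$copy_index[i],
                   anticodon = NA_character_, stringsAsFactors = FALSE)
      pieces <- c(pieces, s_plus)
      pos <- pos + nchar(s_plus)
      key <- feat$label[i]
      if (feat$copy_index[i] == 1L && key %in% names(spec$spacers)) {
        sl <- spec$spacers[[key]]
        pieces <- c(pieces, sample_seq(sl, base_freqs(spec$at_percent,
                                                      spec$at_skew,
                                                      spec$gc_skew)))
        spacer_truth[[length(spacer_truth) + 1L]] <-
          data.frame(after = key, start = pos, end = pos + sl,
                     length = sl, stringsAsFactors = FALSE)
        pos <- pos + sl
      }
    }
    genome <- mito_genome(spec$id, paste(pieces, collapse = ""),
                          do.call(rbind, rows), circular = TRUE)
    layout <- do.call(rbind, rows)
    truth <- list(spec = spec, order = ord, layout = layout,
                  duplications = if (length(dup_truth))
                    do.call(rbind, dup_truth) else NULL,
                  cr = cr_truth,
                  spacers = if (length(spacer_truth))
                    do.call(rbind, spacer_truth) else NULL)
    list(genome = genome, truth = truth)
  })
}

#' Generate a star-tree gene alignment at a target diversity
#'
#' Every taxon is mutated independently from a common ancestral sequence
#' (star tree: no phylogenetic correlation) with per-site substitution
#' probability `q` solving `p = 2q - (4/3)q^2`, i.e.
#' `q = (3/4)(1 - sqrt(1 - (4/3)p))`, so the expected pairwise per-site
#' difference equals `p` (substitutions pick one of the three other bases
#' uniformly; sites i.i.d.).
#'
#' @param gene gene label for the result.
#' @param n_taxa number of taxa (>= 2).
#' @param p target expected pairwise difference per site, in `[0, 0.75]`.
#' @param length alignment length in b.p.
#' @param seed RNG seed.
#' @param at_percent ancestor AT content (percent).
#' @return a [gene_alignment()] with taxa `t1..t<n>`.
#' @export
generate_alignment <- function(gene, n_taxa, p, length, seed = 1L,
                               at_percent = 65) {
  if (p < 0 || p > 0.75)
    stop("p must lie in [0, 0.75]", call. = FALSE)
  if (n_taxa < 2L) stop("need >= 2 taxa", call. = FALSE)
  with_seed(seed, {
    q <- 0.75 * (1 - sqrt(1 - (4 / 3) * p))
    fr <- base_freqs(at_percent, 0, 0)
    anc <- strsplit(sample_seq(length, fr), "", fixed = TRUE)[[1]]
    rows <- vapply(seq_len(n_taxa), function(i) {
      v <- anc
      hit <- which(runif(length) < q)
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(.BASES, b), 1L), character(1))
      paste(v, collapse = "")
    }, character(1))
    gene_alignment(gene, setNames(rows, paste0("t", seq_len(n_taxa))))
  })
}

#' Write a simulated genome bundle
#'
#' Emits the GenBank flat file, the FASTA + feature-table pair, and the
#' ground-truth JSON for a [generate_genome()] result.
#'
#' @param sim result of [generate_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$genome$id
  paths <- c(genbank = file.path(dir, paste0(id, ".gb")),
             fasta = file.path(dir, paste0(id, ".fasta")),
             table = file.path(dir, paste0(id, ".features.tsv")),
             truth = file.path(dir, paste0(id, ".truth.json")))
  write_genbank(sim$genome, paths[["genbank"]])
  write_feature_table(sim$genome, paths[["fasta"]], paths[["table"]])
  truth <- sim$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(paths)
}
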