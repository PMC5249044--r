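# Duplicated tRNA genes and remolding calls.
#
# A duplicated tRNA that is highly similar to a NON-cognate isoacceptor
# suggests remolding (identity switch via anticodon mutation); a pair that
# is only similar to itself suggests a recent in-place duplication.

#' Find duplicated tRNA labels
#'
#' @param genome a [mito_genome()].
#' @return data.frame with columns `label`, `n_copies` for every tRNA label
#'   annotated more than once (zero rows if none).
#' @export
find_duplicate_trnas <- function(genome) {
  fe <- genome$features[genome$features$kind == "tRNA", , drop = FALSE]
  if (!nrow(fe))
    return(data.frame(label = character(), n_copies = integer()))
  tb <- table(fe$label)
  dup <- tb[tb >= 2L]
  data.frame(label = names(dup), n_copies = as.integer(dup),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan a genome for tRNA remolding candidates
#'
#' For every duplicated tRNA label, each copy is compared (global alignment
#' identity, [pairwise_identity()]) against every other tRNA gene in the
#' genome. `best_donor` is the non-cognate label with maximal identity over
#' either copy. Calls: `remolded-candidate` when the best donor identity
#' reaches `donor_threshold`; otherwise `recent-duplicate` when the
#' within-pair identity reaches `within_threshold` or exceeds every donor
#' identity (the copies are closer to each other than to any non-cognate
#' tRNA); otherwise `ambiguous`.
#' Comparison is nucleotide-level on coding-sense sequences; the anticodon
#' (when annotated) is reported, not masked.
#'
#' @param genome a [mito_genome()].
#' @param donor_threshold minimal donor identity (percent) for a
#'   remolded-candidate call (default 65).
#' @param within_threshold minimal within-pair identity (percent) for a
#'   recent-duplicate call (default 85).
#' @return data.frame with one row per duplicated label: `label`,
#'   `n_copies`, `within_identity`, `best_donor`, `donor_identity`,
#'   `donor_copy` (which copy matched the donor), `call`.
#' @export
remolding_scan <- function(genome, donor_threshold = 65,
                           within_threshold = 85) {
  dups <- find_duplicate_trnas(genome)
  if (!nrow(dups))
    return(data.frame(label = character(), n_copies = integer(),
                      within_identity = numeric(), best_donor = character(),
                      donor_identity = numeric(), donor_copy = integer(),
                      call = character()))
  fe <- genome$features[genome$features$kind == "tRNA", , drop = FALSE]
  seqs <- lapply(seq_len(nrow(fe)), function(i)
    gene_sequence(genome, fe[i, , drop = FALSE]))
  rows <- lapply(seq_len(nrow(dups)), function(k) {
    lab <- dups$label[k]
    ci <- which(fe$label == lab)
    oi <- which(fe$label != lab)
    within <- max(vapply(utils::combn(ci, 2L, simplify = FALSE), function(p)
      pairwise_identity(seqs[[p[1]]], seqs[[p[2]]])$percent_identity,
      numeric(1)))
    best_donor <- NA_character_; donor_id <- NA_real_; donor_copy <- NA_integer_
    if (length(oi)) {
      grid <- expand.grid(copy = ci, other = oi)
      ids <- vapply(seq_len(nrow(grid)), function(r)
        pairwise_identity(seqs[[grid$copy[r]]],
                          seqs[[grid$other[r]]])$percent_identity,
        numeric(1))
      b <- which.max(ids)
      best_donor <- fe$label[grid$other[b]]
      donor_id <- ids[b]
      donor_copy <- fe$copy_index[grid$copy[b]]
    }
    call <- if (!is.na(donor_id) && donor_id >= donor_threshold)
      "remolded-candidate"
    else if (within >= within_threshold ||
             (!is.na(donor_id) && within > donor_id)) "recent-duplicate"
    else "ambiguous"
    data.frame(label = lab, n_copies = dups$n_copies[k],
               within_identity = within, best_donor = best_donor,
               donor_identity = donor_id, donor_copy = donor_copy,
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise identity matrix over all tRNA genes of a genome
#'
#' @param genome a [mito_genome()].
#' @return symmetric numeric matrix of percent identities; dimnames are
#'   `label` (or `label.copy_index` for duplicates).
#' @export
trna_identity_matrix <- function(genome) {
  seqs <- gene_sequences(genome, "tRNA")
  n <- length(seqs)
  if (n < 2L) stop("fewer than 2 tRNA genes", call. = FALSE)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    m[i, j] <- m[j, i] <-
      pairwise_identity(seqs[[i]], seqs[[j]])$percent_identity
  }
  m
}
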