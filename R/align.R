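# Global pairwise alignment (Needleman-Wunsch, linear gap penalty) used for
# tRNA/region identity and the codon-aware protein aligner. Written as a
# vectorized per-row recurrence: with linear gaps the within-row dependency
#   d[i,j] = max(e[j], d[i,j-1] + gap),  e[j] = max(diag + s, up + gap)
# unrolls to d[i,j] = max_k<=j (e[k] + gap*(j-k)) = cummax(e - gap*j) + gap*j.

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, gap -2
#' (linear) by default. Traceback ties are broken deterministically with
#' precedence diagonal > up (gap in `b`) > left (gap in `a`), the "high
#' road".
#'
#' @param a,b sequences (character strings; any alphabet).
#' @param match,mismatch,gap scoring parameters.
#' @return list with `score`, `aligned_a`, `aligned_b`, `matches`,
#'   `columns`.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(va); m <- length(vb)
  if (n == 0L || m == 0L) stop("empty sequence", call. = FALSE)
  D <- matrix(0, n + 1L, m + 1L)
  D[1, ] <- gap * (0:m)
  D[, 1] <- gap * (0:n)
  jj <- seq_len(m)
  gj <- gap * jj
  for (i in seq_len(n)) {
    s <- ifelse(vb == va[i], match, mismatch)
    e <- pmax(D[i, jj] + s, D[i, jj + 1L] + gap)
    # horizontal closure: d[j] = max_{k<=j}(e[k] + gap*(j-k)); also allow
    # the all-gap path from D[i+1,1]
    D[i + 1L, jj + 1L] <- cummax(c(D[i + 1L, 1L], e - gj))[-1L] + gj
  }
  # deterministic traceback, precedence diag > up > left
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] ==
          D[i, j] + (if (va[i] == vb[j]) match else mismatch)) {
      ra <- c(va[i], ra); rb <- c(vb[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + gap) {
      ra <- c(va[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(vb[j], rb); j <- j - 1L
    }
  }
  list(score = D[n + 1L, m + 1L],
       aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       matches = sum(ra == rb & ra != "-"),
       columns = length(ra))
}

#' Percent identity from global alignment
#'
#' Identity is 100 * matches / alignment columns under the package's fixed
#' global-alignment scoring (match +1, mismatch -1, gap -2, deterministic
#' traceback), reported to 2 decimal places as `percent_identity`.
#'
#' @inheritParams nw_align
#' @return an object of class `identity_result`: list with
#'   `percent_identity`, `matches`, `aligned_length`, `score`.
#' @export
#' @examples
#' pairwise_identity("ACGT", "ACGT")$percent_identity  # 100
pairwise_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  al <- nw_align(toupper(a), toupper(b), match, mismatch, gap)
  structure(list(percent_identity = round(100 * al$matches / al$columns, 2),
                 matches = al$matches, aligned_length = al$columns,
                 score = al$score),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("identity %.2f%% (%d/%d columns, score %g)\n",
              x$percent_identity, x$matches, x$aligned_length, x$score))
  invisible(x)
}

#' Identity between two genomic regions
#'
#' Convenience wrapper around [pairwise_identity()] for comparing
#' non-coding regions (e.g. a duplicated control-region flank against the
#' original).
#'
#' @inheritParams pairwise_identity
#' @return an `identity_result`.
#' @export
region_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  pairwise_identity(a, b, match, mismatch, gap)
}

# ---------------------------------------------------------------------------
# Minimal codon-aware multiple aligner: translate under table 5, center-star
# protein alignment with the NW core, back-translate gaps to codon triples.
# Desk-scale convenience; externally produced alignments are first-class
# input everywhere else.

translate5 <- function(cds) {
  code <- mito_code()
  cod <- cds_codons(cds)
  aa <- code[cod]
  aa[is.na(aa)] <- "X"
  aa[aa == "*"] <- "X"  # internal stops aligned as unknowns
  paste(aa, collapse = "")
}

# merge pairwise center alignments into an MSA by gap propagation
#' Codon-aware multiple alignment
#'
#' Translates coding-sense CDS under the invertebrate mitochondrial code,
#' builds a center-star protein alignment (center = longest sequence, global
#' pairwise alignments against it), and back-translates so gaps come in
#' whole codons. Trailing partial codons are dropped.
#'
#' @param seqs named character vector of coding-sense CDS (>= 2).
#' @param gene label stored on the result.
#' @return a [gene_alignment()].
#' @export
codon_aware_align <- function(seqs, gene = "gene") {
  if (length(seqs) < 2L) stop("need >= 2 sequences", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s)
    substr(s, 1L, 3L * (nchar(s) %/% 3L)), character(1))
  prot <- vapply(seqs, translate5, character(1))
  center <- which.max(nchar(prot))
  others <- setdiff(seq_along(seqs), center)
  pals <- lapply(others, function(i)
    nw_align(prot[center], prot[i], match = 1, mismatch = -1, gap = -2))
  # column map: for each pairwise alignment, positions of center residues
  n_c <- nchar(prot[center])
  # master gap pattern: for each center-residue boundary, max insertions
  ins <- matrix(0L, nrow = length(others), ncol = n_c + 1L)
  for (k in seq_along(pals)) {
    ca <- strsplit(pals[[k]]$aligned_a, "", fixed = TRUE)[[1]]
    slot <- 0L; run <- 0L
    for (ch in ca) {
      if (ch == "-") run <- run + 1L
      else { ins[k, slot + 1L] <- run; slot <- slot + 1L; run <- 0L }
    }
    ins[k, n_c + 1L] <- run
  }
  max_ins <- apply(ins, 2, max)
  width <- n_c + sum(max_ins)
  rows <- matrix("-", nrow = length(seqs), ncol = width)
  # lay out center row
  col_of_res <- integer(n_c)
  col <- 0L
  for (r in seq_len(n_c)) {
    col <- col + max_ins[r] + 1L
    col_of_res[r] <- col
  }
  vc <- strsplit(prot[center], "", fixed = TRUE)[[1]]
  rows[center, col_of_res] <- vc
  for (k in seq_along(pals)) {
    i <- others[k]
    ca <- strsplit(pals[[k]]$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(pals[[k]]$aligned_b, "", fixed = TRUE)[[1]]
    out <- character(width)
    out[] <- "-"
    slot <- 0L; pend <- character(0)
    place_run <- function(out, slot, pend) {
      if (length(pend)) {
        # right-align the inserted residues just before this residue column
        base <- if (slot == 0L) 0L else col_of_res[slot]
        cols <- base + seq_along(pend)
        out[cols] <- pend
      }
      out
    }
    for (p in seq_along(ca)) {
      if (ca[p] == "-") {
        pend <- c(pend, cb[p])
      } else {
        out <- place_run(out, slot, pend)
        pend <- character(0)
        slot <- slot + 1L
        out[col_of_res[slot]] <- cb[p]
      }
    }
    out <- place_run(out, slot, pend)
    rows[i, ] <- out
  }
  # back-translate: protein column -> codon or "---"
  nt_rows <- vapply(seq_along(seqs), function(i) {
    cods <- cds_codons(seqs[i])
    r <- rows[i, ]
    filled <- character(length(r))
    ci <- 0L
    for (p in seq_along(r)) {
      if (r[p] == "-") filled[p] <- "---"
      else { ci <- ci + 1L; filled[p] <- cods[ci] }
    }
    paste(filled, collapse = "")
  }, character(1))
  gene_alignment(gene, setNames(nt_rows, names(seqs)))
}
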