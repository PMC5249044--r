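# Per-gene nucleotide diversity (pi) from aligned sequences.
#
# pi is the plain mean, over all C(n,2) sequence pairs, of the per-site
# difference proportion; sites containing a gap or N in ANY row are excluded
# first ("complete deletion", the DnaSP default). No (n/(n-1)) correction.

#' Construct a gene alignment
#'
#' @param gene canonical gene label.
#' @param seqs named character vector of equal-length aligned sequences over
#'   `A,C,G,T,N,-` (names are taxon/genome ids).
#' @return an object of class `gene_alignment`: list with `gene`, `taxa`,
#'   `seqs`, `length`.
#' @export
gene_alignment <- function(gene, seqs) {
  if (length(seqs) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned rows must have equal length", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("t", seq_along(seqs))
  structure(list(gene = gene, taxa = names(seqs), seqs = seqs,
                 length = nchar(seqs[[1]])),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("gene_alignment %s: %d taxa x %d sites\n",
              x$gene, length(x$taxa), x$length))
  invisible(x)
}

#' Read a per-gene alignment from aligned FASTA
#'
#' @param path aligned FASTA file.
#' @param gene gene label (default: file name without extension).
#' @return a [gene_alignment()].
#' @export
read_gene_alignment <- function(path, gene = NULL) {
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  gene_alignment(gene, setNames(as.character(ss), names(ss)))
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment a [gene_alignment()].
#' @param path output path.
#' @export
write_gene_alignment <- function(alignment, path) {
  ss <- Biostrings::BStringSet(alignment$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Nucleotide diversity (pi)
#'
#' Average pairwise per-site nucleotide difference among the aligned rows.
#' Sites with a gap or N in any row are excluded (complete deletion);
#' set `deletion = "pairwise"` to instead drop sites per pair.
#'
#' @param alignment a [gene_alignment()], or a named character vector of
#'   aligned sequences.
#' @param deletion `"complete"` (default) or `"pairwise"` treatment of
#'   gap/N-containing sites.
#' @return an object of class `pi_result`: list with `gene`, `pi`,
#'   `n_taxa`, `n_sites` (sites used; for pairwise deletion, the minimum
#'   over pairs).
#' @export
#' @examples
#' a <- gene_alignment("toy", c(s1 = "AAAA", s2 = "AAAT"))
#' nucleotide_diversity(a)$pi   # 0.25
nucleotide_diversity <- function(alignment,
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (!inherits(alignment, "gene_alignment"))
    alignment <- gene_alignment("gene", alignment)
  m <- do.call(rbind, strsplit(alignment$seqs, "", fixed = TRUE))
  ok <- m %in% .BASES
  dim(ok) <- dim(m)
  n <- nrow(m)
  pairs <- utils::combn(n, 2L)
  if (deletion == "complete") {
    use <- colSums(ok) == n
    if (!any(use)) stop("zero usable sites after complete deletion",
                        call. = FALSE)
    m <- m[, use, drop = FALSE]
    d <- apply(pairs, 2, function(p) mean(m[p[1], ] != m[p[2], ]))
    n_sites <- sum(use)
  } else {
    res <- apply(pairs, 2, function(p) {
      u <- ok[p[1], ] & ok[p[2], ]
      if (!any(u)) return(c(NA_real_, 0))
      c(mean(m[p[1], u] != m[p[2], u]), sum(u))
    })
    d <- res[1, ]
    if (all(is.na(d))) stop("zero usable sites in every pair", call. = FALSE)
    n_sites <- min(res[2, res[2, ] > 0])
  }
  structure(list(gene = alignment$gene, pi = mean(d, na.rm = TRUE),
                 n_taxa = n, n_sites = as.integer(n_sites)),
            class = "pi_result")
}

#' @export
print.pi_result <- function(x, ...) {
  cat(sprintf("pi(%s) = %.4f  [%d taxa, %d sites]\n",
              x$gene, x$pi, x$n_taxa, x$n_sites))
  invisible(x)
}

#' Nucleotide diversity per gene over a taxon panel
#'
#' Restricts each alignment to the panel taxa present in it and computes
#' [nucleotide_diversity()] per gene. Genes with fewer than 2 panel taxa are
#' omitted with a warning.
#'
#' @param alignments list of [gene_alignment()] objects.
#' @param panel character vector of taxon ids; `NULL` uses all taxa.
#' @param deletion passed to [nucleotide_diversity()].
#' @return data.frame with columns `gene`, `n_taxa`, `n_sites`, `pi`.
#' @export
panel_pi <- function(alignments, panel = NULL,
                     deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (!is.null(panel) && !length(panel)) stop("empty panel", call. = FALSE)
  rows <- list()
  for (al in alignments) {
    keep <- if (is.null(panel)) al$taxa else intersect(al$taxa, panel)
    if (length(keep) < 2L) {
      warning("gene ", al$gene, " has < 2 panel taxa; omitted",
              call. = FALSE)
      next
    }
    sub <- gene_alignment(al$gene, al$seqs[keep])
    p <- nucleotide_diversity(sub, deletion)
    rows[[length(rows) + 1L]] <-
      data.frame(gene = p$gene, n_taxa = p$n_taxa, n_sites = p$n_sites,
                 pi = p$pi, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), n_taxa = integer(),
                      n_sites = integer(), pi = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
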