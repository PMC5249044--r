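# Codon usage under the invertebrate mitochondrial code (translation table
# 5), start/stop classification, GC3s, and Wright's effective number of
# codons (Nc).

# genetic code table 5 as a named vector codon -> amino acid ('*' = stop)
mito_code <- function() {
  gc5 <- Biostrings::getGeneticCode("5")
  setNames(as.character(gc5), names(gc5))
}

# synonymous family partition of table 5; Leu (6 codons) and Ser (8 codons)
# are kept as single families with their own degeneracy class by default;
# split_families = TRUE splits them 2+4 / 4+4 by codon block.
codon_families <- function(split_families = FALSE) {
  code <- mito_code()
  sense <- names(code)[code != "*"]
  fam <- code[sense]
  if (split_families) {
    fam[sense %in% c("TTA", "TTG")] <- "L_TTR"
    fam[sense %in% c("CTT", "CTC", "CTA", "CTG")] <- "L_CTN"
    fam[sense %in% c("TCT", "TCC", "TCA", "TCG")] <- "S_TCN"
    fam[sense %in% c("AGT", "AGC", "AGA", "AGG")] <- "S_AGN"
  }
  split(sense, fam)
}

.ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"), paste0),
                               c("T", "C", "A", "G"), paste0))

# split coding-sense CDS into codons; trailing partial codon dropped;
# codons containing N/ambiguity are dropped from counts
cds_codons <- function(cds_set) {
  unlist(lapply(toupper(cds_set), function(s) {
    n_cod <- nchar(s) %/% 3L
    if (n_cod == 0L) return(character(0))
    substring(s, seq(1L, by = 3L, length.out = n_cod),
              seq(3L, by = 3L, length.out = n_cod))
  }), use.names = FALSE)
}

#' Codon usage table
#'
#' Pools codon counts over a set of coding-sense CDS under the invertebrate
#' mitochondrial code. Incomplete trailing codons, stop codons and codons
#' containing ambiguity characters are excluded.
#'
#' @param cds_set character vector of coding-sense CDS.
#' @return an object of class `codon_usage`: data.frame with columns
#'   `codon`, `aa`, `count`, `percent` (percents sum to 100), 62 sense-codon
#'   rows, plus attribute `n_codons`.
#' @export
#' @examples
#' cu <- codon_usage("TTTTTA")
#' cu[cu$count > 0, ]     # TTT 50%, TTA 50%
codon_usage <- function(cds_set) {
  if (!length(cds_set)) stop("empty CDS set", call. = FALSE)
  code <- mito_code()
  cod <- cds_codons(cds_set)
  cod <- cod[cod %in% names(code)]
  cod <- cod[code[cod] != "*"]
  if (!length(cod)) stop("no countable codons in CDS set", call. = FALSE)
  sense <- .ALL_CODONS[code[.ALL_CODONS] != "*"]
  counts <- table(factor(cod, levels = sense))
  out <- data.frame(codon = sense, aa = unname(code[sense]),
                    count = as.integer(counts),
                    percent = 100 * as.integer(counts) / length(cod),
                    stringsAsFactors = FALSE)
  attr(out, "n_codons") <- length(cod)
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' Classify start and stop codons of a CDS
#'
#' Mitochondrial PCGs initiate at ATA/ATG or at the unusual starts ATT, ATC,
#' TTG, GTG, and may end in a truncated stop (`T` or `TA`) completed by
#' post-transcriptional polyadenylation, recognized here when the CDS length
#' modulo 3 is 1 or 2.
#'
#' @param cds coding-sense CDS, at least 4 nt.
#' @return list with `start`, `stop`, `start_standard` (in the six-codon
#'   mitochondrial start set), `stop_truncated`.
#' @export
#' @examples
#' classify_start_stop("ATGAAATAA")  # ATG / TAA
#' classify_start_stop("GTGAAAT")    # GTG / truncated "T"
classify_start_stop <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 4L) stop("CDS shorter than 4 nt", call. = FALSE)
  start <- substr(cds, 1L, 3L)
  rem <- nchar(cds) %% 3L
  stop_cod <- if (rem == 0L) substr(cds, nchar(cds) - 2L, nchar(cds))
              else substr(cds, nchar(cds) - rem + 1L, nchar(cds))
  list(start = start, stop = stop_cod,
       start_standard = start %in% c("ATA", "ATG", "ATT", "ATC", "TTG", "GTG"),
       stop_truncated = rem != 0L)
}

#' Wright's effective number of codons (Nc)
#'
#' For each synonymous family with codon count `n` and within-family codon
#' frequencies `p`, the codon homozygosity is `F = (n * sum(p^2) - 1)/(n - 1)`.
#' Nc sums, over the degeneracy classes of the family partition, the number
#' of families in the class divided by the mean F of that class. Families
#' with fewer than 2 codons (or F <= 0) are imputed by the mean F of
#' same-degeneracy families; if the whole class is missing, by the
#' reciprocal of the degeneracy. Nc is capped at the number of sense codons.
#'
#' Under translation table 5 with the default single-family convention for
#' Leu and Ser the partition has 12 two-fold, 6 four-fold, one six-fold and
#' one eight-fold family (62 sense codons), so Nc ranges from 20 (extreme
#' bias) to 62 (uniform usage).
#'
#' @param cds_set character vector of coding-sense CDS (typically the 13
#'   PCGs of one genome). Stop codons are excluded.
#' @param split_families split the Leu and Ser families into their 2+4 / 4+4
#'   codon blocks instead of the single-family convention?
#' @return an object of class `enc_result`: list with `nc`, `gc3s`,
#'   `family_homozygosity` (mean F per degeneracy class), `n_codons`.
#' @export
enc <- function(cds_set, split_families = FALSE) {
  fams <- codon_families(split_families)
  cod <- cds_codons(cds_set)
  code <- mito_code()
  cod <- cod[cod %in% names(code) & code[cod] != "*"]
  if (length(cod) < 2L) stop("fewer than 2 sense codons", call. = FALSE)
  counts <- table(factor(cod, levels = unlist(fams, use.names = FALSE)))

  deg <- vapply(fams, length, integer(1))
  f_hat <- vapply(names(fams), function(f) {
    n_i <- as.numeric(counts[fams[[f]]])
    n <- sum(n_i)
    if (n < 2) return(NA_real_)
    p <- n_i / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  f_hat[!is.na(f_hat) & f_hat <= 0] <- NA_real_

  classes <- sort(unique(deg))
  classes <- classes[classes > 1L]  # single-codon families add their count
  f_bar <- setNames(numeric(length(classes)), classes)
  for (k in classes) {
    fk <- f_hat[deg == k]
    f_bar[as.character(k)] <- if (any(!is.na(fk))) mean(fk, na.rm = TRUE)
                              else 1 / k
  }
  nc <- sum(deg == 1L) +
    sum(vapply(classes, function(k)
      sum(deg == k) / f_bar[as.character(k)], numeric(1)))
  nc <- min(nc, sum(deg))
  structure(list(nc = nc, gc3s = gc3s(cds_set, split_families),
                 family_homozygosity = f_bar, n_codons = length(cod)),
            class = "enc_result")
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("Nc = %.2f | GC3s = %.3f | %d codons\n",
              x$nc, x$gc3s, x$n_codons))
  invisible(x)
}

#' GC content at synonymous third codon positions (GC3s)
#'
#' Fraction of G+C at the third positions of codons belonging to synonymous
#' families (degeneracy >= 2); single-codon families and stops are excluded.
#' Under translation table 5 every sense codon belongs to a synonymous
#' family. Set `all_sites = TRUE` for plain third-position GC over all sense
#' codons regardless of partition.
#'
#' @inheritParams enc
#' @param all_sites ignore the synonymous-family restriction?
#' @return fraction in `[0, 1]`.
#' @export
gc3s <- function(cds_set, split_families = FALSE, all_sites = FALSE) {
  fams <- codon_families(split_families)
  cod <- cds_codons(cds_set)
  code <- mito_code()
  cod <- cod[cod %in% names(code) & code[cod] != "*"]
  if (length(cod) < 2L) stop("fewer than 2 sense codons", call. = FALSE)
  if (!all_sites) {
    syn <- unlist(fams[vapply(fams, length, integer(1)) >= 2L],
                  use.names = FALSE)
    cod <- cod[cod %in% syn]
  }
  third <- substr(cod, 3L, 3L)
  mean(third %in% c("G", "C"))
}

#' Correlation between Nc and GC3s across genomes
#'
#' Pearson correlation between the effective number of codons and GC3s over
#' a set of genomes; a strong positive correlation indicates that codon
#' usage bias tracks third-position base composition (mutational bias)
#' rather than translational selection.
#'
#' @param results list of [enc()] results (or a data.frame with columns
#'   `nc` and `gc3s`), one per genome; at least 3.
#' @return list with `r` (Pearson coefficient) and `n`.
#' @export
enc_gc3s_correlation <- function(results) {
  if (is.data.frame(results)) {
    nc <- results$nc; g3 <- results$gc3s
  } else {
    nc <- vapply(results, function(x) x$nc, numeric(1))
    g3 <- vapply(results, function(x) x$gc3s, numeric(1))
  }
  if (length(nc) < 3L) stop("need at least 3 genomes", call. = FALSE)
  if (stats::sd(nc) == 0 || stats::sd(g3) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  list(r = cor(nc, g3), n = length(nc))
}
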