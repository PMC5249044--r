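# Annotated mitogenome container and I/O.
#
# Internal coordinates are 0-based half-open on the (+) strand; all file
# formats use 1-based inclusive coordinates. A feature with start > end
# encodes a wrap around the origin of a circular genome; normalization to a
# contiguous sequence happens only at extraction time, so deposited
# coordinates are preserved.

.BASES <- c("A", "C", "G", "T")

# reverse complement of a plain character string (N and ambiguity codes kept)
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# substring with circular wrap: 0-based half-open (start, end); start > end
# means the slice crosses the origin.
extract_span <- function(sequence, start, end, circular) {
  L <- nchar(sequence)
  if (start < end) return(substr(sequence, start + 1L, end))
  if (!circular) stop("wrap-around span on a linear sequence", call. = FALSE)
  paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end))
}

span_length <- function(start, end, genome_length) {
  ifelse(start < end, end - start, genome_length - start + end)
}

new_feature_df <- function(label = character(), kind = character(),
                           start = integer(), end = integer(),
                           strand = character(), copy_index = integer(),
                           anticodon = character()) {
  data.frame(label = label, kind = kind, start = as.integer(start),
             end = as.integer(end), strand = strand,
             copy_index = as.integer(copy_index), anticodon = anticodon,
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitochondrial genome
#'
#' @param id accession-like identifier.
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive).
#' @param features data.frame with columns `label`, `kind` (`PCG`, `tRNA`,
#'   `rRNA`, `CR`, `spacer`), `start`, `end` (0-based half-open on the (+)
#'   strand; `start > end` encodes an origin-spanning feature on a circular
#'   genome), `strand` (`"+"`/`"-"`), and optionally `copy_index` and
#'   `anticodon`.
#' @param circular is the molecule circular?
#' @return an object of class `mito_genome`: a list with elements `id`,
#'   `sequence`, `circular`, `features` (sorted by `start`), `length`.
#' @export
mito_genome <- function(id, sequence, features = NULL, circular = TRUE) {
  sequence <- toupper(gsub("[^A-Za-z]", "", sequence))
  if (!grepl("^[ACGTN]*$", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  L <- nchar(sequence)
  if (L == 0L) stop("empty genome sequence", call. = FALSE)
  if (is.null(features)) features <- new_feature_df()
  if (!("copy_index" %in% names(features)))
    features$copy_index <- 1L
  if (!("anticodon" %in% names(features)))
    features$anticodon <- NA_character_
  features <- new_feature_df(features$label, features$kind,
                             features$start, features$end,
                             features$strand, features$copy_index,
                             features$anticodon)
  if (nrow(features)) {
    bad <- features$start < 0L | features$start >= L | features$end < 0L |
      features$end > L
    if (any(bad))
      stop("feature coordinates outside [0, genome length]: ",
           paste(features$label[bad], collapse = ", "), call. = FALSE)
    wrap <- features$start >= features$end
    if (any(wrap) && !circular)
      stop("wrap-around feature on a linear genome: ",
           paste(features$label[wrap], collapse = ", "), call. = FALSE)
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'", call. = FALSE)
    dup <- duplicated(features[, c("label", "copy_index")])
    if (any(dup))
      stop("duplicate (label, copy_index): ",
           paste(features$label[dup], collapse = ", "), call. = FALSE)
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = id, sequence = sequence, circular = circular,
                 features = features, length = L),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("mito_genome %s: %s b.p., %s, %d features\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features)) {
    k <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(k), k), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the coding-sense sequence of a feature
#'
#' Returns the (+)-strand slice for a `+` feature and the reverse complement
#' for a `-` feature, so downstream per-gene statistics are computed on the
#' mRNA-like sense. Origin-spanning features on circular genomes are handled.
#'
#' @param genome a [mito_genome()].
#' @param feature either a single row of `genome$features`, a feature row
#'   index, or a label (optionally with `copy` to disambiguate duplicates).
#' @param copy copy index used when `feature` is a label.
#' @return a DNA string.
#' @export
gene_sequence <- function(genome, feature, copy = 1L) {
  stopifnot(inherits(genome, "mito_genome"))
  if (is.character(feature)) {
    i <- which(genome$features$label == feature &
                 genome$features$copy_index == copy)
    if (length(i) != 1L)
      stop("feature '", feature, "' (copy ", copy, ") not found", call. = FALSE)
    feature <- genome$features[i, , drop = FALSE]
  } else if (is.numeric(feature)) {
    feature <- genome$features[feature, , drop = FALSE]
  }
  if (!is.data.frame(feature) || nrow(feature) != 1L)
    stop("'feature' must identify exactly one feature", call. = FALSE)
  s <- extract_span(genome$sequence, feature$start, feature$end,
                    genome$circular)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Coding-sense sequences of all features of a kind
#'
#' @param genome a [mito_genome()].
#' @param kind feature kind to extract (default `"PCG"`).
#' @return named character vector (names `label` or `label.copy_index` for
#'   duplicated labels).
#' @export
gene_sequences <- function(genome, kind = "PCG") {
  fe <- genome$features[genome$features$kind %in% kind, , drop = FALSE]
  if (!nrow(fe)) return(setNames(character(0), character(0)))
  nm <- ifelse(fe$copy_index > 1L,
               paste0(fe$label, ".", fe$copy_index), fe$label)
  out <- vapply(seq_len(nrow(fe)), function(i)
    gene_sequence(genome, fe[i, , drop = FALSE]), character(1))
  setNames(out, nm)
}

# ---------------------------------------------------------------------------
# GenBank flat files

# parse a GenBank location string into (start0, end0, strand); supports
# complement(), two-interval join() for origin wraps, and <,> partial marks.
parse_gb_location <- function(loc, genome_length, line = NA) {
  raw <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  if (grepl("^complement\\(", raw)) {
    strand <- "-"
    raw <- sub("^complement\\((.*)\\)$", "\\1", raw)
  }
  if (grepl("^join\\(", raw)) {
    raw <- sub("^join\\((.*)\\)$", "\\1", raw)
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("unsupported multi-interval location at line ", line, ": ", loc,
           call. = FALSE)
    iv <- lapply(parts, parse_gb_interval, loc = loc, line = line)
    if (iv[[1]][2] != genome_length || iv[[2]][1] != 1L)
      stop("join() that is not an origin wrap at line ", line, ": ", loc,
           call. = FALSE)
    return(list(start = iv[[1]][1] - 1L, end = iv[[2]][2], strand = strand))
  }
  iv <- parse_gb_interval(raw, loc = loc, line = line)
  list(start = iv[1] - 1L, end = iv[2], strand = strand)
}

parse_gb_interval <- function(x, loc, line) {
  if (grepl("^\\d+$", x)) return(c(as.integer(x), as.integer(x)))
  m <- regmatches(x, regexec("^(\\d+)\\.\\.(\\d+)$", x))[[1]]
  if (length(m) != 3L)
    stop("malformed GenBank location at line ", line, ": ", loc,
         call. = FALSE)
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Read a GenBank flat file
#'
#' Parses a single-record GenBank flat file with `gene`/`CDS`/`tRNA`/`rRNA`/
#' `D-loop`/`misc_feature` annotations and an `ORIGIN` sequence block.
#' Coordinates (1-based inclusive, `complement()`, origin-spanning
#' two-interval `join()`) are converted to the internal 0-based half-open
#' convention; circular topology is read from the `LOCUS` line; labels are
#' canonicalized with [canonical_label()]. Plain `gene` features duplicating
#' a CDS/tRNA/rRNA interval are dropped.
#'
#' @param path file path.
#' @return a [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i))
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  locus <- lines[locus_i[1]]
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  circular <- grepl("circular", locus, ignore.case = TRUE)

  ori_i <- grep("^ORIGIN", lines)
  if (!length(ori_i))
    stop("malformed GenBank record (no ORIGIN) at line ", length(lines),
         ": ", path, call. = FALSE)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > ori_i[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence))
    stop("malformed GenBank record (empty ORIGIN) at line ", ori_i[1],
         ": ", path, call. = FALSE)
  L <- nchar(sequence)

  feat_i <- grep("^FEATURES", lines)
  feats <- new_feature_df()
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(ori_i[1] - 1L)]
    block_line <- (feat_i[1] + 1L):(ori_i[1] - 1L)
    # feature headers start at column 6; qualifiers at column 22
    hdr <- grepl("^ {4,5}\\S", block)
    idx <- which(hdr)
    rows <- list()
    for (k in seq_along(idx)) {
      i0 <- idx[k]
      i1 <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      parts <- strsplit(trimws(block[i0]), "\\s+")[[1]]
      key <- parts[1]
      loc <- paste(parts[-1], collapse = "")
      # location may continue on following lines until a qualifier starts
      j <- i0 + 1L
      while (j <= i1 && !grepl("^\\s+/", block[j])) {
        loc <- paste0(loc, trimws(block[j])); j <- j + 1L
      }
      quals <- block[seq.int(j, length.out = max(0L, i1 - j + 1L))]
      get_qual <- function(name) {
        m <- grep(paste0("^\\s*/", name, "="), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub("^\"|\"$", "", sub(paste0("^\\s*/", name, "="), "", m[1]))
      }
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     "D-loop" = "CR", misc_feature = NA, gene = "gene", NULL)
      if (is.null(kind)) next
      lab_raw <- get_qual("gene")
      if (is.na(lab_raw)) lab_raw <- get_qual("product")
      if (is.na(lab_raw)) lab_raw <- get_qual("note")
      if (is.na(kind)) { # misc_feature: only keep CR/spacer-like annotations
        if (is.na(lab_raw)) next
        lab <- canonical_label(lab_raw, warn = FALSE)
        if (!(lab %in% c("CR", "spacer"))) next
        kind <- lab
      }
      pos <- parse_gb_location(loc, L, line = block_line[i0])
      lab <- if (!is.na(lab_raw)) canonical_label(lab_raw) else key
      if (kind == "gene") {
        kind <- label_kind(lab)
        if (is.na(kind)) kind <- "gene"
      }
      if (lab %in% c("CR", "spacer")) kind <- lab
      note <- get_qual("note")
      copy_i <- if (!is.na(note) && grepl("^copy \\d+$", note))
        as.integer(sub("^copy ", "", note)) else NA_integer_
      rows[[length(rows) + 1L]] <-
        data.frame(label = lab, kind = kind, start = pos$start, end = pos$end,
                   strand = pos$strand, anticodon = get_qual("anticodon"),
                   copy_note = copy_i, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      feats <- do.call(rbind, rows)
      # drop bare 'gene' rows shadowed by a typed feature on the same span
      typed <- feats$kind != "gene"
      keykey <- paste(feats$label, feats$start, feats$end)
      feats <- feats[typed | !(keykey %in% keykey[typed]), , drop = FALSE]
      feats$kind[feats$kind == "gene"] <- "PCG" # last resort
      # copy_index from /note="copy N" when present; remaining occurrences
      # of the same label take the smallest unused indices in genome order
      feats <- feats[order(feats$start, feats$end), , drop = FALSE]
      feats$copy_index <- NA_integer_
      for (lab in unique(feats$label)) {
        i <- which(feats$label == lab)
        ci <- feats$copy_note[i]
        free <- setdiff(seq_len(length(i) + sum(!is.na(ci))), ci)
        ci[is.na(ci)] <- free[seq_len(sum(is.na(ci)))]
        feats$copy_index[i] <- ci
      }
      feats$copy_note <- NULL
    }
  }
  mito_genome(id, sequence, feats, circular)
}

#' Write a GenBank flat file
#'
#' Emits a minimal single-record flat file ([read_genbank()] round-trips it):
#' `LOCUS` with length and topology, typed features (`CDS`, `tRNA`, `rRNA`,
#' `D-loop` for the control region, `misc_feature` for spacers) with 1-based
#' inclusive locations (`complement()`, origin-spanning `join()`), and the
#' `ORIGIN` sequence block.
#'
#' @param genome a [mito_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome$length
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                   genome$id, L,
                   if (genome$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
           "FEATURES             Location/Qualifiers")
  fe <- genome$features
  fmt_loc <- function(start, end, strand) {
    loc <- if (start < end) sprintf("%d..%d", start + 1L, end)
           else sprintf("join(%d..%d,1..%d)", start + 1L, L, end)
    if (strand == "-") sprintf("complement(%s)", loc) else loc
  }
  for (i in seq_len(nrow(fe))) {
    key <- switch(fe$kind[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop", spacer = "misc_feature", "misc_feature")
    out <- c(out, sprintf("     %-16s%s", key,
                          fmt_loc(fe$start[i], fe$end[i], fe$strand[i])),
             sprintf("                     /gene=\"%s\"", fe$label[i]))
    if (!is.na(fe$anticodon[i]))
      out <- c(out, sprintf("                     /anticodon=\"%s\"",
                            fe$anticodon[i]))
    if (fe$copy_index[i] > 1L)
      out <- c(out, sprintf("                     /note=\"copy %d\"",
                            fe$copy_index[i]))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA + feature table

#' Read a genome from FASTA plus a feature table
#'
#' The table is a TSV with header `label kind start end strand copy_index`
#' (coordinates 1-based inclusive; `start > end` encodes an origin-spanning
#' feature on a circular genome; `copy_index` and an optional `anticodon`
#' column may be omitted).
#'
#' @param fasta path to a single-record FASTA.
#' @param table path to the feature table TSV.
#' @param circular is the molecule circular?
#' @return a [mito_genome()].
#' @export
read_feature_table <- function(fasta, table, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L)
    stop("expected a single-record FASTA: ", fasta, call. = FALSE)
  sequence <- as.character(ss[[1]])
  id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  tb <- read.delim(table, stringsAsFactors = FALSE)
  need <- c("label", "kind", "start", "end", "strand")
  if (!all(need %in% names(tb)))
    stop("feature table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  L <- nchar(sequence)
  if (any(tb$start < 1L | tb$start > L | tb$end < 1L | tb$end > L))
    stop("feature coordinate outside sequence [1, ", L, "]", call. = FALSE)
  if (!("copy_index" %in% names(tb))) tb$copy_index <- 1L
  if (!("anticodon" %in% names(tb))) tb$anticodon <- NA_character_
  tb$anticodon <- as.character(tb$anticodon)
  if (anyDuplicated(tb[, c("label", "copy_index")]))
    stop("duplicate (label, copy_index) in feature table", call. = FALSE)
  feats <- new_feature_df(canonical_label(tb$label, warn = FALSE), tb$kind,
                          tb$start - 1L, tb$end, tb$strand, tb$copy_index,
                          tb$anticodon)
  # 1-based inclusive wrap rows (start > end) already map to start0 >= end
  mito_genome(id, sequence, feats, circular)
}

#' Write the FASTA + feature table pair for a genome
#'
#' @param genome a [mito_genome()].
#' @param fasta,table output paths.
#' @return invisibly, a list with both paths.
#' @export
write_feature_table <- function(genome, fasta, table) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, fasta, width = 70L)
  fe <- genome$features
  tb <- data.frame(label = fe$label, kind = fe$kind, start = fe$start + 1L,
                   end = fe$end, strand = fe$strand,
                   copy_index = fe$copy_index, anticodon = fe$anticodon,
                   stringsAsFactors = FALSE)
  write.table(tb, table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, table = table))
}
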