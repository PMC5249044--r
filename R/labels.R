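# Canonical gene nomenclature and the pancrustacean ground pattern.

.PCG_LABELS <- c("cox1", "cox2", "cox3", "nad1", "nad2", "nad3", "nad4",
                 "nad4l", "nad5", "nad6", "atp6", "atp8", "cytB")
.RRNA_LABELS <- c("rrnS", "rrnL")
.TRNA_LABELS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                  "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                  "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                  "trnY")

# Synonym dictionary: deposited records vary widely in gene naming.
.LABEL_SYNONYMS <- local({
  syn <- list(
    cox1 = c("cox1", "coxi", "coi", "co1", "cox-1", "mt-co1"),
    cox2 = c("cox2", "coxii", "coii", "co2", "cox-2", "mt-co2"),
    cox3 = c("cox3", "coxiii", "coiii", "co3", "cox-3", "mt-co3"),
    nad1 = c("nad1", "nd1", "nadh1"), nad2 = c("nad2", "nd2", "nadh2"),
    nad3 = c("nad3", "nd3", "nadh3"), nad4 = c("nad4", "nd4", "nadh4"),
    nad4l = c("nad4l", "nd4l", "nadh4l"),
    nad5 = c("nad5", "nd5", "nadh5"), nad6 = c("nad6", "nd6", "nadh6"),
    atp6 = c("atp6", "atpase6", "atpase 6", "atp-6"),
    atp8 = c("atp8", "atpase8", "atpase 8", "atp-8"),
    cytB = c("cytb", "cob", "cyb", "cyt b", "cytochrome b"),
    rrnS = c("rrns", "12s", "12s rrna", "12s ribosomal rna", "srrna",
             "s-rrna", "rns", "small subunit ribosomal rna", "ssu"),
    rrnL = c("rrnl", "16s", "16s rrna", "16s ribosomal rna", "lrrna",
             "l-rrna", "rnl", "large subunit ribosomal rna", "lsu"),
    CR = c("cr", "control region", "d-loop", "dloop", "at-rich region",
           "a+t rich region", "putative control region"),
    spacer = c("spacer", "intergenic spacer", "non-coding", "noncoding")
  )
  aa3 <- c(trnA = "ala", trnC = "cys", trnD = "asp", trnE = "glu",
           trnF = "phe", trnG = "gly", trnH = "his", trnI = "ile",
           trnK = "lys", trnM = "met", trnN = "asn", trnP = "pro",
           trnQ = "gln", trnR = "arg", trnT = "thr", trnV = "val",
           trnW = "trp", trnY = "tyr")
  for (lab in names(aa3)) {
    a <- substring(lab, 4)
    syn[[lab]] <- c(tolower(lab), paste0("trn", tolower(a)),
                    paste0("trna-", aa3[[lab]]), paste0("trna-", tolower(a)),
                    paste0("trna_", aa3[[lab]]), aa3[[lab]])
  }
  # Leu and Ser isoacceptors, disambiguated by codon family / anticodon.
  syn$trnL1 <- c("trnl1", "trnl-cun", "trna-leu(cun)", "trna-leu (cun)",
                 "trnl(tag)", "trna-leu(tag)", "l1")
  syn$trnL2 <- c("trnl2", "trnl-uur", "trna-leu(uur)", "trna-leu (uur)",
                 "trnl(taa)", "trna-leu(taa)", "l2")
  syn$trnS1 <- c("trns1", "trns-agn", "trna-ser(agn)", "trna-ser (agn)",
                 "trns(tct)", "trna-ser(tct)", "trna-ser(gct)", "s1")
  syn$trnS2 <- c("trns2", "trns-ucn", "trna-ser(ucn)", "trna-ser (ucn)",
                 "trns(tga)", "trna-ser(tga)", "s2")
  out <- character(0)
  for (lab in names(syn)) out[syn[[lab]]] <- lab
  out
})

#' Canonicalize a mitochondrial gene label
#'
#' Maps the many synonyms found in deposited records (COI, ND4L, 12S rRNA,
#' tRNA-Leu(UUR), ...) onto the canonical labels used throughout the package
#' (`cox1..cox3`, `nad1..nad6`, `nad4l`, `atp6`, `atp8`, `cytB`, `rrnS`,
#' `rrnL`, `trnX` with `L1/L2` and `S1/S2` disambiguation, `CR`, `spacer`).
#'
#' @param label character vector of raw labels.
#' @param warn warn when a label is not recognized (it is then preserved
#'   verbatim).
#' @return character vector of canonical labels.
#' @export
#' @examples
#' canonical_label(c("COI", "ND4L", "12S rRNA", "tRNA-Leu(UUR)"))
canonical_label <- function(label, warn = TRUE) {
  key <- tolower(trimws(label))
  hit <- .LABEL_SYNONYMS[key]
  unknown <- is.na(hit)
  if (any(unknown) && warn) {
    warning("unrecognized gene label(s) kept verbatim: ",
            paste(unique(label[unknown]), collapse = ", "), call. = FALSE)
  }
  hit[unknown] <- label[unknown]
  unname(hit)
}

# Feature kind implied by a canonical label, NA if unknown.
label_kind <- function(label) {
  ifelse(label %in% .PCG_LABELS, "PCG",
  ifelse(label %in% .RRNA_LABELS, "rRNA",
  ifelse(label %in% .TRNA_LABELS | grepl("^trn", label), "tRNA",
  ifelse(label == "CR", "CR",
  ifelse(label == "spacer", "spacer", NA_character_)))))
}

#' The pancrustacean mitochondrial ground pattern
#'
#' The inferred ancestral gene arrangement of Pancrustacea (the reference
#' order used for rearrangement analysis), linearized at `cox1`. Genes on
#' the (+) strand have strand `"+"`.
#'
#' @param scope which features to keep: `"PCG"` (13 protein-coding genes),
#'   `"PCG+rRNA"`, or `"all"` (37 genes plus the control region).
#' @return a data.frame with columns `label`, `kind`, `strand`.
#' @export
#' @examples
#' ground_pattern("PCG")
ground_pattern <- function(scope = c("all", "PCG", "PCG+rRNA")) {
  scope <- match.arg(scope)
  lab <- c("cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3",
           "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1", "trnE", "trnF",
           "nad5", "trnH", "nad4", "nad4l", "trnT", "trnP", "nad6", "cytB",
           "trnS2", "nad1", "trnL1", "rrnL", "trnV", "rrnS", "CR", "trnI",
           "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY")
  strand <- c("+", "+", "+", "+", "+", "+", "+", "+",
              "+", "+", "+", "+", "+", "+", "+", "-",
              "-", "-", "-", "-", "+", "-", "+", "+",
              "+", "-", "-", "-", "-", "-", "+", "+",
              "-", "+", "+", "+", "-", "-")
  pat <- data.frame(label = lab, kind = label_kind(lab), strand = strand,
                    stringsAsFactors = FALSE)
  keep <- switch(scope,
                 "PCG" = pat$kind == "PCG",
                 "PCG+rRNA" = pat$kind %in% c("PCG", "rRNA"),
                 "all" = rep(TRUE, nrow(pat)))
  out <- pat[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
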