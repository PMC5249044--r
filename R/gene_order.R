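# Signed gene-order signatures and rearrangement comparison.
#
# A signature is the circular gene order linearized at an anchor gene
# (default cox1): features filtered to scope, sorted by start, rotated so
# the anchor leads, and reflected/sign-flipped if the anchor lies on the
# (-) strand, so any rotation or full reflection of a genome yields the
# same signature. Breakpoints count signed adjacencies (with the circular
# closure) present in one signature but absent from the other; the signed
# adjacency (a,b) is equivalent to its reverse complement (-b,-a).

#' Signed gene-order signature
#'
#' @param genome a [mito_genome()], or a data.frame with columns `label`,
#'   `strand` (and optionally `kind`, `copy_index`) already in genomic
#'   order (e.g. [ground_pattern()]).
#' @param scope `"PCG"`, `"PCG+rRNA"` or `"all"`.
#' @param anchor anchor gene label; must be present and unique in scope.
#' @return an object of class `gene_order_signature`: list with `anchor`,
#'   `scope`, `elements` (data.frame `label`, `sign` where sign is +1/-1).
#' @export
gene_order_signature <- function(genome, scope = c("PCG", "PCG+rRNA", "all"),
                                 anchor = "cox1") {
  scope <- match.arg(scope)
  if (inherits(genome, "mito_genome")) {
    fe <- genome$features[order(genome$features$start), , drop = FALSE]
  } else {
    fe <- genome
    if (is.null(fe$kind)) fe$kind <- label_kind(fe$label)
  }
  if (is.null(fe$copy_index)) fe$copy_index <- 1L
  keep <- switch(scope,
                 "PCG" = fe$kind == "PCG",
                 "PCG+rRNA" = fe$kind %in% c("PCG", "rRNA"),
                 "all" = fe$kind %in% c("PCG", "rRNA", "tRNA", "CR"))
  fe <- fe[keep, , drop = FALSE]
  lab <- ifelse(fe$copy_index > 1L, paste0(fe$label, ".", fe$copy_index),
                fe$label)
  sgn <- ifelse(fe$strand == "+", 1L, -1L)
  ai <- which(lab == anchor)
  if (length(ai) != 1L)
    stop("anchor '", anchor, "' not present exactly once in scope; ",
         "try another anchor (e.g. cytB, rrnL)", call. = FALSE)
  n <- length(lab)
  rot <- c(seq.int(ai, n), seq_len(ai - 1L))
  lab <- lab[rot]; sgn <- sgn[rot]
  if (sgn[1] < 0L) { # reflect so the anchor reads +
    lab <- c(lab[1], rev(lab[-1]))
    sgn <- -c(sgn[1], rev(sgn[-1]))
  }
  structure(list(anchor = anchor, scope = scope,
                 elements = data.frame(label = lab, sign = sgn,
                                       stringsAsFactors = FALSE)),
            class = "gene_order_signature")
}

#' @export
print.gene_order_signature <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.gene_order_signature <- function(x, ...) {
  paste(sprintf("%s,%s", x$elements$label,
                ifelse(x$elements$sign > 0, "+", "-")), collapse = ";")
}

# signed adjacency set with circular closure, canonicalized under the
# reverse-complement equivalence (a,b) ~ (-b,-a)
signed_adjacencies <- function(labels, signs) {
  n <- length(labels)
  a <- paste0(ifelse(signs > 0, "+", "-"), labels)
  neg <- function(x) ifelse(substr(x, 1, 1) == "+",
                            sub("^\\+", "-", x), sub("^-", "+", x))
  nxt <- c(seq.int(2L, n), 1L)
  fwd <- paste(a, a[nxt], sep = ">")
  rev_ <- paste(neg(a[nxt]), neg(a), sep = ">")
  pmin(fwd, rev_)
}

unsigned_neighbors <- function(labels) {
  n <- length(labels)
  prv <- c(n, seq_len(n - 1L)); nxt <- c(seq.int(2L, n), 1L)
  nb <- lapply(seq_len(n),
               function(i) sort(c(labels[prv[i]], labels[nxt[i]])))
  setNames(nb, labels)
}

#' Compare two gene-order signatures
#'
#' Breakpoints count the signed adjacencies (with circular closure, up to
#' reverse-complement equivalence) of `sig` absent from `ref`, after
#' restricting both signatures to their shared label set; labels private to
#' one signature are reported, not counted. `inverted` lists labels whose
#' strand sign differs; `translocated` lists labels whose unsigned neighbor
#' pair differs from the reference (an operational definition: a moved gene
#' and the genes flanking its old and new sites all qualify).
#'
#' @param sig,ref [gene_order_signature()] objects of the same scope.
#' @return an object of class `rearrangement_report`: list with
#'   `breakpoints`, `translocated`, `inverted`, `only_in_sig`,
#'   `only_in_ref`, `identical`.
#' @export
compare_orders <- function(sig, ref) {
  stopifnot(inherits(sig, "gene_order_signature"),
            inherits(ref, "gene_order_signature"))
  if (sig$scope != ref$scope)
    stop("signatures have different scopes", call. = FALSE)
  ls_ <- sig$elements$label; lr <- ref$elements$label
  shared <- intersect(ls_, lr)
  if (!length(shared)) stop("disjoint label sets", call. = FALSE)
  ks <- sig$elements[ls_ %in% shared, , drop = FALSE]
  kr <- ref$elements[lr %in% shared, , drop = FALSE]
  adj_s <- signed_adjacencies(ks$label, ks$sign)
  adj_r <- signed_adjacencies(kr$label, kr$sign)
  breakpoints <- sum(!(adj_s %in% adj_r))
  sign_s <- setNames(ks$sign, ks$label)
  sign_r <- setNames(kr$sign, kr$label)
  inverted <- shared[sign_s[shared] != sign_r[shared]]
  nb_s <- unsigned_neighbors(ks$label)
  nb_r <- unsigned_neighbors(kr$label)
  translocated <- shared[!vapply(shared, function(l)
    identical(nb_s[[l]], nb_r[[l]]), logical(1))]
  structure(list(breakpoints = breakpoints,
                 translocated = translocated, inverted = inverted,
                 only_in_sig = setdiff(ls_, lr),
                 only_in_ref = setdiff(lr, ls_),
                 identical = breakpoints == 0L && !length(inverted)),
            class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("breakpoints: %d%s\n", x$breakpoints,
              if (x$identical) " (identical order)" else ""))
  if (length(x$translocated))
    cat("translocated:", paste(x$translocated, collapse = ", "), "\n")
  if (length(x$inverted))
    cat("inverted:", paste(x$inverted, collapse = ", "), "\n")
  if (length(x$only_in_sig))
    cat("only in query:", paste(x$only_in_sig, collapse = ", "), "\n")
  invisible(x)
}

#' Compare many genomes against a reference order
#'
#' @param genomes list of [mito_genome()] objects (or signatures).
#' @param ref reference [gene_order_signature()] (default: the
#'   pancrustacean ground pattern at the requested scope).
#' @param scope,anchor passed to [gene_order_signature()].
#' @return list with `reports` (one [compare_orders()] report per genome)
#'   and `distance` (symmetric pairwise breakpoint-distance matrix over
#'   genomes plus the reference).
#' @export
batch_compare <- function(genomes, ref = NULL,
                          scope = c("PCG", "PCG+rRNA", "all"),
                          anchor = "cox1") {
  scope <- match.arg(scope)
  if (!length(genomes)) stop("need at least one genome", call. = FALSE)
  sigs <- lapply(genomes, function(g) {
    if (inherits(g, "gene_order_signature")) g
    else gene_order_signature(g, scope, anchor)
  })
  nms <- vapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    if (inherits(g, "mito_genome")) g$id else paste0("g", i)
  }, character(1))
  if (is.null(ref)) ref <- gene_order_signature(ground_pattern(), scope,
                                                anchor)
  reports <- setNames(lapply(sigs, compare_orders, ref = ref), nms)
  all_sigs <- c(sigs, list(ref))
  all_nms <- c(nms, "reference")
  k <- length(all_sigs)
  d <- matrix(0L, k, k, dimnames = list(all_nms, all_nms))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i < j) {
      d[i, j] <- compare_orders(all_sigs[[i]], all_sigs[[j]])$breakpoints
      d[j, i] <- d[i, j]
    }
  }
  list(reports = reports, distance = d)
}
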