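# Pipeline orchestration: run every analysis stage over a set of genomes
# and write a TSV report bundle (plus a JSON sidecar of full-precision
# values). Every number in the bundle comes from exactly one module
# operation; printed-table rounding (3 d.p. skews, 2 d.p. percents) is
# applied only in the TSVs.

round_cols <- function(df, cols3 = character(), cols2 = character()) {
  for (c3 in intersect(cols3, names(df))) df[[c3]] <- round(df[[c3]], 3)
  for (c2 in intersect(cols2, names(df))) df[[c2]] <- round(df[[c2]], 2)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Load a pipeline run configuration
#'
#' YAML with keys: `genbank` (paths), `fasta_tables` (list of
#' `fasta`/`table` pairs), `alignments` (aligned FASTA paths), `panels`
#' (named taxon lists), `out_dir`, `seed`, `params` (per-stage overrides:
#' `window`, `step`, `scope`, `anchor`, `donor_threshold`,
#' `within_threshold`, `cr_min_length`, `poly_t_min`). Unknown keys are
#' rejected; referenced files must exist.
#'
#' @param path YAML file.
#' @return list of validated configuration values.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("genbank", "fasta_tables", "alignments", "panels", "out_dir",
             "seed", "params")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  files <- c(unlist(cfg$genbank), unlist(cfg$fasta_tables),
             unlist(cfg$alignments))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("configured file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Run the full comparative pipeline
#'
#' Computes, for a set of annotated genomes: the genome summary (length,
#' AT%, AT-skew, GC-skew), partition statistics per annotation category,
#' per-gene coding-sense skews, codon usage and ENC/GC3s with the Nc-GC3s
#' correlation, codon-position AT, gene-order reports against a reference
#' arrangement, tRNA-duplication/remolding reports, and ranked
#' control-region candidates; per-gene nucleotide diversity when alignments
#' are supplied. Results are returned as a list of data.frames and, when
#' `out_dir` is given, written as a TSV bundle with a full-precision JSON
#' sidecar and a run log.
#'
#' @param genomes list of [mito_genome()] objects.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param alignments optional list of [gene_alignment()] objects.
#' @param panels optional named list of taxon-id vectors for [panel_pi()].
#' @param reference reference [gene_order_signature()] scope source
#'   (default [ground_pattern()]).
#' @param scope gene-order scope (default `"PCG"`).
#' @param params list of stage-parameter overrides (see
#'   [load_run_config()]).
#' @return invisibly, a named list of result tables.
#' @export
run_all <- function(genomes, out_dir = NULL, alignments = NULL,
                    panels = NULL, reference = ground_pattern(),
                    scope = "PCG", params = list()) {
  if (!length(genomes)) stop("no genomes supplied", call. = FALSE)
  ids <- vapply(genomes, function(g) g$id, character(1))
  get_par <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default

  failed <- character(0)
  stage <- function(fun) {
    lapply(genomes, function(g) {
      tryCatch(fun(g), error = function(e) {
        failed <<- c(failed, sprintf("%s: %s", g$id, conditionMessage(e)))
        NULL
      })
    })
  }

  summary_tab <- do.call(rbind, stage(function(g) {
    cs <- composition_stats(g$sequence)
    data.frame(genome = g$id, length = g$length, at_percent = cs$at_percent,
               at_skew = cs$at_skew, gc_skew = cs$gc_skew,
               stringsAsFactors = FALSE)
  }))
  partition_tab <- do.call(rbind, stage(function(g)
    cbind(genome = g$id, genome_partition_stats(g))))
  gene_tab <- do.call(rbind, stage(function(g) gene_composition_table(g)))
  codon_pos_tab <- do.call(rbind, stage(function(g) {
    at3 <- at_by_codon_position(unname(gene_sequences(g, "PCG")),
                                warn_internal_stops = FALSE)
    data.frame(genome = g$id, pos1 = at3[["pos1"]], pos2 = at3[["pos2"]],
               pos3 = at3[["pos3"]], stringsAsFactors = FALSE)
  }))
  usage_tab <- do.call(rbind, stage(function(g)
    cbind(genome = g$id, as.data.frame(codon_usage(
      unname(gene_sequences(g, "PCG")))))))
  enc_tab <- do.call(rbind, stage(function(g) {
    e <- enc(unname(gene_sequences(g, "PCG")))
    data.frame(genome = g$id, nc = e$nc, gc3s = e$gc3s,
               n_codons = e$n_codons, stringsAsFactors = FALSE)
  }))
  enc_cor <- if (!is.null(enc_tab) && nrow(enc_tab) >= 3L)
    tryCatch(enc_gc3s_correlation(enc_tab), error = function(e) NULL)
  else NULL

  ref_sig <- gene_order_signature(reference, scope,
                                  anchor = get_par("anchor", "cox1"))
  order_res <- tryCatch(
    batch_compare(genomes, ref = ref_sig, scope = scope,
                  anchor = get_par("anchor", "cox1")),
    error = function(e) { failed <<- c(failed, conditionMessage(e)); NULL })
  order_tab <- if (!is.null(order_res)) do.call(rbind, lapply(ids, function(id) {
    r <- order_res$reports[[id]]
    data.frame(genome = id, breakpoints = r$breakpoints,
               identical = r$identical,
               translocated = paste(r$translocated, collapse = ","),
               inverted = paste(r$inverted, collapse = ","),
               stringsAsFactors = FALSE)
  }))

  trna_tab <- do.call(rbind, stage(function(g) {
    rs <- remolding_scan(g, get_par("donor_threshold", 65),
                         get_par("within_threshold", 85))
    if (nrow(rs)) cbind(genome = g$id, rs) else NULL
  }))
  cr_tab <- do.call(rbind, stage(function(g) {
    rc <- suppressWarnings(
      rank_cr_candidates(g, get_par("cr_min_length", 50L),
                         get_par("poly_t_min", 10L)))
    if (nrow(rc)) cbind(genome = g$id, as.data.frame(rc)) else NULL
  }))

  pi_tab <- if (!is.null(alignments)) {
    if (is.null(panels)) panel_pi(alignments)
    else do.call(rbind, lapply(names(panels), function(p)
      cbind(panel = p, panel_pi(alignments, panels[[p]]))))
  }

  results <- list(genome_summary = summary_tab, partitions = partition_tab,
                  gene_skews = gene_tab, codon_position_at = codon_pos_tab,
                  codon_usage = usage_tab, enc = enc_tab,
                  enc_gc3s_correlation = enc_cor, gene_order = order_tab,
                  trna_duplications = trna_tab, cr_candidates = cr_tab,
                  pi = pi_tab, failures = failed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(round_cols(summary_tab, c("at_skew", "gc_skew"),
                         "at_percent"),
              file.path(out_dir, "genome_summary.tsv"))
    write_tsv(round_cols(partition_tab, c("at_skew", "gc_skew"),
                         "at_percent"),
              file.path(out_dir, "partitions.tsv"))
    write_tsv(round_cols(gene_tab, c("at_skew", "gc_skew"), "at_percent"),
              file.path(out_dir, "gene_skews.tsv"))
    write_tsv(round_cols(codon_pos_tab, character(),
                         c("pos1", "pos2", "pos3")),
              file.path(out_dir, "codon_position_at.tsv"))
    write_tsv(round_cols(usage_tab, character(), "percent"),
              file.path(out_dir, "codon_usage.tsv"))
    et <- enc_tab
    et$nc <- round(et$nc, 2); et$gc3s <- round(et$gc3s, 3)
    write_tsv(et, file.path(out_dir, "enc_gc3s.tsv"))
    if (!is.null(order_tab))
      write_tsv(order_tab, file.path(out_dir, "gene_order.tsv"))
    if (!is.null(trna_tab))
      write_tsv(round_cols(trna_tab, character(),
                           c("within_identity", "donor_identity")),
                file.path(out_dir, "trna_duplications.tsv"))
    if (!is.null(cr_tab))
      write_tsv(round_cols(cr_tab, character(),
                           c("at_percent", "at_excess")),
                file.path(out_dir, "cr_candidates.tsv"))
    if (!is.null(pi_tab)) {
      pt <- pi_tab; pt$pi <- round(pt$pi, 4)
      write_tsv(pt, file.path(out_dir, "pi.tsv"))
    }
    jsonlite::write_json(
      results[!vapply(results, is.null, logical(1))],
      file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, dataframe = "rows", null = "null")
    log_lines <- c(
      sprintf("mitoarch %s", as.character(utils::packageVersion("mitoarch"))),
      sprintf("genomes: %s", paste(ids, collapse = ", ")),
      sprintf("scope: %s", scope),
      if (!is.null(enc_cor)) sprintf("enc_gc3s_r: %.4f", enc_cor$r),
      if (length(failed)) c("stage failures:", paste(" -", failed))
      else "all stages completed")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  if (length(failed))
    warning("stage failure(s): ", paste(failed, collapse = "; "),
            call. = FALSE)
  invisible(results)
}
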