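#' End-to-end annotation audit of an enzyme class
#'
#' Runs the full pipeline: length/ambiguity filter, exact-duplicate
#' collapse, optional greedy 90% identity reduction with characterised
#' members restored, identity of every analysed record to its closest
#' characterised sequence, Markov clustering of the similarity graph,
#' per-cluster alignment and entropy-based representative selection, and
#' the misannotation classification. Every stage logs its record counts
#' via `message()`; the run is deterministic given the inputs and seed.
#'
#' @param records a [seq_records] collection, or `NULL` to read `fasta`.
#' @param fasta,domain_table,characterised optional input paths: a FASTA
#'   file, a domain TSV ([read_domain_table()]) and a characterised-id list
#'   (one per line; or a character vector of ids).
#' @param blast_tab optional BLAST tabular file; when given, the MCL graph
#'   is built from its bitscores instead of internal alignments.
#' @param filter a [filter_spec()].
#' @param params an [align_params()].
#' @param k prefilter word size (default 3).
#' @param reduce run the greedy identity reduction before the audit?
#' @param greedy_threshold identity threshold of the reduction (default 90).
#' @param inflation MCL inflation (default 1.4).
#' @param selection_target information fraction for representative
#'   selection (default 0.85).
#' @param identity_threshold misannotation identity threshold in percent
#'   (default 25).
#' @param top_n prefilter candidates aligned per query.
#' @param spec,reference_sequence optional conserved-residue check, see
#'   [classify()].
#' @param out_dir optional directory for artifacts (`report.json`,
#'   `per_record.tsv`, `clusters.tsv`, `selection.tsv`, `histograms.tsv`).
#' @param seed integer seed (the pipeline itself is deterministic; the seed
#'   is set for reproducibility of any downstream randomness).
#' @param verbose log stage-by-stage record counts?
#' @return A list with `report` (a `misannotation_report`), `clusters`
#'   (MCL `cluster_set`), `selections` (per-cluster `selection_result`),
#'   `records` (the analysed records) and `removed_counts`.
#' @export
run_audit <- function(records = NULL, fasta = NULL, domain_table = NULL,
                      characterised = NULL, blast_tab = NULL,
                      filter = filter_spec(), params = align_params(),
                      k = 3L, reduce = FALSE, greedy_threshold = 90,
                      inflation = 1.4, selection_target = 0.85,
                      identity_threshold = 25, top_n = 1L,
                      spec = NULL, reference_sequence = NULL,
                      out_dir = NULL, seed = 1L, verbose = TRUE) {
  set.seed(seed)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("audit stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(records)) {
    if (is.null(fasta)) stop("supply 'records' or 'fasta'")
    records <- stage("read", read_fasta(fasta))
  }
  if (!is.null(domain_table))
    records <- stage("domains",
                     attach_architectures(records,
                                          read_domain_table(domain_table)))
  if (!is.null(characterised))
    records <- stage("characterised", mark_characterised(records,
                                                         characterised))
  say("input: ", nrow(records), " records")
  filt <- stage("filter", filter_sequences(records, filter))
  say("filter: kept ", nrow(filt$kept), " (removed ",
      paste(names(filt$removed_counts), filt$removed_counts,
            sep = "=", collapse = ", "), ")")
  recs <- stage("deduplicate", deduplicate(filt$kept))
  say("deduplicate: ", nrow(recs), " unique sequences")
  char_ids <- recs$id[recs$characterised]
  if (length(char_ids) == 0L)
    warning("no characterised sequences: all identities will be 0")
  if (reduce) {
    red <- stage("reduce",
                 greedy_identity_cluster(recs, greedy_threshold, 5L, params))
    keep <- stage("restore", restore_characterised(red, char_ids))
    recs <- as_seq_records(recs[match(keep, recs$id), , drop = FALSE])
    say("reduce: ", length(red$clusters), " clusters at ",
        greedy_threshold, "% -> ", nrow(recs),
        " representatives (+ restored characterised)")
  }
  graph <- stage("graph", {
    if (!is.null(blast_tab))
      graph_from_blast(read_blast_tab(blast_tab), nodes = recs$id)
    else similarity_graph(recs, params)
  })
  clusters <- stage("mcl", mcl(graph, inflation = inflation))
  say("mcl: ", length(clusters$clusters), " clusters")
  selections <- stage("select", lapply(clusters$clusters, function(cl) {
    sub <- as_seq_records(recs[match(cl, recs$id), , drop = FALSE])
    msa <- center_star_msa(sub, params)
    select_representatives(msa, selection_target)
  }))
  say("select: ", sum(vapply(selections, function(s) length(s$selected),
                             integer(1))),
      " representatives across clusters (target ", selection_target, ")")
  report <- stage("classify",
                  classify(recs, char_ids, threshold_pct = identity_threshold,
                           spec = spec, reference_sequence = reference_sequence,
                           k = k, top_n = top_n, params = params))
  say(sprintf("classify: %.1f%% below %g%% identity, %.1f%% non-canonical",
              100 * report$class_summary$fraction_below_threshold,
              identity_threshold,
              100 * report$class_summary$fraction_non_canonical))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"), "json")
    write_report(report, file.path(out_dir, "per_record.tsv"), "tsv")
    write_clusters(clusters, file.path(out_dir, "clusters.tsv"), "tsv")
    sel_tab <- do.call(rbind, lapply(seq_along(selections), function(i)
      data.frame(cluster_index = i,
                 step = seq_along(selections[[i]]$selected),
                 id = selections[[i]]$selected,
                 explained_after_step =
                   selections[[i]]$explained_after_step)))
    write.table(sel_tab, file.path(out_dir, "selection.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    hist_tab <- data.frame(bin = 0:100, report$class_summary$histograms,
                           check.names = FALSE)
    write.table(hist_tab, file.path(out_dir, "histograms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("artifacts written to ", out_dir)
  }
  list(report = report, clusters = clusters, selections = selections,
       records = recs, removed_counts = filt$removed_counts)
}

#' Diff two annotation snapshots
#'
#' Deduplicates both snapshots (done on construction), counts records per
#' architecture multiset and writes the per-architecture deltas.
#'
#' @param snapA,snapB [annotation_snapshot()] objects.
#' @param out optional path of a TSV artifact.
#' @return The [version_diff()] data frame.
#' @export
run_versions <- function(snapA, snapB, out = NULL) {
  diff <- version_diff(snapA, snapB)
  if (!is.null(out)) write_version_diff(diff, out)
  diff
}
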