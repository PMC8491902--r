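#' Compare two domain architectures
#'
#' Two proteins have the same architecture when the multisets of their
#' domain labels are equal — order is disregarded, but copy number counts,
#' so a domain duplication is a difference.
#'
#' @param a,b character vectors of domain labels (may be empty).
#' @return `TRUE` or `FALSE`.
#' @examples
#' same_architecture(c("DAO", "Fer2_BFD"), c("Fer2_BFD", "DAO"))  # TRUE
#' same_architecture("DAO", c("DAO", "DAO"))                      # FALSE
#' @export
same_architecture <- function(a, b) {
  identical(sort(as.character(a)), sort(as.character(b)))
}

# canonical string key of an architecture multiset
arch_key <- function(a) {
  if (length(a) == 0L) "unknown" else paste(sort(a), collapse = "+")
}

#' Canonical architectures of a characterised set
#'
#' @param characterised a [seq_records] collection of characterised
#'   sequences, at least one with a known (non-empty) architecture.
#' @return A list of distinct architecture multisets (sorted label vectors)
#'   observed among the characterised records.
#' @export
canonical_architectures <- function(characterised) {
  archs <- characterised$architecture[lengths(characterised$architecture) > 0]
  if (length(archs) == 0L)
    stop("no canonical reference: no characterised record has a known ",
         "architecture")
  unique(lapply(archs, sort))
}

#' Specify conserved residues of a reference enzyme
#'
#' Positions are 1-based indices into the ungapped reference sequence; the
#' expected letters must match the reference at those positions.
#'
#' @param reference_id accession of the reference enzyme.
#' @param positions strictly increasing integer positions.
#' @param expected one residue letter per position.
#' @return A `residue_spec` list.
#' @export
residue_spec <- function(reference_id, positions, expected) {
  positions <- as.integer(positions)
  expected <- toupper(as.character(expected))
  if (length(positions) != length(expected))
    stop("'positions' and 'expected' must have equal length")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  structure(list(reference_id = reference_id, positions = positions,
                 expected = expected),
            class = "residue_spec")
}

#' Read a residue spec from a small JSON config
#'
#' @param path JSON file with fields `reference_id`, `positions`,
#'   `expected`.
#' @return A [residue_spec()].
#' @export
read_residue_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  residue_spec(x$reference_id, x$positions, x$expected)
}

#' Check conserved active-site residues in a query
#'
#' The query is globally aligned to the reference; a specified position is
#' conserved when the query column aligned to that reference residue holds
#' the expected letter. A reference position aligned to a query gap scores
#' not conserved.
#'
#' @param query a single-row [seq_records] collection or list with
#'   `sequence`.
#' @param spec a [residue_spec()].
#' @param reference_sequence ungapped reference amino-acid string.
#' @param params an [align_params()] object.
#' @return A list with `conserved` (named logical, one per position) and
#'   `fraction`.
#' @export
conserved_residues <- function(query, spec, reference_sequence,
                               params = align_params()) {
  reference_sequence <- toupper(reference_sequence)
  ref_letters <- substring(reference_sequence, spec$positions, spec$positions)
  if (!identical(ref_letters, spec$expected))
    stop("residue spec inconsistent with reference sequence at position(s) ",
         paste(spec$positions[ref_letters != spec$expected], collapse = ", "))
  al <- global_align(query$sequence[1], reference_sequence, params)
  qa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  ra <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(ra != "-")
  cols <- match(spec$positions, ref_pos)
  conserved <- qa[cols] == spec$expected & qa[cols] != "-"
  names(conserved) <- paste0(spec$expected, spec$positions)
  list(conserved = conserved, fraction = mean(conserved))
}

#' Classify an enzyme class for likely misannotation
#'
#' For every record the identity to the closest characterised sequence is
#' computed ([closest_characterised()]), the architecture is compared to the
#' canonical architectures of the characterised set, and (optionally)
#' conserved active-site residues are checked. A record is flagged
#' `below_threshold` when its maximum identity is strictly below
#' `threshold_pct`, and `canonical_architecture` when its domain multiset
#' equals any canonical one. Records with unknown (empty) architectures are
#' scored non-canonical but are excluded from the non-canonical fraction's
#' denominator unless `include_unknown = TRUE`, since an absent architecture
#' may simply reflect a partially sequenced gene.
#'
#' @param records a [seq_records] collection (architectures attached).
#' @param characterised_ids accessions of the characterised subset.
#' @param threshold_pct identity threshold in percent (default 25; the
#'   twilight zone below which function transfer is unreliable).
#' @param spec optional [residue_spec()] for conserved-residue checks.
#' @param reference_sequence reference sequence for `spec`.
#' @param k k-tuple word size of the prefilter.
#' @param top_n prefilter candidates aligned per query.
#' @param params an [align_params()] object.
#' @param include_unknown count unknown-architecture records in the
#'   non-canonical fraction's denominator?
#' @return A `misannotation_report`: list with `per_record` (data frame:
#'   `id`, `superkingdom`, `max_identity_pct`, `closest_characterised_id`,
#'   `below_threshold`, `canonical_architecture`, `architecture_known`,
#'   `conserved_residue_fraction`) and `class_summary` (list: `n`,
#'   `n_characterised`, `n_unknown_architecture`,
#'   `fraction_below_threshold`, `fraction_non_canonical`, `histograms` —
#'   per-superkingdom identity counts with bins `[i, i+1)` for i = 0..99
#'   plus a closed bin at 100).
#' @export
classify <- function(records, characterised_ids, threshold_pct = 25,
                     spec = NULL, reference_sequence = NULL,
                     k = 3L, top_n = 1L, params = align_params(),
                     include_unknown = FALSE) {
  char <- records[records$id %in% characterised_ids, , drop = FALSE]
  canon <- if (nrow(char) &&
               any(lengths(char$architecture) > 0)) {
    canonical_architectures(char)
  } else {
    list()
  }
  char_profiles_corpus <- NULL
  if (nrow(char)) {
    profs <- c(lapply(records$sequence, kmer_profile, k = k))
    char_profiles_corpus <- corpus_distinct_words(profs)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    closest_characterised(records[i, , drop = FALSE], char, k = k,
                          top_n = top_n, params = params,
                          corpus_distinct = char_profiles_corpus)
  }))
  arch_known <- lengths(records$architecture) > 0
  canonical <- vapply(records$architecture, function(a) {
    length(a) > 0 && any(vapply(canon, same_architecture, logical(1), b = a))
  }, logical(1))
  crf <- rep(NA_real_, nrow(records))
  if (!is.null(spec) && !is.null(reference_sequence)) {
    crf <- vapply(seq_len(nrow(records)), function(i)
      conserved_residues(records[i, , drop = FALSE], spec,
                         reference_sequence, params)$fraction, numeric(1))
  }
  per_record <- data.frame(
    id = records$id,
    superkingdom = records$superkingdom,
    max_identity_pct = res$identity_pct,
    closest_characterised_id = res$subject,
    below_threshold = res$identity_pct < threshold_pct,
    canonical_architecture = canonical,
    architecture_known = arch_known,
    conserved_residue_fraction = crf,
    stringsAsFactors = FALSE)
  n <- nrow(records)
  denom_arch <- if (include_unknown) n else sum(arch_known)
  hist_mat <- identity_histograms(per_record)
  summary <- list(
    n = n,
    n_characterised = nrow(char),
    n_unknown_architecture = sum(!arch_known),
    fraction_below_threshold = if (n) mean(per_record$below_threshold) else NA,
    fraction_non_canonical = if (denom_arch)
      sum(!canonical & (include_unknown | arch_known)) / denom_arch
      else NA,
    threshold_pct = threshold_pct,
    histograms = hist_mat)
  structure(list(per_record = per_record, class_summary = summary),
            class = "misannotation_report")
}

# per-superkingdom identity histograms, bins [i, i+1) for i = 0..99 plus a
# closed [100, 100] bin
identity_histograms <- function(per_record) {
  bins <- pmin(floor(per_record$max_identity_pct), 100)
  kingdoms <- sort(unique(per_record$superkingdom))
  out <- sapply(kingdoms, function(kg) {
    tabulate(bins[per_record$superkingdom == kg] + 1L, nbins = 101L)
  })
  out <- matrix(out, nrow = 101L,
                dimnames = list(0:100, kingdoms))
  out
}

#' @export
print.misannotation_report <- function(x, ...) {
  s <- x$class_summary
  cat(sprintf(paste0(
    "misannotation_report: %d records (%d characterised)\n",
    "  below %g%% identity to closest characterised: %.1f%%\n",
    "  non-canonical architecture: %.1f%%",
    " (%d with unknown architecture)\n"),
    s$n, s$n_characterised, s$threshold_pct,
    100 * s$fraction_below_threshold,
    100 * s$fraction_non_canonical, s$n_unknown_architecture))
  invisible(x)
}

#' Mean pairwise identity within and between architecture groups
#'
#' @param records a [seq_records] collection.
#' @param groups named list of id vectors, one per group; or `NULL` to
#'   group records by their architecture multiset automatically.
#' @param params an [align_params()] object.
#' @return A square numeric matrix of mean percent identities; diagonal
#'   entries are within-group means (NA for singleton groups), off-diagonal
#'   entries between-group means.
#' @export
architecture_identity_matrix <- function(records, groups = NULL,
                                         params = align_params()) {
  if (is.null(groups)) {
    keys <- vapply(records$architecture, arch_key, character(1))
    groups <- split(records$id, keys)
  }
  unknown <- setdiff(unlist(groups, use.names = FALSE), records$id)
  if (length(unknown))
    stop("group member(s) not in records: ", paste(unknown, collapse = ", "))
  ids <- unlist(groups, use.names = FALSE)
  recs <- records[match(ids, records$id), , drop = FALSE]
  n <- nrow(recs)
  pid <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(n - 1L, 0L))) {
    js <- (i + 1L):n
    al <- align_many(recs$sequence[js], recs$sequence[i], params)
    pid[i, js] <- al$identity_pct
    pid[js, i] <- al$identity_pct
  }
  G <- length(groups)
  out <- matrix(NA_real_, G, G, dimnames = list(names(groups), names(groups)))
  for (g in seq_len(G)) {
    for (h in g:G) {
      block <- pid[groups[[g]], groups[[h]], drop = FALSE]
      vals <- if (g == h) block[upper.tri(block)] else as.vector(block)
      out[g, h] <- out[h, g] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  out
}

#' Per-architecture diff of two annotation snapshots
#'
#' Counts the records of each architecture multiset in both snapshots;
#' unknown architectures are pooled under `"unknown"`. Growth of an enzyme
#' class concentrated in non-canonical architectures is a signature of
#' misannotation being perpetuated by automatic transfer.
#'
#' @param snapA,snapB [annotation_snapshot()] objects (deduplicated on
#'   construction).
#' @return A `version_diff`: data frame with columns `architecture`,
#'   `count_a`, `count_b`, `delta` (`count_b - count_a`), plus attributes
#'   `totals` and `version_labels`.
#' @export
version_diff <- function(snapA, snapB) {
  keyA <- vapply(snapA$records$architecture, arch_key, character(1))
  keyB <- vapply(snapB$records$architecture, arch_key, character(1))
  archs <- sort(unique(c(keyA, keyB)))
  count_a <- vapply(archs, function(a) sum(keyA == a), integer(1))
  count_b <- vapply(archs, function(a) sum(keyB == a), integer(1))
  out <- data.frame(architecture = archs, count_a = count_a,
                    count_b = count_b, delta = count_b - count_a,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "totals") <- c(n_a = nrow(snapA$records),
                           n_b = nrow(snapB$records))
  attr(out, "version_labels") <- c(snapA$version_label, snapB$version_label)
  class(out) <- c("version_diff", "data.frame")
  out
}

#' Write a version diff as TSV
#'
#' @param diff a [version_diff()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_version_diff <- function(diff, path) {
  write.table(as.data.frame(diff), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a misannotation report
#'
#' @param report a `misannotation_report`.
#' @param path output path; `.json` writes the full report, `.tsv` the
#'   per-record table.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(report$per_record, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    s <- report$class_summary
    payload <- list(
      class_summary = s[c("n", "n_characterised", "n_unknown_architecture",
                          "fraction_below_threshold",
                          "fraction_non_canonical", "threshold_pct")],
      histograms = as.data.frame(s$histograms),
      per_record = report$per_record)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
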