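#' Construct a collection of annotated sequence records
#'
#' The central container of the package: one row per protein annotated to an
#' enzyme class, carrying the residue string, the superkingdom of the source
#' organism, whether the protein has experimental characterisation, and its
#' domain architecture (an ordered vector of domain labels, empty when
#' unknown).
#'
#' @param id character vector of unique, non-empty accessions.
#' @param sequence character vector of amino-acid strings; upper-cased on
#'   input. The 20 standard residue letters plus `X` are accepted.
#' @param superkingdom one of `"Bacteria"`, `"Archaea"`, `"Eukaryota"`,
#'   `"Unknown"`; recycled.
#' @param characterised logical; experimental evidence at protein level.
#' @param architecture list of character vectors (one per record), each the
#'   ordered domain labels along the protein; `character(0)` means unknown.
#'
#' @return A data frame of class `seq_records` with columns `id`, `sequence`,
#'   `superkingdom`, `characterised` and a list column `architecture`.
#' @examples
#' recs <- seq_records(c("a", "b"), c("MKV", "MKL"))
#' nrow(recs)
#' @export
seq_records <- function(id, sequence,
                        superkingdom = "Unknown",
                        characterised = FALSE,
                        architecture = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  n <- length(id)
  if (length(sequence) != n)
    stop("'id' and 'sequence' must have the same length")
  if (any(!nzchar(id)))
    stop("record ids must be non-empty")
  if (anyDuplicated(id))
    stop("record ids must be unique within a collection: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(nchar(sequence) < 1L))
    stop("sequences must have length >= 1")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad))
    stop("non-standard residue letters in: ", paste(id[bad], collapse = ", "))
  superkingdom <- rep_len(as.character(superkingdom), n)
  ok <- superkingdom %in% c("Bacteria", "Archaea", "Eukaryota", "Unknown")
  if (!all(ok))
    stop("superkingdom must be Bacteria, Archaea, Eukaryota or Unknown")
  characterised <- rep_len(as.logical(characterised), n)
  if (is.null(architecture))
    architecture <- rep(list(character(0)), n)
  if (!is.list(architecture) || length(architecture) != n)
    stop("'architecture' must be a list with one element per record")
  architecture <- lapply(architecture, function(a) {
    a <- as.character(a)
    if (any(!nzchar(a))) stop("architecture labels must be non-empty strings")
    a
  })
  out <- data.frame(id = id, sequence = sequence,
                    superkingdom = superkingdom,
                    characterised = characterised,
                    stringsAsFactors = FALSE)
  out$architecture <- architecture
  class(out) <- c("seq_records", "data.frame")
  out
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("seq_records: %d records (%d characterised)\n",
              nrow(x), sum(x$characterised)))
  invisible(x)
}

as_seq_records <- function(x) {
  stopifnot(is.data.frame(x))
  class(x) <- c("seq_records", "data.frame")
  rownames(x) <- NULL
  x
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are upper-cased. Superkingdom, characterised status and
#' architectures are left at their defaults and can be attached afterwards
#' (see [attach_architectures()] and [mark_characterised()]).
#'
#' @param path path to a FASTA file.
#' @return A [seq_records] collection (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(seq_records(character(0), character(0))[0, ])
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA in ", path, ": line ", nonblank[1],
         " does not start with '>'")
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seq_records(ids, as.character(aa))
}

#' Write sequence records as FASTA
#'
#' Sequences are wrapped at 60 columns, so [read_fasta()] round-trips the
#' collection exactly.
#'
#' @param records a [seq_records] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Collapse exact-sequence duplicates
#'
#' Identical sequences are collapsed to the first-encountered record (input
#' order is the tie-break). The characterised flag of the retained record is
#' the OR over its duplicate group: characterisation is evidence about the
#' sequence, not the accession.
#'
#' @param records a [seq_records] collection.
#' @return The deduplicated collection, in first-occurrence order.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  grp <- match(records$sequence, unique(records$sequence))
  keep <- !duplicated(grp)
  out <- records[keep, , drop = FALSE]
  out$characterised <- as.logical(tapply(records$characterised, grp, any))
  as_seq_records(out)
}

#' Length and ambiguity filter settings
#'
#' Defaults follow the audit's pre-alignment cleanup: drop sequences shorter
#' than 200 or longer than 580 residues, and any containing the ambiguity
#' letter `X`.
#'
#' @param min_length,max_length inclusive residue-length bounds.
#' @param drop_ambiguous drop sequences containing `X`?
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_length = 200L, max_length = 580L,
                        drop_ambiguous = TRUE) {
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  if (min_length < 1L || min_length > max_length)
    stop("need 1 <= min_length <= max_length")
  structure(list(min_length = min_length, max_length = max_length,
                 drop_ambiguous = isTRUE(drop_ambiguous)),
            class = "filter_spec")
}

#' Filter sequences by length and ambiguity
#'
#' Each removed sequence is counted once, under the first matching reason in
#' the order too short, too long, ambiguous.
#'
#' @param records a [seq_records] collection.
#' @param spec a [filter_spec()].
#' @return A list with `kept` (the surviving records) and `removed_counts`,
#'   a named integer vector `too_short`, `too_long`, `ambiguous`.
#' @export
filter_sequences <- function(records, spec = filter_spec()) {
  len <- nchar(records$sequence)
  too_short <- len < spec$min_length
  too_long <- !too_short & len > spec$max_length
  ambiguous <- !too_short & !too_long &
    spec$drop_ambiguous & grepl("X", records$sequence, fixed = TRUE)
  drop <- too_short | too_long | ambiguous
  list(kept = as_seq_records(records[!drop, , drop = FALSE]),
       removed_counts = c(too_short = sum(too_short),
                          too_long = sum(too_long),
                          ambiguous = sum(ambiguous)))
}

#' Read a per-sequence domain table
#'
#' Expects a TSV with columns `id`, `domain`, `start` (1-based, inclusive
#' start coordinate of the domain hit). Domains of each sequence are ordered
#' by ascending start.
#'
#' @param path path to the TSV.
#' @return A named list mapping id to a character vector of domain labels.
#' @export
read_domain_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "domain", "start")
  if (!all(need %in% names(tab)))
    stop("domain table must have columns id, domain, start")
  start_num <- suppressWarnings(as.numeric(tab$start))
  bad <- is.na(start_num) | start_num != floor(start_num)
  if (any(bad))
    stop("non-integer start coordinate at data row ", which(bad)[1])
  if (anyDuplicated(tab[c("id", "start")]))
    stop("duplicate (id, start) pair in domain table")
  tab$start <- as.integer(start_num)
  tab <- tab[order(tab$id, tab$start), , drop = FALSE]
  split(tab$domain, tab$id)
}

#' Attach architectures from a domain table to records
#'
#' Records absent from the table keep an empty (unknown) architecture.
#'
#' @param records a [seq_records] collection.
#' @param domains a named list as returned by [read_domain_table()].
#' @return The records with the `architecture` column filled in.
#' @export
attach_architectures <- function(records, domains) {
  records$architecture <- lapply(records$id, function(i) {
    a <- domains[[i]]
    if (is.null(a)) character(0) else as.character(a)
  })
  as_seq_records(records)
}

#' Mark records as experimentally characterised
#'
#' @param records a [seq_records] collection.
#' @param ids character vector of characterised accessions, or a path to a
#'   file with one id per line.
#' @return The records with the `characterised` flag set for `ids`.
#' @export
mark_characterised <- function(records, ids) {
  if (length(ids) == 1L && file.exists(ids))
    ids <- read_id_list(ids)
  missing <- setdiff(ids, records$id)
  if (length(missing))
    warning("characterised ids not present in records: ",
            paste(missing, collapse = ", "))
  records$characterised <- records$characterised | records$id %in% ids
  as_seq_records(records)
}

#' @rdname mark_characterised
#' @param path file with one accession per line.
#' @export
read_id_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the standard 12-column tab-separated format. All rows are parsed
#' (including self-hits); duplicate query-subject pairs are collapsed keeping
#' the best bitscore.
#'
#' @param path path to the BLAST tabular file.
#' @return A data frame with columns `query`, `subject`, `bitscore`,
#'   `evalue`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query = character(0), subject = character(0),
                      bitscore = numeric(0), evalue = numeric(0))
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("BLAST tabular line ", which(nf != 12L)[1],
         " has ", nf[nf != 12L][1], " columns, expected 12")
  m <- do.call(rbind, fields)
  hits <- data.frame(query = m[, 1], subject = m[, 2],
                     bitscore = as.numeric(m[, 12]),
                     evalue = as.numeric(m[, 11]),
                     stringsAsFactors = FALSE)
  ord <- order(hits$query, hits$subject, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("query", "subject")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Bundle records as a dated annotation snapshot
#'
#' @param version_label free-text version label (e.g. `"2017.1"`).
#' @param records a [seq_records] collection; deduplicated on construction.
#' @return An `annotation_snapshot` list with `version_label` and `records`.
#' @export
annotation_snapshot <- function(version_label, records) {
  structure(list(version_label = as.character(version_label),
                 records = deduplicate(records)),
            class = "annotation_snapshot")
}

#' @export
print.annotation_snapshot <- function(x, ...) {
  cat(sprintf("annotation_snapshot %s: %d records\n",
              x$version_label, nrow(x$records)))
  invisible(x)
}
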