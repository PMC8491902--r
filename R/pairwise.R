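#' Global alignment scoring parameters
#'
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`), or a square numeric score matrix.
#' @param gap_open gap opening score (non-positive); a gap of length L costs
#'   `|gap_open| + L * |gap_extend|`.
#' @param gap_extend gap extension score per gapped position (non-positive).
#' @return An `align_params` list.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_open = -10, gap_extend = -0.5) {
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("need gap_open <= gap_extend <= 0")
  if (is.character(substitution_matrix)) {
    mat <- get(utils::data(list = substitution_matrix,
                           package = "Biostrings",
                           envir = environment()))
  } else {
    mat <- substitution_matrix
    if (!is.matrix(mat) || nrow(mat) != ncol(mat))
      stop("substitution_matrix must be a square score matrix or a name")
  }
  structure(list(substitution_matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

#' Count overlapping k-tuples of a protein sequence
#'
#' Windows containing the ambiguity letter `X` are skipped.
#'
#' @param sequence amino-acid string of length >= `k`.
#' @param k word size (default 3).
#' @param id optional accession carried along.
#' @return A `kmer_profile` list with `id`, `k`, `counts` (named integer
#'   vector) and `distinct` (number of distinct words).
#' @examples
#' kmer_profile("AAAA", 3)$counts
#' @export
kmer_profile <- function(sequence, k = 3L, id = NULL) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  k <- as.integer(k)
  if (L < k) stop("sequence shorter than word size")
  words <- substring(sequence, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  words <- words[!grepl("X", words, fixed = TRUE)]
  counts <- table(words)
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(id = id, k = k, counts = counts,
                 distinct = length(counts)),
            class = "kmer_profile")
}

#' Normalised Google distance between two k-tuple profiles
#'
#' Adapts the normalised Google distance to k-mer sets: with `f(p)` the
#' number of distinct words of profile `p`, `f(p, q)` the distinct shared
#' words and `N` the corpus-wide distinct word count,
#' `d = (max(log f(p), log f(q)) - log f(p, q)) / (log N - min(log f(p),
#' log f(q)))`, clamped to `[0, 1]`. No shared words gives 1; identical word
#' sets give 0.
#'
#' @param p,q [kmer_profile()] objects with the same word size.
#' @param corpus_distinct distinct word count `N` of the corpus the profiles
#'   come from; must be at least the distinct count of either profile.
#' @return A distance in `[0, 1]`.
#' @export
google_distance <- function(p, q, corpus_distinct) {
  if (p$k != q$k) stop("profiles have different word sizes")
  fp <- p$distinct; fq <- q$distinct
  if (fp == 0L || fq == 0L) stop("empty profile")
  if (corpus_distinct < max(fp, fq))
    stop("corpus_distinct smaller than a profile's distinct word count")
  shared <- intersect(names(p$counts), names(q$counts))
  fpq <- length(shared)
  if (fpq == 0L) return(1)
  if (fpq == fp && fpq == fq) return(0)
  num <- max(log(fp), log(fq)) - log(fpq)
  den <- log(corpus_distinct) - min(log(fp), log(fq))
  if (den <= 0) return(1)
  min(max(num / den, 0), 1)
}

#' Distinct word count of a profile corpus
#'
#' @param profiles list of [kmer_profile()] objects.
#' @return Number of distinct words across all profiles.
#' @export
corpus_distinct_words <- function(profiles) {
  length(unique(unlist(lapply(profiles, function(p) names(p$counts)),
                       use.names = FALSE)))
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' Biostrings. A gap of length L costs `|gap_open| + L * |gap_extend|`.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param params an [align_params()] object.
#' @return A list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings) and `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = params$substitution_matrix,
    gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend),
    type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

# identity over ALL alignment columns (gap columns count in the denominator)
identity_stats <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop("aligned strings differ in length")
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  matches <- sum(ca == cb & ca != "-")
  cols <- length(ca)
  list(matches = matches, aligned_columns = cols,
       identity_pct = 100 * matches / cols)
}

#' Percent identity of an aligned pair
#'
#' Identity is defined over all alignment columns: 100 x (columns with
#' identical non-gap residues) / (total columns, gap columns included).
#'
#' @param aligned_a,aligned_b equal-length gapped strings.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("AC-D", "ACED")  # 75
#' @export
percent_identity <- function(aligned_a, aligned_b) {
  identity_stats(aligned_a, aligned_b)$identity_pct
}

# Vectorised alignment of many queries against one subject; returns a
# data.frame of identity stats and scores. Column count is recovered from
# the fast accessors: total columns = L_query + L_subject - aligned pairs,
# since every non-paired residue sits in its own gap column.
align_many <- function(queries, subject, params = align_params()) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = params$substitution_matrix,
    gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend),
    type = "global")
  matches <- Biostrings::nmatch(pa)
  pairs <- matches + Biostrings::nmismatch(pa)
  cols <- nchar(queries) + nchar(subject) - pairs
  data.frame(matches = matches, aligned_columns = cols,
             identity_pct = 100 * matches / cols,
             score = Biostrings::score(pa),
             row.names = NULL)
}

# scores only (cheapest path; used for bitscore similarity graphs)
align_scores <- function(queries, subject, params = align_params()) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = params$substitution_matrix,
    gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend),
    type = "global", scoreOnly = TRUE)
}

#' Identity to the closest characterised sequence
#'
#' Ranks the characterised set by ascending k-tuple [google_distance()] to
#' the query (ties broken by subject id), aligns the `top_n` best-ranked
#' candidates globally, and reports the best percent identity among them.
#' With `top_n = 1` this is the prefilter-then-align shortcut; with
#' `top_n = length(characterised ids)` it is the exhaustive maximum.
#'
#' @param query a single-row [seq_records] collection, or a list with `id`
#'   and `sequence`.
#' @param characterised a [seq_records] collection of characterised
#'   sequences (may include the query itself, which then self-matches
#'   at 100).
#' @param k k-tuple word size for the prefilter.
#' @param top_n number of prefilter candidates to align.
#' @param params an [align_params()] object.
#' @param corpus_distinct optional distinct word count of a wider corpus;
#'   defaults to the distinct words of the query plus the characterised set.
#' @return A one-row data frame: `query`, `subject` (NA if no characterised
#'   sequences), `identity_pct`, `matches`, `aligned_columns`,
#'   `prefilter_distance`.
#' @export
closest_characterised <- function(query, characterised, k = 3L, top_n = 1L,
                                  params = align_params(),
                                  corpus_distinct = NULL) {
  qid <- query$id[1]; qseq <- query$sequence[1]
  empty <- data.frame(query = qid, subject = NA_character_,
                      identity_pct = 0, matches = 0L, aligned_columns = 0L,
                      prefilter_distance = NA_real_,
                      stringsAsFactors = FALSE)
  if (is.null(characterised) || nrow(characterised) == 0L) return(empty)
  qp <- kmer_profile(qseq, k)
  cps <- lapply(characterised$sequence, kmer_profile, k = k)
  if (is.null(corpus_distinct))
    corpus_distinct <- corpus_distinct_words(c(list(qp), cps))
  d <- vapply(cps, function(cp) google_distance(qp, cp, corpus_distinct),
              numeric(1))
  ord <- order(d, characterised$id)
  take <- ord[seq_len(min(top_n, length(ord)))]
  al <- align_many(characterised$sequence[take], qseq, params)
  best <- which.max(al$identity_pct)
  data.frame(query = qid, subject = characterised$id[take[best]],
             identity_pct = al$identity_pct[best],
             matches = al$matches[best],
             aligned_columns = al$aligned_columns[best],
             prefilter_distance = d[take[best]],
             stringsAsFactors = FALSE)
}

#' Rank agreement between the k-tuple prefilter and alignment identity
#'
#' Computes, over all unordered pairs of the sample, the Spearman rank
#' correlation between the alignment-free [google_distance()] and the
#' alignment dissimilarity `100 - identity_pct`. High agreement justifies
#' using the cheap distance to nominate alignment candidates.
#'
#' @param records a [seq_records] collection with at least 3 members.
#' @param k k-tuple word size.
#' @param params an [align_params()] object.
#' @return A list with `spearman_rho` (NA if every distance is tied) and
#'   `n_pairs`.
#' @export
rank_agreement <- function(records, k = 3L, params = align_params()) {
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records for rank agreement")
  profiles <- lapply(records$sequence, kmer_profile, k = k)
  N <- corpus_distinct_words(profiles)
  gd <- numeric(0); ad <- numeric(0)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    gd <- c(gd, vapply(js, function(j)
      google_distance(profiles[[i]], profiles[[j]], N), numeric(1)))
    al <- align_many(records$sequence[js], records$sequence[i], params)
    ad <- c(ad, 100 - al$identity_pct)
  }
  rho <- if (length(unique(gd)) == 1L || length(unique(ad)) == 1L) {
    NA_real_
  } else {
    suppressWarnings(cor(gd, ad, method = "spearman"))
  }
  list(spearman_rho = rho, n_pairs = length(gd))
}

#' Write identity results as TSV
#'
#' @param results a data frame of [closest_characterised()] rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_identity_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
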