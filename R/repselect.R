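#' Build a multiple-sequence-alignment view
#'
#' @param aligned named character vector of equal-length gapped rows (gap
#'   symbol `-`), or a named `AAStringSet`.
#' @return An `msa_view`: list with `ids`, `mat` (character matrix, rows are
#'   sequences) and `n_col`.
#' @export
msa_view <- function(aligned) {
  if (inherits(aligned, "AAStringSet"))
    aligned <- setNames(as.character(aligned), names(aligned))
  ids <- names(aligned)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("aligned rows must carry unique non-empty names")
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L)
    stop("all aligned rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, n_col = ncol(mat)),
            class = "msa_view")
}

#' Read an aligned FASTA file as an MSA view
#'
#' @param path path to aligned FASTA (equal-width rows).
#' @return An `msa_view`.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  msa_view(aa)
}

# per-column relative frequencies as a list of named numeric vectors;
# gap '-' counts as an ordinary 21st symbol
column_frequencies <- function(msa) {
  n <- nrow(msa$mat)
  lapply(seq_len(msa$n_col), function(j) {
    tab <- table(msa$mat[, j])
    setNames(as.numeric(tab) / n, names(tab))
  })
}

#' Per-column Shannon entropy of an alignment
#'
#' `H_j = -sum_a p_{j,a} log2 p_{j,a}` over the residue symbols plus the gap
#' symbol; invariant columns score 0 bits.
#'
#' @param msa an [msa_view()].
#' @return Numeric vector of entropies in bits, one per column.
#' @export
column_entropy <- function(msa) {
  vapply(column_frequencies(msa), function(p) -sum(p * log2(p)), numeric(1))
}

#' Fraction of alignment information covered by a subset of rows
#'
#' Each column contributes its entropy `H_j`, weighted by the fraction of
#' the column's symbol mass that the subset exhibits: `c_j(S)` sums the
#' full-alignment frequencies of the symbols present among the subset rows
#' at column j. The explained fraction is
#' `sum_j H_j c_j(S) / sum_j H_j`. An alignment with no variable columns is
#' fully explained by any single row.
#'
#' @param msa an [msa_view()].
#' @param subset character vector of row ids (must be rows of the MSA).
#' @return Fraction in `[0, 1]`; 0 for an empty subset by convention.
#' @export
information_explained <- function(msa, subset) {
  if (length(subset) == 0L) return(0)
  idx <- match(subset, msa$ids)
  if (anyNA(idx)) stop("subset ids not in MSA: ",
                       paste(subset[is.na(idx)], collapse = ", "))
  freqs <- column_frequencies(msa)
  H <- vapply(freqs, function(p) -sum(p * log2(p)), numeric(1))
  total <- sum(H)
  if (total == 0) return(1)
  cov <- vapply(seq_len(msa$n_col), function(j) {
    present <- unique(msa$mat[idx, j])
    sum(freqs[[j]][present])
  }, numeric(1))
  sum(H * cov) / total
}

#' Greedy entropy-weighted representative selection
#'
#' Starting from the empty set, repeatedly adds the row giving the largest
#' marginal increase of [information_explained()] (ties broken by lowest
#' row index) until the target fraction of the alignment's information is
#' explained or every row has been selected. The coverage objective is
#' monotone and submodular, so the greedy order is a principled
#' approximation to the best subset of each size.
#'
#' @param msa an [msa_view()].
#' @param target stop once this fraction of information is explained
#'   (default 0.85).
#' @return A `selection_result`: list with `selected` (ordered ids),
#'   `explained_after_step` (non-decreasing fractions), `target` and
#'   `total_information` (bits).
#' @export
select_representatives <- function(msa, target = 0.85) {
  if (!(target > 0 && target <= 1)) stop("target must be in (0, 1]")
  n <- nrow(msa$mat)
  freqs <- column_frequencies(msa)
  H <- vapply(freqs, function(p) -sum(p * log2(p)), numeric(1))
  total <- sum(H)
  # cov_mass[j] tracks the symbol mass already covered at column j;
  # marginal gain of row i = sum_j H_j * (new symbol mass row i adds at j)
  covered <- lapply(seq_len(msa$n_col), function(j) character(0))
  selected <- integer(0)
  explained <- numeric(0)
  current <- 0
  while (length(selected) < n) {
    gains <- rep(0, n)
    for (i in setdiff(seq_len(n), selected)) {
      g <- 0
      for (j in which(H > 0)) {
        sym <- msa$mat[i, j]
        if (!(sym %in% covered[[j]])) g <- g + H[j] * freqs[[j]][[sym]]
      }
      gains[i] <- g
    }
    gains[selected] <- -Inf
    pick <- which.max(gains)   # ties -> lowest row index
    selected <- c(selected, pick)
    for (j in seq_len(msa$n_col)) {
      sym <- msa$mat[pick, j]
      if (!(sym %in% covered[[j]])) covered[[j]] <- c(covered[[j]], sym)
    }
    current <- if (total == 0) 1 else current + gains[pick] / total
    explained <- c(explained, min(current, 1))
    if (explained[length(explained)] >= target) break
  }
  structure(list(selected = msa$ids[selected],
                 explained_after_step = explained,
                 target = target, total_information = total),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d selected, explained %.3f (target %.2f)\n",
              length(x$selected),
              x$explained_after_step[length(x$explained_after_step)],
              x$target))
  invisible(x)
}

#' Center-star multiple alignment via pairwise global alignments
#'
#' Aligns every sequence to a center (the longest sequence, ties by id) and
#' merges the pairwise alignments with the once-a-gap-always-a-gap rule.
#' Adequate for entropy-based selection within a cluster of related
#' sequences; an externally produced MSA can be supplied to [msa_view()]
#' instead whenever higher alignment quality is needed.
#'
#' @param records a [seq_records] collection (>= 1 row).
#' @param params an [align_params()] object.
#' @return An `msa_view` over all records.
#' @export
center_star_msa <- function(records, params = align_params()) {
  n <- nrow(records)
  if (n == 0L) stop("no records to align")
  if (n == 1L)
    return(msa_view(setNames(records$sequence, records$id)))
  ord <- order(-nchar(records$sequence), records$id)
  center <- records[ord[1], , drop = FALSE]
  others <- records[ord[-1], , drop = FALSE]
  Lc <- nchar(center$sequence)
  # slot g[pos+1] = gaps inserted into the center before residue pos+1
  aligned <- lapply(others$sequence, function(s)
    global_align(s, center$sequence, params))
  slot_gaps <- function(center_row) {
    ch <- strsplit(center_row, "", fixed = TRUE)[[1]]
    g <- integer(Lc + 1L); pos <- 0L
    for (c0 in ch) {
      if (c0 == "-") g[pos + 1L] <- g[pos + 1L] + 1L else pos <- pos + 1L
    }
    g
  }
  gaps <- lapply(aligned, function(al) slot_gaps(al$aligned_b))
  maxg <- Reduce(pmax, gaps, integer(Lc + 1L))
  pad <- function(s, width) paste0(s, strrep("-", width - nchar(s)))
  rebuild <- function(al, g) {
    ca <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
    sa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
    segs <- character(Lc + 1L)   # run of row chars in each inter-residue slot
    resid <- character(Lc)       # row char aligned to each center residue
    pos <- 0L
    for (k in seq_along(ca)) {
      if (ca[k] == "-") segs[pos + 1L] <- paste0(segs[pos + 1L], sa[k])
      else { pos <- pos + 1L; resid[pos] <- sa[k] }
    }
    out <- pad(segs[1L], maxg[1L])
    for (p in seq_len(Lc))
      out <- paste0(out, resid[p], pad(segs[p + 1L], maxg[p + 1L]))
    out
  }
  center_row <- {
    ch <- strsplit(center$sequence, "", fixed = TRUE)[[1]]
    out <- strrep("-", maxg[1L])
    for (p in seq_len(Lc))
      out <- paste0(out, ch[p], strrep("-", maxg[p + 1L]))
    out
  }
  rows <- c(setNames(center_row, center$id),
            setNames(mapply(rebuild, aligned, gaps), others$id))
  msa_view(rows[records$id])   # restore input row order
}

#' Write a selection result as TSV or JSON
#'
#' @param selection a `selection_result`.
#' @param path output path.
#' @param format `"tsv"` (step, id, explained_after_step) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(selection[c("selected", "explained_after_step",
                                     "target", "total_information")],
                         path, auto_unbox = FALSE, digits = NA)
  } else {
    tab <- data.frame(step = seq_along(selection$selected),
                      id = selection$selected,
                      explained_after_step = selection$explained_after_step)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
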