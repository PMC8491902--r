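#' Build an all-vs-all similarity graph from sequence records
#'
#' Every unordered pair is globally aligned; an edge is kept when its weight
#' is positive. With `weight_kind = "bitscore"` the weight is the alignment
#' score clamped at zero, so unrelated pairs (negative global scores) simply
#' produce no edge, mirroring the absence of a BLAST hit. With
#' `weight_kind = "identity"` the weight is the percent identity.
#'
#' @param records a [seq_records] collection.
#' @param params an [align_params()] object.
#' @param weight_kind `"bitscore"` or `"identity"`.
#' @return A `similarity_graph`: list with `nodes`, `edges` (data frame
#'   `from`, `to`, `weight`; no self-loops) and `weight_kind`.
#' @export
similarity_graph <- function(records, params = align_params(),
                             weight_kind = c("bitscore", "identity")) {
  weight_kind <- match.arg(weight_kind)
  n <- nrow(records)
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(max(n - 1L, 0L))) {
    js <- (i + 1L):n
    wij <- if (weight_kind == "bitscore") {
      pmax(align_scores(records$sequence[js], records$sequence[i], params), 0)
    } else {
      align_many(records$sequence[js], records$sequence[i], params)$identity_pct
    }
    keep <- wij > 0
    from <- c(from, rep(records$id[i], sum(keep)))
    to <- c(to, records$id[js][keep])
    w <- c(w, wij[keep])
  }
  structure(list(nodes = records$id,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
                 weight_kind = weight_kind),
            class = "similarity_graph")
}

#' Build a similarity graph from BLAST tabular hits
#'
#' Self-hits are dropped; reciprocal hits are symmetrised keeping the best
#' weight.
#'
#' @param hits data frame from [read_blast_tab()].
#' @param weight_kind `"bitscore"` or `"neg_log_evalue"` (the latter uses
#'   `-log10(evalue)`, capped at 300 for zero E-values).
#' @param nodes optional node set; defaults to all ids seen in the hits.
#' @return A `similarity_graph`.
#' @export
graph_from_blast <- function(hits,
                             weight_kind = c("bitscore", "neg_log_evalue"),
                             nodes = NULL) {
  weight_kind <- match.arg(weight_kind)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  w <- if (weight_kind == "bitscore") hits$bitscore
       else pmin(-log10(pmax(hits$evalue, 1e-300)), 300)
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  key <- paste(a, b, sep = "\r")
  best <- tapply(w, key, max)
  pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  if (is.null(nodes))
    nodes <- sort(unique(c(hits$query, hits$subject)))
  edges <- if (is.null(pairs)) {
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  } else {
    data.frame(from = pairs[, 1], to = pairs[, 2],
               weight = as.numeric(best), stringsAsFactors = FALSE)
  }
  edges <- edges[edges$weight > 0, , drop = FALSE]
  structure(list(nodes = nodes, edges = edges, weight_kind = weight_kind),
            class = "similarity_graph")
}

graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  A
}

new_cluster_set <- function(clusters, representative, method, params_used) {
  structure(list(clusters = clusters, representative = representative,
                 method = method, params_used = params_used),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set (%s): %d clusters over %d members\n",
              x$method, length(x$clusters), sum(lengths(x$clusters))))
  invisible(x)
}

#' Markov clustering of a similarity graph
#'
#' The column-stochastic transition matrix (self-loops added at the node's
#' maximum incident weight) is alternately expanded (matrix squared) and
#' inflated (elementwise power, columns renormalised), with entries below
#' `prune_below` dropped, until the matrix changes by less than 1e-8 or
#' `max_iter` is reached. Clusters are the connected components of the
#' non-zero support of the limit matrix. The inflation parameter controls
#' granularity; 1.4 is a coarse setting suited to protein families.
#'
#' @param graph a `similarity_graph`.
#' @param inflation inflation exponent, must exceed 1.
#' @param max_iter iteration cap; non-convergence raises a warning and
#'   clusters are read from the current matrix.
#' @param prune_below entries below this are zeroed each iteration.
#' @return A `cluster_set` with `method = "mcl"`. Each cluster's
#'   representative is its highest-degree member in the input graph (ties
#'   broken by id).
#' @export
mcl <- function(graph, inflation = 1.4, max_iter = 100L, prune_below = 1e-5) {
  if (length(graph$nodes) == 0L) stop("empty graph")
  if (inflation <= 1) stop("inflation must be > 1")
  A <- graph_adjacency(graph)
  n <- nrow(A)
  loop <- apply(A, 1, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  normalise <- function(M) {
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) { M[cbind(which(dead), which(dead))] <- 1; cs[dead] <- 1 }
    sweep(M, 2, cs, "/")
  }
  M <- normalise(A)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2 ^ inflation
    M2[M2 < prune_below] <- 0
    M2 <- normalise(M2)
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; clusters read from current matrix")
  support <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  clusters <- split(graph$nodes, memb)
  names(clusters) <- NULL
  deg <- table(factor(c(graph$edges$from, graph$edges$to),
                      levels = graph$nodes))
  reps <- vapply(clusters, function(cl) {
    d <- deg[cl]
    cl[order(-as.integer(d), cl)][1]
  }, character(1))
  ord <- order(vapply(clusters, function(cl) min(match(cl, graph$nodes)),
                      integer(1)))
  new_cluster_set(clusters[ord], reps[ord], "mcl",
                  list(inflation = inflation, prune_below = prune_below))
}

#' Greedy identity clustering with a shared-word prefilter
#'
#' Emulates CD-HIT's longest-first incremental clustering, but scores
#' candidates by true global-alignment identity. Records are sorted by
#' descending length (ties by id); each record joins the first existing
#' cluster whose representative (founder) aligns at or above the identity
#' threshold, and otherwise founds a new cluster. A candidate representative
#' sharing no words of size `prefilter_k` with the record is skipped without
#' aligning.
#'
#' @param records a non-empty [seq_records] collection.
#' @param threshold_pct identity threshold in percent (default 90).
#' @param prefilter_k word size of the shared-word prescreen (default 5).
#' @param params an [align_params()] object.
#' @return A `cluster_set` with `method = "greedy_identity"`.
#' @export
greedy_identity_cluster <- function(records, threshold_pct = 90,
                                    prefilter_k = 5L,
                                    params = align_params()) {
  if (nrow(records) == 0L) stop("no records to cluster")
  ord <- order(-nchar(records$sequence), records$id)
  recs <- records[ord, , drop = FALSE]
  words <- lapply(recs$sequence, function(s) {
    if (nchar(s) < prefilter_k) character(0)
    else names(kmer_profile(s, prefilter_k)$counts)
  })
  rep_idx <- integer(0)           # index into recs of each cluster founder
  members <- list()
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      r <- rep_idx[ci]
      if (length(intersect(words[[i]], words[[r]])) == 0L) next
      al <- global_align(recs$sequence[i], recs$sequence[r], params)
      if (percent_identity(al$aligned_a, al$aligned_b) >= threshold_pct) {
        members[[ci]] <- c(members[[ci]], recs$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      members[[length(members) + 1L]] <- recs$id[i]
    }
  }
  new_cluster_set(members, recs$id[rep_idx], "greedy_identity",
                  list(threshold_pct = threshold_pct,
                       prefilter_k = prefilter_k))
}

#' Representatives plus re-added characterised sequences
#'
#' Clustering keeps only representatives, which can silently drop
#' characterised sequences that landed inside a cluster; these are added
#' back so the analysis set never loses experimental evidence.
#'
#' @param clusters a `cluster_set`.
#' @param characterised_ids character vector of characterised accessions.
#' @return Character vector: representatives first, then characterised ids
#'   not already among them (deduplicated, stable order).
#' @export
restore_characterised <- function(clusters, characterised_ids) {
  all_members <- unlist(clusters$clusters, use.names = FALSE)
  missing <- setdiff(characterised_ids, all_members)
  if (length(missing))
    warning("characterised ids absent from clustering: ",
            paste(missing, collapse = ", "))
  unique(c(clusters$representative, characterised_ids))
}

#' Write a cluster set as TSV or MCL-style text
#'
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @param format `"tsv"` (columns cluster_index, member_id,
#'   is_representative) or `"mcl"` (one tab-separated cluster per line).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, format = c("tsv", "mcl")) {
  format <- match.arg(format)
  if (format == "mcl") {
    writeLines(vapply(clusters$clusters, paste, character(1),
                      collapse = "\t"), path)
  } else {
    tab <- data.frame(
      cluster_index = rep(seq_along(clusters$clusters),
                          lengths(clusters$clusters)),
      member_id = unlist(clusters$clusters, use.names = FALSE),
      stringsAsFactors = FALSE)
    tab$is_representative <- tab$member_id ==
      clusters$representative[tab$cluster_index]
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
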