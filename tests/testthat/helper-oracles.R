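# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive global-alignment optimum under affine gap costs: plain
# recursion over every monotone alignment path (no DP tables shared with
# the implementation). Gap of length L costs go + L * ge.
brute_align_score <- function(a, b, mat = blosum62, go = 10, ge = 0.5) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  La <- length(ca); Lb <- length(cb)
  rec <- function(i, j, prev) {
    if (i > La && j > Lb) return(0)
    best <- -Inf
    if (i <= La && j <= Lb)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= La)
      best <- max(best, -(ge + if (prev != "gb") go else 0) +
                    rec(i + 1L, j, "gb"))
    if (j <= Lb)
      best <- max(best, -(ge + if (prev != "ga") go else 0) +
                    rec(i, j + 1L, "ga"))
    best
  }
  rec(1L, 1L, "m")
}

# hand evaluation of Shannon entropy for a frequency vector
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# membership vector (named by id) of a cluster_set, for ARI comparisons
cluster_membership <- function(cl, ids) {
  m <- rep(seq_along(cl$clusters), lengths(cl$clusters))
  names(m) <- unlist(cl$clusters, use.names = FALSE)
  unname(m[ids])
}

# a small synthetic class used by several suites
small_class <- function(seed = 7, sizes = c(10L, 8L, 6L),
                        within = c(0.70, 0.95), characterised = c(2L, 0L, 0L),
                        indel_rate = 0.01) {
  generate_ec_class(class_config(
    seed = seed, n_families = length(sizes), family_sizes = sizes,
    within_identity = within, characterised_per_family = characterised,
    architectures = list(c("FMN_dh"), c("DAO"),
                         c("DAO", "Fer2_BFD"))[seq_along(sizes)],
    indel_rate = indel_rate))
}
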