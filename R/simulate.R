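AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson style background frequencies; used by the "blosum"
# root background to give random pairs twilight-zone identities
AA_BACKGROUND <- c(A = 0.078, C = 0.019, D = 0.054, E = 0.063, F = 0.039,
                   G = 0.073, H = 0.022, I = 0.052, K = 0.057, L = 0.090,
                   M = 0.022, N = 0.045, P = 0.052, Q = 0.043, R = 0.051,
                   S = 0.071, T = 0.058, V = 0.064, W = 0.013, Y = 0.032)

#' Draw a random protein sequence
#'
#' @param length residue length.
#' @param background `"uniform"` residue frequencies, or `"blosum"` for
#'   natural background frequencies.
#' @param seed optional integer seed.
#' @return An amino-acid string.
#' @export
random_protein <- function(length, background = c("uniform", "blosum"),
                           seed = NULL) {
  background <- match.arg(background)
  if (!is.null(seed)) set.seed(seed)
  prob <- if (background == "uniform") NULL else AA_BACKGROUND
  paste(sample(AA20, length, replace = TRUE, prob = prob), collapse = "")
}

#' Mutate a sequence to a target identity
#'
#' Substitutes `ceiling((1 - target_identity) * L)` positions, chosen
#' without replacement, each to a uniformly drawn different residue, so the
#' realised ungapped substitution identity is exactly
#' `1 - substituted / L` before indels. Single-residue indels are then
#' applied at `indel_rate` per site (half deletions, half insertions).
#'
#' @param sequence amino-acid string.
#' @param target_identity fractional identity in (0.05, 1].
#' @param indel_rate per-site indel probability (default 0).
#' @param seed optional integer seed.
#' @return The mutated sequence.
#' @export
mutate_to_identity <- function(sequence, target_identity, indel_rate = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_identity > 1) stop("target_identity must be <= 1")
  if (target_identity < 0.05)
    stop("target_identity below random-identity floor (0.05)")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(chars)
  n_sub <- ceiling((1 - target_identity) * L)
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    chars[pos] <- vapply(chars[pos], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (ch in chars) {
      u <- runif(1)
      if (u < indel_rate / 2) {
        next                                   # deletion
      } else if (u < indel_rate) {
        out <- c(out, ch, sample(AA20, 1L))    # insertion after the site
      } else {
        out <- c(out, ch)
      }
    }
    chars <- out
  }
  paste(chars, collapse = "")
}

#' Generate a sequence family around a root
#'
#' Member 1 is the unmutated root; each further member is the root mutated
#' to an identity drawn uniformly from `within_identity`.
#'
#' @param root root amino-acid string.
#' @param n family size (>= 1).
#' @param within_identity length-2 interval of fractional identities.
#' @param indel_rate per-site indel probability.
#' @param seed optional integer seed.
#' @return Character vector of `n` sequences.
#' @export
generate_family <- function(root, n, within_identity = c(0.7, 0.95),
                            indel_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 1L) stop("family size must be >= 1")
  if (n == 1L) return(root)
  u <- runif(n - 1L, min(within_identity), max(within_identity))
  c(root, vapply(u, function(ui)
    mutate_to_identity(root, ui, indel_rate), character(1)))
}

#' Configuration of a synthetic enzyme class
#'
#' The defaults emulate the structure an annotation audit assumes: one
#' canonical family holding all characterised members and sharing a
#' canonical architecture, plus several unrelated families with distinct
#' architectures (the planted misannotations), with a strongly bacterial
#' taxonomy mix (about 91% Bacteria, 6% Eukaryota, 2.6% Archaea) and a
#' planted misannotated fraction of 0.40.
#'
#' @param seed integer seed driving all randomness of the generator.
#' @param n_families number of families (>= 1); family 1 is canonical by
#'   default.
#' @param family_sizes integer sizes per family.
#' @param root_length root sequence length in residues (default 350, well
#'   inside the 200-580 length filter).
#' @param within_identity fractional identity interval within families.
#' @param canonical_family_index which family is the canonical one.
#' @param characterised_per_family number of characterised members per
#'   family.
#' @param architectures one domain-label vector per family; must be
#'   pairwise distinct as multisets.
#' @param superkingdom_weights sampling weights over Bacteria, Archaea,
#'   Eukaryota.
#' @param indel_rate per-site indel probability within families.
#' @param root_background residue background for root sampling.
#' @return A `class_config` list.
#' @export
class_config <- function(seed = 1L,
                         n_families = 5L,
                         family_sizes = c(60L, 12L, 10L, 10L, 8L),
                         root_length = 350L,
                         within_identity = c(0.70, 0.95),
                         canonical_family_index = 1L,
                         characterised_per_family = c(5L, 0L, 0L, 0L, 0L),
                         architectures = list(
                           c("FMN_dh"),
                           c("DAO"),
                           c("DAO", "Fer2_BFD"),
                           c("FAD_binding_4", "FAD-oxidase_C"),
                           c("FAD_binding_4", "FAD-oxidase_C", "CCG")),
                         superkingdom_weights = c(Bacteria = 0.914,
                                                  Archaea = 0.026,
                                                  Eukaryota = 0.060),
                         indel_rate = 0.01,
                         root_background = "uniform") {
  if (n_families < 1L) stop("need at least one family")
  if (length(family_sizes) != n_families ||
      length(characterised_per_family) != n_families ||
      length(architectures) != n_families)
    stop("family_sizes, characterised_per_family and architectures must ",
         "all have one entry per family")
  keys <- vapply(architectures, arch_key, character(1))
  if (anyDuplicated(keys))
    stop("family architectures must be pairwise distinct")
  if (any(characterised_per_family > family_sizes))
    stop("characterised_per_family cannot exceed family_sizes")
  if (!(min(within_identity) > 0 && max(within_identity) <= 1))
    stop("within_identity must lie in (0, 1]")
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 family_sizes = as.integer(family_sizes),
                 root_length = as.integer(root_length),
                 within_identity = within_identity,
                 canonical_family_index = as.integer(canonical_family_index),
                 characterised_per_family =
                   as.integer(characterised_per_family),
                 architectures = architectures,
                 superkingdom_weights = superkingdom_weights,
                 indel_rate = indel_rate,
                 root_background = root_background),
            class = "class_config")
}

#' Generate a synthetic enzyme class with ground truth
#'
#' Draws one independent random root per family (rejection sampling
#' enforces pairwise root alignment identity below 30%), expands each
#' family around its root, attaches architectures and superkingdoms, and
#' marks the designated characterised members. Deterministic under the
#' config seed.
#'
#' @param config a [class_config()].
#' @param params an [align_params()] used for the root-identity check.
#' @return A list with `snapshot` (an [annotation_snapshot()]) and `truth`
#'   (data frame: `id`, `family_index`, `is_misannotated`, `superkingdom`,
#'   `architecture` key).
#' @export
generate_ec_class <- function(config = class_config(),
                              params = align_params()) {
  set.seed(config$seed)
  roots <- character(0)
  for (f in seq_len(config$n_families)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      cand <- random_protein(config$root_length,
                             background = config$root_background)
      if (length(roots) == 0L) { ok <- TRUE; break }
      ids <- align_many(roots, cand, params)$identity_pct
      if (all(ids < 30)) { ok <- TRUE; break }
    }
    if (!ok) stop("roots too similar; increase root_length")
    roots <- c(roots, cand)
  }
  id <- character(0); sequence <- character(0); fam <- integer(0)
  characterised <- logical(0)
  for (f in seq_len(config$n_families)) {
    n <- config$family_sizes[f]
    seqs <- generate_family(roots[f], n, config$within_identity,
                            config$indel_rate)
    id <- c(id, sprintf("fam%02d_seq%03d", f, seq_len(n)))
    sequence <- c(sequence, seqs)
    fam <- c(fam, rep.int(f, n))
    characterised <- c(characterised,
                       seq_len(n) <= config$characterised_per_family[f])
  }
  kingdoms <- sample(names(config$superkingdom_weights), length(id),
                     replace = TRUE, prob = config$superkingdom_weights)
  records <- seq_records(id, sequence, superkingdom = kingdoms,
                         characterised = characterised,
                         architecture = config$architectures[fam])
  truth <- data.frame(
    id = id, family_index = fam,
    is_misannotated = fam != config$canonical_family_index,
    superkingdom = kingdoms,
    architecture = vapply(config$architectures[fam], arch_key, character(1)),
    stringsAsFactors = FALSE)
  list(snapshot = annotation_snapshot("synthetic", records), truth = truth)
}

#' Write a synthetic class as the pipeline's input files
#'
#' Emits `sequences.fasta`, `domains.tsv` (id, domain, start — starts are
#' synthetic placeholders spaced 150 residues apart), `characterised.txt`
#' and `truth.json` into a directory: exactly the input contract of
#' [run_audit()].
#'
#' @param class_data result of [generate_ec_class()].
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_class_dataset <- function(class_data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- class_data$snapshot$records
  write_fasta(recs, file.path(dir, "sequences.fasta"))
  rows <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
    a <- recs$architecture[[i]]
    if (length(a) == 0L) return(NULL)
    data.frame(id = recs$id[i], domain = a,
               start = seq(10L, by = 150L, length.out = length(a)))
  }))
  write.table(rows, file.path(dir, "domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(recs$id[recs$characterised],
             file.path(dir, "characterised.txt"))
  jsonlite::write_json(class_data$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Generate Michaelis-Menten data with multiplicative noise
#'
#' `v_i = V_max * S_i / (K_M + S_i) * (1 + e_i)` with
#' `e_i ~ Normal(0, noise_cv)`.
#'
#' @param K_M,V_max generating parameters (positive).
#' @param concentrations substrate concentrations in M.
#' @param noise_cv coefficient of variation of the noise (0 = exact).
#' @param seed optional integer seed.
#' @return Data frame with `substrate_M`, `velocity_M_per_s`.
#' @export
generate_kinetic_data <- function(K_M, V_max, concentrations,
                                  noise_cv = 0, seed = NULL) {
  if (K_M <= 0 || V_max <= 0) stop("K_M and V_max must be positive")
  if (!is.null(seed)) set.seed(seed)
  S <- as.numeric(concentrations)
  v <- V_max * S / (K_M + S)
  if (noise_cv > 0) v <- v * (1 + rnorm(length(S), 0, noise_cv))
  data.frame(substrate_M = S, velocity_M_per_s = v)
}

#' Generate a screening plate with known hit labels
#'
#' Blanks are drawn first and fix the plate's limit of detection
#' (blank mean + 4 SD). Hit proteins receive all replicates above
#' `LOD + lod_margin`; non-hits stay below `LOD - lod_margin` (floored at
#' zero). All proteins are scored soluble in every expression replicate, so
#' activity alone decides the call.
#'
#' @param n_hits,n_nonhits protein counts.
#' @param lod_margin signal distance kept from the LOD on either side.
#' @param n_replicates replicates per protein.
#' @param blank_mean,blank_sd blank signal distribution.
#' @param seed optional integer seed.
#' @return A list with `measurements` (list of [plate_measurement()], with
#'   pre-subtracted signals), `blanks`, `lod` and `truth` (data frame
#'   `protein_id`, `is_hit`).
#' @export
generate_plate <- function(n_hits, n_nonhits, lod_margin = 5,
                           n_replicates = 3L, blank_mean = 10, blank_sd = 1,
                           seed = NULL) {
  if (n_hits < 0 || n_nonhits < 0) stop("counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  blanks <- rnorm(max(n_replicates, 2L), blank_mean, blank_sd)
  lod <- detection_limit(blanks)
  ids <- c(if (n_hits) sprintf("hit%03d", seq_len(n_hits)),
           if (n_nonhits) sprintf("neg%03d", seq_len(n_nonhits)))
  is_hit <- c(rep(TRUE, n_hits), rep(FALSE, n_nonhits))
  measurements <- lapply(seq_along(ids), function(i) {
    base <- if (is_hit[i]) lod + lod_margin else max(lod - lod_margin, 0)
    sig <- base + runif(n_replicates, 0, lod_margin / 2) *
      (if (is_hit[i]) 1 else -1)
    plate_measurement(ids[i], "substrate", signals = sig,
                      soluble_calls = rep(TRUE, n_replicates))
  })
  list(measurements = measurements, blanks = blanks, lod = lod,
       truth = data.frame(protein_id = ids, is_hit = is_hit,
                          stringsAsFactors = FALSE))
}
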