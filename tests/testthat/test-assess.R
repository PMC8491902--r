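test_that("architecture comparison is order-blind but copy-number aware", {
  expect_true(same_architecture("FMN_dh", "FMN_dh"))
  expect_true(same_architecture(c("DAO", "Fer2_BFD"), c("Fer2_BFD", "DAO")))
  expect_false(same_architecture("DAO", c("DAO", "DAO")))
  expect_true(same_architecture(character(0), character(0)))
})

test_that("architecture equality is an equivalence relation", {
  set.seed(41)
  labels <- c("DAO", "FMN_dh", "CCG", "Fer2_BFD")
  archs <- replicate(12, sample(labels, sample(0:4, 1), replace = TRUE),
                     simplify = FALSE)
  for (a in archs) expect_true(same_architecture(a, a))        # reflexive
  for (a in archs) for (b in archs) {
    expect_equal(same_architecture(a, b), same_architecture(b, a))
    for (cc in archs)                                          # transitive
      if (same_architecture(a, b) && same_architecture(b, cc))
        expect_true(same_architecture(a, cc))
  }
})

test_that("canonical architectures are the distinct characterised multisets", {
  recs <- seq_records(c("a", "b", "c"), c("MKV", "MKL", "MKW"),
                      characterised = TRUE,
                      architecture = list(c("FMN_dh"),
                                          c("FMN_dh", "Cyt_B5"),
                                          c("Cyt_B5", "FMN_dh")))
  canon <- canonical_architectures(recs)
  expect_equal(length(canon), 2L)
  bare <- seq_records("a", "MKV", characterised = TRUE)
  expect_error(canonical_architectures(bare), "no canonical reference")
})

test_that("conserved residues are checked through the alignment", {
  set.seed(43)
  ref <- random_protein(80)
  pos <- c(5L, 20L, 41L, 60L)
  spec <- residue_spec("ref", pos,
                       substring(ref, pos, pos))
  q_same <- seq_records("q1", ref)
  out <- conserved_residues(q_same[1, ], spec, ref)
  expect_true(all(out$conserved))
  expect_equal(out$fraction, 1)
  # one specified position mutated -> fraction (m-1)/m
  chars <- strsplit(ref, "")[[1]]
  orig <- chars[20]
  chars[20] <- setdiff(c("W", "Y"), orig)[1]
  out2 <- conserved_residues(list(sequence = paste(chars, collapse = "")),
                             spec, ref)
  expect_equal(sum(out2$conserved), 3L)
  expect_equal(out2$fraction, 3 / 4)
  # deletion spanning a specified position scores it not conserved
  del <- paste(strsplit(ref, "")[[1]][-(18:22)], collapse = "")
  out3 <- conserved_residues(list(sequence = del), spec, ref)
  expect_false(out3$conserved[[2]])
  expect_error(residue_spec("r", c(5, 5), c("A", "A")), "increasing")
  expect_error(conserved_residues(q_same[1, ],
                                  residue_spec("ref", 1, "B"), ref),
               "inconsistent")
})

test_that("classify recovers planted misannotation fractions exactly", {
  cls <- small_class(seed = 47, sizes = c(12L, 8L), characterised = c(3L, 0L))
  recs <- cls$snapshot$records
  rep <- classify(recs, recs$id[recs$characterised])
  expect_equal(rep$class_summary$fraction_non_canonical, 8 / 20)
  expect_equal(rep$class_summary$fraction_below_threshold, 8 / 20)
  truth <- cls$truth$is_misannotated[match(rep$per_record$id, cls$truth$id)]
  expect_equal(rep$per_record$below_threshold, truth)
  expect_equal(!rep$per_record$canonical_architecture, truth)
})

test_that("every record characterised means nothing below threshold", {
  cls <- small_class(seed = 53, sizes = c(6L), characterised = c(6L))
  recs <- cls$snapshot$records
  rep <- classify(recs, recs$id)
  expect_equal(rep$class_summary$fraction_below_threshold, 0)
  expect_true(all(rep$per_record$max_identity_pct == 100))
})

test_that("the identity threshold is strict (less than)", {
  # W|AAA vs W|CCC aligns gaplessly (gaps cost >= 10.5 and gain nothing),
  # giving exactly 1 match / 4 columns = 25%
  recs <- seq_records(c("q", "s"), c("WAAA", "WCCC"),
                      characterised = c(FALSE, TRUE),
                      architecture = list("D1", "D1"))
  rep <- classify(recs, "s", threshold_pct = 25)
  expect_equal(rep$per_record$max_identity_pct[1], 25)
  expect_false(rep$per_record$below_threshold[1])
})

test_that("unknown architectures are flagged but excluded from the fraction", {
  cls <- small_class(seed = 59, sizes = c(6L, 4L), characterised = c(2L, 0L))
  recs <- cls$snapshot$records
  recs$architecture[[6]] <- character(0)   # canonical member, arch unknown
  rep <- classify(recs, recs$id[recs$characterised])
  expect_equal(rep$class_summary$n_unknown_architecture, 1L)
  expect_false(rep$per_record$canonical_architecture[6])
  expect_equal(rep$class_summary$fraction_non_canonical, 4 / 9)
  rep_inc <- classify(recs, recs$id[recs$characterised],
                      include_unknown = TRUE)
  expect_equal(rep_inc$class_summary$fraction_non_canonical, 5 / 10)
})

test_that("below-threshold fraction is monotone in the threshold", {
  cls <- small_class(seed = 61, sizes = c(8L, 6L), characterised = c(2L, 0L))
  recs <- cls$snapshot$records
  fr <- vapply(c(5, 25, 60, 95), function(th)
    classify(recs, recs$id[recs$characterised],
             threshold_pct = th)$class_summary$fraction_below_threshold,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("histogram counts sum to record counts per superkingdom", {
  cls <- small_class(seed = 67)
  recs <- cls$snapshot$records
  rep <- classify(recs, recs$id[recs$characterised])
  h <- rep$class_summary$histograms
  expect_equal(colSums(h),
               c(table(factor(recs$superkingdom, levels = colnames(h)))))
  expect_equal(sum(h), nrow(recs))
  expect_equal(rownames(h)[1], "0")
  expect_equal(rownames(h)[101], "100")
})

test_that("architecture identity matrix separates planted groups", {
  cls <- small_class(seed = 71, sizes = c(5L, 5L), characterised = c(1L, 0L))
  recs <- cls$snapshot$records
  m <- architecture_identity_matrix(recs)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(diag(m) > 50))
  expect_lt(m[1, 2], 25)
  expect_equal(m[1, 2], m[2, 1])
  # hand-computable within-mean for a 2-member group
  two <- seq_records(c("a", "b"), c("WWWWAAAA", "WWWWCCCC"))
  al <- global_align(two$sequence[1], two$sequence[2])
  m2 <- architecture_identity_matrix(two, groups = list(g = c("a", "b")))
  expect_equal(m2["g", "g"], percent_identity(al$aligned_a, al$aligned_b))
  single <- architecture_identity_matrix(two, groups = list(g = "a", h = "b"))
  expect_true(is.na(single["g", "g"]))   # singleton within-mean undefined
  expect_error(architecture_identity_matrix(two, groups = list(g = "zz")),
               "not in records")
})

test_that("version diffs count architectures and their deltas", {
  mkrec <- function(ids, arch) seq_records(ids,
    vapply(seq_along(ids), function(i) random_protein(30), ""),
    architecture = rep(list(arch), length(ids)))
  set.seed(73)
  a1 <- mkrec(paste0("a", 1:4), "FMN_dh")
  a2 <- mkrec(paste0("b", 1:5), "DAO")
  snapA <- annotation_snapshot("2017.1", rbind(a1, a2))
  expect_equal(unique(version_diff(snapA, snapA)$delta), 0L)
  a3 <- mkrec(paste0("c", 1:5), "DAO")
  snapB <- annotation_snapshot("2019.2", rbind(a1, a2, a3))
  d <- version_diff(snapA, snapB)
  expect_equal(d$delta[d$architecture == "DAO"], 5L)
  expect_equal(attr(d, "totals"), c(n_a = 9L, n_b = 14L))
  # record absent from B contributes -1 to its architecture
  snapC <- annotation_snapshot("2019.2", rbind(a1[-1, ], a2))
  d2 <- version_diff(snapA, snapC)
  expect_equal(d2$delta[d2$architecture == "FMN_dh"], -1L)
  # unknown architectures pool under "unknown"
  u <- seq_records("u1", random_protein(30))
  d3 <- version_diff(snapA, annotation_snapshot("x", rbind(a1, u)))
  expect_equal(d3$count_b[d3$architecture == "unknown"], 1L)
})

test_that("reports serialise to JSON and TSV", {
  cls <- small_class(seed = 79, sizes = c(5L, 3L), characterised = c(2L, 0L))
  recs <- cls$snapshot$records
  rep <- classify(recs, recs$id[recs$characterised])
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$class_summary$fraction_non_canonical,
               rep$class_summary$fraction_non_canonical)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, tsv, format = "tsv")
  expect_equal(nrow(read.delim(tsv)), nrow(recs))
})
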