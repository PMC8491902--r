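test_that("read_fasta parses entries and tokenizes headers", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P05414|GOX length=369", "MKVLAA", "CDEF",
               ">b2 some description", "mklw"), path)
  recs <- read_fasta(path)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$id, c("sp|P05414|GOX", "b2"))
  expect_equal(recs$sequence, c("MKVLAACDEF", "MKLW"))  # upper-cased, joined
})

test_that("read_fasta handles empty files and rejects malformed input", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKVLAA", ">a"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("fasta writing round-trips records exactly", {
  set.seed(21)
  recs <- seq_records(c("longid|x", "b", "c"),
                      c(random_protein(150), random_protein(61),
                        random_protein(60)))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("seq_records enforces its invariants", {
  expect_error(seq_records(c("a", "a"), c("MK", "MK")), "unique")
  expect_error(seq_records("", "MK"), "non-empty")
  expect_error(seq_records("a", ""), "length")
  expect_error(seq_records("a", "MK", superkingdom = "Virus"), "superkingdom")
  expect_error(seq_records("a", "MKB"), "non-standard")
  expect_error(seq_records("a", "MK", architecture = list("")), "non-empty")
})

test_that("deduplicate collapses to first-seen and ORs characterised flags", {
  recs <- seq_records(c("a", "b", "c", "d"),
                      c("MKVL", "MKVL", "MKWW", "MKVL"),
                      characterised = c(FALSE, TRUE, FALSE, FALSE))
  out <- deduplicate(recs)
  expect_equal(out$id, c("a", "c"))
  expect_equal(out$characterised, c(TRUE, FALSE))
  # idempotent
  expect_equal(deduplicate(out), out)
  # all distinct: unchanged
  distinct <- seq_records(c("x", "y"), c("MKA", "MKC"))
  expect_equal(deduplicate(distinct), distinct)
})

test_that("filter_sequences applies length bounds inclusively and counts by reason", {
  mk <- function(n) paste(rep("A", n), collapse = "")
  recs <- seq_records(paste0("s", 1:6),
                      c(mk(199), mk(200), mk(580), mk(581),
                        paste0(mk(250), "X", mk(50)), mk(300)))
  out <- filter_sequences(recs)
  expect_equal(out$kept$id, c("s2", "s3", "s6"))
  expect_equal(out$removed_counts,
               c(too_short = 1L, too_long = 1L, ambiguous = 1L))
  # partition: kept + removed == input
  expect_equal(nrow(out$kept) + sum(out$removed_counts), nrow(recs))
  # drop_ambiguous = FALSE keeps the X-containing sequence
  lax <- filter_sequences(recs, filter_spec(drop_ambiguous = FALSE))
  expect_true("s5" %in% lax$kept$id)
  expect_error(filter_spec(min_length = 0), "min_length")
  expect_error(filter_spec(min_length = 10, max_length = 5), "min_length")
})

test_that("domain tables order architectures by start coordinate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdomain\tstart", "B\tFer2_BFD\t300", "A\tFMN_dh\t10",
               "B\tDAO\t5"), path)
  dom <- read_domain_table(path)
  expect_equal(dom[["A"]], "FMN_dh")
  expect_equal(dom[["B"]], c("DAO", "Fer2_BFD"))
  recs <- attach_architectures(seq_records(c("A", "B", "C"),
                                           c("MK", "MK", "MK")[1:3] |>
                                             paste0(c("A", "C", "W"))), dom)
  expect_equal(recs$architecture[[3]], character(0))  # absent id -> unknown
})

test_that("domain tables reject bad starts and duplicate coordinates", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdomain\tstart", "A\tDAO\tten"), bad)
  expect_error(read_domain_table(bad), "non-integer")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tdomain\tstart", "A\tDAO\t5", "A\tCCG\t5"), dup)
  expect_error(read_domain_table(dup), "duplicate")
})

test_that("BLAST tabular parsing keeps best bitscore per pair", {
  row <- function(q, s, ev, bs)
    paste(q, s, "90", "100", "1", "0", "1", "100", "1", "100", ev, bs,
          sep = "\t")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(row("a", "a", "1e-50", "200"), row("a", "b", "1e-10", "50"),
               row("a", "b", "1e-20", "80"), row("b", "c", "1e-5", "30")),
             path)
  hits <- read_blast_tab(path)
  expect_equal(nrow(hits), 3L)  # self-hit retained, duplicate collapsed
  expect_equal(hits$bitscore[hits$query == "a" & hits$subject == "b"], 80)
  empty <- withr::local_tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(read_blast_tab(empty)), 0L)
  bad <- withr::local_tempfile()
  writeLines("a\tb\tonly-three", bad)
  expect_error(read_blast_tab(bad), "expected 12")
})

test_that("mark_characterised flags listed ids and warns on unknowns", {
  recs <- seq_records(c("a", "b"), c("MKA", "MKC"))
  out <- mark_characterised(recs, "b")
  expect_equal(out$characterised, c(FALSE, TRUE))
  expect_warning(mark_characterised(recs, c("b", "zz")), "zz")
})
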