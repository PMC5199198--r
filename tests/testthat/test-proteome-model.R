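test_that("FASTA reading preserves order, lengths and ids", {
  lens <- c(545, 393, 130, 75)
  path <- withr::local_tempfile(fileext = ".fasta")
  set.seed(11)
  writeLines(unlist(lapply(seq_along(lens), function(i) {
    c(sprintf(">prot%d some description", i), random_seq(lens[i]))
  })), path)
  p <- read_proteome_fasta(path, "UPA")
  expect_s3_class(p, "proteome")
  expect_equal(nrow(p$proteins), 4)
  expect_equal(p$proteins$length, lens)
  expect_equal(p$proteins$protein_id, sprintf("prot%d", 1:4))
})

test_that("minimal and malformed FASTA inputs", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "M"), path)
  p <- read_proteome_fasta(path, "mini")
  expect_equal(p$proteins$length, 1L)

  writeLines(c(">p1", "MKV", ">p1", "MKT"), path)
  expect_error(read_proteome_fasta(path, "dup"), "Duplicate protein id")

  writeLines(c(">p1", "MK7V"), path)
  expect_error(read_proteome_fasta(path, "bad"), "Invalid residue '7'")

  writeLines(character(0), path)
  expect_error(read_proteome_fasta(path, "empty"), "empty")

  expect_error(read_proteome_fasta(tempfile(), "missing"), "not found")
})

test_that("sequences are upper-cased and terminal stops stripped", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "mkvl*", ">p2", "MKTA"), path)
  p <- read_proteome_fasta(path, "x")
  expect_equal(p$proteins$sequence, c("MKVL", "MKTA"))
})

test_that("FASTA round-trip is lossless", {
  p <- generate_base_proteome(6, c(40, 90), seed = 3, proteome_id = "rt")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(p, path)
  p2 <- read_proteome_fasta(path, "rt")
  expect_equal(p2$proteins$protein_id, p$proteins$protein_id)
  expect_equal(p2$proteins$sequence, p$proteins$sequence)
})

test_that("metadata table parsing, defaults and validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "proteome_id\tspecies_group_id\tis_reference\tpriority_score\tannotation_level\tprevious_state",
    "P1\tsp1\t1\t2\t100\t1",
    "P3\tsp2\t0\t1\t5\t0"), path)
  md <- read_metadata_table(path)
  expect_true(md$is_reference[md$proteome_id == "P1"])
  expect_equal(md$priority_score, c(2L, 1L))
  expect_equal(md$previous_state, c(1L, 0L))

  # previous_state column omitted: defaults to 1 (never processed before)
  writeLines(c(
    "proteome_id\tspecies_group_id\tis_reference\tpriority_score\tannotation_level",
    "P1\tsp1\t0\t1\t0"), path)
  expect_equal(read_metadata_table(path)$previous_state, 1L)

  # a reference proteome must carry priority score 2
  writeLines(c(
    "proteome_id\tspecies_group_id\tis_reference\tpriority_score\tannotation_level\tprevious_state",
    "P2\tsp1\t1\t1\t0\t1"), path)
  expect_error(read_metadata_table(path), "priority_score")

  writeLines(c("proteome_id\tis_reference", "P1\t0"), path)
  expect_error(read_metadata_table(path), "missing column")
})

test_that("metadata round-trips through the table format", {
  md <- toy_metadata(c("A", "B", "C"), is_reference = c(TRUE, FALSE, FALSE),
                     annotation_level = c(7L, 0L, 3L),
                     previous_state = c(1L, 0L, 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata_table(md, path)
  expect_equal(read_metadata_table(path), md)
})

test_that("results table writing is deterministic and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  statuses <- tibble::tibble(
    proteome_id = c("B", "A"),
    status = c("non-redundant", "redundant"),
    representatives = list(character(0), "B"))
  write_results_table(statuses, path)
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expect_equal(out$proteome_id, c("A", "B"))  # sorted
  expect_equal(out$representatives, c("B", NA))
  back <- read_results_table(path)
  expect_equal(back$representatives, list("B", character(0)))

  statuses$representatives <- list(character(0), character(0))
  expect_error(write_results_table(statuses, path), "without a representative")
})

test_that("proteome construction enforces its invariants", {
  expect_error(proteome("x", tibble::tibble(protein_id = character(0),
                                            sequence = character(0))),
               "no proteins")
  p <- toy_proteome("x", c("MKVL", "GG"))
  expect_equal(p$proteins$length, c(4L, 2L))
  expect_error(toy_proteome("x", c("MKVL", "M1")), "Invalid residue")
  expect_error(
    proteome("x", tibble::tibble(protein_id = c("a", "a"),
                                 sequence = c("MK", "MV"))),
    "Duplicate")
  # extended residues are accepted
  expect_silent(toy_proteome("x", "MKBZXUO"))
})
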