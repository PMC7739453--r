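test_that("FASTA parsing joins lines, upper-cases and takes the first header token", {
  p <- write_tmp_fasta(c(">P1 some description", "MKV"))
  rec <- read_fasta(p)
  expect_equal(rec$protein_id, "P1")
  expect_equal(rec$residues, "MKV")

  p2 <- write_tmp_fasta(c(">P1", "MK", "V", ">P2", "aag"))
  rec2 <- read_fasta(p2)
  expect_equal(rec2$protein_id, c("P1", "P2"))
  expect_equal(rec2$residues, c("MKV", "AAG"))
})

test_that("FASTA integrity errors: duplicates, missing and empty files", {
  dup <- write_tmp_fasta(c(">P1", "MKV", ">P1", "AAG"))
  expect_error(read_fasta(dup), "P1")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
  empty <- write_tmp_fasta(character(0))
  expect_error(read_fasta(empty))
})

test_that("non-standard residue letters are accepted with a warning", {
  p <- write_tmp_fasta(c(">P1", "MKXV"))
  expect_warning(rec <- read_fasta(p), "non-standard")
  expect_equal(rec$residues, "MKXV")
})

test_that("pair lists parse, validate identifiers and labels", {
  recs <- data.frame(protein_id = c("P1", "P2", "P3"),
                     residues = c("MKV", "AAG", "CCW"))
  p <- write_tmp_pairs(c("# comment", "P1\tP2\t1", "P1 P3 0"))
  pairs <- read_pairs(p, recs)
  expect_equal(pairs$id_a, c("P1", "P1"))
  expect_equal(pairs$label, c(1L, 0L))

  expect_error(read_pairs(write_tmp_pairs("P1\tP9\t0"), recs), "P9")
  expect_error(read_pairs(write_tmp_pairs("P1\tP2\t2"), recs), "label")
  expect_error(read_pairs(write_tmp_pairs(c("P1 P2 1", "P2 P1 0")), recs),
               "conflicting")
  # identical duplicates collapse to a single pair (set semantics)
  expect_equal(nrow(read_pairs(write_tmp_pairs(c("P1 P2 1", "P2 P1 1")),
                               recs)), 1L)
})

test_that("writing then re-reading a pair file reproduces the pair set", {
  gen <- tiny_planted_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(gen$dataset$pairs, path)
  back <- read_pairs(path, gen$dataset$records)
  expect_equal(back, gen$dataset$pairs, ignore_attr = TRUE)
})

test_that("dataset assembly enforces referential and label integrity", {
  recs <- data.frame(protein_id = c("P1", "P2"), residues = c("MKV", "AAG"))
  ok <- ppi_dataset(recs, data.frame(id_a = "P1", id_b = "P2", label = 1L))
  expect_s3_class(ok, "ppi_dataset")
  expect_error(
    ppi_dataset(recs, data.frame(id_a = "P1", id_b = "P9", label = 1L)),
    "P9")
  expect_error(
    ppi_dataset(recs, data.frame(id_a = c("P1", "P2"), id_b = c("P2", "P1"),
                                 label = c(1L, 0L))),
    "conflicting")
})

test_that("benchmark verification reports counts and never raises on failure", {
  gen <- synth_generate(synthetic_config(
    n_proteins = 10, n_groups = 2, seq_length_range = c(20L, 25L),
    motif_length = 5L, p_within = 1, p_between = 0.3,
    prevalence = 0.6, n_pairs = 10L, seed = 3))
  rep_ok <- verify_benchmark(gen$dataset,
                             benchmark_profile(10, 6, 4, name = "toy"))
  expect_true(all(rep_ok$pass))
  # total always equals positives + negatives
  expect_equal(rep_ok$observed[rep_ok$check == "total_pairs"],
               sum(rep_ok$observed[rep_ok$check %in%
                                     c("positive_pairs", "negative_pairs")]))
  rep_bad <- verify_benchmark(gen$dataset,
                              benchmark_profile(12, 6, 6, 50, name = "wrong"))
  expect_false(all(rep_bad$pass))
  expect_output(print(rep_bad), "FAIL")
})
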