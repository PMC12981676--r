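test_that("read_fasta parses single and wrapped records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKV"), f)
  out <- read_fasta(f)
  expect_equal(out$protein_id, "p1")
  expect_equal(out$sequence, "MKV")

  writeLines(c(">p1 description text", "MKV", "LLA", ">p2", "acd", "efg"), f)
  out <- read_fasta(f)
  expect_equal(out$protein_id, c("p1", "p2"))
  expect_equal(out$sequence, c("MKVLLA", "ACDEFG"))
})

test_that("read_fasta rejects malformed input with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")

  writeLines(c(">p1", "MKB"), f)
  expect_error(read_fasta(f), "illegal residue.*B")

  writeLines(c(">p1", "MKV", ">p1", "AAA"), f)
  expect_error(read_fasta(f), "duplicate.*p1")

  writeLines(c("MKV"), f)
  expect_error(read_fasta(f), "header")
})

test_that("interaction tables read from CSV and TSV with sniffed delimiter", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug_id,protein_id,affinity",
               "d1,p1,5.2", "d2,p1,6.0", "d1,p2,4.8"), f)
  out <- read_interaction_table(f)
  expect_equal(nrow(out), 3L)
  expect_equal(out$affinity, c(5.2, 6.0, 4.8))
  expect_equal(out$drug_id, c("d1", "d2", "d1"))

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_id\tprotein_id\taffinity",
               "d1\tp1\t5.2", "d2\tp1\t6"), ft)
  out_t <- read_interaction_table(ft)
  expect_equal(out_t$affinity, c(5.2, 6.0))
  expect_equal(out_t$protein_id, c("p1", "p1"))
})

test_that("interaction table errors name the problem", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("drug,protein_id,affinity", "d1,p1,5.2"), f)
  expect_error(read_interaction_table(f), "missing column.*drug_id.*found")

  writeLines(c("drug_id,protein_id,affinity", "d1,p1,5.2", "d2,p2,NA"), f)
  expect_error(read_interaction_table(f), "row 2")
})

test_that("read_matrix handles text and NPY, rejects bad shapes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 0"), f)
  expect_equal(read_matrix(f), matrix(c(0, 1, 1, 0), 2, 2))

  m <- matrix(rnorm(12), 3, 4)
  fn <- withr::local_tempfile(fileext = ".npy")
  write_npy(m, fn)
  expect_identical(read_matrix(fn), m)

  writeLines(c("0 1", "1 0 2"), f)
  expect_error(read_matrix(f), "ragged")

  writeLines(c("0 x", "1 0"), f)
  expect_error(read_matrix(f), "non-finite|non-numeric")
})

test_that("NPY reader enforces rank 2 and reads numpy-written files", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  d <- withr::local_tempdir()
  script <- file.path(d, "w.py")
  writeLines(c(
    "import numpy as np",
    sprintf("np.save('%s/a.npy', np.arange(6, dtype=np.float64).reshape(2, 3))", d),
    sprintf("np.save('%s/b.npy', np.asfortranarray(np.arange(6, dtype=np.float32).reshape(3, 2)))", d),
    sprintf("np.save('%s/c.npy', np.arange(4, dtype=np.float64))", d)), script)
  system2(py, script)
  expect_equal(read_matrix(file.path(d, "a.npy")),
               matrix(0:5, 2, 3, byrow = TRUE))
  expect_equal(read_matrix(file.path(d, "b.npy")),
               matrix(0:5, 3, 2, byrow = TRUE))
  expect_error(read_matrix(file.path(d, "c.npy")), "2-D")
})

test_that("predictions round-trip with 6 decimals and empty y_true", {
  preds <- tibble::tibble(drug_id = c("d1", "d2"), protein_id = c("p1", "p2"),
                          y_true = c(5.123456789, NA), y_pred = c(5.1, 4.9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(preds, f)
  lines <- readLines(f)
  expect_equal(length(lines), 3L)
  expect_match(lines[2], "5.123457")
  expect_match(lines[3], "^d2,p2,,4.900000$")
  back <- read_predictions(f)
  expect_equal(back$y_pred, c(5.1, 4.9), tolerance = 1e-6)
  expect_true(is.na(back$y_true[2]))
})

test_that("a large predictions table writes one line per record plus header", {
  n <- 1000L
  preds <- tibble::tibble(drug_id = sprintf("d%04d", 1:n),
                          protein_id = "p1", y_true = runif(n),
                          y_pred = runif(n))
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(preds, f)
  expect_equal(length(readLines(f)), n + 1L)
})

test_that("record constructors enforce the width and shape invariants", {
  expect_error(protein_record("p", "MKB"), "illegal")
  expect_error(protein_record("p", "MKV", embeddings = matrix(0, 3, 10)),
               "width")
  expect_error(protein_record("p", "MKV",
                              embeddings = matrix(0, 4, 1152)), "tokens")
  ok <- protein_record("p", "MKV", embeddings = matrix(0, 5, 1152),
                       has_special_tokens = TRUE)
  expect_s3_class(ok, "protein_record")
  bad_contact <- matrix(2, 3, 3)
  expect_error(protein_record("p", "MKV", contact = bad_contact), "\\[0, 1\\]")
  expect_error(protein_record("p", "MKV", contact = matrix(0.2, 2, 3)),
               "square")

  expect_error(drug_record("d", "CCO", embeddings = matrix(0, 3, 100)),
               "width")
  g <- weighted_graph(matrix(0, 2, 88), rbind(c(0, 1), c(1, 0)), c(1, 1))
  expect_s3_class(drug_record("d", "CCO", graph = g), "drug_record")
  g_bad <- weighted_graph(matrix(0, 2, 5), rbind(c(0, 1), c(1, 0)), c(1, 1))
  expect_error(drug_record("d", "CCO", graph = g_bad), "feature width")
})

test_that("weighted_graph validates indices, weights and edge pairing", {
  nf <- matrix(0, 3, 4)
  expect_error(weighted_graph(nf, rbind(c(0, 3), c(3, 0)), c(1, 1)),
               "\\[0, 3\\)")
  expect_error(weighted_graph(nf, rbind(c(0, 1), c(1, 0)), c(1)), "length")
  expect_error(weighted_graph(nf, rbind(c(0, 1), c(1, 0)), c(1, -1)), "> 0")
  expect_error(weighted_graph(nf, rbind(c(0, 1)), c(1)), "both directions")
  g <- weighted_graph(nf, matrix(integer(0), 0, 2), numeric(0))
  expect_equal(nrow(g$edges), 0L)
})

test_that("interaction_table and the pKd converter validate input", {
  expect_error(interaction_table("d", "p", Inf), "finite")
  expect_equal(kd_to_pkd(1), 9)       # 1 nM -> pKd 9
  expect_equal(kd_to_pkd(1000), 6)    # 1 uM -> pKd 6
  expect_error(kd_to_pkd(-1), "positive")
})
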