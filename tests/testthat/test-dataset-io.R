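# The pKd transform, labeling, negative-sample matrix and splits.

test_that("kd_to_pkd matches the closed form and its boundary values", {
  expect_identical(kd_to_pkd(0), 10)
  expect_equal(kd_to_pkd(10000), -log10(10000e-9 + 1e-10))
  expect_equal(kd_to_pkd(50), -log10(50e-9 + 1e-10))
  expect_equal(kd_to_pkd(10000), 4.9999957, tolerance = 1e-7)
  expect_equal(kd_to_pkd(50), 7.3001624, tolerance = 1e-7)
  # strictly decreasing, always positive
  grid <- seq(0, 10000, length.out = 5000)
  pk <- kd_to_pkd(grid)
  expect_true(all(diff(pk) < 0))
  expect_true(all(pk > 0) && all(pk <= 10))
  expect_error(kd_to_pkd(-1), "finite")
  expect_error(kd_to_pkd(Inf), "finite")
})

test_that("pkd_to_kd inverts kd_to_pkd", {
  kd <- c(0, 0.3, 50, 777, 10000)
  expect_equal(pkd_to_kd(kd_to_pkd(kd)), kd, tolerance = 1e-9)
})

test_that("labeling is positive iff kd <= boundary, matching the pKd order", {
  expect_identical(label_pair(50, 50), "positive")
  expect_identical(label_pair(50 + 1e-9, 50), "negative")
  expect_identical(label_pair(10, 50), "positive")
  # order isomorphism under the transform
  kd <- runif(200, 0, 10000)
  b <- 50
  expect_identical(label_pair(kd, b) == "positive",
                   kd_to_pkd(kd) >= kd_to_pkd(b))
})

test_that("negative matrix sampling respects column admissibility", {
  base <- toy_affinity_matrix(matrix(c(10, 100,
                                       10, 100,
                                       10, 100), nrow = 2))
  nm <- build_negative_matrix(base, boundary = 50, seed = 3)
  # drug 2 (Kd 100) is the unique admissible negative in every column
  expect_true(all(nm == base$drug_smiles[2]))

  base3 <- toy_affinity_matrix(matrix(c(10, 60, 70), nrow = 3))
  nm1 <- build_negative_matrix(base3, boundary = 50, seed = 9)
  expect_true(all(nm1[1, ] %in% base3$drug_smiles[2:3]))
  expect_identical(nm1, build_negative_matrix(base3, boundary = 50, seed = 9))

  # negatives never reference a drug labeled positive for that column
  spec <- synthetic_spec(8, 5, seed = 21)
  ds <- generate_extended_dataset(spec)
  for (j in seq_along(ds$base$protein_ids)) {
    pos_smiles <- ds$base$drug_smiles[ds$base$kd[, j] <= ds$boundary]
    expect_false(any(ds$negative_smiles[, j] %in% pos_smiles))
  }
})

test_that("an all-positive column triggers the cross-column fallback", {
  base <- toy_affinity_matrix(matrix(c(10, 20,      # column 1: all positive
                                       10, 100), nrow = 2))
  expect_warning(nm <- build_negative_matrix(base, boundary = 50, seed = 1),
                 "no negative")
  expect_true(all(nm[, 1] == base$drug_smiles[2]))  # pooled negatives
  # no negatives anywhere -> error
  allpos <- toy_affinity_matrix(matrix(c(10, 20), nrow = 2))
  expect_error(suppressWarnings(build_negative_matrix(allpos, boundary = 50)),
               "no drug")
})

test_that("split sizes follow floor-with-remainder-to-train and partition the input", {
  recs <- data.frame(x = seq_len(10))
  s <- split_records(recs, seed = 1)
  expect_identical(vapply(s, nrow, 1L),
                   c(train = 7L, validation = 1L, test = 2L))
  # Davis-sized arithmetic without materializing records
  n <- 30056
  expect_identical(c(n - floor(0.1 * n) - floor(0.2 * n), floor(0.1 * n), floor(0.2 * n)),
                   c(21040, 3005, 6011))
  for (n in c(3, 17, 101)) {
    recs <- data.frame(x = seq_len(n))
    s <- split_records(recs, seed = n)
    ids <- sort(unlist(lapply(s, `[[`, "x"), use.names = FALSE))
    expect_identical(ids, seq_len(n))          # disjoint cover
    expect_identical(s, split_records(recs, seed = n))  # seeded determinism
  }
  expect_error(split_records(data.frame(x = 1:2)), "at least 3")
})

test_that("round-trip through the four-file layout preserves the dataset", {
  spec <- synthetic_spec(6, 4, seed = 11)
  ds <- generate_extended_dataset(spec)
  dir <- withr::local_tempdir()
  write_extended_dataset(ds, dir, seed = 11)
  back <- read_extended_dataset(
    file.path(dir, "drugs.tsv"), file.path(dir, "proteins.fasta"),
    file.path(dir, "affinities.tsv"), file.path(dir, "negatives.tsv")
  )
  expect_identical(back$base$drug_ids, ds$base$drug_ids)
  expect_identical(back$base$drug_smiles, ds$base$drug_smiles)
  expect_identical(back$base$protein_ids, ds$base$protein_ids)
  expect_identical(back$base$protein_seqs, ds$base$protein_seqs)
  expect_equal(back$base$kd, ds$base$kd, tolerance = 1e-12)
  expect_identical(as.vector(back$negative_smiles), as.vector(ds$negative_smiles))
  expect_identical(back$labels, ds$labels)
})

test_that("shape mismatches and malformed SMILES are rejected with context", {
  spec <- synthetic_spec(2, 3, seed = 2)
  ds <- generate_extended_dataset(spec)
  dir <- withr::local_tempdir()
  write_extended_dataset(ds, dir)
  # truncate the negatives file to 2 columns
  nm <- utils::read.delim(file.path(dir, "negatives.tsv"), check.names = FALSE,
                          colClasses = "character")
  utils::write.table(nm[, 1:3], file.path(dir, "negatives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_extended_dataset(file.path(dir, "drugs.tsv"),
                          file.path(dir, "proteins.fasta"),
                          file.path(dir, "affinities.tsv"),
                          file.path(dir, "negatives.tsv")),
    "negative-sample matrix"
  )
  # corrupt one drug SMILES
  drugs <- utils::read.delim(file.path(dir, "drugs.tsv"), colClasses = "character")
  drugs$smiles[2] <- "C("
  utils::write.table(drugs, file.path(dir, "drugs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_extended_dataset(file.path(dir, "drugs.tsv"),
                          file.path(dir, "proteins.fasta"),
                          file.path(dir, "affinities.tsv")),
    "row 2"
  )
})

test_that("a 1x1 dataset yields a single record", {
  base <- affinity_matrix("d1", "CCO", "p1", "MKV", matrix(10))
  ds <- suppressWarnings(extend_dataset(base, negative_smiles = matrix("CCN")))
  expect_identical(nrow(as_affinity_records(ds)), 1L)
})
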