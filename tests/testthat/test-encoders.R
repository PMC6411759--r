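test_that("KSAAP has fixed dimension and matches hand-derived compositions", {
  v <- encode_ksaap(pad_peptide("ACDE"))
  expect_length(v, 2000L)
  ## k = 1 pairs of ACDE: (A,D) and (C,E), each half of the two valid pairs
  k1 <- v[grep("^k1_", names(v))]
  expect_equal(unname(v["k1_AD"]), 0.5)
  expect_equal(unname(v["k1_CE"]), 0.5)
  expect_equal(sum(k1), 1)
  expect_equal(sum(k1 > 0), 2L)

  ## homopolymer: pair (A,A) has composition 1 at every spacing
  h <- encode_ksaap(pad_peptide("AAAAAAA"))
  expect_equal(unname(h[paste0("k", 0:4, "_AA")]), rep(1, 5))
  expect_equal(sum(h), 5)
})

test_that("KSAAP matches the brute-force pair enumeration oracle", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_peptide()
    expect_equal(unname(encode_ksaap(pad_peptide(s))),
                 brute_ksaap(pad_peptide(s)))
  }
})

test_that("KSAAP is invariant to the amount of gap padding and normalized", {
  set.seed(55)
  for (i in 1:30) {
    s <- random_peptide()
    a <- encode_ksaap(pad_peptide(s, 25))
    b <- encode_ksaap(pad_peptide(s, 40))
    expect_equal(unname(a), unname(b))
    expect_true(all(a >= 0))
    for (k in 0:4) {
      block <- a[grep(paste0("^k", k, "_"), names(a))]
      if (nchar(s) - k - 1 > 0) expect_equal(sum(block), 1)
      else expect_equal(sum(block), 0)
    }
  }
  expect_error(encode_ksaap(pad_peptide("ACDE"), k_max = 24), "exceeds")
})

test_that("AAindex encoding is position-major with zeroed gap positions", {
  tab <- default_aaindex()
  v <- encode_aaindex(pad_peptide("KLLR"), tab)
  expect_length(v, 200L)
  ## positions 5..25 are padding: all channels zero
  expect_true(all(v[-(1:32)] == 0))
  expect_equal(unname(v[1:8]), unname(tab[, "K"]))
  expect_equal(unname(v[9:16]), unname(tab[, "L"]))

  ## toy single-index table: direct lookup
  toy <- matrix(0, 1, 20, dimnames = list("HI1", aa_alphabet()))
  toy["HI1", "A"] <- 0.5
  tv <- encode_aaindex(pad_peptide("A"), toy)
  expect_length(tv, 25L)
  expect_equal(unname(tv[1]), 0.5)
  expect_true(all(tv[-1] == 0))
})

test_that("default index table is 8 x 20, scaled rows span [0, 1]", {
  tab <- default_aaindex()
  expect_equal(dim(tab), c(8L, 20L))
  expect_equal(colnames(tab), aa_alphabet())
  expect_equal(unname(apply(tab, 1, min)), rep(0, 8))
  expect_equal(unname(apply(tab, 1, max)), rep(1, 8))
  raw <- default_aaindex(scale = FALSE)
  expect_equal(unname(raw["hydropathy", "I"]), 4.5)  # most hydrophobic
})

test_that("index tables round-trip through TSV", {
  tab <- default_aaindex(scale = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(index = rownames(tab), tab, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_aaindex_table(path, scale = FALSE)
  expect_equal(back, tab, ignore_attr = TRUE)
})

test_that("PSI-BLAST PSSM files parse to the hand-checked matrix", {
  path <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    "             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V",
    "    1 K     -1   2   0   1  -3   1   1  -2  -1  -3  -3   5  -2  -3  -1   0  -1  -3  -2  -3",
    "    2 L     -2  -2  -4  -4  -1  -2  -3  -4  -3   2   4  -3   2   0  -3  -3  -1  -2  -1   1",
    "    3 R     -2   6  -1  -2  -4   1   0  -3   0  -3  -2   2  -2  -3  -2  -1  -1  -3  -2  -3",
    ""), path)
  prof <- read_pssm(path)
  expect_s3_class(prof, "pssm_profile")
  expect_equal(prof$L, 3L)
  expect_equal(dim(prof$matrix), c(3L, 20L))
  ## hand-parsed spot values, re-ordered to alphabetical columns
  expect_equal(unname(prof$matrix[1, "K"]), 5)
  expect_equal(unname(prof$matrix[1, "A"]), -1)
  expect_equal(unname(prof$matrix[2, "L"]), 4)
  expect_equal(unname(prof$matrix[3, "R"]), 6)
  expect_equal(unname(prof$matrix[3, "V"]), -3)
})

test_that("malformed PSSM files are rejected", {
  short_row <- withr::local_tempfile()
  writeLines(c("header", "    1 K   -1   2   0"), short_row)
  expect_error(read_pssm(short_row), "score columns")
  headers_only <- withr::local_tempfile()
  writeLines(c("Last position-specific scoring matrix", "  A R N"),
             headers_only)
  expect_error(read_pssm(headers_only), "no PSSM matrix rows")
})

test_that("PSSM write/read round-trips integer profiles", {
  set.seed(9)
  s <- random_peptide(12)
  prof <- simulate_pssm(s, concentration = 2, seed = 3, id = "rt")
  path <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(prof, path, sequence = s)
  back <- read_pssm(path, id = "rt")
  expect_equal(back$matrix, prof$matrix)
})

test_that("pKSAAP has dimension 2000 and matches the brute-force oracle", {
  set.seed(77)
  for (i in 1:40) {
    s <- random_peptide(sample(4:20, 1))
    prof <- simulate_pssm(s, concentration = 2, seed = i, id = "x")
    v <- encode_pksaap(prof)
    expect_length(v, 2000L)
    expect_equal(unname(v), brute_pksaap(plogis(prof$matrix)))
  }
})

test_that("one-hot pKSAAP reproduces the sequence KSAAP exactly", {
  set.seed(33)
  for (i in 1:30) {
    s <- random_peptide()
    expect_equal(unname(encode_pksaap(onehot_profile(s))),
                 unname(encode_ksaap(pad_peptide(s))))
  }
  ## 2-row profile, k = 0: feature (a, b) = M[1, a] * M[2, b]
  prof <- simulate_pssm("KL", concentration = 1, seed = 2, id = "two")
  M <- plogis(prof$matrix)
  v <- encode_pksaap(prof)
  expect_equal(matrix(v[1:400], 20, 20, byrow = TRUE), M[1, ] %o% M[2, ],
               ignore_attr = TRUE)
  expect_true(all(v[401:2000] == 0))  # no valid pairs at k >= 1
})

test_that("structural encodings expose the right channels and padding", {
  set.seed(4)
  sp <- simulate_structural(random_peptide(10), "SPIDER2", seed = 1)
  v <- encode_structural(sp)
  expect_length(v, 200L)
  expect_true(all(v[names(v)[grep("_phi|_psi|_theta|_tau", names(v))]] >= -1))
  expect_true(all(abs(v[grep("_phi$", names(v))]) <= 1))
  p2 <- simulate_structural(random_peptide(4), "PEP2D", seed = 2)
  w <- encode_structural(p2)
  expect_length(w, 75L)
  ## positions 5..25 zero-filled
  expect_true(all(w[-(1:12)] == 0))
  ## angle rescaling: raw phi / 180
  expect_equal(unname(v[grep("^p01_phi$", names(v))]),
               as.data.frame(sp)$phi[1] / 180)
})

test_that("structural tables validate flavor, probabilities, and row count", {
  bad <- data.frame(helix = c(0.5, 0.2), sheet = c(0.2, 0.2), coil = c(0.2, 0.6))
  expect_error(structural_table(bad, "PEP2D"), "sum to 1")
  expect_error(structural_table(data.frame(ASA = 1), "SPIDER2"), "missing column")
  long <- simulate_structural(strrep("A", 25), "PEP2D", seed = 5)
  over <- structural_table(rbind(as.data.frame(long), as.data.frame(long)[1:3, ]),
                           "PEP2D")
  expect_warning(v <- encode_structural(over), "truncated")
  expect_length(v, 75L)
  ## TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(long), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_structural_table(path, "PEP2D")
  expect_equal(as.data.frame(back), as.data.frame(long), tolerance = 1e-12)
})

test_that("encoders are deterministic and produce finite values", {
  set.seed(12)
  ds <- tiny_dataset(6, seed = 12)
  x1 <- encode_dataset(ds, "KSAAP")
  x2 <- encode_dataset(ds, "KSAAP")
  expect_identical(x1, x2)
  a1 <- encode_dataset(ds, "AAindex")
  expect_identical(a1, encode_dataset(ds, "AAindex"))
  expect_true(all(is.finite(x1)), all(is.finite(a1)))
  expect_equal(dim(x1), c(12L, 2000L))
  expect_equal(dim(a1), c(12L, 200L))
  ## pKSAAP without profiles falls back to one-hot with a message
  expect_message(pk <- encode_dataset(ds, "pKSAAP"), "one-hot")
  expect_equal(unname(pk), unname(encode_dataset(ds, "KSAAP")))
})
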