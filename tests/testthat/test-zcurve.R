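test_that("phase decomposition follows the 1-based every-third-base rule", {
  pd <- phase_decompose("ACGTACGTA")
  expect_identical(pd$s0, "ACGTACGTA")
  expect_identical(pd$s1, "ATG")
  expect_identical(pd$s2, "CAT")
  expect_identical(pd$s3, "GCA")

  expect_identical(phase_decompose("A")[c("s1", "s2", "s3")],
                   list(s1 = "A", s2 = "", s3 = ""))
  expect_identical(phase_decompose("AAAAAA")[c("s1", "s2", "s3")],
                   list(s1 = "AA", s2 = "AA", s3 = "AA"))

  # lengths partition and interleaving reconstructs the original
  set.seed(41)
  for (seq in random_dna(20, 1L, 50L)) {
    pd <- phase_decompose(seq)
    expect_identical(sum(nchar(c(pd$s1, pd$s2, pd$s3))), nchar(seq))
    expect_identical(pd$s1, oracle_phase(seq, 1L))
    expect_identical(pd$s2, oracle_phase(seq, 2L))
    expect_identical(pd$s3, oracle_phase(seq, 3L))
  }
  expect_error(phase_decompose(""), "empty")
})

test_that("sequence validation uppercases and rejects non-ACGT symbols", {
  expect_identical(validate_dna("acgt"), "ACGT")
  expect_error(validate_dna("ACGNT"), "non-ACGT")
  expect_error(validate_dna("ACG-T"), "non-ACGT")
})

test_that("k-mer counting matches brute-force window enumeration", {
  expect_identical(count_kmers("AACG", 1L)[c("A", "C", "G", "T")],
                   c(A = 2L, C = 1L, G = 1L, T = 0L))
  expect_identical(count_kmers("AAAA", 2L)[["AA"]], 3L)
  expect_identical(sum(count_kmers("AC", 3L)), 0L)
  expect_error(count_kmers("ACGT", 4L), "must be 1, 2 or 3")

  set.seed(42)
  for (seq in random_dna(10)) {
    for (k in 1:3) {
      counts <- count_kmers(seq, k)
      expect_identical(sum(counts), max(0L, nchar(seq) - k + 1L))
      for (word in sample(names(counts), min(5L, length(counts)))) {
        expect_identical(counts[[word]], oracle_count_word(seq, word))
      }
    }
  }
})

test_that("mononucleotide Z coordinates match the base-class contrasts", {
  expect_equal(mono_z("ACGT"), c(x = 0, y = 0, z = 0))
  expect_equal(mono_z("AAAA"), c(x = 1, y = 1, z = 1))
  expect_equal(mono_z("AACG", normalize = FALSE), c(x = 2, y = 2, z = 0))

  # identities: x + y = 2(A - T), x - y = 2(G - C)
  set.seed(43)
  for (seq in random_dna(30)) {
    v <- mono_z(seq, normalize = FALSE)
    counts <- count_kmers(seq, 1L)
    expect_identical(v[["x"]] + v[["y"]], 2 * (counts[["A"]] - counts[["T"]]))
    expect_identical(v[["x"]] - v[["y"]], 2 * (counts[["G"]] - counts[["C"]]))
    # complement antisymmetry: (x, y, z) -> (-x, -y, z)
    w <- mono_z(complement_seq(seq), normalize = FALSE)
    expect_equal(unname(w), unname(c(-v["x"], -v["y"], v["z"])))
  }
})

test_that("di/trinucleotide Z parameters match the context contrasts", {
  v <- kmer_z("AAAA", 2L)
  expect_equal(v[["A.x"]], 1)
  expect_equal(v[["A.y"]], 1)
  expect_equal(v[["A.z"]], 1)
  expect_equal(unname(v[4:12]), rep(0, 9))

  v <- kmer_z("ACGT", 2L, normalize = FALSE)
  expect_equal(unname(v), c(-1, 1, -1, 1, -1, -1, -1, -1, 1, 0, 0, 0))

  expect_length(kmer_z("ACGTACGTT", 3L), 48L)
  expect_warning(z <- kmer_z("AC", 3L), "shorter than k")
  expect_equal(unname(z), rep(0, 48))
})

test_that("encoding dimensions reproduce the seven admissible Z-spaces", {
  seq <- strrep("ACGTACGGT", 3L)  # 27 bp, enough for every family
  configs <- list(
    list(zspace(TRUE, FALSE, FALSE), 12L),
    list(zspace(FALSE, TRUE, FALSE), 48L),
    list(zspace(TRUE, TRUE, FALSE), 60L),
    list(zspace(FALSE, FALSE, TRUE), 192L),
    list(zspace(TRUE, FALSE, TRUE), 204L),
    list(zspace(FALSE, TRUE, TRUE), 240L),
    list(zspace(TRUE, TRUE, TRUE), 252L)
  )
  for (cfg in configs) {
    expect_identical(zspace_dim(cfg[[1]]), cfg[[2]])
    expect_length(encode_zcurve(seq, cfg[[1]]), cfg[[2]])
    expect_length(zspace_component_names(cfg[[1]]), cfg[[2]])
  }
  expect_error(zspace(FALSE, FALSE, FALSE), "at least one")
})

test_that("encoding equals the brute-force oracle on random sequences", {
  set.seed(44)
  zc <- zspace()
  for (seq in random_dna(40, 30L, 400L)) {
    expect_equal(unname(encode_zcurve(seq, zc)),
                 oracle_encode(seq), tolerance = 1e-12)
  }
  # raw counts too
  zc_raw <- zspace(normalize = FALSE)
  for (seq in random_dna(10, 30L, 100L)) {
    expect_equal(unname(encode_zcurve(seq, zc_raw)),
                 oracle_encode(seq, normalize = FALSE))
  }
})

test_that("encoding is length-invariant and bounded when normalized", {
  zc <- zspace()
  v1 <- encode_zcurve(paste(rep("ACGGT", 60), collapse = ""), zc)   # 300 bp
  v2 <- encode_zcurve(paste(rep("ACGGT", 600), collapse = ""), zc)  # 3000 bp
  expect_identical(length(v1), length(v2))

  set.seed(45)
  for (seq in random_dna(20, 9L, 2000L)) {
    v <- encode_zcurve(seq, zc)
    expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
  }
  # homopolymers attain the bounds
  expect_equal(max(encode_zcurve(strrep("A", 30))), 1)
  expect_equal(min(encode_zcurve(strrep("G", 30))), -1)
})

test_that("too-short sequences are rejected with the family named", {
  expect_error(encode_zcurve("ACGTAC", zspace()), "trinucleotide")
  expect_error(encode_zcurve("AC", zspace(di = FALSE, tri = FALSE)),
               "mononucleotide")
  # 9 bp is the minimum for the trinucleotide family
  expect_length(encode_zcurve("ACGTACGTA", zspace()), 252L)
})

test_that("batch encoding preserves order, shape and reports offender ids", {
  set.seed(46)
  tbl <- tibble::tibble(id = paste0("s", 1:10),
                        seq = random_dna(10, 300L, 300L))
  enc <- encode_sequences(tbl, zspace())
  expect_identical(dim(z_matrix(enc)), c(10L, 252L))
  expect_identical(enc$id, tbl$id)
  expect_equal(unname(z_matrix(enc)[4, ]),
               unname(encode_zcurve(tbl$seq[4], zspace())))

  empty <- encode_sequences(tibble::tibble(id = character(), seq = character()))
  expect_identical(nrow(empty), 0L)
  expect_identical(ncol(z_matrix(empty)), 252L)

  bad <- dplyr::bind_rows(tbl, tibble::tibble(id = "tiny", seq = "AC"))
  expect_error(encode_sequences(bad, zspace()), "tiny")
})

test_that("encodings round-trip through the TSV writer", {
  tbl <- tibble::tibble(id = c("a", "b"),
                        seq = c(strrep("ACGGT", 20), strrep("TTGCA", 30)))
  enc <- encode_sequences(tbl, zspace(tri = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_encoding_tsv(enc, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_identical(names(back), names(enc))
  expect_equal(as.matrix(back[-1]), z_matrix(enc), ignore_attr = TRUE)
})
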