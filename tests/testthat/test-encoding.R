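all_x_window <- paste0(strrep("X", 10), "C", strrep("X", 10))
poly_a_window <- paste0(strrep("A", 10), "C", strrep("A", 10))

test_that("binary encoding is one-hot over the fixed 21-letter alphabet", {
  v <- encode_be(poly_a_window)
  expect_length(v, 420L)
  # alanine is the first alphabet slot
  expect_equal(unname(v[1:21]), c(1, rep(0, 20)))
  # every positional sub-vector sums to exactly 1
  sums <- colSums(matrix(v, nrow = 21))
  expect_equal(unname(sums), rep(1, 20))
  expect_equal(sum(v), 20)
})

test_that("X residues occupy the 21st one-hot slot", {
  v <- encode_be(all_x_window)
  m <- matrix(v, nrow = 21)
  expect_equal(unname(m[21, ]), rep(1, 20))
  expect_equal(sum(m[1:20, ]), 0)
})

test_that("malformed windows are rejected by the encoders", {
  expect_error(encode_be("ACDC"), "odd length")
  expect_error(encode_be(paste0(strrep("A", 10), "D", strrep("A", 10))),
               "central residue")
  expect_error(encode_be(paste0(strrep("A", 10), "C", strrep("Z", 10))),
               "alphabet")
})

test_that("AAindex encoding is a position-major property profile", {
  tab <- aa_property_table()
  expect_equal(unname(encode_aaindex(all_x_window, tab)), rep(0, 280))
  v <- encode_aaindex(poly_a_window, tab)
  expect_length(v, 280L)
  expect_equal(unname(v), rep(unname(tab$aaindex14["A", ]), 20))
})

test_that("HQI encoding places the 8 index values at the probe position", {
  tab <- aa_property_table()
  expect_equal(unname(encode_hqi(all_x_window, tab)), rep(0, 160))
  # single non-X probe residue at flank position 3
  fl <- rep("X", 20)
  fl[3] <- "W"
  w <- paste0(paste(fl[1:10], collapse = ""), "C",
              paste(fl[11:20], collapse = ""))
  v <- encode_hqi(w, tab)
  expect_length(v, 160L)
  expect_equal(unname(v[17:24]), unname(tab$hqi8["W", ]))
  expect_equal(sum(v[-(17:24)] != 0), 0L)
})

test_that("property tables cover the alphabet, scale to [0,1], zero X", {
  tab <- aa_property_table()
  for (m in list(tab$aaindex14, tab$hqi8)) {
    expect_setequal(rownames(m), AA21_T)
    expect_true(all(is.finite(m)))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(m["X", ]), rep(0, ncol(m)))
    # min-max scaling: each property attains both 0 and 1 on canonical rows
    expect_equal(unname(apply(m[AA20_T, ], 2, min)), rep(0, ncol(m)))
    expect_equal(unname(apply(m[AA20_T, ], 2, max)), rep(1, ncol(m)))
  }
  raw <- aa_property_table(scale = FALSE)
  expect_gt(max(raw$aaindex14[, "molecular_weight"]), 1)
})

test_that("KSAAP counts adjacent and k-spaced pairs over the full window", {
  v <- encode_ksaap(poly_a_window, k_values = 0)
  expect_equal(unname(v[c("KSAAP.k0.AA", "KSAAP.k0.AC", "KSAAP.k0.CA")]),
               c(18, 1, 1))
  expect_equal(sum(v), 20)
  full <- encode_ksaap(poly_a_window)
  expect_length(full, 1323L)
  for (k in 0:2) {
    block <- full[grep(paste0("^KSAAP\\.k", k, "\\."), names(full))]
    expect_equal(sum(block), 20 - k)
  }
})

test_that("KSAAP agrees with a brute-force pair-enumeration oracle", {
  set.seed(91)
  for (i in 1:200) {
    w <- random_window()
    expect_equal(unname(encode_ksaap(w)), brute_force_ksaap(w))
  }
})

test_that("KSAAP k values are validated", {
  expect_error(encode_ksaap(poly_a_window, k_values = integer(0)),
               "non-empty")
  expect_error(encode_ksaap(poly_a_window, k_values = c(1, 0)),
               "increasing")
  expect_error(encode_ksaap(poly_a_window, k_values = 20), "no pairs")
})

test_that("amino-acid composition follows F_a = R_a / flank length", {
  v <- encode_aac(poly_a_window)
  expect_equal(unname(v["AAC.A"]), 1)
  expect_equal(sum(v), 1)

  w <- paste0(strrep("A", 10), "C", strrep("G", 10))
  v <- encode_aac(w)
  expect_equal(unname(v[c("AAC.A", "AAC.G")]), c(0.5, 0.5))

  # X counts toward the denominator but not any canonical residue
  w <- paste0(strrep("X", 10), "C", strrep("A", 10))
  v <- encode_aac(w)
  expect_equal(unname(v["AAC.A"]), 0.5)
  expect_equal(sum(v), 0.5)
})

test_that("canonical composition plus X fraction is exactly one", {
  set.seed(17)
  for (i in 1:50) {
    w <- random_window()
    fl <- strsplit(w, "")[[1]][-11]
    expect_equal(sum(encode_aac(w)) + sum(fl == "X") / 20, 1)
  }
})

test_that("assembled vectors concatenate blocks in fixed order", {
  v <- assemble_features(poly_a_window)
  expect_length(v, 2203L)
  map <- attr(v, "block_map")
  expect_equal(map$block, c("BE", "AAindex", "KSAAP", "AAC", "HQI"))
  expect_equal(map$length, c(420L, 280L, 1323L, 20L, 160L))
  # contiguous, non-overlapping offsets
  expect_equal(map$start, cumsum(c(1L, map$length[-5])))
  expect_equal(sum(map$length), 2203L)

  aac_only <- assemble_features(poly_a_window, blocks = "AAC")
  expect_length(aac_only, 20L)
  expect_equal(attr(aac_only, "block_map")$start, 1L)
  expect_error(assemble_features(poly_a_window, blocks = character(0)),
               "at least one")
  expect_error(assemble_features(poly_a_window, blocks = "PSSM"), "unknown")
})

test_that("block order in the output is fixed regardless of request order", {
  a <- assemble_features(poly_a_window, blocks = c("HQI", "BE"))
  b <- assemble_features(poly_a_window, blocks = c("BE", "HQI"))
  expect_identical(a, b)
  expect_equal(attr(a, "block_map")$block, c("BE", "HQI"))
})

test_that("encoding is deterministic and permutation-sensitivity is per block", {
  set.seed(23)
  w <- random_window()
  expect_identical(assemble_features(w), assemble_features(w))

  fl <- strsplit(poly_a_window, "")[[1]][-11]
  fl[1] <- "W"; fl[20] <- "D"
  mk <- function(f) paste0(paste(f[1:10], collapse = ""), "C",
                           paste(f[11:20], collapse = ""))
  w1 <- mk(fl)
  w2 <- mk(rev(fl))
  expect_equal(encode_aac(w1), encode_aac(w2))
  expect_false(isTRUE(all.equal(encode_be(w1), encode_be(w2))))
  expect_false(isTRUE(all.equal(encode_aaindex(w1), encode_aaindex(w2))))
  expect_false(isTRUE(all.equal(encode_hqi(w1), encode_hqi(w2))))
  expect_false(isTRUE(all.equal(encode_ksaap(w1), encode_ksaap(w2))))
})

test_that("encode_fragments stacks rows and feature_block subsets them", {
  frags <- generate_fragments(3, 3, seed = 5)
  x <- encode_fragments(frags)
  expect_equal(dim(x), c(6L, 2203L))
  expect_equal(unname(x[2, ]),
               as.numeric(assemble_features(frags$window[2])))
  aac <- feature_block(x, "AAC")
  expect_equal(ncol(aac), 20L)
  expect_equal(unname(aac[1, ]), unname(encode_aac(frags$window[1])))
  two <- feature_block(x, c("BE", "HQI"))
  expect_equal(attr(two, "block_map")$start, c(1L, 421L))
  expect_error(feature_block(x[, 1:5], "AAC"), "block_map")
})
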