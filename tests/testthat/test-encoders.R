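test_that("AAC-PSSM averages profile rows (20 components)", {
  prof <- random_profile(5L, 21L)
  fv <- encode_aac_pssm(prof)
  expect_identical(fv$dim, 20L)
  expect_equal(unname(fv$values), oracle_aac_pssm(prof$norm),
               tolerance = 1e-12)

  const <- manual_profile(matrix(0.5, 7, 20))
  expect_true(all(encode_aac_pssm(const)$values == 0.5))

  # invariant under any permutation of profile rows
  perm <- prof
  perm$norm <- prof$norm[c(3, 1, 5, 2, 4), ]
  expect_equal(encode_aac_pssm(perm)$values, fv$values)
})

test_that("PSSM composition groups rows by residue (400 components)", {
  # homopolymer: only the A-group row is nonzero and equals colSums / L
  prof <- random_profile(5L, 8L)
  rec <- protein_record("homo", "AAAAA")
  prof$sequence <- rec$sequence
  fv <- encode_pssm_composition(prof, rec)
  expect_identical(fv$dim, 400L)
  expect_equal(unname(fv$values[1:20]), unname(colSums(prof$norm) / 5),
               tolerance = 1e-12)
  expect_true(all(fv$values[21:400] == 0))

  rec8 <- random_record(8L, 13L)
  prof8 <- random_profile(8L, 14L)
  prof8$sequence <- rec8$sequence
  expect_equal(unname(encode_pssm_composition(prof8, rec8)$values),
               oracle_pssm_comp(prof8$norm, rec8$sequence),
               tolerance = 1e-12)

  # length mismatch between sequence and profile is an integrity error
  expect_error(encode_pssm_composition(random_profile(6L, 1L),
                                       random_record(5L, 2L)),
               "integrity")
})

test_that("DPC-PSSM captures adjacent-position products (400 components)", {
  prof <- random_profile(7L, 31L)
  fv <- encode_dpc_pssm(prof)
  expect_identical(fv$dim, 400L)
  expect_equal(unname(fv$values), oracle_dpc_pssm(prof$norm),
               tolerance = 1e-12)

  # one-hot rows: row 1 hot at residue a, row 2 hot at b -> y[a, b] = 1 only
  a <- 3L; b <- 17L
  onehot <- matrix(0, 2, 20)
  onehot[1, a] <- 1; onehot[2, b] <- 1
  v <- encode_dpc_pssm(manual_profile(onehot))$values
  expect_equal(unname(v[(a - 1L) * 20L + b]), 1)
  expect_equal(sum(v), 1)

  # constant profile: every entry c^2
  cst <- manual_profile(matrix(0.3, 6, 20))
  expect_equal(unname(encode_dpc_pssm(cst)$values), rep(0.09, 400),
               tolerance = 1e-12)

  # row order matters for this feature
  flipped <- manual_profile(onehot[2:1, ])
  expect_false(isTRUE(all.equal(encode_dpc_pssm(flipped)$values, v)))

  expect_error(encode_dpc_pssm(manual_profile(matrix(0.5, 1, 20))),
               "single-row")
})

test_that("AADP-PSSM is the exact concatenation of AAC-PSSM and DPC-PSSM", {
  prof <- random_profile(6L, 44L)
  fv <- encode_aadp_pssm(prof)
  expect_identical(fv$dim, 420L)
  expect_equal(unname(fv$values[1:20]),
               unname(encode_aac_pssm(prof)$values))
  expect_equal(unname(fv$values[21:420]),
               unname(encode_dpc_pssm(prof)$values))
})

test_that("MEDP combines the difference matrix with its row average (420 components)", {
  prof <- random_profile(9L, 55L)
  fv <- encode_medp(prof)
  expect_identical(fv$dim, 420L)
  expect_equal(unname(fv$values), oracle_medp(prof$norm), tolerance = 1e-12)

  # the EDP block is definitionally the row-average of the EEDP block
  eedp <- matrix(fv$values[1:400], 20, 20, byrow = TRUE)
  expect_equal(unname(fv$values[401:420]), unname(colMeans(eedp)),
               tolerance = 1e-12)

  # constant profile: every interior difference is zero
  cst <- manual_profile(matrix(0.4, 5, 20))
  expect_true(all(encode_medp(cst)$values == 0))

  expect_error(encode_medp(manual_profile(matrix(0.5, 2, 20))), "L >= 3")
})

test_that("AAC counts residue frequencies", {
  expect_equal(unname(encode_aac(protein_record("x", "AAA"))$values),
               c(1, rep(0, 19)))
  v <- encode_aac(protein_record("x", "ACDA"))$values
  expect_equal(unname(v[c("aac.A", "aac.C", "aac.D") |>
                          match(names(v))]), c(0.5, 0.25, 0.25))
  rec <- random_record(30L, 77L)
  chars <- strsplit(rec$sequence, "")[[1L]]
  oracle <- vapply(AA_ALPHABET, function(a) sum(chars == a) / 30, numeric(1))
  expect_equal(unname(encode_aac(rec)$values), unname(oracle),
               tolerance = 1e-12)
  expect_equal(sum(encode_aac(rec)$values), 1, tolerance = 1e-12)
  # noncanonical residues contribute zero
  expect_equal(sum(encode_aac(protein_record("x", "AXA"))$values), 2 / 3,
               tolerance = 1e-12)
})

test_that("DPC counts sliding-window dipeptide frequencies", {
  v <- encode_dpc(protein_record("x", "AC"))$values
  expect_equal(unname(v["dpc.AC"]), 1)
  expect_equal(sum(v), 1)
  v4 <- encode_dpc(protein_record("x", "AAAA"))$values
  expect_equal(unname(v4["dpc.AA"]), 1)

  rec <- random_record(25L, 78L)
  chars <- strsplit(rec$sequence, "")[[1L]]
  oracle <- numeric(400)
  names(oracle) <- paste0("dpc.", rep(AA_ALPHABET, each = 20),
                          rep(AA_ALPHABET, times = 20))
  for (k in 1:24) {
    key <- paste0("dpc.", chars[k], chars[k + 1])
    oracle[key] <- oracle[key] + 1 / 24
  }
  expect_equal(encode_dpc(rec)$values, oracle, tolerance = 1e-12)
  expect_error(encode_dpc(protein_record("x", "A")), "single-residue")
})

test_that("QSOrder follows the quasi-sequence-order formulas for both matrices", {
  rec <- random_record(40L, 91L)
  nlag <- 5L; w <- 0.1
  fv <- encode_qsorder(rec, nlag = nlag, w = w)
  expect_identical(fv$dim, 2L * (20L + nlag))
  expect_identical(encode_qsorder(rec, nlag = 30L)$dim, 100L)

  # direct-summation oracle
  chars <- strsplit(rec$sequence, "")[[1L]]
  f <- vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1))
  oracle_block <- function(d) {
    tau <- numeric(nlag)
    for (l in 1:nlag) {
      for (k in 1:(40 - l)) {
        tau[l] <- tau[l] + d[chars[k], chars[k + l]]^2
      }
    }
    den <- sum(f) + w * sum(tau)
    c(f / den, w * tau / den)
  }
  oracle <- c(oracle_block(physchem_surrogate_matrix()),
              oracle_block(grantham_matrix()))
  expect_equal(unname(fv$values), unname(oracle), tolerance = 1e-12)

  # with no coupling weight the composition block is proportional to AAC
  fv0 <- encode_qsorder(rec, nlag = nlag, w = 0)
  expect_equal(unname(fv0$values[1:20] / sum(fv0$values[1:20])),
               unname(encode_aac(rec)$values), tolerance = 1e-12)

  expect_error(encode_qsorder(random_record(10L, 3L), nlag = 30L),
               "smaller nlag")
})

test_that("PAAC follows the pseudo amino-acid composition recursion", {
  rec <- random_record(40L, 92L)
  lambda <- 5L; w <- 0.05
  fv <- encode_paac(rec, lambda = lambda, w = w)
  expect_identical(fv$dim, 20L + lambda)
  expect_identical(encode_paac(rec, lambda = 30L)$dim, 50L)

  chars <- strsplit(rec$sequence, "")[[1L]]
  scales <- virionpred:::.paac_standardized_scales()
  f <- vapply(AA_ALPHABET, function(a) sum(chars == a) / 40, numeric(1))
  theta <- numeric(lambda)
  for (l in 1:lambda) {
    s <- 0
    for (k in 1:(40 - l)) {
      s <- s + ((scales$hydrophobicity[chars[k]] -
                   scales$hydrophobicity[chars[k + l]])^2 +
                (scales$hydrophilicity[chars[k]] -
                   scales$hydrophilicity[chars[k + l]])^2 +
                (scales$sidechain_mass[chars[k]] -
                   scales$sidechain_mass[chars[k + l]])^2) / 3
    }
    theta[l] <- s / (40 - l)
  }
  den <- sum(f) + w * sum(theta)
  expect_equal(unname(fv$values), unname(c(f / den, w * theta / den)),
               tolerance = 1e-12)

  # zero weight: first 20 entries equal AAC, coupling entries vanish
  fv0 <- encode_paac(rec, lambda = lambda, w = 0)
  expect_equal(unname(fv0$values[1:20]), unname(encode_aac(rec)$values),
               tolerance = 1e-12)
  expect_true(all(fv0$values[21:25] == 0))

  expect_error(encode_paac(random_record(10L, 4L), lambda = 30L), "lambda")
})

test_that("profile-derived feature values stay within the normalized bounds", {
  for (seed in 1:5) {
    prof <- random_profile(10L, seed + 200L)
    expect_true(all(encode_aac_pssm(prof)$values >= 0 &
                      encode_aac_pssm(prof)$values <= 1))
    expect_true(all(encode_dpc_pssm(prof)$values >= 0 &
                      encode_dpc_pssm(prof)$values <= 1))
  }
})

test_that("the feature-table batch path names rows by id and respects encoders", {
  ds <- generate_dataset(synth_spec(n_pos = 2L, n_neg = 3L,
                                    length_range = c(20L, 30L), seed = 5L))
  m <- encode_feature_matrix(ds$records, ds$profiles, "AADP_PSSM")
  expect_identical(dim(m), c(5L, 420L))
  expect_identical(rownames(m),
                   vapply(ds$records, `[[`, character(1), "id"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(m, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_identical(dim(back), c(5L, 421L))
  expect_equal(back[[2L]], unname(m[, 1L]), tolerance = 1e-12)

  # a protein without a profile fails loudly, naming protein and encoder
  expect_error(encode_feature_matrix(ds$records, ds$profiles["pos_001"],
                                     "MEDP"),
               "pos_002.*MEDP")
})
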