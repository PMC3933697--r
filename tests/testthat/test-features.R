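test_that("chemical composition gives class fractions in fixed order", {
  expect_equal(unname(chemical_composition("RK")[1:5]), c(1, 0, 0, 0, 0))
  expect_equal(unname(chemical_composition("PG")[1:5]), c(0, 0, 0, 0, 1))
  # two residues of each class
  expect_equal(unname(chemical_composition("RKDESTAVPG")[1:5]),
               rep(0.2, 5))
  expect_named(chemical_composition("A"),
               c("positive", "negative", "polar", "hydrophobic", "special"))
  expect_error(chemical_composition(""), "empty")
})

test_that("amino-acid composition and occurrence count residues", {
  v <- aa_composition("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(aa_composition(paste(AA, collapse = ""))[AA]),
               rep(0.05, 20))
  o <- aa_occurrence("AAAA")
  expect_equal(unname(o["A"]), 4)
  expect_equal(unname(aa_occurrence("AC")[c("A", "C", "D")]), c(1, 1, 0))
  for (L in c(1, 7, 50)) {
    res <- random_residues(L)
    expect_equal(sum(aa_occurrence(res)), L)
    expect_equal(sum(aa_composition(res)), 1)
  }
  expect_error(aa_composition(""), "empty")
})

test_that("ambiguous residues are dropped with a warning before extraction", {
  expect_warning(s <- idr_sequence("x", "AXAB"), "dropped 2")
  expect_equal(s$length, 2L)
  expect_equal(s$n_dropped, 2L)
  expect_equal(suppressWarnings(unname(aa_composition("AXA")["A"])), 1)
})

test_that("CTD block handles degenerate and single-boundary cases", {
  p <- default_property_partitions()$hydrophobicity
  # homopolymer entirely in group 1 (R is polar under hydrophobicity)
  L <- 6
  v <- ctd_block(strrep("R", L), p)
  expect_equal(unname(v[1:3]), c(1, 0, 0))
  expect_equal(unname(v[4:6]), c(0, 0, 0))
  expect_equal(unname(v[7:11]),
               c(1 / L, ceiling(0.25 * L) / L, ceiling(0.5 * L) / L,
                 ceiling(0.75 * L) / L, 1))
  expect_equal(unname(v[12:21]), rep(0, 10))
  # A(group2) -> D(group1) under hydrophobicity: one 1-2 boundary
  v2 <- ctd_block("AD", p)
  expect_equal(unname(v2[4:6]), c(1, 0, 0))
  # length-1 sequence: transitions are zero, not NaN
  expect_equal(unname(ctd_block("A", p)[4:6]), c(0, 0, 0))
})

test_that("CTD blocks match the enumeration oracle for all five properties", {
  parts <- default_property_partitions()
  set.seed(11)
  for (rep in 1:20) {
    res <- random_residues(30)
    for (nm in names(parts)) {
      expect_equal(unname(ctd_block(res, parts[[nm]], nm)),
                   oracle_ctd(res, parts[[nm]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("a partition that does not cover the alphabet is rejected", {
  bad <- list(c("A"), c("C"), c("D"))
  expect_error(ctd_block("ACD", bad), "partition")
  expect_error(ctd_block("A", list(AA, AA, AA)), "partition")
})

test_that("Dubchak vectors concatenate composition/occurrence with 5 CTD blocks", {
  set.seed(2)
  res <- random_residues(40)
  vc <- dubchak_features(res, "composition")
  vo <- dubchak_features(res, "occurrence")
  expect_length(vc, 125)
  expect_length(vo, 125)
  expect_equal(vc[1:20], aa_composition(res), ignore_attr = TRUE)
  expect_equal(vo[1:20], aa_occurrence(res), ignore_attr = TRUE)
  # remaining 105 entries identical between modes
  expect_equal(unname(vc[21:125]), unname(vo[21:125]))
  expect_error(dubchak_features(res, "composition", partitions = list()),
               "5 property partitions")
})

test_that("sequence bigrams count adjacent pairs over L-1 windows", {
  v <- sequence_bigrams("AA")
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)
  v2 <- sequence_bigrams("ACA")
  expect_equal(unname(v2[c("AC", "CA")]), c(0.5, 0.5))
  expect_warning(z <- sequence_bigrams("A"), "too short")
  expect_equal(sum(z), 0)
  expect_length(z, 400)
})

test_that("alternate bigrams count one-gap pairs over L-2 windows", {
  expect_equal(unname(alternate_bigrams("ACA")["AA"]), 1)
  v <- alternate_bigrams("ACDE")
  expect_equal(unname(v[c("AD", "CE")]), c(0.5, 0.5))
  expect_warning(z <- alternate_bigrams("AC"), "too short")
  expect_equal(sum(z), 0)
})

test_that("bigram families agree with the exhaustive pair-enumeration oracle", {
  set.seed(7)
  for (rep in 1:100) {
    L <- sample(3:200, 1)
    res <- random_residues(L)
    expect_equal(unname(sequence_bigrams(res)), unname(oracle_bigrams(res, 0L)),
                 tolerance = 1e-12)
    expect_equal(unname(alternate_bigrams(res)), unname(oracle_bigrams(res, 1L)),
                 tolerance = 1e-12)
  }
})

test_that("composition features are permutation invariant, bigrams are not", {
  set.seed(5)
  res <- random_residues(60)
  perm <- sample(res)
  expect_equal(chemical_composition(res), chemical_composition(perm))
  expect_equal(aa_composition(res), aa_composition(perm))
  expect_equal(aa_occurrence(res), aa_occurrence(perm))
  # witness pair with equal composition but different adjacency
  expect_false(isTRUE(all.equal(sequence_bigrams("ACC"), sequence_bigrams("CAC"))))
})

test_that("profile bigrams follow the PSSM transition formula", {
  # delta rows: one-hot A then one-hot C
  m <- matrix(0, 2, 20); m[1, 1] <- 1; m[2, 2] <- 1
  v <- profile_bigrams(pssm_matrix("d", m))
  expect_equal(unname(v["AC"]), 1)
  expect_equal(sum(v), 1)
  # uniform rows: every component (L-1)/400
  for (L in c(2, 5, 30)) {
    u <- matrix(1 / 20, L, 20)
    vu <- profile_bigrams(pssm_matrix("u", u))
    expect_equal(unname(vu), rep((L - 1) / 400, 400), tolerance = 1e-12)
  }
})

test_that("profile bigrams of a one-hot PSSM equal scaled sequence bigrams", {
  set.seed(9)
  for (rep in 1:25) {
    L <- sample(2:120, 1)
    res <- random_residues(L)
    expect_equal(unname(profile_bigrams(one_hot_pssm(res))),
                 unname((L - 1) * sequence_bigrams(res)),
                 tolerance = 1e-9)
  }
})

test_that("profile bigrams reject unnormalized rows and warn on 1-row PSSMs", {
  bad <- matrix(0.3, 3, 20)
  expect_error(profile_bigrams(bad), "normalized")
  one <- matrix(1 / 20, 1, 20)
  expect_warning(z <- profile_bigrams(one), "single row")
  expect_equal(sum(z), 0)
})

test_that("the seven families emit their fixed dimensions via feature_matrix", {
  set.seed(3)
  seqs <- lapply(1:4, function(i)
    idr_sequence(paste0("idr", i), random_residues(sample(10:60, 1))))
  pssms <- lapply(seqs, function(s) generate_pssm(s, 20, seed = 1))
  names(pssms) <- vapply(seqs, function(s) s$idr_id, character(1))
  dims <- c(chemical_composition = 5, aa_composition = 20,
            composition_dubchak = 125, occurrence_dubchak = 125,
            sequence_bigrams = 400, alternate_bigrams = 400,
            profile_bigrams = 400)
  for (fam in names(dims)) {
    m <- feature_matrix(seqs, fam, pssms = pssms)
    expect_equal(dim(m), c(4L, unname(dims[fam])))
    expect_equal(rownames(m), names(pssms))
    expect_false(is.null(colnames(m)))
  }
})

test_that("feature_matrix omits and counts IDRs without a PSSM", {
  seqs <- list(idr_sequence("a", "ACDEFACDEF"), idr_sequence("b", "KLMNPKLMNP"))
  pssms <- list(a = generate_pssm("ACDEFACDEF", 20, seed = 1, idr_id = "a"))
  expect_message(m <- feature_matrix(seqs, "profile_bigrams", pssms = pssms),
                 "1 IDR")
  expect_equal(rownames(m), "a")
})
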