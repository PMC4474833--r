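# Dual-isotope peptide chemistry: digestion, masses, envelopes, database
# lookup and MS1 ratio quantification.

test_that("tryptic digestion enumerates peptides and missed cleavages", {
  d0 <- digest("MKAAR", max_missed = 0)
  expect_setequal(d0$sequence, c("MK", "AAR"))
  d1 <- digest("MKAAR", max_missed = 1)
  expect_setequal(d1$sequence, c("MK", "AAR", "MKAAR"))
  expect_equal(d1$missed_cleavages[d1$sequence == "MKAAR"], 1L)
  # proline suppression
  dp <- digest("AKPAR", max_missed = 0)
  expect_setequal(dp$sequence, c("AKPAR"))
  dn <- digest("AKPAR", max_missed = 0, proline_rule = FALSE)
  expect_setequal(dn$sequence, c("AK", "PAR"))
  expect_error(digest("MKXQR"), "unknown residue 'X' at position 3")
})

test_that("digestion matches a brute-force substring oracle", {
  set.seed(101)
  for (rep in 1:5) {
    prot <- random_protein(200)
    for (mm in 0:2) {
      got <- digest(prot, max_missed = mm)
      want <- oracle_digest(prot, max_missed = mm)
      key <- function(d) sort(paste(d$sequence, d$missed_cleavages))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("composition and monoisotopic mass are exact", {
  g <- composition_and_mass("G", carbamidomethyl = FALSE)
  expect_equal(unname(g$composition[c("C", "H", "N", "O")]), c(2, 5, 1, 2))
  expect_equal(g$monoisotopic_mass, 75.03203, tolerance = 1e-7)
  # heavy - light = n_N * per-nitrogen shift, any peptide and mods
  set.seed(7)
  for (i in 1:25) {
    pep <- random_protein(sample(5:25, 1))
    l <- composition_and_mass(pep, label = "N14")
    h <- composition_and_mass(pep, label = "N15")
    expect_equal(h$monoisotopic_mass - l$monoisotopic_mass,
                 l$n_N * 0.9970349, tolerance = 1e-6)
  }
  expect_error(composition_and_mass(""), "non-empty")
  expect_error(composition_and_mass("GAV", oxidized_m = 2), "not methionine")
})

test_that("peptide mass is additive over concatenation", {
  water <- composition_and_mass("G")$monoisotopic_mass -
    composition_and_mass("GG")$monoisotopic_mass +
    composition_and_mass("G")$monoisotopic_mass
  set.seed(11)
  for (lab in c("N14", "N15")) {
    for (i in 1:10) {
      a <- random_protein(sample(3:12, 1))
      b <- random_protein(sample(3:12, 1))
      ma <- composition_and_mass(a, label = lab)$monoisotopic_mass
      mb <- composition_and_mass(b, label = lab)$monoisotopic_mass
      mab <- composition_and_mass(paste0(a, b), label = lab)$monoisotopic_mass
      expect_equal(mab, ma + mb - water, tolerance = 1e-9)
    }
  }
})

test_that("isotope envelopes are normalized with increasing m/z", {
  set.seed(23)
  for (i in 1:20) {
    pep <- random_protein(sample(5:30, 1))
    cm <- composition_and_mass(pep)
    for (lab in c("N14", "N15")) {
      env <- isotope_envelope(cm$composition, lab,
                              charge = sample(1:4, 1))
      expect_equal(attr(env, "total_intensity"), 1, tolerance = 1e-9)
      expect_true(all(diff(env$peaks$mz) > 0))
      expect_true(all(env$peaks$intensity > 0))
    }
  }
  expect_error(isotope_envelope(c(C = 0), "N14"), "empty or invalid")
  expect_error(isotope_envelope(c(C = 2, N = 1), "N14", charge = 0),
               "positive integer")
})

test_that("the 15N envelope shifts by one nitrogen mass unit per nitrogen", {
  set.seed(31)
  for (i in 1:10) {
    pep <- random_protein(sample(6:20, 1))
    cm <- composition_and_mass(pep)
    z <- sample(1:3, 1)
    e14 <- isotope_envelope(cm$composition, "N14", z)
    e15 <- isotope_envelope(cm$composition, "N15", z,
                            n15_incorporation = 1.0)
    expect_equal((e15$monoisotopic_mz - e14$monoisotopic_mz) * z,
                 cm$n_N * n15_mass_shift(), tolerance = 1e-9)
    # at full incorporation the lightest heavy peak sits at the shifted mono
    expect_equal(min(e15$peaks$mz), e15$monoisotopic_mz, tolerance = 1e-9)
  }
})

test_that("partial incorporation follows the binomial closed form", {
  # 10 nitrogens at 99% incorporation: the all-heavy monoisotopic peak
  # carries binom(10, 0.99) at k = 10 times the all-light C/H/O/S fraction
  comp <- c(C = 40, H = 62, N = 10, O = 12, S = 1)
  env <- isotope_envelope(comp, "N15", charge = 1, n15_incorporation = 0.99,
                          intensity_floor = 0)
  i_mono <- which.min(abs(env$peaks$mz - env$monoisotopic_mz))
  expect_equal(abs(env$peaks$mz[i_mono] - env$monoisotopic_mz), 0,
               tolerance = 1e-9)
  p0_chos <- prod(c(0.9893^40, 0.999885^62, 0.99757^12, 0.9499^1))
  expect_equal(env$peaks$intensity[i_mono], 0.99^10 * p0_chos,
               tolerance = 1e-9)
})

test_that("dual database counts both labels and all mod expansions", {
  prot <- c(pA = "MKACMDMRAAK")
  idx <- build_dual_db(prot, max_missed = 2, max_var_mods = 2)
  pep <- digest(prot[[1]], max_missed = 2)
  expand <- vapply(pep$sequence, function(s) {
    nm <- sum(strsplit(s, "")[[1]] == "M")
    sum(choose(nm, 0:min(2, nm)))
  }, 0)
  expect_equal(nrow(idx$peptides), 2 * sum(expand))
  expect_true(!is.unsorted(idx$peptides$monoisotopic_mass))
  # a 15N record is always heavier than its 14N twin by n_N shifts
  light <- idx$peptides[idx$peptides$label == "N14", ]
  heavy <- idx$peptides[idx$peptides$label == "N15", ]
  key <- paste(light$sequence, light$oxidized_m, light$missed_cleavages)
  keyh <- paste(heavy$sequence, heavy$oxidized_m, heavy$missed_cleavages)
  m <- match(key, keyh)
  expect_equal(heavy$monoisotopic_mass[m] - light$monoisotopic_mass,
               light$n_N * n15_mass_shift(), tolerance = 1e-9)
})

test_that("candidate lookup equals a linear-scan oracle", {
  set.seed(47)
  prots <- setNames(replicate(6, random_protein(80)), paste0("P", 1:6))
  idx <- build_dual_db(prots, max_missed = 1, max_var_mods = 1)
  proton <- 1.007276466621
  # exact hit
  rec <- idx$peptides[10, ]
  z <- 2
  mz <- (rec$monoisotopic_mass + z * proton) / z
  hit <- candidate_lookup(idx, mz, z, tol_ppm = 10)
  expect_true(rec$sequence %in% hit$sequence)
  # displaced by 20 ppm at 10 ppm tolerance: empty
  far <- candidate_lookup(idx, mz * (1 + 20e-6), z, tol_ppm = 10)
  expect_equal(nrow(far), 0L)
  # random queries agree with the oracle
  for (i in 1:300) {
    z <- sample(1:4, 1)
    mass <- runif(1, min(idx$peptides$monoisotopic_mass) - 2,
                  max(idx$peptides$monoisotopic_mass) + 2)
    if (i %% 3 == 0)  # near a true record to exercise boundaries
      mass <- sample(idx$peptides$monoisotopic_mass, 1) *
        (1 + runif(1, -2e-5, 2e-5))
    mz <- (mass + z * proton) / z
    got <- candidate_lookup(idx, mz, z, tol_ppm = 10)
    want <- oracle_lookup(idx$peptides, mz, z, 10)
    expect_setequal(rownames(got), rownames(want))
  }
  expect_error(candidate_lookup(idx, 500, 0), "charge")
})

test_that("MS1 area ratios are quantified exactly on clean scans", {
  for (r in c(1, 10)) {
    sc <- simulate_ms1("FESEVYILSK", ratio = r, noise = 0)
    q <- quantify_ratio(sc, "FESEVYILSK", charge = 2)
    expect_false(q$missing)
    expect_equal(q$ratio, r, tolerance = 1e-12)
  }
})

test_that("label swap inverts the ratio on noiseless scans", {
  env <- isoturn:::.envelope_pair("GGVIPGEYIPAVDK", 2)
  sc <- simulate_ms1("GGVIPGEYIPAVDK", ratio = 2.5, noise = 0)
  fwd <- quantify_ratio(sc, env, charge = 2)$ratio
  swp <- quantify_ratio(sc, list(n14 = env$n15, n15 = env$n14), charge = 2)$ratio
  expect_equal(fwd * swp, 1, tolerance = 1e-12)
})

test_that("an absent heavy envelope yields a missing ratio with reason", {
  env <- isoturn:::.envelope_pair("FESEVYILSK", 2)
  sc <- simulate_ms1("FESEVYILSK", ratio = 1, noise = 0)
  sc14 <- sc[sc$mz < min(env$n15$peaks$mz) - 0.5, ]
  q <- quantify_ratio(sc14, "FESEVYILSK", charge = 2)
  expect_true(q$missing)
  expect_match(q$reason, "denominator below floor")
  expect_true(is.na(q$ratio))
})

test_that("noisy ratios are recovered without bias", {
  set.seed(909)
  vals <- replicate(100, {
    sc <- simulate_ms1("FESEVYILSK", ratio = 2.5, noise = 1e4)
    quantify_ratio(sc, "FESEVYILSK", charge = 2)$ratio
  })
  expect_equal(mean(vals), 2.5, tolerance = 0.05)
})
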