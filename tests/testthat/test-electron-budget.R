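# Independent oracle: electrons transferred to O2 in full combustion.
# Balancing CxHyOz + a O2 -> x CO2 + (y/2) H2O by oxygen atoms gives
# a = x + y/4 - z/2; each O2 accepts 4 electrons, so ne = 4a.
combustion_ne <- function(x, y, z) {
  a <- x + y / 4 - z / 2
  4 * a
}

test_that("electron equivalents match the combustion-balancing oracle", {
  cases <- list(
    c("CH2O2", 1, 2, 2),    # formic
    c("C2H4O2", 2, 4, 2),   # acetic
    c("C3H6O2", 3, 6, 2),   # propionic
    c("C4H8O2", 4, 8, 2),   # butyric / isobutyric
    c("C3H6O3", 3, 6, 3),   # lactic
    c("C4H6O4", 4, 6, 4),   # succinic
    c("C6H12O2", 6, 12, 2)) # 4-methylvaleric
  for (cs in cases) {
    expect_equal(electron_equivalents(cs[1]),
                 combustion_ne(as.numeric(cs[2]), as.numeric(cs[3]),
                               as.numeric(cs[4])),
                 info = cs[1])
  }
  expect_equal(electron_equivalents("C2H4O2"), 8)
  expect_equal(electron_equivalents("C4H8O2"), 20)
  expect_equal(electron_equivalents("C6H12O2"), 32)
})

test_that("non-CHO formulas demand an explicit electron count", {
  expect_error(electron_equivalents("C2H7NO2"), "explicit ne")
  expect_error(electron_equivalents("CH4S"), "explicit ne")
})

test_that("registry carries ne and exact COD = 8 ne for every organic", {
  reg <- compound_registry()
  organics <- reg[!is.na(reg$formula), ]
  expect_equal(nrow(organics), 8)
  for (i in seq_len(nrow(organics))) {
    expect_equal(organics$ne[i], electron_equivalents(organics$formula[i]))
    expect_identical(organics$cod_gO2_per_mol[i], 8 * organics$ne[i])
  }
  expect_equal(compound_ne("hydrogen"), 2)
  expect_equal(compound_ne("thiosulfate"), 8)
  expect_equal(compound_ne("iron(III)"), 1)
  expect_error(compound_ne("unobtainium"), "not in registry")
})

test_that("medium recipe mass converts to molarity", {
  expect_equal(mass_to_mM(1.36, "sodium formate"), 20, tolerance = 1e-3)
})

test_that("coulombic efficiency evaluates the F ne dP V / Q formula", {
  expect_equal(coulombic_efficiency(1, 8, 0.25, 200),
               FARADAY * 8 * 0.001 * 0.25 / 200 * 100)
  expect_equal(coulombic_efficiency(1, 8, 0.25, 200), 96.49,
               tolerance = 1e-4)
  expect_equal(coulombic_efficiency(0, 8, 0.25, 200), 0)
  expect_true(is.na(coulombic_efficiency(1, 8, 0.25, 0)))
  expect_error(coulombic_efficiency(-1, 8, 0.25, 200), "donor-side")
})

test_that("CE is homogeneous of degree zero in (delta, Q)", {
  base <- coulombic_efficiency(0.7, 14, 0.25, 123)
  for (k in c(2, 10, 0.5)) {
    expect_equal(coulombic_efficiency(k * 0.7, 14, 0.25, k * 123), base)
  }
})

test_that("COD decreases convert at 8 g O2 per mol of electrons", {
  # 8 g O2 consumed in total (32 g/L over 0.25 L) -> one faraday
  expect_equal(cod_to_coulombs(32, 0.25)$coulombs_C, FARADAY)
  expect_equal(cod_to_coulombs(0, 0.25)$coulombs_C, 0)
  up <- cod_to_coulombs(-0.5, 0.25)
  expect_equal(up$coulombs_C, 0)
  expect_true(up$carbon_fixation_flag)
})

test_that("organic-acid COD correction is linear and uses 8 ne g/mol", {
  # 1 mM acetate in 0.25 L: 0.25 mmol x 64 g/mol = 0.016 g O2
  expect_equal(organic_acid_cod_correction(1, 8, 0.25), 0.016)
  expect_equal(organic_acid_cod_correction(numeric(0), numeric(0), 0.25), 0)
  d <- c(a = 0.4, b = 1.1); ne <- c(8, 20)
  expect_equal(organic_acid_cod_correction(2 * d, ne, 0.25),
               2 * organic_acid_cod_correction(d, ne, 0.25))
})

test_that("yeast-extract coulombs subtract product COD before converting", {
  cod <- cod_measurement("r", 0.30, 0.28)
  # products worth 0.016 g O2 in 0.25 L: corrected final = 0.28 - 0.064
  q <- yeast_extract_coulombs(cod, 0.016, 0.25)
  expect_equal(q$coulombs_C, (0.30 - (0.28 - 0.064)) * 0.25 / 8 * FARADAY)
  expect_false(q$carbon_fixation_flag)
  # COD rise beyond products -> floored at zero with the fixation flag
  cod_up <- cod_measurement("r", 0.30, 0.45)
  q_up <- yeast_extract_coulombs(cod_up, 0, 0.25)
  expect_equal(q_up$coulombs_C, 0)
  expect_true(q_up$carbon_fixation_flag)
})

test_that("thiosulfate is a donor only with near-stoichiometric sulfate yield", {
  # 1 S2O3^2- -> 2 SO4^2- + 8 e-
  ok <- thiosulfate_donor_check(-10, 20, 0.25)
  expect_true(ok$is_donor)
  expect_equal(ok$q_thiosulfate_C, 0.010 * 0.25 * 8 * FARADAY)

  # sulfate also consumed: acceptor use, not donation
  expect_false(thiosulfate_donor_check(-10, -5, 0.25)$is_donor)
  # ratio 0.45 just below the default 0.5 tolerance band
  expect_false(thiosulfate_donor_check(-10, 9, 0.25)$is_donor)
  # ratio exactly at the band edge is accepted
  expect_true(thiosulfate_donor_check(-10, 10, 0.25)$is_donor)
  # thiosulfate produced: nothing to donate
  expect_false(thiosulfate_donor_check(3, 5, 0.25)$is_donor)
})

test_that("formate coulombs route consumption donor-side only", {
  expect_equal(formate_coulombs(-20, 0.25), 0.020 * 0.25 * 2 * FARADAY)
  expect_equal(formate_coulombs(-20, 0.25), 965, tolerance = 1e-3)
  expect_equal(formate_coulombs(0, 0.25), 0)
  expect_equal(formate_coulombs(5, 0.25), 0)
})

test_that("donor budget classification follows the coverage rules", {
  # products covered by the cathode alone
  b1 <- build_donor_budget(200, c(x = 150 / (FARADAY * 8 * 0.25) * 1000),
                           c(x = 8), 0.25)
  expect_equal(b1$q_products_C, 150)
  expect_equal(b1$classification, "cathode_sufficient")
  expect_equal(b1$ce_total_percent, 75)
  expect_false(b1$ce_over_100)

  # products need the formate donor too
  b2 <- build_donor_budget(200, c(x = 300 / (FARADAY * 8 * 0.25) * 1000),
                           c(x = 8), 0.25, q_formate_C = 200)
  expect_equal(b2$classification, "multi_donor_electrofermentation")
  expect_equal(b2$ce_total_percent, 150)
  expect_true(b2$ce_over_100)

  # products exceed every accounted donor
  b3 <- build_donor_budget(200, c(x = 900 / (FARADAY * 8 * 0.25) * 1000),
                           c(x = 8), 0.25, q_formate_C = 200,
                           q_yeast_extract_C = 200)
  expect_equal(b3$classification, "donor_deficit_flag")

  # per-product CEs sum to the total
  b4 <- build_donor_budget(500, c(a = 0.5, b = 0.2), c(a = 8, b = 20), 0.25)
  expect_equal(sum(b4$ce_percent), b4$ce_total_percent)
})

test_that("iron reduction extent applies the magnetite one-third cap", {
  r <- iron_reduction_extent(0.9, 3.2)
  expect_equal(r$fraction_reduced, 0.28125)
  expect_true(r$magnetite_consistent)
  expect_true(iron_reduction_extent(1, 3)$magnetite_consistent)
  expect_false(iron_reduction_extent(0.6 * 3, 3)$magnetite_consistent)
  expect_error(iron_reduction_extent(4, 3), "cannot exceed")
})
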