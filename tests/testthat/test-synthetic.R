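test_that("scenario constructor enforces label-consistent draws", {
  expect_error(scenario("abiotic", 1e-4, c(cathode = 10), numeric(0), 1),
               "abiotic")
  expect_error(scenario("electrotroph", 1e-4, c(formate = 10),
                        c("acetic acid" = 1), 1), "cathode only")
  expect_error(scenario("fermenter", 1e-4, c(yeast_extract = 10),
                        c("acetic acid" = 0.5), 1), "sum to 1")
  expect_error(scenario("fermenter", 1e-4, c(yeast_extract = 10),
                        c("acetic acid" = 1), 1.2), "efficiency")
})

test_that("generated traces realize the configured cathode draw exactly", {
  scen <- scenario("electrotroph", 1e-4, c(cathode = 200),
                   c("acetic acid" = 1), 1, noise = scenario_noise(0))
  tr <- generate_trace(scen, dt_s = 120)
  total <- integrate_current(tr)
  baseline_part <- 1e-4 * 6 * 86400
  expect_equal(total - baseline_part, 200, tolerance = 1e-9)
  # biocoulombs recover the draw up to the tiny pre-1h logistic tail
  expect_equal(biocoulombs(tr), 200, tolerance = 1e-4)
})

test_that("abiotic traces hold the baseline with fold increase 1", {
  scen <- scenario_preset("abiotic", noise_scale = 0)
  tr <- generate_trace(scen)
  expect_equal(fold_increase(tr)$ratio, 1.0)
  expect_equal(biocoulombs(tr), 0)
})

test_that("a plateau of 5x the baseline drives the fold increase toward 6", {
  # draw sized so the rescaled plateau equals 5x baseline
  base <- 1e-4
  t <- seq(0, 6 * 86400, by = 120)
  ramp <- stats::plogis(1.5e-4 * (t - 86400))
  draw <- 5 * base * sum(ramp[-length(t)] * diff(t))
  scen <- scenario("electrotroph", base, c(cathode = draw),
                   c("acetic acid" = 1), 1, noise = scenario_noise(0))
  fi <- fold_increase(generate_trace(scen, dt_s = 120))
  expect_equal(fi$ratio, 6, tolerance = 1e-3)
  expect_gt(fi$t_at_max_s, 86400)
})

test_that("generation is deterministic under a fixed seed", {
  s1 <- scenario_preset("electro_fermenter", seed = 99)
  tr_a <- generate_trace(s1, reactor_id = "r1")
  tr_b <- generate_trace(s1, reactor_id = "r1")
  expect_identical(tr_a$current_A, tr_b$current_A)
  tr_c <- generate_trace(s1, reactor_id = "r2")
  expect_false(identical(tr_a$current_A, tr_c$current_A))

  d1 <- generate_experiment(master_seed = 5)
  d2 <- generate_experiment(master_seed = 5)
  expect_identical(d1$reactors[[2]]$trace$current_A,
                   d2$reactors[[2]]$trace$current_A)
  expect_identical(d1$amplicon$counts, d2$amplicon$counts)
  d3 <- generate_experiment(master_seed = 6)
  expect_false(identical(d1$amplicon$counts, d3$amplicon$counts))
})

test_that("noiseless chemistry inverts the CE formula exactly", {
  # cathode draw 200 C, acetate-only, efficiency 1 -> 200/(F*8*0.25) mol/L
  scen <- scenario("electrotroph", 1e-4, c(cathode = 200),
                   c("acetic acid" = 1), 1, noise = scenario_noise(0))
  reactor <- reactor_record("r", "LC2", 75, 4.5, "CO2")
  chem <- generate_chemistry(scen, reactor)
  expect_equal(unname(chem$truth$deltas_mM["acetic acid"]),
               200 / (FARADAY * 8 * 0.25) * 1000)
  expect_equal(unname(chem$truth$deltas_mM["acetic acid"]), 1.036,
               tolerance = 1e-3)
  expect_equal(series_delta_mM(chem$metabolites[["acetic acid"]]),
               unname(chem$truth$deltas_mM["acetic acid"]))
})

test_that("product coulombs equal efficiency times the donor draws", {
  scen <- scenario("electro_fermenter", 8e-5,
                   c(cathode = 100, yeast_extract = 100),
                   c("acetic acid" = 0.5, "butyric acid" = 0.5), 0.75,
                   noise = scenario_noise(0))
  reactor <- reactor_record("r", "LC2", 30, 7, "CO2")
  chem <- generate_chemistry(scen, reactor)
  reg <- compound_registry()
  q <- sum(vapply(names(scen$product_profile), function(p)
    FARADAY * compound_ne(p, reg) *
      (chem$truth$deltas_mM[[p]] / 1000) * 0.25, numeric(1)))
  expect_equal(q, 0.75 * 200)
  expect_lte(q, 200) # conservation: products never exceed donors
})

test_that("abiotic chemistry leaves concentrations and COD unchanged", {
  scen <- scenario_preset("abiotic", noise_scale = 0)
  reactor <- reactor_record("r", "LC2", 30, 7, "NO3")
  chem <- generate_chemistry(scen, reactor)
  expect_length(chem$metabolites, 0)
  expect_equal(chem$cod$cod_initial_gO2_per_L, chem$cod$cod_final_gO2_per_L)
})

test_that("infeasible draws are rejected", {
  scen <- scenario("methylotroph", 8e-5, c(formate = 5000),
                   c("acetic acid" = 1), 1, noise = scenario_noise(0),
                   initial_mM = c(formate = 20))
  reactor <- reactor_record("r", "BJ", 30, 10, "HCOO")
  expect_error(generate_chemistry(scen, reactor), "exceeds the initial")
})

test_that("amplicon counts follow the taxon profile within sampling error", {
  scen <- scenario("fermenter", 8e-5, c(yeast_extract = 100),
                   c("acetic acid" = 1), 1,
                   taxon_profile = c(ASV_01 = 0.5, ASV_03 = 0.5),
                   amplicon_depth = 100000, seed = 21)
  bio <- generate_biology(scen, "r")
  # binomial sd at p = 0.5, n = 1e5 is ~158; allow 3 sigma
  expect_lt(abs(bio$amplicon_counts[["ASV_01"]] - 50000), 3 * 158.2)
  expect_equal(sum(bio$amplicon_counts), 100000)
})

test_that("blank scenarios produce blank biology", {
  scen <- scenario_preset("abiotic", noise_scale = 0)
  bio <- generate_biology(scen, "r")
  expect_equal(bio$biofilm$score, 0L)
  expect_lt(bio$qpcr$bacterial_copies_per_cm2, 1e5)
})

test_that("experiments carry one bundle and truth row per scenario", {
  ds <- generate_experiment(master_seed = 2)
  expect_length(ds$reactors, 5)
  expect_equal(nrow(ds$truth), 5)
  expect_setequal(ds$truth$label, c("electrotroph", "electro_fermenter",
                                    "fermenter", "methylotroph", "abiotic"))
  expect_equal(colnames(ds$amplicon$counts), ds$truth$reactor_id)
})
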