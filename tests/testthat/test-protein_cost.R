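simple_state <- function(dg0, ...) thermo_state(dg0, ...)

test_that("driving force follows the mass-action concentration correction", {
  st <- simple_state(c(r = 0))
  # all concentrations 1 M: dG' = dG'0
  expect_equal(driving_force(st, c(A = -1, B = 1), c(A = 0, B = 0), "r"), 0)
  # 10-fold substrate excess: dG' = -RT ln 10
  dg <- driving_force(st, c(A = -1, B = 1), c(A = log(10 * 1e-3), B = log(1e-3)), "r")
  expect_equal(dg, -st$RT * log(10))
  expect_equal(dg, -5.708, tolerance = 1e-3)              # kJ/mol at 298.15 K
  # doubling stoichiometry doubles the concentration term
  dg2 <- driving_force(st, c(A = -2, B = 2), c(A = log(10 * 1e-3), B = log(1e-3)), "r")
  expect_equal(dg2, 2 * dg)
  expect_error(driving_force(st, c(A = -1, Z = 1), c(A = 0), "r"),
               regexp = "Z", class = "od_validation_error")
})

test_that("efficiencies hit their analytic anchors", {
  st <- simple_state(c(r = 0))
  kin <- enzyme_kinetics("r", kcat = 10, km = c(A = 1), enzyme_mass = 100)
  # dG' = -RT ln 10  =>  eta_therm = 1 - 1/10
  lc <- c(A = log(10 * 1e-3), B = log(1e-3))
  eff <- efficiencies(st, kin, c(A = -1, B = 1), lc)
  expect_equal(unname(eff["eta_therm"]), 0.9)
  # substrate at Km (1 mM) => eta_sat = 0.5
  st2 <- simple_state(c(r = -50))
  eff2 <- efficiencies(st2, kin, c(A = -1, B = 1), c(A = log(1e-3), B = log(1e-3)))
  expect_equal(unname(eff2["eta_sat"]), 0.5)
  # strongly driven reaction saturates eta_therm -> 1
  eff3 <- efficiencies(simple_state(c(r = -500)), kin, c(A = -1, B = 1),
                       c(A = log(1e-3), B = log(1e-3)))
  expect_equal(unname(eff3["eta_therm"]), 1)
  # dG' >= 0 is not a running direction
  expect_error(efficiencies(simple_state(c(r = 10)), kin, c(A = -1, B = 1),
                            c(A = log(1e-3), B = log(1e-3))),
               class = "od_infeasible_direction")
})

test_that("reaction cost combines mass, kcat and efficiencies", {
  kin <- enzyme_kinetics("r", kcat = 10, km = c(A = 1), enzyme_mass = 100)
  expect_equal(reaction_cost(kin, eta_therm = 0.9, eta_sat = 0.5), 100 / (10 * 0.5 * 0.9))
  expect_equal(reaction_cost(kin, 0.9, 0.5), 22.22, tolerance = 1e-3)
  expect_equal(reaction_cost(kin, 1, 1), 10)              # ideal-enzyme floor
  kin2 <- enzyme_kinetics("r", kcat = 5, km = c(A = 1), enzyme_mass = 100)
  expect_equal(reaction_cost(kin2, 0.9, 0.5), 2 * reaction_cost(kin, 0.9, 0.5))
  expect_equal(reaction_cost(kin, 0.9, 0.5, flux = 2), 2 * reaction_cost(kin, 0.9, 0.5))
  expect_error(reaction_cost(kin, 0, 0.5), class = "od_infinite_cost")
})

test_that("max-min driving force flags thermodynamically impossible pathways", {
  rxns <- list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1))
  st_ok <- simple_state(c(r1 = -10, r2 = -10))
  mdf <- max_min_driving_force(rxns, st_ok)
  expect_gt(mdf$mdf, 0)
  st_bad <- simple_state(c(r1 = 50, r2 = 50))
  expect_error(minimize_pathway_cost(rxns, list(
    enzyme_kinetics("r1", 10, c(A = 1), 100),
    enzyme_kinetics("r2", 10, c(B = 1), 100)), st_bad),
    class = "od_thermo_infeasible")
  err <- tryCatch(minimize_pathway_cost(rxns, list(
    enzyme_kinetics("r1", 10, c(A = 1), 100),
    enzyme_kinetics("r2", 10, c(B = 1), 100)), st_bad), error = function(e) e)
  expect_match(conditionMessage(err), "r1|r2")
})

test_that("optimized cost matches the dense grid oracle within 1%", {
  # two metabolites, one reaction
  k1 <- list(r1 = enzyme_kinetics("r1", 10, c(A = 1), 100))
  rx1 <- list(r1 = c(A = -1, B = 1))
  st1 <- simple_state(c(r1 = -20))
  opt1 <- minimize_pathway_cost(rx1, k1, st1)
  grid1 <- oracle_grid_cost(rx1, k1, st1, pts = 50)
  expect_lte(opt1$total_cost, grid1 * (1 + 1e-6))
  expect_equal(opt1$total_cost, grid1, tolerance = 0.01)

  # three metabolites, two-reaction chain
  rx2 <- list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1))
  k2 <- list(r1 = enzyme_kinetics("r1", 10, c(A = 1), 100),
             r2 = enzyme_kinetics("r2", 25, c(B = 0.5), 150))
  st2 <- simple_state(c(r1 = -8, r2 = -8))
  opt2 <- minimize_pathway_cost(rx2, k2, st2)
  grid2 <- oracle_grid_cost(rx2, k2, st2, pts = 50)
  expect_lte(opt2$total_cost, grid2 * (1 + 1e-6))
  expect_equal(opt2$total_cost, grid2, tolerance = 0.01)

  # four metabolites, three-reaction chain with a bimolecular step
  rx3 <- list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1),
              r3 = c(C = -1, A = -0.2, D = 1))
  k3 <- list(r1 = enzyme_kinetics("r1", 10, c(A = 1), 100),
             r2 = enzyme_kinetics("r2", 25, c(B = 0.5), 150),
             r3 = enzyme_kinetics("r3", 5, c(C = 2, A = 1), 200))
  st3 <- simple_state(c(r1 = -8, r2 = -8, r3 = -15))
  opt3 <- minimize_pathway_cost(rx3, k3, st3)
  grid3 <- oracle_grid_cost(rx3, k3, st3, pts = 20)
  expect_lte(opt3$total_cost, grid3 * (1 + 1e-6))
  expect_equal(opt3$total_cost, grid3, tolerance = 0.02)
})

test_that("tightening an intermediate's ceiling cannot lower the optimal cost", {
  rxns <- list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1))
  kin <- list(r1 = enzyme_kinetics("r1", 10, c(A = 1), 100),
              r2 = enzyme_kinetics("r2", 25, c(B = 0.5), 150))
  st_wide <- simple_state(c(r1 = -8, r2 = -8))
  st_tight <- thermo_state(c(r1 = -8, r2 = -8),
                           conc_lb = c(A = 1e-6, B = 1e-6, C = 1e-6),
                           conc_ub = c(A = 1e-2, B = 1e-4, C = 1e-2))
  wide <- minimize_pathway_cost(rxns, kin, st_wide)$total_cost
  tight <- minimize_pathway_cost(rxns, kin, st_tight)$total_cost
  expect_gte(tight, wide - 1e-9)
  # grid oracle agrees on the ordering
  expect_gte(oracle_grid_cost(rxns, kin, st_tight, 40),
             oracle_grid_cost(rxns, kin, st_wide, 40) - 1e-9)
})

test_that("thermodynamic contribution is a percentage that vanishes for driven pathways", {
  kin <- list(r1 = enzyme_kinetics("r1", 10, c(A = 1), 100))
  rxns <- list(r1 = c(A = -1, B = 1))
  weak <- minimize_pathway_cost(rxns, kin, simple_state(c(r1 = -3)))
  strong <- minimize_pathway_cost(rxns, kin, simple_state(c(r1 = -300)))
  expect_gte(weak$thermo_contribution, 0)
  expect_lt(weak$thermo_contribution, 100)
  expect_lt(strong$thermo_contribution, 1e-6)
  expect_gt(weak$thermo_contribution, strong$thermo_contribution)
})

test_that("kinetics and Gibbs-energy TSV tables load into typed objects", {
  kf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tkcat\tenzyme_mass\tdg0",
               "r1\t10\t100\t-20", "r2\t25\t150\t-8"), kf)
  writeLines(c("reaction_id\tmetabolite_id\tkm_mM",
               "r1\tA\t1", "r2\tB\t0.5"), mf)
  tab <- read_kinetics_tsv(kf, mf)
  expect_named(tab$kinetics, c("r1", "r2"))
  expect_equal(tab$kinetics$r2$km, c(B = 0.5))
  expect_equal(tab$dg0, c(r1 = -20, r2 = -8))
  cost <- minimize_pathway_cost(list(r1 = c(A = -1, B = 1), r2 = c(B = -1, C = 1)),
                                tab$kinetics, thermo_state(tab$dg0))
  expect_gt(cost$total_cost, 100 / 10 + 150 / 25)         # above the ideal floor
})
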