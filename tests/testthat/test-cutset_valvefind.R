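toy_setup <- function(name = "branched_toy") {
  m <- build_fixture(name)
  list(model = m, efms = partition_modes(enumerate_efms(m)))
}

test_that("target-mode selection keeps only modes below the yield threshold", {
  s <- toy_setup()
  tg <- select_target_modes(s$efms, yield_threshold = 1.0)
  expect_setequal(tg$mode_indices, which(s$efms$partition == "S_x"))
  expect_equal(sort(tg$yields), c(0, 0, 1))

  expect_error(select_target_modes(s$efms, yield_threshold = 1.01),
               class = "od_infeasible_design")
  expect_equal(length(select_target_modes(s$efms, yield_threshold = 0)$mode_indices), 0L)
})

test_that("minimal cut sets equal the brute-force hitting-set oracle", {
  s <- toy_setup()
  tg <- select_target_modes(s$efms, 1.0)
  deletable <- toy_deletable(s$model)
  mcs <- enumerate_mcs(tg, s$efms, deletable = deletable, max_cardinality = 3L)
  expected <- oracle_hitting_sets(s$efms$orig_supports[tg$mode_indices],
                                  deletable, 3L)
  expect_true(support_sets_equal(unclass(mcs), expected))
  expect_true(support_sets_equal(unclass(mcs),
                                 list("v1", c("v2", "v3"), c("v2", "v5"),
                                      c("v3", "v4"), c("v4", "v5"))))
  # ordering: cardinality then lexicographic
  expect_equal(mcs[[1]], "v1")
  expect_equal(vapply(mcs, paste, "", collapse = "+"),
               c("v1", "v2+v3", "v2+v5", "v3+v4", "v4+v5"))

  # every returned set hits all targets and is minimal
  for (cs in mcs) {
    hits <- vapply(s$efms$orig_supports[tg$mode_indices],
                   function(T) any(T %in% cs), TRUE)
    expect_true(all(hits))
    for (r in cs) {
      sub <- setdiff(cs, r)
      expect_false(all(vapply(s$efms$orig_supports[tg$mode_indices],
                              function(T) any(T %in% sub), TRUE)))
    }
  }

  expect_equal(unclass(enumerate_mcs(tg, s$efms, deletable = deletable,
                                     max_cardinality = 1L)), list("v1"))
})

test_that("a target mode without deletable reactions is reported uncuttable", {
  s <- toy_setup()
  tg <- select_target_modes(s$efms, 1.0)
  expect_error(enumerate_mcs(tg, s$efms, deletable = c("v2", "v4")),
               class = "od_uncuttable_mode")
})

test_that("valves restore growth through the reopened branch", {
  m <- build_fixture("branched_toy")
  expect_equal(find_valves(m, "v1"),
               data.frame(reaction = "v1", restored_growth_fraction = 1),
               ignore_attr = TRUE)
  v25 <- find_valves(m, c("v2", "v5"))
  expect_setequal(v25$reaction, c("v2", "v5"))
  expect_equal(v25$restored_growth_fraction, c(1, 1))
  # unreachable growth threshold filters everything out
  expect_equal(nrow(find_valves(m, "v1", growth_fraction = 1.01)), 0L)
  # wild type must grow
  m0 <- m; m0$reactions$ub[m0$reactions$id == "v_bio"] <- 0
  expect_error(find_valves(m0, "v1"), class = "od_validation_error")
})

test_that("valve-off audit: zero growth, guaranteed yield, precursor leaks", {
  m <- build_fixture("branched_toy")
  off <- audit_valve_off(m, "v1", precursors = c("B", "C", "D", "E"))
  expect_equal(off$precursor_count, 0L)
  expect_equal(off$growth, 0)
  expect_equal(off$product_yield, 1.0)
  expect_equal(audit_valve_off(m, "v1", precursors = "P")$precursor_count, 1L)
  # valve on (nothing deleted): all growth-route precursors synthesizable
  on <- audit_valve_off(m, character(0), precursors = c("B", "C", "D", "E"))
  expect_equal(on$precursor_count, 4L)
})

test_that("designs are ranked by score, then cardinality, then lexicographically", {
  s <- toy_setup()
  tg <- select_target_modes(s$efms, 1.0)
  mcs <- enumerate_mcs(tg, s$efms, deletable = toy_deletable(s$model),
                       max_cardinality = 3L)
  designs <- rank_designs(s$model, mcs, growth_fraction = 0.9,
                          precursors = c("B", "C", "D", "E"))
  expect_length(designs, 5L)
  top <- designs[[1]]
  expect_equal(top$cutset, "v1")
  expect_equal(top$valve_id, "v1")
  expect_equal(top$score, 0.8)          # reduced network equals the original
  expect_equal(top$restored_growth_fraction, 1)
  expect_equal(top$precursors_off_count, 0L)
  expect_equal(top$product_yield_valve_off, 1)
  # equal scores -> lower cardinality first; within size-2 sets, lexicographic
  df <- as.data.frame(designs)
  expect_equal(df$score, rep(0.8, 5))
  expect_equal(df$cutset, c("v1", "v2+v3", "v2+v5", "v3+v4", "v4+v5"))

  # the defining valve contract, checked by FBA on each design
  mu_wt <- fba(s$model)$objective
  for (d in designs) {
    off <- audit_valve_off(s$model, d$cutset)
    expect_equal(off$growth, 0)
    expect_gte(off$product_yield, 1)
    reduced <- apply_pathway(s$model, pathway_config(
      "on", removed_reaction_ids = setdiff(d$cutset, d$valve_id)))
    expect_gte(fba(reduced)$objective, 0.9 * mu_wt)
  }
})

test_that("designs whose reduced network cannot score rank last", {
  # diamond variant: cutting the trunk leaves no biomass-only mode set
  m <- build_strong_coupling()
  efms <- partition_modes(enumerate_efms(m))
  # all modes are coupled or product-only; score is undefined even wild type
  designs <- rank_designs(m, list(c("v1")), growth_fraction = 0)
  if (length(designs)) {
    expect_true(designs[[length(designs)]]$score_undefined)
    expect_true(is.na(designs[[length(designs)]]$score))
  }
  # EFM/FBA agreement: a mode survives a deletion iff its support avoids it
  toy <- toy_setup()
  for (cs in list("v1", c("v2", "v5"))) {
    surviving <- Filter(function(s) !any(cs %in% s), toy$efms$orig_supports)
    md <- apply_pathway(toy$model, pathway_config("cut", removed_reaction_ids = cs))
    expect_true(support_sets_equal(enumerate_efms(md)$supports, surviving))
  }
})
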