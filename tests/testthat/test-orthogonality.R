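toy_efms <- function(name = "branched_toy")
  partition_modes(enumerate_efms(build_fixture(name)))

test_that("pair similarity is the shared fraction of the biomass support", {
  expect_equal(pair_similarity(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(pair_similarity(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(pair_similarity(c("R_up", "v7", "v8"),
                               c("R_up", "v1", "v2", "v4", "v_bio")), 0.2)
  expect_error(pair_similarity(c("a"), character(0)), class = "od_validation_error")
})

test_that("average similarity matches hand-computed support arithmetic", {
  expect_equal(average_similarity(toy_efms()), 0.2)
  # redundant variant adds a size-4 biomass mode sharing only the uptake
  expect_equal(average_similarity(toy_efms("branched_toy_redundant")),
               (0.2 + 0.2 + 0.25) / 3)
})

test_that("orthogonality score is 1 - AS on unimodal distributions", {
  res <- orthogonality_score(toy_efms())
  expect_equal(res$score, 0.8)
  expect_false(res$multimodal)
  res2 <- orthogonality_score(toy_efms("branched_toy_redundant"))
  expect_equal(res2$score, 1 - (0.2 + 0.2 + 0.25) / 3, tolerance = 1e-12)
  expect_lt(res2$score, res$score)      # a shared redundant route lowers the score
})

test_that("score hits its boundary values for disjoint and nested supports", {
  # fully shared: biomass support contained in every product support
  sx <- list(c("u", "a", "b"))
  st <- list(c("u", "a", "b", "t"))
  fake <- structure(list(supports = c(st, sx),
                         partition = c("S_t", "S_x"), m = 1L, n = 1L,
                         model = build_fixture("branched_toy"),
                         modes = matrix(0, 2, 0), mapping = data.frame()),
                    class = "od_efm_set")
  expect_equal(orthogonality_score(fake)$score, 0.0)
  fake$supports <- list(c("t1", "t2"), c("x1", "x2"))
  expect_equal(orthogonality_score(fake)$score, 1.0)
})

test_that("score is undefined without biomass-only or product-only modes", {
  expect_error(orthogonality_score(toy_efms("linear_chain")),
               class = "od_undefined_score")
  sc <- partition_modes(enumerate_efms(build_strong_coupling()))
  expect_error(orthogonality_score(sc), class = "od_undefined_score")
  err <- tryCatch(orthogonality_score(sc), error = function(e) e)
  expect_match(conditionMessage(err), "undefined")
})

test_that("bimodality coefficient separates unimodal, uniform and two-point data", {
  set.seed(42)
  expect_lt(bimodality_coefficient(rnorm(1000)), 5 / 9)
  expect_gt(bimodality_coefficient(rep(c(0, 1), each = 500)), 5 / 9)
  # balanced two-point mixture approaches b = 1
  expect_equal(bimodality_coefficient(rep(c(0, 1), each = 5000)), 1, tolerance = 1e-3)
  # uniform sits at the 5/9 boundary in the large-N limit
  u <- seq(0, 1, length.out = 20000)
  expect_equal(bimodality_coefficient(u), 5 / 9, tolerance = 1e-3)
  expect_error(bimodality_coefficient(c(0, 1, 0)), class = "od_validation_error")
})

test_that("multimodal per-pair distributions use the highest-density mode", {
  sx <- c(lapply(1:20, function(i) c("u", sprintf("x%da", i), sprintf("x%db", i))),
          lapply(1:10, function(i) c("u", "s1", "s2")))
  st <- list(c("u", "s1", "s2", "t"))
  fake <- structure(list(supports = c(st, sx),
                         partition = c("S_t", rep("S_x", 30)), m = 1L, n = 30L,
                         model = build_fixture("branched_toy"),
                         modes = matrix(0, 31, 0), mapping = data.frame()),
                    class = "od_efm_set")
  # o-values: 20 pairs at 1 - 1/3 = 2/3, 10 pairs at 0 -> bimodal
  res <- orthogonality_score(fake)
  expect_true(res$multimodal)
  expect_gt(res$bimodality_coefficient, 5 / 9)
  expect_equal(res$score, 2 / 3, tolerance = 0.05)   # tallest-bin midpoint
  expect_equal(res$mode_estimate, res$score)
})

test_that("precursor-supporting reactions are counted over product modes", {
  efms <- toy_efms()
  m <- build_fixture("branched_toy")
  # the product mode {R_up, v7, v8} produces no B
  expect_equal(unname(precursor_reaction_metrics(efms, m, precursors = "B")),
               c(0, 0))
  # v7 produces P, and R_up produces A: both sit in the product mode
  expect_equal(unname(precursor_reaction_metrics(efms, m, precursors = "P")),
               c(1, 1))
  expect_equal(unname(precursor_reaction_metrics(efms, m, precursors = c("A", "P"))),
               c(2, 2))
  expect_equal(unname(precursor_reaction_metrics(efms, m, precursors = character(0))),
               c(0, 0))
  # consumption does not count as support: v8 consumes P
  expect_equal(unname(precursor_reaction_metrics(efms, m, precursors = "E")),
               c(0, 0))
})

test_that("score distribution comparison is a two-sample KS test", {
  a <- orthogonality_score(toy_efms())$per_pair
  b <- orthogonality_score(toy_efms("branched_toy_redundant"))$per_pair
  self <- compare_score_distributions(a, a)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_equal(compare_score_distributions(a, b)$statistic, 1 / 3, tolerance = 1e-12)
  expect_equal(compare_score_distributions(c(0, 0), c(1, 1))$statistic, 1)
})

test_that("score is invariant to mode and reaction ordering", {
  efms <- toy_efms("branched_toy_redundant")
  base <- orthogonality_score(efms)$score
  perm <- efms
  ord <- c(3, 1, 4, 2)
  perm$supports <- efms$supports[ord]
  perm$partition <- efms$partition[ord]
  perm$supports <- lapply(perm$supports, rev)
  expect_equal(orthogonality_score(perm)$score, base)
})

test_that("a reaction shared by all modes never increases the score", {
  set.seed(7)
  for (rep in 1:25) {
    nt <- sample(1:4, 1); nx <- sample(1:4, 1)
    st <- lapply(seq_len(nt), function(i) unique(c("u", sample(letters, sample(2:6, 1)))))
    sx <- lapply(seq_len(nx), function(i) unique(c("u", sample(letters, sample(2:6, 1)))))
    os_of <- function(st, sx)
      1 - mean(vapply(sx, function(x)
        mean(vapply(st, pair_similarity, 0, x_support = x)), 0))
    shared <- "Z"
    st2 <- lapply(st, c, shared); sx2 <- lapply(sx, c, shared)
    expect_lte(os_of(st2, sx2), os_of(st, sx) + 1e-12)
  }
})
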