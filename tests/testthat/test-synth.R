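test_that("Saaty snapping is symmetric in x and 1/x and preserves reciprocity", {
  expect_equal(saaty_snap(c(2.2, 1 / 2.2)), c(2, 1 / 2))
  expect_equal(saaty_snap(1), 1)
  expect_equal(saaty_snap(100), 9)  # clamped to the scale edge
  A <- consistent_matrix_from_weights(c(0.5, 0.3, 0.2), snap = TRUE)
  expect_equal(unname(A[1, ]), c(1, 2, 3))
  expect_equal(unname(A[2, 3]), 2)  # 1.5 snaps up to 2 in log space
  expect_lt(max(abs(t(A) * A - 1)), 1e-15)
  cr <- consistency_ratio(A)
  expect_lte(cr$CR, 0.1)
  expect_error(consistent_matrix_from_weights(c(1, 0)), "positive")
})

test_that("uniform weights give the all-ones matrix; no snap keeps ratios", {
  expect_equal(unname(consistent_matrix_from_weights(rep(0.25, 4))),
               matrix(1, 4, 4))
  A <- consistent_matrix_from_weights(c(0.5, 0.3, 0.2))
  expect_equal(unname(A[1, ]), c(1, 5 / 3, 2.5))
  expect_equal(unname(A[2, 3]), 1.5)
  expect_equal(consistency_ratio(A)$CR, 0)
})

test_that("the generator is deterministic under its seed", {
  m1 <- quiet_synth(seed = 71, n_participants = 2, noise = 0.1,
                    dematel_noise = 0.5)
  m2 <- quiet_synth(seed = 71, n_participants = 2, noise = 0.1,
                    dematel_noise = 0.5)
  expect_identical(m1$truth, m2$truth)
  expect_identical(m1$judgment_sets, m2$judgment_sets)
  m3 <- quiet_synth(seed = 72, n_participants = 2, noise = 0.1,
                    dematel_noise = 0.5)
  expect_false(identical(m1$truth$scores, m3$truth$scores))
})

test_that("zero noise reproduces the ground-truth matrices for everyone", {
  md <- quiet_synth(seed = 73, n_participants = 3)
  for (js in md$judgment_sets) {
    expect_identical(js$anp[names(md$truth$cluster_matrices)],
                     md$truth$cluster_matrices)
    expect_identical(js$dematel, md$truth$influence)
  }
})

test_that("generated matrices respect the elicitation scales", {
  md <- quiet_synth(seed = 74, n_participants = 3, noise = 0.2,
                    dematel_noise = 0.8)
  vals <- danpselect:::saaty_scale_values()
  for (js in md$judgment_sets) {
    for (A in js$anp) {
      expect_lt(max(abs(t(A) * A - 1)), 1e-12)
      off <- A[row(A) != col(A)]
      expect_true(all(vapply(off, function(v) any(abs(v - vals) < 1e-12),
                             logical(1))))
    }
    for (D in js$dematel) {
      expect_true(all(D %in% 0:4))
      expect_equal(unname(diag(D)), rep(0, nrow(D)))
    }
  }
})

test_that("out-of-scale influence scores are clipped with a warning", {
  expect_warning(
    synth_model(synthesis_spec(seed = 75, n_participants = 4, noise = 0,
                               dematel_noise = 2)),
    "clipped"
  )
})

test_that("group aggregation stays close to truth at moderate noise", {
  # scaled-down Monte-Carlo: 15 seeds, 6 participants, noise 0.1
  worst <- 0
  for (s in 1:15) {
    md <- quiet_synth(seed = 400 + s, n_participants = 6, noise = 0.1)
    agg <- aggregate_judgments(md$judgment_sets)
    for (nm in names(md$truth$cluster_matrices)) {
      if (nrow(agg$anp[[nm]]) < 2) next
      l1 <- sum(abs(principal_priorities(agg$anp[[nm]])$weights -
                      md$truth$cluster_priorities[[nm]]))
      worst <- max(worst, l1)
    }
  }
  expect_lt(worst, 0.05)
})

test_that("the case-study fixture embeds the illustrative matrices", {
  m <- sixsigma_model()
  expect_true(validate_reciprocal(m$comparison_example)$valid)
  expect_equal(unname(diag(m$influence_example)), rep(0, 3))
  expect_true(all(m$influence_example %in% 0:4))
  expect_equal(nrow(m$elements), 24)
  # shipped CSVs match the in-code matrices
  expect_equal(read_matrix_csv(system.file("extdata", "strategy_influence.csv",
                                           package = "danpselect")),
               m$influence_example)
  expect_equal(read_matrix_csv(system.file("extdata", "cost_comparison.csv",
                                           package = "danpselect")),
               m$comparison_example)
})
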