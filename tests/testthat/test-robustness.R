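test_that("judgment counts reproduce the published totals for the case study", {
  net <- sixsigma_model()$network
  expect_identical(count_judgments(net, "anp"), 500L)
  expect_identical(count_judgments(net, "danp"), 550L)
  # decomposition: 6 strategy + 44 sub-criteria + 450 alternative judgments
  expect_identical(3L * 2L + (5L * 4L + 4L * 3L + 3L * 2L + 3L * 2L) +
                     15L * 6L * 5L, 500L)
})

test_that("judgment counts equal brute-force enumeration on random shapes", {
  set.seed(53)
  for (rep in 1:10) {
    sizes <- sample(1:6, sample(2:4, 1), replace = TRUE)
    n_alt <- sample(1:7, 1)
    spec <- synthesis_spec(n_strategies = sample(1:4, 1),
                           criteria_sizes = sizes, n_alternatives = n_alt,
                           n_participants = 1, noise = 0, dematel_noise = 0,
                           min_gap = 0, seed = rep)
    md <- suppressWarnings(synth_model(spec))
    js <- md$judgment_sets[[1]]
    # enumerate off-diagonal cells over the elicited forms
    anp_cells <- sum(vapply(js$anp, function(m) nrow(m) * (nrow(m) - 1),
                            numeric(1)))
    dem_cells <- sum(vapply(js$dematel, function(m) nrow(m) * (nrow(m) - 1),
                            numeric(1)))
    # single-element clusters and single alternatives elicit no judgments,
    # and the generator emits matrices only for its contexts
    expect_identical(count_judgments(md$network, "anp"), as.integer(anp_cells))
    expect_identical(count_judgments(md$network, "danp"),
                     as.integer(anp_cells + dem_cells))
  }
})

test_that("incremental judgment accounting matches the published figures", {
  net <- sixsigma_model()$network
  # +12 ordered judgments per sub-criterion matrix when a 7th project joins
  expect_identical(incremental_judgments(net, list(type = "add_alternative"),
                                         "anp"), 12L * 15L)
  expect_identical(incremental_judgments(net, list(type = "add_alternative"),
                                         "danp"), 12L * 15L)
  add_cost <- list(type = "add_subcriterion", cluster = "Cost")
  expect_identical(incremental_judgments(net, add_cost, "anp"), 30L)
  expect_identical(incremental_judgments(net, add_cost, "danp"), 36L)
})

test_that("incremental counts reconcile with before/after totals", {
  m <- sixsigma_model()
  net <- m$network
  js <- suppressWarnings(aggregate_judgments(sixsigma_judgments(
    seed = 2, n_participants = 2)))
  sc <- add_duplicate_subcriterion(net, js, "Cost", "S15", "S16")
  for (method in c("anp", "danp")) {
    delta <- count_judgments(sc$network, method) - count_judgments(net, method)
    # published convention: the enlarged within-cluster comparison matrix is
    # not counted, so the increment falls 2 * |Cost| short of the true delta
    expect_identical(delta - incremental_judgments(net, sc, method), 2L * 3L)
    expect_identical(delta,
                     incremental_judgments(net, sc, method,
                                           include_within_cluster = TRUE))
  }
  # alternative insertion has no hidden within-cluster term
  sca <- add_duplicate_alternative(net, js, "C4", "C7")
  expect_identical(count_judgments(sca$network, "anp") -
                     count_judgments(net, "anp"),
                   incremental_judgments(net, sca, "anp"))
})

test_that("duplicate-alternative insertion preserves structure", {
  m <- sixsigma_model()
  js <- suppressWarnings(aggregate_judgments(sixsigma_judgments(
    seed = 3, n_participants = 2)))
  sc <- add_duplicate_alternative(m$network, js, "C4", "C7")
  expect_length(sc$network$alternatives, 7)
  for (s in danpselect:::subcriteria(m$network)) {
    A <- sc$judgments$anp[[s]]
    expect_equal(dim(A), c(7, 7))
    # clone column duplicates the target's judgments
    others <- paste0("C", c(1, 2, 3, 5, 6))
    expect_equal(A[others, "C7"], A[others, "C4"], ignore_attr = TRUE)
    expect_equal(A["C7", "C4"], 1)
    # reciprocity preserved
    expect_lt(max(abs(t(A) * A - 1)), 1e-9)
  }
  expect_error(add_duplicate_alternative(m$network, js, "C9"), "C9")
})

test_that("duplicate sub-criterion insertion preserves structure", {
  m <- sixsigma_model()
  js <- suppressWarnings(aggregate_judgments(sixsigma_judgments(
    seed = 4, n_participants = 2)))
  sc <- add_duplicate_subcriterion(m$network, js, "Risk", "S15", "S16")
  risk <- danpselect:::network_cluster(sc$network, "Risk")
  expect_identical(risk$elements, c("S13", "S14", "S15", "S16"))
  A <- sc$judgments$anp$Risk
  expect_equal(dim(A), c(4, 4))
  expect_lt(max(abs(t(A) * A - 1)), 1e-9)
  D <- sc$judgments$dematel$Risk
  expect_equal(dim(D), c(4, 4))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D["S16", "S13"], D["S15", "S13"])
  # the clone rates alternatives exactly like its target
  expect_equal(sc$judgments$anp$S16, js$anp$S15)
  # insertion into another cluster enlarges that cluster
  sc2 <- add_duplicate_subcriterion(m$network, js, "Cost", "S15", "S16")
  expect_length(danpselect:::network_cluster(sc2$network, "Cost")$elements, 4)
  expect_error(add_duplicate_subcriterion(m$network, js, "Nope", "S15"),
               "Nope")
  expect_error(add_duplicate_subcriterion(m$network, js, "Risk", "S99"),
               "S99")
})

test_that("rank stability metrics match hand-computed cases", {
  same <- rank_stability(c("C4", "C3", "C2"), c("C4", "C3", "C2"))
  expect_true(same$preserved)
  expect_equal(same$kendall_tau, 1)

  # the published ANP failure mode: the leader drops to penultimate
  before <- paste0("C", c(4, 3, 2, 5, 6, 1))
  after <- paste0("C", c(3, 2, 5, "4_clone", 6, 4, 1))
  st <- rank_stability(before, after)
  expect_false(st$preserved)
  expect_equal(st$displacements$displacement[st$displacements$item == "C4"], 4)

  rev6 <- rank_stability(paste0("C", 1:6), paste0("C", 6:1))
  expect_equal(rev6$kendall_tau, -1)

  expect_error(rank_stability(c("A", "B"), c("A")), "missing")
  g <- glance(st)
  expect_equal(g$max_displacement, 4)
})

test_that("cloning an alternative splits its mass and keeps relative order", {
  md <- quiet_synth(seed = 61)
  js <- md$judgment_sets[[1]]
  base <- run_anp(md$network, js)
  sc <- add_duplicate_alternative(md$network, js, "C1", "C1b")
  after <- run_anp(sc$network, sc$judgments)
  # clone and target tie exactly
  w <- stats::setNames(after$ranking$weight, after$ranking$alternative)
  expect_equal(unname(w["C1"]), unname(w["C1b"]), tolerance = 1e-9)
  st <- rank_stability(base$ranking, after$ranking)
  expect_s3_class(st, "stability_report")
  expect_equal(nrow(st$displacements), 6)
})
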