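# Saaty scale values available to a respondent: 1/9 .. 1/2, 1, 2 .. 9.
saaty_scale_values <- function() sort(c(1 / (9:2), 1:9))

#' Snap a positive value (or comparison matrix) to the Saaty scale
#'
#' Maps each value to the nearest admissible scale value in log space, so x
#' and 1/x are treated symmetrically. For a matrix, the upper triangle is
#' snapped and the lower triangle filled with reciprocals, preserving
#' reciprocity exactly; the diagonal is set to 1.
#'
#' @param x positive numeric vector or square positive matrix.
#' @return the snapped object.
#' @export
#' @examples
#' saaty_snap(c(1.7, 2.5, 0.4))
saaty_snap <- function(x) {
  vals <- saaty_scale_values()
  snap1 <- function(v) vals[which.min(abs(log(v) - log(vals)))]
  if (is.matrix(x)) {
    if (any(x <= 0)) stopf("comparison values must be positive")
    n <- nrow(x)
    out <- diag(n)
    dimnames(out) <- dimnames(x)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        s <- snap1(x[i, j])
        out[i, j] <- s
        out[j, i] <- 1 / s
      }
    }
    out
  } else {
    if (any(x <= 0)) stopf("comparison values must be positive")
    vapply(x, snap1, numeric(1))
  }
}

#' Build a perfectly consistent comparison matrix from weights
#'
#' For a positive weight vector `w`, the matrix `a_ij = w_i / w_j` is
#' transitive (`a_ij = a_ik * a_kj`) and has `w` as its principal
#' eigenvector with `lambda_max = n` and CR = 0. With `snap = TRUE` entries
#' are mapped to the discrete Saaty scale (reciprocity preserved), which
#' reintroduces a small, bounded inconsistency.
#'
#' @param w positive weight vector (need not sum to 1).
#' @param snap snap entries to the Saaty scale.
#' @param labels optional element labels (defaults to `names(w)`).
#' @return a reciprocal comparison matrix.
#' @export
#' @examples
#' consistent_matrix_from_weights(c(0.5, 0.3, 0.2))
consistent_matrix_from_weights <- function(w, snap = FALSE, labels = NULL) {
  if (any(w <= 0)) stopf("weights must be strictly positive")
  A <- outer(w, w, "/")
  labels <- labels %||% names(w) %||% paste0("E", seq_along(w))
  dimnames(A) <- list(labels, labels)
  if (snap) A <- saaty_snap(A)
  A
}

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic decision model
#'
#' Parameter record for the synthetic-data generator. The defaults emulate
#' the bundled healthcare case study's structure: 3 strategies, criteria
#' clusters of 5/4/3/3 sub-criteria, 6 alternatives and 6 participants.
#'
#' @param n_strategies strategy-cluster size.
#' @param criteria_sizes named integer vector of criteria-cluster sizes.
#' @param n_alternatives number of project alternatives.
#' @param n_participants number of judges.
#' @param noise multiplicative judgment noise: each pairwise comparison is
#'   perturbed by `exp(rnorm(1, 0, noise))` before snapping.
#' @param dematel_noise additive noise (scale points, sd) on the 0--4
#'   influence scores before rounding and clipping.
#' @param min_gap minimum separation between consecutive composed true
#'   alternative scores; ground truths closer than this are redrawn so the
#'   true ranking is well defined.
#' @param seed integer; fully determines the generated model.
#' @return an object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(n_strategies = 3,
                           criteria_sizes = c(Benefit = 5, Opportunity = 4,
                                              Cost = 3, Risk = 3),
                           n_alternatives = 6, n_participants = 6,
                           noise = 0.1, dematel_noise = 0.5,
                           min_gap = 0.02, seed = 1) {
  if (is.null(names(criteria_sizes))) {
    names(criteria_sizes) <- paste0("Criteria", seq_along(criteria_sizes))
  }
  stopifnot(n_strategies >= 1, all(criteria_sizes >= 1), n_alternatives >= 1,
            n_participants >= 1, noise >= 0, dematel_noise >= 0)
  structure(list(n_strategies = n_strategies,
                 criteria_sizes = criteria_sizes,
                 n_alternatives = n_alternatives,
                 n_participants = n_participants,
                 noise = noise, dematel_noise = dematel_noise,
                 min_gap = min_gap, seed = as.integer(seed)),
            class = "synthesis_spec")
}

#' Generate a synthetic decision model with known ground truth
#'
#' Draws true priority vectors for every elicitation context and true
#' influence matrices for every cluster, materialises them as snapped
#' consistent comparison matrices, and simulates the participants' noisy
#' judgments. The stored ground truth (priorities and ranking) is the exact
#' solution of the noise-free snapped model — i.e. of the model a perfectly
#' reliable respondent could actually express on the discrete scale — so a
#' zero-noise run of the pipeline recovers it exactly. Alternative ground
#' truths whose composed scores are closer than `min_gap` are redrawn so
#' that the true ranking is unambiguous.
#'
#' @param spec a [synthesis_spec()].
#' @param network optional [decision_network()] whose shape matches `spec`;
#'   its labels are used instead of generated ones.
#' @return a list with `network`, `truth` (true matrices, priorities,
#'   influence matrices, composed scores and ranking) and `judgment_sets`
#'   (one [judgment_set()] per participant).
#' @export
#' @examples
#' model <- synth_model(synthesis_spec(seed = 7, n_participants = 2))
#' model$truth$ranking$alternative[1]
synth_model <- function(spec, network = NULL) {
  stopifnot(inherits(spec, "synthesis_spec"))
  if (is.null(network)) {
    network <- synth_network(spec)
  } else {
    sizes <- vapply(criteria_clusters(network),
                    function(cl) length(cl$elements), integer(1))
    if (!identical(unname(sizes), unname(as.integer(spec$criteria_sizes))) ||
        length(network$alternatives) != spec$n_alternatives) {
      stopf("network shape does not match the synthesis spec")
    }
  }
  with_seed(spec$seed, generate_model(spec, network))
}

synth_network <- function(spec) {
  strategy_labels <- paste0("ST", seq_len(spec$n_strategies))
  crit_names <- names(spec$criteria_sizes)
  sub_labels <- paste0("S", seq_len(sum(spec$criteria_sizes)))
  sub_split <- split(sub_labels,
                     rep(seq_along(spec$criteria_sizes), spec$criteria_sizes))
  clusters <- c(
    list(cluster("Strategies", "strategy", strategy_labels)),
    lapply(seq_along(crit_names), function(i) {
      cluster(crit_names[i], "criterion", sub_split[[i]])
    })
  )
  blocks <- c(
    lapply(c("Strategies", crit_names), function(nm) list(from = nm, to = nm)),
    lapply(crit_names, function(nm) list(from = nm, to = "alternatives"))
  )
  decision_network(
    goal = "Select the most beneficial improvement project",
    clusters = clusters,
    alternatives = paste0("C", seq_len(spec$n_alternatives)),
    blocks = blocks,
    cluster_weights = stats::setNames(
      rep(1 / length(crit_names), length(crit_names)), crit_names)
  )
}

rdirichlet1 <- function(n, shape = 3) {
  g <- stats::rgamma(n, shape = shape)
  g / sum(g)
}

# Make a generated 0-4 influence matrix analysable: every element must
# receive some influence (zero columns make inner dependence undefined) and
# the matrix must not be doubly balanced (all row sums and all column sums
# equal), which normalises to spectral radius exactly 1 where the
# total-relation series diverges. Repairs are deterministic: restore a unit
# link into zeroed columns, then nudge the first adjustable off-diagonal
# entry until the balance is broken.
repair_influence <- function(A) {
  n <- nrow(A)
  if (n == 1) return(A)
  for (j in which(colSums(A) == 0)) A[if (j == 1) 2 else 1, j] <- 1
  for (guard in 1:25) {
    k <- min(1 / max(rowSums(A)), 1 / max(colSums(A)))
    if (max(Mod(eigen(A * k, only.values = TRUE)$values)) < 1 - 1e-9) break
    off <- row(A) != col(A)
    up <- which(off & A < 4)
    if (length(up)) {
      A[up[1]] <- A[up[1]] + 1
    } else {
      down <- which(off & A > 0)
      A[down[1]] <- A[down[1]] - 1
    }
  }
  A
}

generate_model <- function(spec, network) {
  n_alt <- spec$n_alternatives
  alts <- network$alternatives
  subs <- subcriteria(network)
  rw <- criteria_weights(network)

  draw_context <- function(labels, base_log = NULL) {
    w <- if (is.null(base_log)) {
      rdirichlet1(length(labels))
    } else {
      # project quality is correlated across sub-criteria: a shared base
      # log-quality plus a context-specific deviation
      v <- exp(base_log + stats::rnorm(length(labels), 0, 0.4))
      v / sum(v)
    }
    w <- stats::setNames(w, labels)
    A <- consistent_matrix_from_weights(w, snap = TRUE)
    pr <- if (length(labels) > 1) principal_priorities(A)$weights else w
    list(w_raw = w, matrix = A, priorities = pr)
  }

  # within-cluster contexts
  cluster_ctx <- list()
  for (cl in network$clusters) cluster_ctx[[cl$label]] <- draw_context(cl$elements)

  # alternatives per sub-criterion, redrawn until the composed true scores
  # are separated by at least min_gap
  gw_sub <- unlist(lapply(criteria_clusters(network), function(cl) {
    cluster_ctx[[cl$label]]$priorities * rw[[cl$label]]
  }))
  names(gw_sub) <- subs
  for (try in seq_len(1000)) {
    base_log <- stats::rnorm(n_alt, 0, 0.8)
    alt_ctx <- lapply(subs, function(s) draw_context(alts, base_log))
    names(alt_ctx) <- subs
    scores <- Reduce(`+`, lapply(subs, function(s) {
      gw_sub[[s]] * alt_ctx[[s]]$priorities
    }))
    if (n_alt == 1 || min(abs(diff(sort(scores)))) >= spec$min_gap) break
    if (try == 1000) stopf("could not draw separated ground truth; lower min_gap")
  }

  # true influence matrices, integer 0-4, zero diagonal
  influence <- lapply(network$clusters, function(cl) {
    n <- length(cl$elements)
    A <- matrix(sample(0:4, n * n, replace = TRUE), n, n,
                dimnames = list(cl$elements, cl$elements))
    diag(A) <- 0
    repair_influence(A)
  })
  names(influence) <- network_cluster_labels(network)

  truth <- list(
    cluster_priorities = lapply(cluster_ctx, `[[`, "priorities"),
    cluster_matrices = lapply(cluster_ctx, `[[`, "matrix"),
    alternative_priorities = lapply(alt_ctx, `[[`, "priorities"),
    alternative_matrices = lapply(alt_ctx, `[[`, "matrix"),
    influence = influence,
    gw_sub = gw_sub,
    scores = stats::setNames(scores, alts),
    ranking = rank_alternatives(stats::setNames(scores, alts))
  )

  # participants: multiplicative log-normal noise on comparisons (snapped,
  # reciprocity enforced), additive noise on influence scores (rounded and
  # clipped to the 0-4 scale)
  clipped <- 0L
  perturb_comparison <- function(A) {
    n <- nrow(A)
    out <- A
    if (spec$noise > 0 && n > 1) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        v <- A[i, j] * exp(stats::rnorm(1, 0, spec$noise))
        s <- saaty_snap(v)
        out[i, j] <- s
        out[j, i] <- 1 / s
      }
    }
    out
  }
  perturb_influence <- function(A) {
    if (spec$dematel_noise == 0) return(A)
    raw <- A + matrix(stats::rnorm(length(A), 0, spec$dematel_noise),
                      nrow(A))
    out <- round(raw)
    clipped <<- clipped + sum(out < 0 | out > 4)
    out <- pmin(pmax(out, 0), 4)
    diag(out) <- 0
    dimnames(out) <- dimnames(A)
    repair_influence(out)
  }
  judgment_sets <- lapply(seq_len(spec$n_participants), function(p) {
    anp <- c(lapply(truth$cluster_matrices, perturb_comparison),
             lapply(truth$alternative_matrices, perturb_comparison))
    dem <- lapply(truth$influence, perturb_influence)
    judgment_set(sprintf("participant%02d", p), anp = anp, dematel = dem)
  })
  if (clipped > 0) {
    warnf("%d influence scores fell outside the 0-4 scale and were clipped",
          clipped)
  }

  list(network = network, truth = truth, judgment_sets = judgment_sets)
}

#' @rdname synth_model
#' @export
synth_judgment_sets <- function(spec, network = NULL) {
  synth_model(spec, network)$judgment_sets
}

#' The bundled healthcare six-sigma case-study model
#'
#' The decision network of the bundled case study — a public medical centre
#' selecting among six six-sigma improvement projects: 3 strategies
#' (organisational excellence OE, revenue growth RG, high productiveness
#' HP), 15 sub-criteria S1--S15 in four criteria clusters (Benefit 5,
#' Opportunity 4, Cost 3, Risk 3, each with relative weight 0.25), and
#' alternatives C1--C6. Two illustrative elicitation matrices are included:
#' the strategy cluster's DEMATEL influence matrix and the cost cluster's
#' pairwise-comparison matrix. The study's full aggregated judgment
#' matrices were never published; use [sixsigma_judgments()] for a
#' synthetic but fully runnable set of judgments on this structure.
#'
#' @return a list with `network`, `elements` (label/description table),
#'   `influence_example` (strategy-cluster DEMATEL matrix) and
#'   `comparison_example` (cost-cluster ANP matrix).
#' @export
#' @examples
#' m <- sixsigma_model()
#' m$network
sixsigma_model <- function() {
  network <- decision_network(
    goal = "Select the most suitable six-sigma project",
    clusters = list(
      cluster("Strategies", "strategy", c("OE", "RG", "HP")),
      cluster("Benefit", "criterion", paste0("S", 1:5)),
      cluster("Opportunity", "criterion", paste0("S", 6:9)),
      cluster("Cost", "criterion", paste0("S", 10:12)),
      cluster("Risk", "criterion", paste0("S", 13:15))
    ),
    alternatives = paste0("C", 1:6),
    blocks = c(
      lapply(c("Strategies", "Benefit", "Opportunity", "Cost", "Risk"),
             function(nm) list(from = nm, to = nm)),
      lapply(c("Benefit", "Opportunity", "Cost", "Risk"),
             function(nm) list(from = nm, to = "alternatives"))
    ),
    cluster_weights = c(Benefit = 0.25, Opportunity = 0.25,
                        Cost = 0.25, Risk = 0.25)
  )
  elements <- tibble(
    label = c("OE", "RG", "HP", paste0("S", 1:15), paste0("C", 1:6)),
    description = c(
      "Organizational excellence", "Revenue growth", "High productiveness",
      "Cash flow", "Quality level", "Efficiency", "User satisfaction",
      "Reduction of operational cost", "Operational performance",
      "Market share increase", "User loyalty", "Employees' performance",
      "Training", "Human resources", "Associated costs",
      "Technical risks", "Delay risk", "Cost overrun",
      "Optimization of drug inventory",
      "Improving care in Emergency Department",
      "Improving care in Internal Medicine",
      "Improving care in Ginecobstetrics",
      "Improving customer information system",
      "Improving information lead time"
    )
  )
  influence_example <- matrix(
    c(0, 4, 3,
      3, 0, 3,
      3, 4, 0),
    3, 3, byrow = TRUE, dimnames = rep(list(c("OE", "RG", "HP")), 2)
  )
  comparison_example <- matrix(
    c(1, 9, 8,
      1 / 9, 1, 1 / 9,
      1 / 8, 9, 1),
    3, 3, byrow = TRUE, dimnames = rep(list(c("AC", "T", "HR")), 2)
  )
  list(network = network, elements = elements,
       influence_example = influence_example,
       comparison_example = comparison_example)
}

#' @rdname sixsigma_model
#' @param seed integer seed for the synthetic judgments.
#' @param noise,n_participants see [synthesis_spec()].
#' @return for `sixsigma_judgments()`: a list of [judgment_set()] objects on
#'   the case-study structure (synthetic — the study's raw judgments are
#'   unpublished).
#' @export
sixsigma_judgments <- function(seed = 1, noise = 0.1, n_participants = 6) {
  spec <- synthesis_spec(n_participants = n_participants, noise = noise,
                         seed = seed)
  synth_model(spec, network = sixsigma_model()$network)$judgment_sets
}
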