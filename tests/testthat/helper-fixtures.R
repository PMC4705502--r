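# Shared fixture builders; everything is generated in code.

# random reciprocal comparison matrix with entries snapped to the Saaty scale
rand_reciprocal <- function(n) {
  A <- diag(n)
  vals <- c(1 / (9:2), 1:9)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    A[i, j] <- sample(vals, 1)
    A[j, i] <- 1 / A[i, j]
  }
  dimnames(A) <- rep(list(paste0("E", seq_len(n))), 2)
  A
}

# random column-stochastic matrix with strictly positive entries
rand_stochastic <- function(n) {
  W <- matrix(stats::rexp(n * n) + 0.01, n, n)
  W <- sweep(W, 2, colSums(W), "/")
  dimnames(W) <- rep(list(paste0("N", seq_len(n))), 2)
  W
}

# random 0-4 influence matrix with zero diagonal, no zero column and at
# least one positive entry (so the full DEMATEL chain is defined)
rand_influence <- function(n) {
  A <- matrix(sample(0:4, n * n, replace = TRUE), n, n)
  diag(A) <- 0
  for (j in which(colSums(A) == 0)) A[if (j == 1) 2 else 1, j] <- 1
  A
}

# the illustrative strategy-cluster influence matrix of the bundled case study
strategy_influence <- function() sixsigma_model()$influence_example

# the illustrative cost-cluster comparison matrix of the bundled case study
cost_comparison <- function() sixsigma_model()$comparison_example

# a tiny two-cluster model with hand-checkable judgments
tiny_model <- function() {
  net <- decision_network(
    goal = "pick",
    clusters = list(
      cluster("Strategies", "strategy", c("T1", "T2")),
      cluster("Main", "criterion", c("K1", "K2"))
    ),
    alternatives = c("A", "B"),
    blocks = list(list(from = "Strategies", to = "Strategies"),
                  list(from = "Main", to = "Main"),
                  list(from = "Main", to = "alternatives")),
    cluster_weights = c(Main = 1)
  )
  # a12 = r: the first element is r times as important as the second
  two <- function(r, labs) {
    matrix(c(1, 1 / r, r, 1), 2, 2, dimnames = rep(list(labs), 2))
  }
  js <- judgment_set(
    "p1",
    anp = list(
      Strategies = two(1 / 2, c("T1", "T2")),
      Main = two(3, c("K1", "K2")),          # K1 three times K2 -> (0.75, 0.25)
      K1 = two(3, c("A", "B")),              # A three times B under K1
      K2 = two(1 / 3, c("A", "B"))           # B three times A under K2
    ),
    dematel = list(
      Strategies = matrix(c(0, 1, 2, 0), 2, 2,
                          dimnames = rep(list(c("T1", "T2")), 2)),
      Main = matrix(c(0, 2, 1, 0), 2, 2,
                    dimnames = rep(list(c("K1", "K2")), 2))
    )
  )
  list(network = net, judgments = js)
}

# quiet synthetic model: no influence-score clipping warnings
quiet_synth <- function(seed, n_participants = 1, noise = 0,
                        dematel_noise = 0, ...) {
  suppressWarnings(
    synth_model(synthesis_spec(seed = seed, n_participants = n_participants,
                               noise = noise, dematel_noise = dematel_noise,
                               ...))
  )
}
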