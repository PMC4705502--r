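#' Normalise a DEMATEL direct-relation matrix
#'
#' The direct-relation matrix `A` collects pairwise influence scores on the
#' 0--4 scale (no influence to very high influence; real-valued after group
#' aggregation). The normalisation constant is
#' `k = min(1 / max_i sum_j |a_ij|, 1 / max_j sum_i |a_ij|)` — the two-term
#' minimum over the largest absolute row sum and column sum — and the
#' normalised matrix is `M = k * A`.
#'
#' @param A square non-negative matrix with zero diagonal and at least one
#'   positive entry.
#' @param labels optional element labels.
#' @return a list with components `k` and `M`.
#' @export
#' @examples
#' A <- matrix(c(0, 4, 3, 3, 0, 3, 3, 4, 0), 3, 3, byrow = TRUE)
#' normalize_direct_matrix(A)$k # 0.125
normalize_direct_matrix <- function(A, labels = NULL) {
  A <- label_matrix(as.matrix(A), labels)
  check_influence_matrix(A)
  if (all(A == 0)) stopf("all-zero influence matrix: k is undefined")
  k <- min(1 / max(rowSums(abs(A))), 1 / max(colSums(abs(A))))
  list(k = k, M = k * A)
}

check_influence_matrix <- function(A, context = NULL) {
  where <- if (is.null(context)) "" else sprintf(" ('%s')", context)
  if (!is_square(A)) stopf("influence matrix%s must be square", where)
  if (any(A < 0)) stopf("influence matrix%s has negative entries", where)
  if (any(diag(A) != 0)) stopf("influence matrix%s must have a zero diagonal",
                               where)
  invisible(A)
}

#' Total-relation matrix
#'
#' Accumulates direct and all indirect influence:
#' `S = M + M^2 + ... = M (I - M)^{-1}`, which converges exactly when the
#' spectral radius of `M` is below 1. The inverse is computed by a linear
#' solve; a reciprocal-condition estimate below 1e-12 raises a warning.
#'
#' @param M normalised direct-relation matrix (from
#'   [normalize_direct_matrix()]).
#' @return the total-relation matrix `S`.
#' @export
total_relation <- function(M) {
  M <- as.matrix(M)
  if (!is_square(M)) stopf("'M' must be square")
  rho <- max(Mod(eigen(M, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12) {
    stopf("total-relation series does not converge: spectral radius %.6f >= 1",
          rho)
  }
  IM <- diag(nrow(M)) - M
  rc <- rcond(IM)
  if (rc < 1e-12) {
    warnf("(I - M) is ill-conditioned (rcond = %.3g); results may be inaccurate",
          rc)
  }
  S <- t(solve(t(IM), t(M)))  # M %*% solve(IM), via one linear solve
  dimnames(S) <- dimnames(M)
  S
}

#' Prominence and relation indices
#'
#' Row sums `D` (influence dispatched) and column sums `R` (influence
#' received) of the total-relation matrix give the prominence `D + R` (how
#' involved an element is) and the relation `D - R` (its net causal
#' direction).
#'
#' @param S total-relation matrix.
#' @return a tibble with one row per element: `element`, `D`, `R`,
#'   `prominence`, `relation`.
#' @export
prominence_relation <- function(S) {
  S <- label_matrix(as.matrix(S))
  if (!is_square(S)) stopf("'S' must be square")
  D <- rowSums(S)
  R <- colSums(S)
  tibble(element = rownames(S), D = unname(D), R = unname(R),
         prominence = unname(D + R), relation = unname(D - R))
}

#' Classify elements as dispatchers or receivers
#'
#' Elements with positive relation (`D - R`) exert net influence and are
#' dispatchers (high priority as causes); negative relation marks receivers.
#' A relation within `tol` of zero is labelled neutral: with group-averaged
#' scores an exactly balanced element is possible and belongs to neither
#' camp.
#'
#' @param relation numeric vector of `D - R` values.
#' @param tol classification tolerance around zero.
#' @return character vector in `{"dispatcher", "receiver", "neutral"}`.
#' @export
#' @examples
#' classify_roles(c(0.842, -1.424, 0.582))
classify_roles <- function(relation, tol = 1e-9) {
  if (!all(is.finite(relation))) stopf("'relation' must be finite")
  dplyr::case_when(relation > tol ~ "dispatcher",
                   relation < -tol ~ "receiver",
                   TRUE ~ "neutral")
}

#' Inner-dependence matrix
#'
#' Column-normalises the total-relation matrix so every column sums to 1.
#' Column `j` is then the relative influence profile received by the other
#' elements when `j` is stimulated, and is used as a within-cluster
#' supermatrix block in the hybrid DEMATEL-ANP coupling.
#'
#' @param S total-relation matrix with strictly positive column sums.
#' @return a column-stochastic matrix.
#' @export
inner_dependence <- function(S) {
  S <- label_matrix(as.matrix(S))
  cs <- colSums(S)
  if (any(cs <= 0)) {
    stopf("zero column sum for element '%s': inner dependence undefined",
          colnames(S)[which(cs <= 0)[1]])
  }
  sweep(S, 2, cs, "/")
}

#' Run the full DEMATEL procedure on one influence matrix
#'
#' Normalisation, total-relation matrix, prominence/relation indices,
#' dispatcher/receiver classification and the inner-dependence matrix in one
#' call.
#'
#' @inheritParams normalize_direct_matrix
#' @param tol role-classification tolerance passed to [classify_roles()].
#' @return an object of class `dematel` with fields `labels`, `A`, `k`, `M`,
#'   `S`, `inner_dependence` and a per-element `table` (the [tidy()] view).
#' @export
#' @examples
#' A <- matrix(c(0, 4, 3, 3, 0, 3, 3, 4, 0), 3, 3, byrow = TRUE,
#'             dimnames = rep(list(c("OE", "RG", "HP")), 2))
#' fit <- dematel(A)
#' tidy(fit)
dematel <- function(A, labels = NULL, tol = 1e-9) {
  norm <- normalize_direct_matrix(A, labels)
  S <- total_relation(norm$M)
  tab <- prominence_relation(S)
  tab$role <- classify_roles(tab$relation, tol)
  structure(
    list(labels = rownames(S), A = label_matrix(as.matrix(A), labels),
         k = norm$k, M = norm$M, S = S,
         inner_dependence = inner_dependence(S), table = tab),
    class = "dematel"
  )
}

#' @export
print.dematel <- function(x, ...) {
  cat(sprintf("<dematel> %d elements, k = %.6g\n", length(x$labels), x$k))
  print(x$table)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DEMATEL fit
#'
#' @param x a `dematel` object.
#' @param ... unused.
#' @return one row per element: `element`, `D`, `R`, `prominence`,
#'   `relation`, `role`.
#' @export
tidy.dematel <- function(x, ...) x$table

#' @rdname tidy.dematel
#' @return for `glance()`: a one-row tibble with `n`, `k`, the spectral
#'   radius of `M`, total influence mass and the dispatcher count.
#' @export
glance.dematel <- function(x, ...) {
  tibble(
    n = length(x$labels),
    k = x$k,
    spectral_radius = max(Mod(eigen(x$M, only.values = TRUE)$values)),
    total_influence = sum(x$S),
    n_dispatchers = sum(x$table$role == "dispatcher"),
    n_receivers = sum(x$table$role == "receiver")
  )
}

#' Cause-effect plot of a DEMATEL fit
#'
#' Prominence (`D + R`) against relation (`D - R`); dispatchers sit above
#' the horizontal axis, receivers below.
#'
#' @param object a `dematel` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dematel <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$prominence, y = .data$relation,
                               colour = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$element),
                       vjust = -0.8, show.legend = FALSE) +
    ggplot2::labs(x = "Prominence (D + R)", y = "Relation (D - R)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
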