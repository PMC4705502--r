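#' Validate a pairwise-comparison matrix
#'
#' Checks the defining properties of a Saaty-scale reciprocal matrix: unit
#' diagonal, reciprocity (`a_ji = 1/a_ij`), and entries within `[1/9, 9]`.
#' Non-positive entries are a hard error; the other properties are reported
#' as a violation table so elicitation mistakes can be located.
#'
#' @param A positive square matrix.
#' @param tol reciprocity/diagonal tolerance.
#' @return a list with `valid` (logical) and `violations` (tibble with
#'   columns `row`, `col`, `type`, `value`).
#' @export
#' @examples
#' A <- matrix(c(1, 9, 8, 1/9, 1, 1/9, 1/8, 9, 1), 3, 3, byrow = TRUE)
#' validate_reciprocal(A)$valid
validate_reciprocal <- function(A, tol = 1e-9) {
  A <- label_matrix(as.matrix(A))
  if (!is_square(A)) stopf("comparison matrix must be square")
  if (any(A <= 0)) {
    bad <- which(A <= 0, arr.ind = TRUE)[1, ]
    stopf("comparison matrix has non-positive entry at (%s, %s)",
          rownames(A)[bad[1]], colnames(A)[bad[2]])
  }
  n <- nrow(A)
  v <- list()
  for (i in seq_len(n)) {
    if (abs(A[i, i] - 1) > tol) {
      v[[length(v) + 1]] <- tibble(row = rownames(A)[i], col = colnames(A)[i],
                                   type = "diagonal", value = A[i, i])
    }
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (abs(A[j, i] - 1 / A[i, j]) > tol) {
        v[[length(v) + 1]] <- tibble(row = rownames(A)[j], col = colnames(A)[i],
                                     type = "reciprocity", value = A[j, i])
      }
    }
  }
  out_of_scale <- which(A < 1 / 9 - tol | A > 9 + tol, arr.ind = TRUE)
  if (nrow(out_of_scale)) {
    for (r in seq_len(nrow(out_of_scale))) {
      i <- out_of_scale[r, 1]; j <- out_of_scale[r, 2]
      v[[length(v) + 1]] <- tibble(row = rownames(A)[i], col = colnames(A)[j],
                                   type = "scale", value = A[i, j])
    }
  }
  violations <- if (length(v)) bind_rows(v) else {
    tibble(row = character(), col = character(),
           type = character(), value = numeric())
  }
  list(valid = nrow(violations) == 0, violations = violations)
}

#' Principal-eigenvector priorities of a comparison matrix
#'
#' Power iteration from a uniform start vector to the principal eigenvector,
#' normalised to sum 1; the principal eigenvalue is recovered as the
#' Rayleigh quotient at convergence. For a positive matrix the principal
#' eigenvalue is simple and real (Perron-Frobenius), so the iteration always
#' converges; the iteration cap is a guard only.
#'
#' @param A positive reciprocal comparison matrix.
#' @param tol convergence tolerance on the max-norm change of the weight
#'   vector.
#' @param max_iter iteration cap.
#' @return an object of class `anp_priorities`: list with `weights` (named,
#'   sums to 1), `lambda_max`, `iterations`.
#' @export
#' @examples
#' A <- matrix(c(1, 9, 8, 1/9, 1, 1/9, 1/8, 9, 1), 3, 3, byrow = TRUE)
#' principal_priorities(A)$lambda_max # 3.5
principal_priorities <- function(A, tol = 1e-12, max_iter = 10000L) {
  A <- label_matrix(as.matrix(A))
  if (any(A <= 0)) stopf("comparison matrix must be strictly positive")
  n <- nrow(A)
  w <- rep(1 / n, n)
  iterations <- 0L
  repeat {
    v <- as.vector(A %*% w)
    v <- v / sum(v)
    iterations <- iterations + 1L
    if (max(abs(v - w)) < tol) { w <- v; break }
    w <- v
    if (iterations >= max_iter) {
      stopf("power iteration failed to converge in %d iterations", max_iter)
    }
  }
  # polish: a few extra iterations push the residual of the linearly
  # convergent iteration well below the stopping increment
  for (extra in 1:8) {
    v <- as.vector(A %*% w)
    w <- v / sum(v)
  }
  lambda_max <- sum(A %*% w)  # Rayleigh quotient with sum(w) = 1
  structure(list(weights = stats::setNames(w, rownames(A)),
                 lambda_max = lambda_max, iterations = iterations),
            class = "anp_priorities")
}

#' @export
print.anp_priorities <- function(x, ...) {
  cat(sprintf("<anp_priorities> lambda_max = %.6g (%d iterations)\n",
              x$lambda_max, x$iterations))
  print(round(x$weights, 5))
  invisible(x)
}

# Random index (RI) for matrix orders 2..10; the standard table for the
# Saaty 1-9 scale. Orders above 10 are rejected rather than extrapolated.
RI_TABLE <- c(`2` = 0, `3` = 0.58, `4` = 0.9, `5` = 1.12, `6` = 1.24,
              `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.51)

#' Consistency index and ratio of a comparison matrix
#'
#' `CI = (lambda_max - n) / (n - 1)`; `CR = CI / RI` with the random index
#' RI looked up by matrix order (2--10). CI is zero exactly when judgments
#' are fully consistent (`lambda_max = n`); `CR <= 0.1` is the conventional
#' acceptability threshold. For `n = 2` RI is 0 and a reciprocal matrix is
#' always consistent, so CR is defined as 0; a positive CI at `n = 2`
#' signals an upstream bug and errors.
#'
#' @param lambda_max principal eigenvalue.
#' @param n matrix order (2--10).
#' @param tol numeric slack on the `lambda_max >= n` Saaty bound.
#' @return one-row tibble: `n`, `lambda_max`, `CI`, `RI`, `CR`,
#'   `acceptable`.
#' @export
#' @examples
#' consistency(3.5, 3) # CI = 0.25, CR ~ 0.431
consistency <- function(lambda_max, n, tol = 1e-9) {
  if (n < 2) stopf("consistency is undefined for n < 2")
  if (n > 10) {
    stopf("unsupported matrix order n = %d: RI table covers 2 <= n <= 10", n)
  }
  if (lambda_max < n - tol) {
    stopf("lambda_max (%.9g) below matrix order %d violates the Saaty bound",
          lambda_max, n)
  }
  CI <- (lambda_max - n) / (n - 1)
  RI <- unname(RI_TABLE[as.character(n)])
  if (n == 2 && CI > tol) {
    stopf("a 2x2 reciprocal matrix cannot be inconsistent (CI = %.3g)", CI)
  }
  CR <- if (RI == 0) { if (CI <= tol) 0 else Inf } else CI / RI
  tibble(n = as.integer(n), lambda_max = lambda_max, CI = CI, RI = RI,
         CR = CR, acceptable = CR <= 0.1)
}

#' @rdname consistency
#' @param A a comparison matrix: `consistency_ratio()` computes priorities
#'   and the consistency report in one step.
#' @export
consistency_ratio <- function(A, tol = 1e-9) {
  pr <- principal_priorities(A)
  consistency(pr$lambda_max, nrow(as.matrix(A)), tol = tol)
}

#' Global weights from local and cluster weights
#'
#' The global weight of a sub-criterion is its local (within-cluster)
#' weight scaled by the cluster's relative weight: `GW = LW * RW`.
#'
#' @param LW local weight(s) in `[0, 1]`.
#' @param RW cluster relative weight(s) in `[0, 1]`.
#' @return `LW * RW`, recycled elementwise.
#' @export
#' @examples
#' global_weights(0.21883, 0.25) # 0.0547075
global_weights <- function(LW, RW) {
  if (any(LW < 0 | LW > 1) || any(RW < 0 | RW > 1)) {
    stopf("LW and RW must lie in [0, 1]")
  }
  LW * RW
}

#' Rank alternatives by weight
#'
#' Descending by weight; exact ties keep declaration (label) order, so the
#' ranking is deterministic.
#'
#' @param weight_table a data frame with columns `alternative` and `weight`
#'   (or a named numeric vector).
#' @return a tibble `alternative`, `weight`, `rank`, ordered best-first,
#'   with attribute `full_tie` when all weights are equal.
#' @export
rank_alternatives <- function(weight_table) {
  if (is.numeric(weight_table)) {
    weight_table <- tibble(alternative = names(weight_table),
                           weight = unname(weight_table))
  }
  if (!all(c("alternative", "weight") %in% names(weight_table))) {
    stopf("weight table needs 'alternative' and 'weight' columns")
  }
  out <- as_tibble(weight_table[order(-weight_table$weight,
                                      seq_len(nrow(weight_table))), ])
  out$rank <- seq_len(nrow(out))
  attr(out, "full_tie") <- nrow(out) > 1 &&
    diff(range(out$weight)) < .Machine$double.eps * 100
  out
}
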