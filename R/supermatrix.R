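#' Assemble the raw ANP supermatrix
#'
#' Builds the node-ordered partitioned supermatrix over all network elements
#' plus the alternatives. Each declared block `from -> to` is filled
#' column-wise: for a block targeting the alternatives, the column of source
#' element `x` receives the priority vector of the alternatives with respect
#' to `x`; a within-cluster block (`from == to`) is filled with a
#' column-stochastic inner-dependence matrix supplied via `inner_blocks`
#' (identity when not supplied — elements influence only themselves, the
#' independence assumption of plain ANP). Undeclared blocks stay zero and
#' alternative columns carry an identity block: alternatives are absorbing
#' sinks, which makes the limit of a hierarchical supermatrix reproduce
#' weighted-sum composition.
#'
#' @param network a [decision_network()].
#' @param priorities named list of priority vectors; for
#'   cluster-to-alternatives blocks the key is the source element label, for
#'   a cross-cluster block `from = X, to = Y` the key is `"Y|x"`.
#' @param inner_blocks named list (by cluster label) of column-stochastic
#'   within-cluster matrices; missing entries default to identity.
#' @return an object of class `supermatrix` (`form = "raw"`).
#' @export
build_supermatrix <- function(network, priorities, inner_blocks = NULL) {
  elements <- network_elements(network)
  nodes <- c(elements, network$alternatives)
  node_cluster <- stats::setNames(
    c(unlist(lapply(network$clusters,
                    function(cl) rep(cl$label, length(cl$elements)))),
      rep("alternatives", length(network$alternatives))),
    nodes
  )
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))

  take_priorities <- function(key, target_nodes) {
    p <- priorities[[key]]
    if (is.null(p)) stopf("missing priority vector for context '%s'", key)
    p <- as.numeric(p)
    if (length(p) != length(target_nodes)) {
      stopf("priority vector for '%s' has length %d, expected %d",
            key, length(p), length(target_nodes))
    }
    if (any(p < 0) || sum(p) <= 0) stopf("invalid priority vector for '%s'", key)
    p / sum(p)
  }

  for (b in network$blocks) {
    src <- network_cluster(network, b$from)
    if (identical(b$to, "alternatives")) {
      for (x in src$elements) {
        W[network$alternatives, x] <- take_priorities(x, network$alternatives)
      }
    } else if (identical(b$to, b$from)) {
      B <- inner_blocks[[b$from]]
      if (is.null(B)) B <- diag(length(src$elements))
      B <- as.matrix(B)
      if (nrow(B) != length(src$elements) || ncol(B) != length(src$elements)) {
        stopf("inner block for cluster '%s' has wrong dimension", b$from)
      }
      W[src$elements, src$elements] <- B
    } else {
      tgt <- network_cluster(network, b$to)
      for (x in src$elements) {
        key <- paste(b$to, x, sep = "|")
        W[tgt$elements, x] <- take_priorities(key, tgt$elements)
      }
    }
  }
  # alternatives are sinks
  for (a in network$alternatives) W[a, a] <- 1

  new_supermatrix(W, node_cluster, form = "raw")
}

new_supermatrix <- function(W, node_cluster, form, info = list()) {
  structure(list(W = W, nodes = colnames(W), node_cluster = node_cluster,
                 form = form, info = info),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix:%s> %d nodes, %d clusters\n", x$form,
              length(x$nodes), length(unique(x$node_cluster))))
  if (!is.null(x$info$path)) {
    cat(sprintf("  limit path: %s (%d squarings)\n",
                x$info$path, x$info$squarings))
  }
  invisible(x)
}

# Cluster-level weighting matrix: entry (target, source) is the weight given
# to the target cluster's block within a source cluster's columns. By
# default, a source cluster splits its column mass between its own inner
# block (weight `inner_weight`, when declared and not the only target) and
# the remaining target clusters, equally.
default_cluster_weights <- function(sm, inner_weight = 0.5) {
  cl <- unique(sm$node_cluster)
  cwm <- matrix(0, length(cl), length(cl), dimnames = list(cl, cl))
  for (src in setdiff(cl, "alternatives")) {
    src_cols <- sm$nodes[sm$node_cluster == src]
    mass <- vapply(cl, function(tgt) {
      sum(abs(sm$W[sm$node_cluster == tgt, src_cols, drop = FALSE]))
    }, numeric(1))
    targets <- names(mass)[mass > 0]
    if (!length(targets)) next
    if (src %in% targets && length(targets) > 1) {
      cwm[src, src] <- inner_weight
      others <- setdiff(targets, src)
      cwm[others, src] <- (1 - inner_weight) / length(others)
    } else {
      cwm[targets, src] <- 1 / length(targets)
    }
  }
  cwm["alternatives", "alternatives"] <- 1
  cwm
}

#' Weight a raw supermatrix into column-stochastic form
#'
#' Scales each block by its cluster-level weight so every non-zero column
#' sums to 1 ("all columns must sum to unity"). The cluster weight matrix
#' has one column per source cluster, giving the weight of each target
#' cluster's block; its non-zero columns must sum to 1.
#'
#' @param raw a raw `supermatrix` from [build_supermatrix()].
#' @param cluster_weight_matrix optional target-by-source cluster weighting
#'   matrix; defaults to an equal split with `inner_weight` on a declared
#'   inner block.
#' @param inner_weight default within-cluster block weight used when
#'   `cluster_weight_matrix` is not given.
#' @return a `supermatrix` with `form = "weighted"`.
#' @export
weight_supermatrix <- function(raw, cluster_weight_matrix = NULL,
                               inner_weight = 0.5) {
  stopifnot(inherits(raw, "supermatrix"))
  cwm <- cluster_weight_matrix %||% default_cluster_weights(raw, inner_weight)
  cl <- unique(raw$node_cluster)
  if (!all(cl %in% rownames(cwm)) || !all(cl %in% colnames(cwm))) {
    stopf("cluster weight matrix must cover every cluster")
  }
  W <- raw$W
  for (src in cl) {
    src_cols <- raw$nodes[raw$node_cluster == src]
    for (tgt in cl) {
      tgt_rows <- raw$nodes[raw$node_cluster == tgt]
      blk <- W[tgt_rows, src_cols, drop = FALSE]
      if (any(blk != 0)) {
        # renormalise each non-zero block column to 1 before scaling
        cs <- colSums(blk)
        nz <- cs > 0
        blk[, nz] <- sweep(blk[, nz, drop = FALSE], 2, cs[nz], "/")
        W[tgt_rows, src_cols] <- blk * cwm[tgt, src]
      }
    }
  }
  cs <- colSums(W)
  bad <- which(abs(cs - 1) > 1e-9)
  if (length(bad)) {
    node <- raw$nodes[bad[1]]
    if (raw$node_cluster[node] == "alternatives") {
      stopf("alternative column '%s' lost its sink mass", node)
    }
    stopf(paste0("column '%s' sums to %.9f after weighting; the network is ",
                 "not rankable from this node"), node, cs[bad[1]])
  }
  new_supermatrix(W, raw$node_cluster, form = "weighted",
                  info = list(cluster_weight_matrix = cwm))
}

#' Limit supermatrix
#'
#' Raises the weighted (column-stochastic) supermatrix to limiting powers by
#' repeated squaring until successive powers agree in max-norm. Cyclic
#' structures whose powers oscillate with period 2 (repeated squaring then
#' converges to one phase of the cycle) are resolved by the Cesaro average
#' of two successive powers; the `info$path` field records which route was
#' taken.
#'
#' @param weighted a column-stochastic `supermatrix` (or a plain
#'   column-stochastic matrix, treated as a single-cluster supermatrix).
#' @param tol convergence tolerance in max-norm.
#' @param max_squarings squaring cap (equivalent to the power `2^max_squarings`).
#' @return a `supermatrix` with `form = "limit"`.
#' @export
limit_supermatrix <- function(weighted, tol = 1e-10, max_squarings = 40L) {
  if (is.matrix(weighted)) {
    weighted <- label_matrix(weighted)
    weighted <- new_supermatrix(
      weighted,
      stats::setNames(rep("all", ncol(weighted)), colnames(weighted)),
      form = "weighted")
  }
  stopifnot(inherits(weighted, "supermatrix"))
  W <- weighted$W
  cs <- colSums(W)
  if (any(abs(cs[cs > 0] - 1) > 1e-8)) {
    stopf("limit_supermatrix needs a column-stochastic matrix")
  }
  P <- W
  squarings <- 0L
  repeat {
    Q <- P %*% P
    squarings <- squarings + 1L
    if (max(abs(Q - P)) < tol) { P <- Q; break }
    P <- Q
    if (squarings >= max_squarings) {
      stopf("limit supermatrix did not converge within 2^%d powers",
            max_squarings)
    }
  }
  drift <- W %*% P
  if (max(abs(drift - P)) > 1e-8) {
    # period-2 cycle: average the two phases
    P <- (P + drift) / 2
    path <- "cesaro"
  } else {
    path <- "power"
  }
  new_supermatrix(P, weighted$node_cluster, form = "limit",
                  info = c(weighted$info,
                           list(path = path, squarings = squarings)))
}

#' Normalise stabilised weights by block
#'
#' Rescales node masses cluster-block by cluster-block. Mode `"unit"` (the
#' default for new analyses) makes each block sum to 1; mode `"half"` makes
#' each block sum to 0.5, a reporting convention in which every criteria
#' cluster's local-weight column and the alternatives' global weights each
#' carry half a unit of mass, as used in the bundled case study's published
#' tables. The two modes differ only by the factor 0.5.
#'
#' @param x a limit `supermatrix`, or a named numeric vector of node masses.
#' @param blocks for the vector method, a character vector mapping each node
#'   to its block label (same names as `x`).
#' @param mode `"unit"` or `"half"`.
#' @param ... passed between methods.
#' @return a tibble `node`, `block`, `weight` with each block summing to 1
#'   (`"unit"`) or 0.5 (`"half"`).
#' @export
block_normalize <- function(x, ...) UseMethod("block_normalize")

#' @rdname block_normalize
#' @export
block_normalize.supermatrix <- function(x, mode = c("unit", "half"), ...) {
  if (x$form != "limit") stopf("block_normalize expects a converged limit")
  source_cols <- x$nodes[x$node_cluster != "alternatives"]
  mass <- rowMeans(x$W[, source_cols, drop = FALSE])
  block_normalize(stats::setNames(mass, x$nodes), blocks = x$node_cluster,
                  mode = mode)
}

#' @rdname block_normalize
#' @export
block_normalize.numeric <- function(x, blocks, mode = c("unit", "half"), ...) {
  mode <- match.arg(mode)
  if (is.null(names(x))) stopf("node masses must be named")
  blocks <- blocks[names(x)]
  target <- if (mode == "half") 0.5 else 1
  out <- tibble(node = names(x), block = unname(blocks), weight = unname(x))
  totals <- tapply(out$weight, out$block, sum)
  if (any(totals <= 0)) {
    stopf("block '%s' has zero mass: cannot normalise",
          names(totals)[which(totals <= 0)[1]])
  }
  out$weight <- as.numeric(out$weight / unname(totals[out$block]) * target)
  out
}
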