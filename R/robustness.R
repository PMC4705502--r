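#' Duplicate an alternative into a change scenario
#'
#' Builds the rank-reversal test used to probe adequacy to changes of
#' alternatives: a new alternative is added whose ratings equal those of an
#' existing one. Every alternatives-comparison matrix gains a row and
#' column copying the clone target's judgments, with the mutual comparison
#' between clone and target set to 1 (they are identical by construction),
#' so reciprocity is preserved exactly.
#'
#' @param network a [decision_network()].
#' @param judgments an aggregated [judgment_set()].
#' @param clone_of label of the alternative to duplicate.
#' @param new_label label for the clone.
#' @return an object of class `change_scenario` with fields `network`,
#'   `judgments` (the derived model), `base` (the originals) and `change`
#'   (a descriptor usable with [incremental_judgments()]).
#' @export
add_duplicate_alternative <- function(network, judgments, clone_of,
                                      new_label = paste0(clone_of, "_clone")) {
  if (!clone_of %in% network$alternatives) {
    stopf("unknown alternative '%s'", clone_of)
  }
  if (new_label %in% c(network$alternatives, network_elements(network))) {
    stopf("label '%s' already exists in the network", new_label)
  }
  new_net <- decision_network(
    goal = network$goal, clusters = network$clusters,
    alternatives = c(network$alternatives, new_label),
    blocks = network$blocks, cluster_weights = network$cluster_weights
  )
  new_j <- judgments
  for (s in subcriteria(network)) {
    m <- judgments$anp[[s]]
    if (!is.null(m)) {
      new_j$anp[[s]] <- duplicate_row_col(m, clone_of, new_label,
                                          mutual = 1, diagonal = 1)
    }
  }
  new_change_scenario(network, judgments, new_net, new_j,
                      change = list(type = "add_alternative",
                                    clone_of = clone_of,
                                    new_label = new_label))
}

#' Duplicate a sub-criterion into a change scenario
#'
#' Probes adequacy to changes of criteria: a new sub-criterion joins a
#' cluster with a weight profile equal to an existing one. The cluster's
#' within-cluster comparison matrix and (when present) its DEMATEL
#' influence matrix gain a duplicated row/column, and the clone receives an
#' alternatives-comparison matrix copied from the target's. The DEMATEL
#' diagonal stays zero after insertion.
#'
#' @inheritParams add_duplicate_alternative
#' @param cluster_label cluster receiving the clone.
#' @param clone_of label of the sub-criterion to duplicate (any cluster).
#' @export
add_duplicate_subcriterion <- function(network, judgments, cluster_label,
                                       clone_of,
                                       new_label = paste0(clone_of, "_clone")) {
  cl <- network_cluster(network, cluster_label)
  if (!clone_of %in% network_elements(network)) {
    stopf("unknown sub-criterion '%s'", clone_of)
  }
  if (new_label %in% c(network$alternatives, network_elements(network))) {
    stopf("label '%s' already exists in the network", new_label)
  }
  clusters <- lapply(network$clusters, function(x) {
    if (x$label == cluster_label) {
      cluster(x$label, x$kind, c(x$elements, new_label))
    } else x
  })
  new_net <- decision_network(
    goal = network$goal, clusters = clusters,
    alternatives = network$alternatives,
    blocks = network$blocks, cluster_weights = network$cluster_weights
  )
  new_j <- judgments
  # clone within the host cluster's matrices; the donor column is the clone
  # target when it lives in this cluster, else the new element enters as an
  # average-importance row (all ones / zero influence)
  host <- clone_of %in% cl$elements
  m <- judgments$anp[[cluster_label]]
  if (!is.null(m)) {
    new_j$anp[[cluster_label]] <- if (host) {
      duplicate_row_col(m, clone_of, new_label, mutual = 1, diagonal = 1)
    } else {
      append_row_col(m, new_label, row = 1, col = 1, diagonal = 1)
    }
  }
  d <- judgments$dematel[[cluster_label]]
  if (!is.null(d)) {
    new_j$dematel[[cluster_label]] <- if (host) {
      duplicate_row_col(d, clone_of, new_label, mutual = d[clone_of, clone_of],
                        diagonal = 0)
    } else {
      append_row_col(d, new_label, row = 0, col = 0, diagonal = 0)
    }
  }
  # the clone rates alternatives exactly like its target
  if (!is.null(judgments$anp[[clone_of]])) {
    new_j$anp[[new_label]] <- judgments$anp[[clone_of]]
  }
  new_change_scenario(network, judgments, new_net, new_j,
                      change = list(type = "add_subcriterion",
                                    cluster = cluster_label,
                                    clone_of = clone_of,
                                    new_label = new_label))
}

duplicate_row_col <- function(m, target, new_label, mutual, diagonal) {
  if (!target %in% rownames(m)) {
    stopf("'%s' not found among matrix labels", target)
  }
  n <- nrow(m)
  out <- rbind(cbind(m, m[, target]), c(m[target, ], diagonal))
  rownames(out) <- c(rownames(m), new_label)
  colnames(out) <- c(colnames(m), new_label)
  out[new_label, target] <- mutual
  out[target, new_label] <- if (diagonal == 1) 1 / mutual else mutual
  out
}

append_row_col <- function(m, new_label, row, col, diagonal) {
  out <- rbind(cbind(m, rep(col, nrow(m))), c(rep(row, ncol(m)), diagonal))
  rownames(out) <- c(rownames(m), new_label)
  colnames(out) <- c(colnames(m), new_label)
  out
}

new_change_scenario <- function(base_net, base_j, new_net, new_j, change) {
  structure(list(base = list(network = base_net, judgments = base_j),
                 network = new_net, judgments = new_j, change = change),
            class = "change_scenario")
}

#' @export
print.change_scenario <- function(x, ...) {
  ch <- x$change
  cat(sprintf("<change_scenario> %s: clone of '%s' as '%s'%s\n",
              ch$type, ch$clone_of, ch$new_label,
              if (!is.null(ch$cluster)) paste0(" in cluster '", ch$cluster, "'")
              else ""))
  invisible(x)
}

#' Rank stability between two rankings
#'
#' Compares the preference order before and after a change, over the
#' original items only (any inserted clone is ignored). `preserved` is TRUE
#' exactly when the original items keep their relative order;
#' `kendall_tau` is the Kendall rank correlation over the original items;
#' `displacements` gives each item's position shift within the
#' original-item restriction of the new order (positive = demoted).
#'
#' @param rank_before,rank_after ordered character vectors of item labels
#'   (best first), or ranking tibbles from [rank_alternatives()].
#' @return an object of class `stability_report`.
#' @export
#' @examples
#' rank_stability(c("C4", "C3", "C2"), c("C3", "C2", "C4"))
rank_stability <- function(rank_before, rank_after) {
  as_order <- function(x) {
    if (is.data.frame(x)) x$alternative %||% x$node else as.character(x)
  }
  before <- as_order(rank_before)
  after <- as_order(rank_after)
  if (!all(before %in% after)) {
    stopf("items missing from the new ranking: %s",
          paste(setdiff(before, after), collapse = ", "))
  }
  after_restricted <- after[after %in% before]
  pos_before <- match(before, before)
  pos_after <- match(before, after_restricted)
  tau <- if (length(before) > 1) {
    stats::cor(pos_before, pos_after, method = "kendall")
  } else 1
  structure(
    list(rank_before = before, rank_after = after,
         preserved = identical(before, after_restricted),
         kendall_tau = tau,
         displacements = tibble(item = before,
                                position_before = pos_before,
                                position_after = pos_after,
                                displacement = pos_after - pos_before)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> preserved: %s, Kendall tau = %.3f\n",
              x$preserved, x$kendall_tau))
  print(x$displacements)
  invisible(x)
}

#' @rdname tidy.dematel
#' @export
tidy.stability_report <- function(x, ...) x$displacements

#' @rdname tidy.dematel
#' @export
glance.stability_report <- function(x, ...) {
  tibble(preserved = x$preserved, kendall_tau = x$kendall_tau,
         max_displacement = max(abs(x$displacements$displacement)),
         n_items = length(x$rank_before))
}

#' Count the judgments a method elicits for a network
#'
#' Judgments are counted as ordered off-diagonal matrix entries,
#' `n * (n - 1)` per elicited matrix: the participant answers both
#' directions of each pair. The elicited matrices are the strategy
#' cluster's comparison matrix, one comparison matrix per criteria cluster,
#' and one alternatives-comparison matrix per sub-criterion (criteria
#' cluster weights are fixed, not elicited). DANP adds a DEMATEL influence
#' matrix for the strategy cluster and for each criteria cluster. This is
#' the only convention that reproduces the case study's totals of 500 (ANP)
#' and 550 (DANP) for a 3-strategy, 5/4/3/3-sub-criterion, 6-alternative
#' model.
#'
#' @param network a [decision_network()].
#' @param method `"anp"` or `"danp"`.
#' @return integer judgment count.
#' @export
#' @examples
#' count_judgments(sixsigma_model()$network, "anp")  # 500
#' count_judgments(sixsigma_model()$network, "danp") # 550
count_judgments <- function(network, method = c("anp", "danp")) {
  method <- match.arg(method)
  ordered_pairs <- function(n) n * (n - 1)
  cluster_sizes <- vapply(network$clusters, function(cl) length(cl$elements),
                          integer(1))
  n_alt <- length(network$alternatives)
  n_sub <- length(subcriteria(network))
  total <- sum(ordered_pairs(cluster_sizes)) +   # within-cluster comparisons
    n_sub * ordered_pairs(n_alt)                 # alternatives per sub-criterion
  if (method == "danp") {
    total <- total + sum(ordered_pairs(cluster_sizes)) # DEMATEL per cluster
  }
  as.integer(total)
}

#' Additional judgments required by a change
#'
#' Accounts for the extra elicitation burden of a change, following the
#' case study's convention. Adding an alternative costs `2 * m` new ordered
#' judgments per alternatives matrix (`m` = current alternative count), one
#' matrix per sub-criterion. Adding a sub-criterion costs `m * (m - 1)` for
#' its new alternatives matrix under either method, plus, for DANP, `2 * c`
#' new DEMATEL entries from enlarging its cluster (`c` = cluster size
#' before insertion). The published accounting excludes the enlarged
#' within-cluster pairwise-comparison matrix from both methods' increments;
#' set `include_within_cluster = TRUE` for the internally consistent count
#' in which `incremental = count(after) - count(before)`.
#'
#' @param network the base [decision_network()].
#' @param change a descriptor: `list(type = "add_alternative")` or
#'   `list(type = "add_subcriterion", cluster = <label>)` (as carried by a
#'   [add_duplicate_alternative()] / [add_duplicate_subcriterion()]
#'   scenario).
#' @param method `"anp"` or `"danp"`.
#' @param include_within_cluster also count the two new ordered rows of the
#'   enlarged within-cluster comparison matrix.
#' @return integer count of additional judgments.
#' @export
#' @examples
#' net <- sixsigma_model()$network
#' incremental_judgments(net, list(type = "add_alternative"), "anp") # 180 = 12 * 15
#' incremental_judgments(net, list(type = "add_subcriterion", cluster = "Cost"),
#'                       "anp")  # 30
#' incremental_judgments(net, list(type = "add_subcriterion", cluster = "Cost"),
#'                       "danp") # 36
incremental_judgments <- function(network, change,
                                  method = c("anp", "danp"),
                                  include_within_cluster = FALSE) {
  method <- match.arg(method)
  if (inherits(change, "change_scenario")) change <- change$change
  n_alt <- length(network$alternatives)
  total <- switch(
    change$type,
    add_alternative = 2L * n_alt * length(subcriteria(network)),
    add_subcriterion = {
      c_size <- length(network_cluster(network, change$cluster)$elements)
      inc <- n_alt * (n_alt - 1)                       # new alternatives matrix
      if (method == "danp") inc <- inc + 2L * c_size   # enlarged DEMATEL matrix
      if (include_within_cluster) inc <- inc + 2L * c_size
      inc
    },
    stopf("unknown change type '%s'", change$type)
  )
  as.integer(total)
}
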