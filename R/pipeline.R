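#' Run the plain ANP pipeline
#'
#' From an aggregated (or per-participant) set of pairwise-comparison
#' matrices to ranked alternatives: principal-eigenvector priorities per
#' context, consistency ratios, supermatrix assembly (alternatives as
#' absorbing sinks, independent elements within clusters), weighting,
#' limit, block-normalised weight table and ranking. Matrices whose
#' consistency ratio exceeds `cr_threshold` are flagged with a warning;
#' under `strict = TRUE` the run aborts listing the offending contexts
#' (consistency is usually reviewed post hoc, so warn-and-continue is the
#' default).
#'
#' @param network a [decision_network()].
#' @param judgments a [judgment_set()], or a list of them (aggregated with
#'   [aggregate_judgments()] defaults first).
#' @param strict abort when any comparison matrix has CR above
#'   `cr_threshold`.
#' @param block_norm `"unit"` or `"half"` (see [block_normalize()]).
#' @param inner_weight within-cluster block weight in the weighted
#'   supermatrix when an inner-dependence block is declared.
#' @param cr_threshold consistency-ratio acceptability threshold.
#' @param seed optional integer recorded in the run manifest.
#' @return an object of class `mcdm_result`; see [tidy.mcdm_result()].
#' @export
#' @examples
#' model <- synth_model(synthesis_spec(seed = 1, n_participants = 2))
#' res <- run_anp(model$network, model$judgment_sets)
#' tidy(res)
run_anp <- function(network, judgments, strict = FALSE,
                    block_norm = c("unit", "half"), inner_weight = 0.5,
                    cr_threshold = 0.1, seed = NULL) {
  run_pipeline(network, judgments, method = "anp", strict = strict,
               block_norm = match.arg(block_norm),
               inner_weight = inner_weight, cr_threshold = cr_threshold,
               seed = seed)
}

#' Run the hybrid DEMATEL-ANP (DANP) pipeline
#'
#' As [run_anp()], but each cluster's DEMATEL influence matrix is processed
#' into a total-relation matrix whose column-normalised form (the
#' inner-dependence matrix) replaces that cluster's within-cluster
#' supermatrix block, and local weights are coupled through it. The result
#' additionally carries per-cluster prominence/relation tables with
#' dispatcher/receiver roles.
#'
#' @inheritParams run_anp
#' @param cluster_weights `"fixed"` uses the network's declared relative
#'   weights (equal when unspecified); `"dematel"` derives relative weights
#'   of the criteria clusters by normalising each cluster's total-relation
#'   mass.
#' @return an `mcdm_result` with a non-`NULL` `roles` table.
#' @export
run_danp <- function(network, judgments, strict = FALSE,
                     block_norm = c("unit", "half"), inner_weight = 0.5,
                     cluster_weights = c("fixed", "dematel"),
                     cr_threshold = 0.1, seed = NULL) {
  run_pipeline(network, judgments, method = "danp", strict = strict,
               block_norm = match.arg(block_norm),
               inner_weight = inner_weight, cr_threshold = cr_threshold,
               cluster_weights = match.arg(cluster_weights), seed = seed)
}

# The DANP coupling rule, isolated so alternates can be swapped: local
# weights filtered through the cluster's inner-dependence matrix.
danp_couple_weights <- function(lw, inner_dep) {
  v <- as.vector(inner_dep %*% lw)
  stats::setNames(v / sum(v), names(lw))
}

run_pipeline <- function(network, judgments, method, strict, block_norm,
                         inner_weight, cr_threshold, cluster_weights = "fixed",
                         seed = NULL) {
  stopifnot(inherits(network, "decision_network"))
  if (!inherits(judgments, "judgment_set")) {
    judgments <- aggregate_judgments(judgments)
  }
  validate_judgments(network, judgments, method)
  n_alt <- length(network$alternatives)

  consistency_rows <- list()
  priorities <- list()
  lw <- list()

  prioritise <- function(A, labels, context) {
    dimnames(A) <- list(labels, labels)
    pr <- principal_priorities(A)
    rep_ <- consistency(pr$lambda_max, nrow(A))
    rep_$context <- context
    consistency_rows[[length(consistency_rows) + 1]] <<- rep_
    pr$weights
  }

  # within-cluster local weights
  for (cl in network$clusters) {
    if (length(cl$elements) == 1) {
      lw[[cl$label]] <- stats::setNames(1, cl$elements)
    } else {
      lw[[cl$label]] <- prioritise(judgments$anp[[cl$label]], cl$elements,
                                   cl$label)
    }
  }
  # alternatives with respect to each sub-criterion
  for (s in subcriteria(network)) {
    if (n_alt == 1) {
      priorities[[s]] <- stats::setNames(1, network$alternatives)
    } else {
      priorities[[s]] <- prioritise(judgments$anp[[s]], network$alternatives, s)
    }
  }
  consistency_tbl <- if (length(consistency_rows)) {
    dplyr::relocate(bind_rows(consistency_rows), "context")
  } else {
    tibble(context = character(), n = integer(), lambda_max = numeric(),
           CI = numeric(), RI = numeric(), CR = numeric(),
           acceptable = logical())
  }

  bad <- consistency_tbl$context[consistency_tbl$CR > cr_threshold]
  if (length(bad)) {
    msg <- sprintf("comparison matrices above CR threshold %.2f: %s",
                   cr_threshold, paste(bad, collapse = ", "))
    if (strict) stopf("%s", msg, class = "danpselect_consistency_error")
    warnf("%s", msg)
  }

  # DEMATEL stage (DANP only)
  dematel_fits <- NULL
  roles <- NULL
  inner_blocks <- NULL
  if (method == "danp") {
    dematel_fits <- list()
    inner_blocks <- list()
    for (cl in network$clusters) {
      if (length(cl$elements) == 1) {
        inner_blocks[[cl$label]] <- matrix(1, 1, 1,
                                           dimnames = rep(list(cl$elements), 2))
        next
      }
      A <- judgments$dematel[[cl$label]]
      fit <- withCallingHandlers(
        tryCatch(dematel(A, labels = cl$elements),
                 error = function(e) {
                   stopf("DEMATEL failed for cluster '%s': %s",
                         cl$label, conditionMessage(e))
                 }),
        warning = function(w) {
          warnf("cluster '%s': %s", cl$label, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      dematel_fits[[cl$label]] <- fit
      inner_blocks[[cl$label]] <- fit$inner_dependence
      lw[[cl$label]] <- danp_couple_weights(lw[[cl$label]],
                                            fit$inner_dependence)
    }
    roles <- bind_rows(lapply(names(dematel_fits), function(nm) {
      mutate(tidy(dematel_fits[[nm]]), cluster = nm, .before = 1)
    }))
  }

  # cluster relative weights
  rw <- criteria_weights(network)
  if (method == "danp" && cluster_weights == "dematel") {
    crits <- names(rw)
    mass <- vapply(crits, function(nm) {
      if (is.null(dematel_fits[[nm]])) 1 else sum(dematel_fits[[nm]]$S)
    }, numeric(1))
    rw <- stats::setNames(mass / sum(mass), crits)
  }

  # supermatrix route
  raw <- build_supermatrix(network, priorities, inner_blocks)
  weighted <- weight_supermatrix(raw, inner_weight = inner_weight)
  limit <- limit_supermatrix(weighted)

  # compose alternative scores: global sub-criterion weights through the
  # limit's absorbed distributions
  subs <- subcriteria(network)
  gw_sub <- unlist(lapply(criteria_clusters(network), function(cl) {
    global_weights(lw[[cl$label]], rw[[cl$label]])
  }))
  names(gw_sub) <- subs
  scores <- as.vector(limit$W[network$alternatives, subs, drop = FALSE] %*%
                        gw_sub)
  names(scores) <- network$alternatives

  # weight table
  target <- if (block_norm == "half") 0.5 else 1
  elem_rows <- bind_rows(lapply(network$clusters, function(cl) {
    w <- lw[[cl$label]] * target
    rw_cl <- if (cl$kind == "criterion") rw[[cl$label]] else NA_real_
    tibble(node = cl$elements, cluster = cl$label, kind = cl$kind,
           LW = unname(w), RW = rw_cl,
           GW = if (is.na(rw_cl)) NA_real_ else unname(w) * rw_cl)
  }))
  alt_scores <- scores / sum(scores) * target
  alt_rows <- tibble(node = network$alternatives, cluster = "alternatives",
                     kind = "alternative", LW = NA_real_, RW = NA_real_,
                     GW = unname(alt_scores))
  weights_tbl <- bind_rows(elem_rows, alt_rows)

  ranking <- rank_alternatives(tibble(alternative = network$alternatives,
                                      weight = unname(alt_scores)))

  manifest <- list(
    method = toupper(method),
    options = list(strict = strict, block_norm = block_norm,
                   inner_weight = inner_weight,
                   cr_threshold = cr_threshold,
                   cluster_weights = if (method == "danp") cluster_weights
                   else NULL),
    seed = seed,
    network = list(
      goal = network$goal,
      clusters = lapply(network$clusters,
                        function(cl) cl[c("label", "kind", "elements")]),
      alternatives = network$alternatives,
      n_nodes = length(network_elements(network)) + n_alt
    ),
    limit = list(path = limit$info$path, squarings = limit$info$squarings),
    versions = list(danpselect = as.character(utils::packageVersion("danpselect")),
                    r = paste(R.version$major, R.version$minor, sep = "."))
  )

  structure(
    list(method = toupper(method), weights = weights_tbl, ranking = ranking,
         consistency = consistency_tbl, roles = roles,
         dematel = dematel_fits, local_weights = lw, cluster_weights_used = rw,
         supermatrix = limit, manifest = manifest),
    class = "mcdm_result"
  )
}

#' @export
print.mcdm_result <- function(x, ...) {
  cat(sprintf("<mcdm_result> %s — top alternative: %s\n",
              x$method, x$ranking$alternative[1]))
  print(x$ranking)
  invisible(x)
}

#' Tidy views of a pipeline result
#'
#' `tidy()` returns the block-normalised weight table (one row per element
#' and alternative, with local, relative and global weights); `glance()`
#' summarises the run in one row.
#'
#' @param x an `mcdm_result`.
#' @param ... unused.
#' @export
tidy.mcdm_result <- function(x, ...) x$weights

#' @rdname tidy.mcdm_result
#' @export
glance.mcdm_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_matrices = nrow(x$consistency),
    max_CR = if (nrow(x$consistency)) max(x$consistency$CR) else NA_real_,
    all_consistent = all(x$consistency$acceptable),
    limit_path = x$supermatrix$info$path,
    top_alternative = x$ranking$alternative[1],
    top_weight = x$ranking$weight[1]
  )
}

#' Bar chart of alternative global weights
#'
#' @param object an `mcdm_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mcdm_result <- function(object, ...) {
  df <- object$ranking
  df$alternative <- factor(df$alternative, levels = rev(df$alternative))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alternative, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Global weight",
                  title = sprintf("%s alternative priorities", object$method)) +
    ggplot2::theme_minimal()
}
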