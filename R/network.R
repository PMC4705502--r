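#' Define a decision network
#'
#' A decision network is the structural half of an ANP / DEMATEL-ANP model:
#' a goal, ordered clusters of elements (a strategy cluster and one or more
#' criteria clusters of sub-criteria), the project alternatives, the declared
#' dependency blocks, and optional cluster relative weights (RW).
#'
#' Blocks are declared as `from -> to` pairs of cluster labels, where `from`
#' is the cluster whose elements act as "with respect to" contexts (supermatrix
#' columns) and `to` the cluster receiving priorities (supermatrix rows). The
#' reserved label `"alternatives"` refers to the alternatives block.
#'
#' @param goal goal label.
#' @param clusters a list of clusters built with [cluster()].
#' @param alternatives character vector of alternative labels.
#' @param blocks a list of `list(from =, to =)` dependency declarations.
#' @param cluster_weights optional named numeric vector of relative weights
#'   (RW) for the criteria clusters; must sum to 1. When omitted, equal
#'   weights are assumed by the pipelines.
#' @return an object of class `decision_network`.
#' @seealso [load_network()], [sixsigma_model()]
#' @export
decision_network <- function(goal, clusters, alternatives,
                             blocks = list(), cluster_weights = NULL) {
  stopifnot(is.list(clusters), length(clusters) >= 1)
  if (length(alternatives) < 1) {
    stopf("a rankable network needs at least one alternative")
  }
  labels <- unlist(lapply(clusters, `[[`, "elements"))
  all_labels <- c(labels, alternatives)
  if (anyDuplicated(all_labels)) {
    dup <- all_labels[duplicated(all_labels)][1]
    stopf("duplicate element label '%s' in network", dup)
  }
  cluster_labels <- vapply(clusters, `[[`, character(1), "label")
  if (anyDuplicated(cluster_labels)) {
    stopf("duplicate cluster label '%s'",
          cluster_labels[duplicated(cluster_labels)][1])
  }
  valid_refs <- c(cluster_labels, "alternatives")
  for (b in blocks) {
    if (!all(c("from", "to") %in% names(b))) {
      stopf("each block needs 'from' and 'to' cluster labels")
    }
    for (side in c("from", "to")) {
      if (!b[[side]] %in% valid_refs) {
        stopf("block references unknown cluster '%s'", b[[side]])
      }
    }
    if (b$from == "alternatives") {
      stopf("alternatives are sinks and cannot be a block source")
    }
  }
  criteria <- cluster_labels[vapply(clusters, `[[`, character(1), "kind") ==
                               "criterion"]
  if (!is.null(cluster_weights)) {
    missing <- setdiff(names(cluster_weights), cluster_labels)
    if (length(missing)) {
      stopf("cluster_weights names unknown cluster '%s'", missing[1])
    }
    cw <- cluster_weights[intersect(names(cluster_weights), criteria)]
    if (length(cw) && abs(sum(cw) - 1) > 1e-9) {
      stopf("criteria cluster weights must sum to 1 (got %.12f)", sum(cw))
    }
  }
  structure(
    list(goal = goal, clusters = clusters, alternatives = alternatives,
         blocks = blocks, cluster_weights = cluster_weights),
    class = "decision_network"
  )
}

#' @param label cluster label.
#' @param kind `"strategy"` or `"criterion"`.
#' @param elements ordered character vector of element labels. Ordering is
#'   authoritative: every matrix referencing this cluster is interpreted in
#'   this order.
#' @rdname decision_network
#' @export
cluster <- function(label, kind = c("criterion", "strategy"), elements) {
  kind <- match.arg(kind)
  if (length(elements) < 1) stopf("cluster '%s' has no elements", label)
  if (anyDuplicated(elements)) {
    stopf("duplicate element '%s' within cluster '%s'",
          elements[duplicated(elements)][1], label)
  }
  list(label = label, kind = kind, elements = as.character(elements))
}

#' @export
print.decision_network <- function(x, ...) {
  cat("<decision_network> goal:", x$goal, "\n")
  for (cl in x$clusters) {
    cat(sprintf("  %s [%s]: %s\n", cl$label, cl$kind,
                paste(cl$elements, collapse = ", ")))
  }
  cat("  alternatives:", paste(x$alternatives, collapse = ", "), "\n")
  cat("  blocks:", length(x$blocks), " declared\n")
  invisible(x)
}

network_elements <- function(network) {
  unlist(lapply(network$clusters, `[[`, "elements"), use.names = FALSE)
}

network_cluster_labels <- function(network) {
  vapply(network$clusters, `[[`, character(1), "label")
}

network_cluster <- function(network, label) {
  hit <- network_cluster_labels(network) == label
  if (!any(hit)) stopf("unknown cluster '%s'", label)
  network$clusters[[which(hit)[1]]]
}

criteria_clusters <- function(network) {
  Filter(function(cl) cl$kind == "criterion", network$clusters)
}

subcriteria <- function(network) {
  unlist(lapply(criteria_clusters(network), `[[`, "elements"),
         use.names = FALSE)
}

# Relative weights over the criteria clusters; equal when unspecified.
criteria_weights <- function(network) {
  crits <- vapply(criteria_clusters(network), `[[`, character(1), "label")
  if (is.null(network$cluster_weights)) {
    rw <- rep(1 / length(crits), length(crits))
  } else {
    rw <- unname(network$cluster_weights[crits])
    if (anyNA(rw)) stopf("cluster_weights missing a criteria cluster")
  }
  stats::setNames(rw, crits)
}

#' Load a decision network from a YAML or JSON document
#'
#' The config document mirrors the [decision_network()] arguments:
#' `goal`, `clusters` (each with `label`, `kind`, `elements`),
#' `alternatives`, `blocks` (`from`/`to` pairs) and optional
#' `cluster_weights`. Element ordering is preserved exactly as listed.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` document, or an
#'   already-parsed list.
#' @return a validated `decision_network`.
#' @export
#' @examples
#' f <- system.file("extdata", "sixsigma_network.yaml", package = "danpselect")
#' load_network(f)
load_network <- function(path) {
  doc <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("goal", "clusters", "alternatives")) {
    if (is.null(doc[[field]])) stopf("network document lacks '%s'", field)
  }
  clusters <- lapply(doc$clusters, function(cl) {
    cluster(label = cl$label, kind = cl$kind %||% "criterion",
            elements = unlist(cl$elements))
  })
  cw <- doc$cluster_weights
  if (!is.null(cw)) cw <- unlist(cw)
  decision_network(
    goal = doc$goal, clusters = clusters,
    alternatives = unlist(doc$alternatives),
    blocks = doc$blocks %||% list(),
    cluster_weights = cw
  )
}

#' Bundle one participant's judgment matrices
#'
#' A judgment set holds one participant's ANP pairwise-comparison matrices
#' (keyed by context: a cluster label for within-cluster comparisons, a
#' sub-criterion label for alternative comparisons) and DEMATEL influence
#' matrices (keyed by cluster label).
#'
#' @param participant_id identifier of the participant (or `"group"` for an
#'   aggregated set).
#' @param anp named list of comparison matrices.
#' @param dematel named list of influence matrices.
#' @return an object of class `judgment_set`.
#' @export
judgment_set <- function(participant_id, anp = list(), dematel = list()) {
  for (nm in names(anp)) {
    if (!is_square(anp[[nm]])) stopf("ANP matrix '%s' is not square", nm)
  }
  for (nm in names(dematel)) {
    if (!is_square(dematel[[nm]])) stopf("DEMATEL matrix '%s' is not square", nm)
  }
  structure(list(participant_id = participant_id,
                 anp = anp, dematel = dematel),
            class = "judgment_set")
}

#' @export
print.judgment_set <- function(x, ...) {
  cat(sprintf("<judgment_set> participant '%s': %d ANP, %d DEMATEL matrices\n",
              x$participant_id, length(x$anp), length(x$dematel)))
  invisible(x)
}

# Check that a judgment set covers a network's elicitation contexts with
# correctly sized matrices. Returns required contexts invisibly.
validate_judgments <- function(network, judgments, method = c("anp", "danp")) {
  method <- match.arg(method)
  n_alt <- length(network$alternatives)
  for (cl in network$clusters) {
    n <- length(cl$elements)
    if (n > 1) {
      m <- judgments$anp[[cl$label]]
      if (is.null(m)) stopf("missing ANP matrix for cluster '%s'", cl$label)
      if (nrow(m) != n) {
        stopf("ANP matrix '%s' is %dx%d, cluster has %d elements",
              cl$label, nrow(m), ncol(m), n)
      }
    }
    if (method == "danp" && n > 1) {
      d <- judgments$dematel[[cl$label]]
      if (is.null(d)) stopf("missing DEMATEL matrix for cluster '%s'", cl$label)
      if (nrow(d) != n) {
        stopf("DEMATEL matrix '%s' is %dx%d, cluster has %d elements",
              cl$label, nrow(d), ncol(d), n)
      }
    }
  }
  for (s in subcriteria(network)) {
    m <- judgments$anp[[s]]
    if (is.null(m)) stopf("missing alternatives matrix for sub-criterion '%s'", s)
    if (nrow(m) != n_alt) {
      stopf("alternatives matrix '%s' is %dx%d, model has %d alternatives",
            s, nrow(m), ncol(m), n_alt)
    }
  }
  invisible(c(network_cluster_labels(network), subcriteria(network)))
}

#' Load per-participant judgment matrices from a directory tree
#'
#' Expects `dir/<participant>/anp/<context>.csv` and
#' `dir/<participant>/dematel/<cluster>.csv`, as written by
#' [write_judgments()] and the `simulate` CLI command.
#'
#' @param dir root directory.
#' @return a list of [judgment_set()] objects, one per participant.
#' @export
load_judgments <- function(dir) {
  participants <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(participants)) stopf("no participant directories under '%s'", dir)
  lapply(participants, function(p) {
    read_dir <- function(sub) {
      files <- sort(list.files(file.path(p, sub), pattern = "\\.csv$",
                               full.names = TRUE))
      out <- lapply(files, read_matrix_csv)
      names(out) <- sub("\\.csv$", "", basename(files))
      out
    }
    judgment_set(basename(p), anp = read_dir("anp"),
                 dematel = read_dir("dematel"))
  })
}

#' Write a judgment set (or list of sets) as a directory tree
#'
#' @param judgments a `judgment_set` or list of them.
#' @param dir destination root directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_judgments <- function(judgments, dir) {
  if (inherits(judgments, "judgment_set")) judgments <- list(judgments)
  for (js in judgments) {
    for (sub in c("anp", "dematel")) {
      d <- file.path(dir, js$participant_id, sub)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(js[[sub]])) {
        write_matrix_csv(js[[sub]][[nm]], file.path(d, paste0(nm, ".csv")))
      }
    }
  }
  invisible(dir)
}

#' Aggregate several participants' judgments into one set
#'
#' ANP comparison matrices are combined with the element-wise geometric mean
#' (the standard aggregation of individual judgments; it preserves
#' reciprocity exactly), DEMATEL influence matrices with the element-wise
#' arithmetic mean (keeping the bounded 0--4 scale's interpretation; the
#' result is real-valued). Both schemes are selectable.
#'
#' @param judgment_sets list of [judgment_set()] objects covering identical
#'   contexts with identical dimensions.
#' @param anp_scheme,dematel_scheme `"geometric"` or `"arithmetic"`.
#' @return a single consolidated `judgment_set` with
#'   `participant_id = "group"`.
#' @export
aggregate_judgments <- function(judgment_sets,
                                anp_scheme = c("geometric", "arithmetic"),
                                dematel_scheme = c("arithmetic", "geometric")) {
  anp_scheme <- match.arg(anp_scheme)
  dematel_scheme <- match.arg(dematel_scheme)
  if (inherits(judgment_sets, "judgment_set")) judgment_sets <- list(judgment_sets)
  if (!length(judgment_sets)) stopf("need at least one judgment set")

  combine <- function(kind, scheme) {
    contexts <- names(judgment_sets[[1]][[kind]])
    for (js in judgment_sets[-1]) {
      if (!setequal(names(js[[kind]]), contexts)) {
        off <- c(setdiff(names(js[[kind]]), contexts),
                 setdiff(contexts, names(js[[kind]])))
        stopf("participant '%s' disagrees on %s context '%s'",
              js$participant_id, kind, off[1])
      }
    }
    out <- lapply(contexts, function(ctx) {
      ms <- lapply(judgment_sets, function(js) js[[kind]][[ctx]])
      dims <- vapply(ms, nrow, integer(1))
      if (length(unique(dims)) != 1) {
        stopf("dimension mismatch in %s context '%s'", kind, ctx)
      }
      agg <- if (scheme == "geometric") {
        exp(Reduce(`+`, lapply(ms, log)) / length(ms))
      } else {
        Reduce(`+`, ms) / length(ms)
      }
      dimnames(agg) <- dimnames(ms[[1]])
      agg
    })
    names(out) <- contexts
    out
  }

  judgment_set("group",
               anp = combine("anp", anp_scheme),
               dematel = combine("dematel", dematel_scheme))
}

#' Write a pipeline result bundle to disk
#'
#' Writes the weight table and ranking as CSV, and a JSON run manifest
#' recording the method, options, seed and package version. Reading the
#' weight CSV back reproduces the values exactly.
#'
#' @param result an `mcdm_result` from [run_anp()] or [run_danp()].
#' @param dir destination directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, dir) {
  if (!inherits(result, "mcdm_result")) {
    stopf("'result' must be an mcdm_result (nothing written)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(weights = file.path(dir, "weights.csv"),
             ranking = file.path(dir, "ranking.csv"),
             consistency = file.path(dir, "consistency.csv"),
             manifest = file.path(dir, "manifest.json"))
  write_table <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_table(result$weights, paths["weights"])
  write_table(result$ranking, paths["ranking"])
  write_table(result$consistency, paths["consistency"])
  jsonlite::write_json(result$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a weight table written by [write_results()]
#'
#' @param path path to a `weights.csv`.
#' @return a tibble.
#' @export
read_weight_table <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE))
}
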