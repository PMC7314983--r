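# Ranking evaluation: Mann-Whitney AUC, positive-unlabeled
# cross-validation over the known AD proteins, pooling of sweep results,
# and a random-walk-with-restart baseline over a protein network.

#' Mann-Whitney AUC
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half — computed from midranks,
#' which is exactly the all-pairs count.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (0/1 or logical), same length.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUC needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Positive-unlabeled cross-validated AUC
#'
#' Splits the known AD proteins into `k_folds` folds by a seeded shuffle.
#' For each fold, the held-out proteins are removed from the AD membership
#' row (they become unlabeled), the full iteration is re-run, and the
#' held-out proteins (positives) are scored against the proteins never
#' annotated to AD (negatives) using the final weights.  Held-out
#' positives stay as columns of the matrix — only AD's annotation of them
#' is hidden.
#'
#' @param data An `ibds_data` object.
#' @param config An [ibds_config()]; fold assignment uses a stream derived
#'   from `config$seed`, and fold `f` runs with seed `config$seed + f`.
#' @param k_folds Number of folds. Default 5.
#' @return An `ibds_eval` object: a list with `auc` (mean over folds),
#'   `fold_auc`, `folds` (tibble: `accession`, `fold`), `k_folds`, `seed`.
#' @export
cross_validated_auc <- function(data, config = ibds_config(), k_folds = 5L) {
  stopifnot(inherits(data, "ibds_data"), k_folds >= 2)
  ad_i <- ad_row_index(data)
  known <- data$universe[data$membership[ad_i, ] == 1]
  if (length(known) < k_folds) {
    abort("Need at least k_folds known target proteins")
  }
  # Fold stream: derived from the master seed, separate from the
  # acceptance-draw stream used inside run_ibds.
  known <- sort(known)
  fold_of <- withr::with_seed(
    config$seed + 104729L,
    sample(rep_len(seq_len(k_folds), length(known)))
  )
  negatives <- setdiff(data$universe, known)

  fold_auc <- purrr::map_dbl(seq_len(k_folds), function(f) {
    held_out <- known[fold_of == f]
    masked <- data
    cols <- match(held_out, masked$universe)
    masked$membership[ad_i, cols] <- 0L
    masked$table$proteins[[ad_i]] <-
      setdiff(masked$table$proteins[[ad_i]], held_out)
    masked$table$protein_count[ad_i] <-
      masked$table$protein_count[ad_i] - length(held_out)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- run_ibds(masked, cfg)
    eval_set <- c(held_out, negatives)
    auc(unname(fit$weights[eval_set]),
        eval_set %in% held_out)
  })

  structure(
    list(
      auc = mean(fold_auc),
      fold_auc = fold_auc,
      folds = tibble::tibble(accession = known, fold = fold_of),
      k_folds = as.integer(k_folds),
      seed = config$seed
    ),
    class = "ibds_eval"
  )
}

#' @export
print.ibds_eval <- function(x, ...) {
  cat("<ibds_eval> mean AUC ", format(x$auc), " over ", x$k_folds,
      " folds (", paste(format(x$fold_auc, digits = 4), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Pooled AUC over an initial-value sweep
#'
#' Concatenates the (score, label) pairs of every run in a sweep — one
#' pair per protein per run — and computes a single AUC, summarizing how
#' well the method separates positives from negatives across all initial
#' values at once.
#'
#' @param sweep An `ibds_sweep` (or plain list of `ibds_fit`s).
#' @param positives Character vector of positive accessions; all other
#'   universe proteins count as negatives.
#' @return A single AUC.
#' @export
pooled_sweep_auc <- function(sweep, positives) {
  stopifnot(length(sweep) >= 1)
  pooled <- purrr::map(sweep, function(fit) {
    tibble::tibble(
      score = unname(fit$weights),
      label = names(fit$weights) %in% positives
    )
  })
  pooled <- dplyr::bind_rows(pooled)
  auc(pooled$score, pooled$label)
}

#' Random walk with restart over a protein network
#'
#' Network-propagation baseline: a walker starts from the seed proteins
#' and at each step either follows an edge of the column-normalized
#' adjacency (probability `1 - restart`) or jumps back to a uniformly
#' chosen seed (probability `restart`).  The stationary distribution
#' scores every node.  The graph is treated as undirected; nodes with no
#' edges are given a self-loop so the walk conserves probability mass
#' (isolated nodes then retain score only through restart).
#'
#' @param edges A data frame with columns `protein_a`, `protein_b` and an
#'   optional positive `weight` (default 1 per edge).
#' @param seeds Character vector of seed nodes; all must be in the graph.
#' @param restart Restart probability in (0, 1). Default 0.5.
#' @param tol L1 convergence tolerance. Default 1e-10.
#' @param max_iter Iteration cap. Default 10000.
#' @return A tibble with columns `node` and `score` (summing to 1), sorted
#'   by score descending.
#' @export
rwr <- function(edges, seeds, restart = 0.5, tol = 1e-10, max_iter = 10000L) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b") %in% names(edges)),
            restart > 0, restart < 1)
  weight <- if ("weight" %in% names(edges)) {
    as.numeric(edges$weight)
  } else {
    rep(1, nrow(edges))
  }
  if (any(weight < 0)) {
    abort("Edge weights must be nonnegative")
  }
  nodes <- unique(c(edges$protein_a, edges$protein_b))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) {
    abort("seeds must be non-empty")
  }
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0) {
    abort(paste0("Seed(s) not in graph: ", paste(missing, collapse = ", ")))
  }
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  for (k in seq_along(ia)) {
    if (ia[k] == ib[k]) {
      a[ia[k], ia[k]] <- a[ia[k], ia[k]] + weight[k]
    } else {
      a[ia[k], ib[k]] <- a[ia[k], ib[k]] + weight[k]
      a[ib[k], ia[k]] <- a[ib[k], ia[k]] + weight[k]
    }
  }
  deg <- colSums(a)
  dangling <- deg == 0
  if (any(dangling)) {
    diag(a)[dangling] <- 1
    deg[dangling] <- 1
  }
  w_mat <- sweep(a, 2, deg, "/")          # column-stochastic
  e <- setNames(numeric(n), nodes)
  e[seeds] <- 1 / length(seeds)
  p <- e
  for (it in seq_len(max_iter)) {
    p_next <- (1 - restart) * as.vector(w_mat %*% p) + restart * e
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < tol) {
      break
    }
  }
  names(p) <- nodes
  out <- tibble::tibble(node = nodes, score = unname(p))
  dplyr::arrange(out, dplyr::desc(.data$score), .data$node)
}
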