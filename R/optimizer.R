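# The IBDS iteration.
#
# Protein weights are a probability vector over the universe.  Each
# iteration: (1) recompute every disease's similarity variance from the
# current weights; (2) fit a sparse selector of the similarity vector on
# the one-hot membership matrix — Elastic Net on four iterations out of
# five, least-angle regression on the fifth — with observation weights
# 1/sigma^2 so that diseases with many known proteins count more; (3) bump
# the selected proteins' weights by a tenth of the minimum positive weight,
# paying for it uniformly out of the unselected proteins; (4) accept or
# reject the move by a Metropolis rule under a geometrically cooling
# temperature; (5) stop when the best loss stalls.

#' Configuration for an IBDS run
#'
#' @param initial_mass Total initial weight `s` placed on the known AD
#'   proteins, in (0, 1).  Each known protein starts at `s / k`, each other
#'   protein at `(1 - s) / (N - k)`.  Default 0.6, the value at which known
#'   proteins stand out without freezing the rest of the universe.
#' @param en_per_cycle Number of consecutive Elastic Net iterations between
#'   least-angle-regression iterations. Default 4 (cycle EN,EN,EN,EN,MAR).
#' @param max_iter Maximum number of iterations. Default 500.
#' @param tol Relative best-loss change below which an iteration counts as
#'   stalled. Default 1e-8.
#' @param patience Consecutive stalled iterations before stopping. Default 25.
#' @param temperature0 Initial Metropolis temperature. Default 1.
#' @param cooling Geometric cooling factor per iteration, in (0, 1).
#'   Default 0.95.
#' @param en_l1_ratio Elastic Net mixing parameter (glmnet `alpha`).
#'   Default 0.5.
#' @param en_penalty Elastic Net penalty (glmnet `lambda`). Default 1e-3.
#' @param en_select_rel_threshold An EN coefficient is "selected" when its
#'   magnitude is at least this fraction of the largest magnitude.
#'   Default 1e-3.
#' @param lars_max_active Cap on the least-angle-regression active set;
#'   `NULL` means one less than the number of diseases.
#' @param candidate_threshold Weight above which (strictly) a protein is
#'   reported as an AD candidate. Default 0.001.
#' @param seed Integer master seed; all randomness (acceptance draws, and
#'   derived streams for sweeps and cross-validation folds) descends from it.
#' @return An `ibds_config` list.
#' @export
ibds_config <- function(initial_mass = 0.6,
                        en_per_cycle = 4L,
                        max_iter = 500L,
                        tol = 1e-8,
                        patience = 25L,
                        temperature0 = 1.0,
                        cooling = 0.95,
                        en_l1_ratio = 0.5,
                        en_penalty = 1e-3,
                        en_select_rel_threshold = 1e-3,
                        lars_max_active = NULL,
                        candidate_threshold = 0.001,
                        seed = 1L) {
  stopifnot(initial_mass > 0, initial_mass < 1,
            en_per_cycle >= 1, max_iter >= 1,
            tol > 0, patience >= 1,
            temperature0 > 0, cooling > 0, cooling < 1,
            en_l1_ratio >= 0, en_l1_ratio <= 1, en_penalty > 0,
            en_select_rel_threshold > 0, candidate_threshold >= 0)
  structure(
    list(
      initial_mass = initial_mass,
      en_per_cycle = as.integer(en_per_cycle),
      max_iter = as.integer(max_iter),
      tol = tol,
      patience = as.integer(patience),
      temperature0 = temperature0,
      cooling = cooling,
      en_l1_ratio = en_l1_ratio,
      en_penalty = en_penalty,
      en_select_rel_threshold = en_select_rel_threshold,
      lars_max_active = lars_max_active,
      candidate_threshold = candidate_threshold,
      seed = as.integer(seed)
    ),
    class = "ibds_config"
  )
}

#' Initial weight vector
#'
#' Splits a probability mass of 1 between the known target proteins and the
#' rest of the universe: each of the `k` known proteins gets `s / k`, each
#' of the `N - k` others gets `(1 - s) / (N - k)`.
#'
#' @param s Total mass on the known proteins, in (0, 1).
#' @param known_idx Integer indices of the known proteins.
#' @param n Universe size.
#' @return Numeric weight vector of length `n` summing to 1.
#' @export
init_weights <- function(s, known_idx, n) {
  stopifnot(s > 0, s < 1)
  known_idx <- unique(as.integer(known_idx))
  k <- length(known_idx)
  if (k == 0 || k >= n) {
    abort("known_idx must be a non-empty proper subset of 1..n")
  }
  if (any(known_idx < 1 | known_idx > n)) {
    abort("known_idx out of range")
  }
  w <- rep((1 - s) / (n - k), n)
  w[known_idx] <- s / k
  w
}

#' Fit one sparse selector step
#'
#' Regresses the similarity vector on the binary membership matrix with
#' per-disease observation weights (the precision weights 1/sigma^2,
#' renormalized to mean 1), using either the Elastic Net (`"EN"`, via
#' glmnet, no intercept, no standardization) or least-angle regression
#' (`"MAR"`, capped active set).
#'
#' @param membership Binary disease-by-protein matrix.
#' @param mu Numeric similarity vector (one entry per disease).
#' @param sample_weights Positive per-disease observation weights.
#' @param method `"EN"` or `"MAR"`.
#' @param config An [ibds_config()].
#' @return Numeric coefficient vector, one entry per protein.
#' @export
fit_selector <- function(membership, mu, sample_weights,
                         method = c("EN", "MAR"), config = ibds_config()) {
  method <- match.arg(method)
  stopifnot(nrow(membership) == length(mu),
            length(sample_weights) == length(mu))
  if (any(sample_weights <= 0)) {
    abort("sample_weights must be strictly positive")
  }
  p <- ncol(membership)
  if (all(membership == 0)) {
    warn("Membership matrix has no nonzero column; returning zero coefficients")
    return(numeric(p))
  }
  if (all(mu == 0)) {
    # exact solution under any positive penalty
    return(numeric(p))
  }
  sw <- sample_weights / mean(sample_weights)
  if (method == "EN") {
    coefs <- tryCatch({
      fit <- glmnet::glmnet(
        x = membership, y = mu, weights = sw,
        alpha = config$en_l1_ratio,
        lambda = config$en_penalty * c(16, 8, 4, 2, 1),
        intercept = FALSE, standardize = FALSE
      )
      as.vector(stats::coef(fit, s = config$en_penalty))[-1L]
    }, error = function(e) {
      warn(paste0("Elastic Net fit failed (", conditionMessage(e),
                  "); returning zero coefficients"))
      numeric(p)
    })
  } else {
    max_active <- config$lars_max_active %||% (nrow(membership) - 1L)
    srt <- sqrt(sw)
    coefs <- least_angle_regression(membership * srt, mu * srt,
                                    max_active = max_active)
  }
  coefs
}

#' Indices selected by a coefficient vector
#'
#' Under least-angle regression (`"MAR"`) the unselected proteins have an
#' exactly zero coefficient, so every nonzero coefficient is selected.
#' Under the Elastic Net (`"EN"`) unselected coefficients are merely small,
#' so selection keeps coefficients whose magnitude is at least
#' `rel_threshold` times the largest magnitude (empty when all are zero).
#'
#' @param coefs Numeric coefficient vector (finite).
#' @param method `"EN"` or `"MAR"`.
#' @param rel_threshold Relative magnitude threshold for `"EN"`.
#' @return Integer vector of selected indices (possibly empty).
#' @export
select_proteins <- function(coefs, method = c("EN", "MAR"),
                            rel_threshold = 1e-3) {
  method <- match.arg(method)
  stopifnot(all(is.finite(coefs)))
  if (method == "MAR") {
    return(which(coefs != 0))
  }
  m <- max(abs(coefs))
  if (m == 0) {
    return(integer(0))
  }
  which(abs(coefs) >= rel_threshold * m)
}

#' Bump selected protein weights
#'
#' Increases each selected protein's weight by a tenth of the minimum
#' strictly-positive current weight, and removes the same total mass
#' uniformly from the unselected proteins so the weights keep summing
#' to 1.  Unselected entries driven below zero are clamped at zero and the
#' deficit is re-spread over the remaining positive unselected entries.
#' If the unselected mass cannot pay for the full bump, the bump is scaled
#' down to what is available.
#'
#' @param w Nonnegative weight vector summing to 1.
#' @param selected Integer indices of the proteins to bump (a proper
#'   subset; empty means no change).
#' @return Updated weight vector: nonnegative, summing to 1.
#' @export
update_weights <- function(w, selected) {
  n <- length(w)
  selected <- unique(as.integer(selected))
  if (length(selected) == 0) {
    return(w)
  }
  if (any(selected < 1 | selected > n)) {
    abort("selected indices out of range")
  }
  if (length(selected) == n) {
    abort("Cannot bump every protein: no unselected mass to draw from")
  }
  positive <- w[w > 0]
  if (length(positive) == 0) {
    abort("Weight vector has no positive entry")
  }
  delta <- min(positive) / 10
  unselected <- setdiff(seq_len(n), selected)
  available <- sum(w[unselected])
  need <- delta * length(selected)
  if (need > available) {
    need <- available
    delta <- need / length(selected)
  }
  w[selected] <- w[selected] + delta

  remaining <- need
  for (pass in seq_len(n)) {
    pool <- unselected[w[unselected] > 0]
    if (length(pool) == 0 || remaining <= 1e-15) {
      break
    }
    share <- remaining / length(pool)
    take <- pmin(w[pool], share)
    w[pool] <- w[pool] - take
    remaining <- remaining - sum(take)
  }
  w[w < 0] <- 0
  w / sum(w)
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a candidate whose loss exceeds the current loss
#' by `delta_l` at the given temperature: 1 for any improvement, else
#' `exp(-delta_l / temperature)`.  As the temperature cools, worse moves
#' are accepted ever more rarely.
#'
#' @param delta_l Candidate loss minus current loss (vectorized).
#' @param temperature Strictly positive temperature (vectorized).
#' @return Probabilities in \[0, 1\].
#' @export
acceptance_probability <- function(delta_l, temperature) {
  if (any(temperature <= 0)) {
    abort("temperature must be strictly positive")
  }
  exp(-pmax(delta_l, 0) / temperature)
}

#' Run the IBDS iteration
#'
#' Minimizes the integral loss over disease-similarity distributions by
#' alternating Elastic Net and least-angle-regression selection steps with
#' annealed acceptance (see [ibds_config()] for all knobs).  The returned
#' ranking is computed from the best weights seen, sorted by weight
#' descending with ties broken by accession.
#'
#' @param data An `ibds_data` object (see [build_membership()] or
#'   [generate_synthetic()]).
#' @param config An [ibds_config()].
#' @return An `ibds_fit` object: a list with elements `ranking` (tibble:
#'   `accession`, `weight`, `rank`, `candidate`), `weights` (best weight
#'   vector, named by accession), `loss` (best loss), `log` (one row per
#'   iteration), `state` (final optimizer state), and `config`.
#' @examples
#' ds <- generate_synthetic(synthetic_config(
#'   n_diseases = 8, n_proteins = 60, ad_set_size = 12, seed = 1
#' ))
#' fit <- run_ibds(ds$data, ibds_config(max_iter = 20, seed = 1))
#' head(tidy(fit))
#' @export
run_ibds <- function(data, config = ibds_config()) {
  stopifnot(inherits(data, "ibds_data"))
  table <- data$table
  P <- data$membership
  n <- length(data$universe)
  ad_i <- ad_row_index(data)
  if (length(ad_i) != 1) {
    abort("Data must contain exactly one target (AD) row")
  }
  known_idx <- which(P[ad_i, ] == 1)
  if (length(known_idx) == 0) {
    abort("The target row has no known proteins to initialize from")
  }

  set.seed(config$seed)
  w <- init_weights(config$initial_mass, known_idx, n)
  loss <- total_loss(w, table, P)
  best_w <- w
  best_loss <- loss
  accepted_worse <- 0L
  stall <- 0L
  cycle <- config$en_per_cycle + 1L

  log_rows <- vector("list", config$max_iter)
  t_done <- 0L
  for (t in seq_len(config$max_iter)) {
    variances <- pmax(all_variances(w, P), .SIGMA2_FLOOR)
    sw <- 1 / variances
    method <- if (t %% cycle == 0L) "MAR" else "EN"
    coefs <- fit_selector(P, table$similarity, sw, method, config)
    sel <- select_proteins(coefs, method, config$en_select_rel_threshold)
    if (length(sel) == n) {
      sel <- sel[-which.min(w[sel])]   # keep one mass source
    }
    w_cand <- update_weights(w, sel)
    loss_cand <- total_loss(w_cand, table, P)
    if (!is.finite(loss_cand)) {
      abort(paste0(
        "Non-finite loss at iteration ", t,
        " (method ", method, ", |selected| = ", length(sel),
        ", sum(w) = ", format(sum(w_cand)), ")"
      ))
    }
    # floored so aggressive cooling cannot underflow to an invalid 0
    temperature <- max(config$temperature0 * config$cooling^t, 1e-300)
    prob <- acceptance_probability(loss_cand - loss, temperature)
    accepted <- runif(1) <= prob
    if (accepted) {
      if (loss_cand > loss) {
        accepted_worse <- accepted_worse + 1L
      }
      w <- w_cand
      loss <- loss_cand
    }
    prev_best <- best_loss
    if (loss < best_loss) {
      best_loss <- loss
      best_w <- w
    }
    rel_change <- abs(best_loss - prev_best) / max(abs(prev_best), 1e-12)
    stall <- if (rel_change < config$tol) stall + 1L else 0L

    log_rows[[t]] <- tibble::tibble(
      iteration = t, method = method, n_selected = length(sel),
      loss_candidate = loss_cand, accept_prob = unname(prob),
      accepted = accepted, loss = loss, best_loss = best_loss,
      temperature = temperature
    )
    t_done <- t
    if (stall >= config$patience) {
      break
    }
  }

  names(best_w) <- data$universe
  structure(
    list(
      ranking = rank_weights(data$universe, unname(best_w),
                             config$candidate_threshold),
      weights = best_w,
      loss = best_loss,
      log = dplyr::bind_rows(log_rows[seq_len(t_done)]),
      state = list(
        iteration = t_done,
        weights = stats::setNames(w, data$universe),
        loss = loss,
        best_loss = best_loss,
        temperature = config$temperature0 * config$cooling^t_done,
        accepted_worse_count = accepted_worse,
        converged = stall >= config$patience
      ),
      known_accessions = data$universe[known_idx],
      ad_name = ad_name(table),
      config = config
    ),
    class = "ibds_fit"
  )
}

#' @export
print.ibds_fit <- function(x, ...) {
  cat("<ibds_fit> ", length(x$weights), " proteins; ",
      x$state$iteration, " iterations",
      if (x$state$converged) " (converged)" else "", "\n",
      "  best loss: ", format(x$loss), "; candidates (> ",
      format(x$config$candidate_threshold), "): ",
      sum(x$ranking$candidate), "\n", sep = "")
  invisible(x)
}

#' Candidate proteins of a result
#'
#' Proteins whose weight strictly exceeds the candidate threshold.
#'
#' @param x An `ibds_fit`, a ranking data frame (`accession`, `weight`), or
#'   a named numeric weight vector.
#' @param threshold Weight threshold. Default 0.001.
#' @return Character vector of candidate accessions.
#' @export
candidates <- function(x, threshold = 0.001) {
  UseMethod("candidates")
}

#' @export
candidates.ibds_fit <- function(x, threshold = x$config$candidate_threshold) {
  candidates(x$weights, threshold)
}

#' @export
candidates.data.frame <- function(x, threshold = 0.001) {
  stopifnot(all(c("accession", "weight") %in% names(x)))
  x$accession[x$weight > threshold]
}

#' @export
candidates.numeric <- function(x, threshold = 0.001) {
  if (is.null(names(x))) {
    abort("A numeric weight vector must be named by accession")
  }
  names(x)[x > threshold]
}

#' Run IBDS across the grid of initial masses
#'
#' Repeats [run_ibds()] for initial masses 0.1 through 0.9, each run with
#' its own seed derived from the master seed, so that agreement across
#' initial values can be inspected and results pooled.
#'
#' @param data An `ibds_data` object.
#' @param config An [ibds_config()]; its `initial_mass` is overridden by
#'   the grid.
#' @param initial_masses Numeric vector of initial masses. Default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @return An `ibds_sweep`: a named list of `ibds_fit` objects.
#' @export
initial_value_sweep <- function(data, config = ibds_config(),
                                initial_masses = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(all(initial_masses > 0 & initial_masses < 1))
  fits <- purrr::map(initial_masses, function(s) {
    cfg <- config
    cfg$initial_mass <- s
    cfg$seed <- config$seed + 101L * as.integer(round(100 * s))
    run_ibds(data, cfg)
  })
  names(fits) <- formatC(initial_masses, format = "f", digits = 1)
  structure(fits, class = "ibds_sweep")
}

#' @export
print.ibds_sweep <- function(x, ...) {
  cat("<ibds_sweep> ", length(x), " runs (initial mass ",
      paste(names(x), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
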