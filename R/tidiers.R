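# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an IBDS fit
#'
#' One row per protein: the ranking tibble, plus whether the protein was a
#' known AD protein going into the run.
#'
#' @param x An `ibds_fit`.
#' @param ... Unused.
#' @return A tibble with columns `accession`, `weight`, `rank`,
#'   `candidate`, `known`.
#' @export
tidy.ibds_fit <- function(x, ...) {
  dplyr::mutate(x$ranking, known = .data$accession %in% x$known_accessions)
}

#' One-row summary of an IBDS fit
#'
#' @param x An `ibds_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_proteins`, `n_known`, `iterations`,
#'   `converged`, `loss` (best), `n_candidates`, `accepted_worse`,
#'   `initial_mass`, `seed`.
#' @export
glance.ibds_fit <- function(x, ...) {
  tibble::tibble(
    n_proteins = length(x$weights),
    n_known = length(x$known_accessions),
    iterations = x$state$iteration,
    converged = x$state$converged,
    loss = x$loss,
    n_candidates = sum(x$ranking$candidate),
    accepted_worse = x$state$accepted_worse_count,
    initial_mass = x$config$initial_mass,
    seed = x$config$seed
  )
}

#' Tidy an initial-value sweep
#'
#' Stacks the rankings of all runs with an `initial_mass` column.
#'
#' @param x An `ibds_sweep`.
#' @param ... Unused.
#' @return A tibble with columns `initial_mass`, `accession`, `weight`,
#'   `rank`, `candidate`.
#' @export
tidy.ibds_sweep <- function(x, ...) {
  dplyr::bind_rows(
    purrr::imap(x, function(fit, s) {
      dplyr::mutate(fit$ranking, initial_mass = as.numeric(s),
                    .before = 1)
    })
  )
}

#' Per-run summaries of an initial-value sweep
#'
#' @param x An `ibds_sweep`.
#' @param ... Unused.
#' @return One row per run, as in [glance.ibds_fit()].
#' @export
glance.ibds_sweep <- function(x, ...) {
  dplyr::bind_rows(purrr::map(unclass(x), glance))
}

#' Tidy a cross-validation report
#'
#' @param x An `ibds_eval`.
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `auc`, `n_held_out`.
#' @export
tidy.ibds_eval <- function(x, ...) {
  tibble::tibble(
    fold = seq_along(x$fold_auc),
    auc = x$fold_auc,
    n_held_out = as.integer(table(factor(x$folds$fold,
                                         levels = seq_len(x$k_folds))))
  )
}

#' One-row summary of a cross-validation report
#'
#' @param x An `ibds_eval`.
#' @param ... Unused.
#' @return A one-row tibble: `auc`, `sd_auc`, `k_folds`, `seed`.
#' @export
glance.ibds_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    sd_auc = stats::sd(x$fold_auc),
    k_folds = x$k_folds,
    seed = x$seed
  )
}
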