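# Seeded synthetic benchmark: disease-similarity and disease-protein data
# with the structure the method assumes — similar diseases share proteins
# with the (ground-truth) AD set — plus per-protein truth labels, so every
# pipeline stage is testable without any external download.

#' Configuration of the synthetic benchmark generator
#'
#' Defaults reproduce the marginal structure of the packaged reference
#' table: 39 diseases, a universe of 1,481 proteins, 184 known AD proteins,
#' and the reference per-disease set sizes.  For other dimensions the set
#' sizes are evenly spaced quantiles of the reference counts rescaled to
#' the universe size.
#'
#' @param n_diseases Number of diseases including AD. Default 39.
#' @param n_proteins Universe size. Default 1481.
#' @param ad_set_size Number of known AD proteins. Default 184.
#' @param set_sizes Optional integer vector of per-disease (non-AD) set
#'   sizes, length `n_diseases - 1`; default derived from the reference
#'   table as described above.
#' @param overlap_strength Effect size rho in \[0, 1\]: disease `i` draws
#'   `round(rho * u_i * k_i)` of its `k_i` proteins from the ground-truth
#'   AD set (`u_i ~ U(0.3, 1)`), the rest from non-AD proteins.  At 0 the
#'   data carry no signal. Default 0.7.
#' @param noise_sd Standard deviation tau of the Gaussian noise added to
#'   similarities. Default 0.05.
#' @param known_fraction Fraction of the ground-truth AD set annotated to
#'   the AD row (the rest is hidden, i.e. discoverable). Default 0.65,
#'   making the truth set about 1.5 times the known set.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_diseases = 39L,
                             n_proteins = 1481L,
                             ad_set_size = 184L,
                             set_sizes = NULL,
                             overlap_strength = 0.7,
                             noise_sd = 0.05,
                             known_fraction = 0.65,
                             seed = 1L) {
  stopifnot(n_diseases >= 3, n_proteins > ad_set_size, ad_set_size >= 2,
            overlap_strength >= 0, overlap_strength <= 1,
            noise_sd >= 0, known_fraction > 0, known_fraction <= 1)
  if (is.null(set_sizes)) {
    ref <- load_reference_disease_table()
    ref_sizes <- ref$protein_count[ref$similarity < 1]
    m <- n_diseases - 1L
    if (m == length(ref_sizes) && n_proteins == 1481L) {
      set_sizes <- ref_sizes
    } else {
      q <- stats::quantile(ref_sizes, probs = seq(0, 1, length.out = m),
                           type = 1, names = FALSE)
      set_sizes <- pmax(2L, as.integer(round(q * n_proteins / 1481)))
    }
  }
  set_sizes <- as.integer(set_sizes)
  stopifnot(length(set_sizes) == n_diseases - 1L, all(set_sizes >= 1),
            all(set_sizes <= n_proteins))
  structure(
    list(
      n_diseases = as.integer(n_diseases),
      n_proteins = as.integer(n_proteins),
      ad_set_size = as.integer(ad_set_size),
      set_sizes = set_sizes,
      overlap_strength = overlap_strength,
      noise_sd = noise_sd,
      known_fraction = known_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic benchmark dataset
#'
#' Draws a ground-truth AD protein set of size
#' `round(ad_set_size / known_fraction)`; annotates `ad_set_size` of its
#' members to the AD row (the rest are hidden positives).  Each other
#' disease `i` of set size `k_i` draws `round(rho * u_i * k_i)` proteins
#' from the truth set (`u_i ~ U(0.3, 1)`) and the rest from non-truth
#' proteins, and gets similarity
#' `clip(overlap_fraction * 0.7 + 0.3 + N(0, tau), 0.30, 0.99)`, so that
#' protein overlap with AD and symptom similarity co-vary with
#' controllable strength.  The AD row itself has similarity 1.
#'
#' @param config A [synthetic_config()].
#' @return An `ibds_synthetic` object: a list with `data` (an `ibds_data`
#'   triple over the full universe of `n_proteins` accessions), `truth`
#'   (character vector: the ground-truth AD set), `hidden` (truth members
#'   not annotated to AD), and `config`.
#' @examples
#' ds <- generate_synthetic(synthetic_config(
#'   n_diseases = 10, n_proteins = 80, ad_set_size = 15, seed = 42
#' ))
#' ds$data
#' length(ds$hidden)
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_proteins
  width <- max(4L, nchar(as.character(n)))
  universe <- sprintf(paste0("SYN%0", width, "d"), seq_len(n))
  truth_size <- min(round(config$ad_set_size / config$known_fraction),
                    n - max(config$set_sizes))
  if (truth_size < config$ad_set_size) {
    abort("Infeasible sizes: universe too small for the truth set")
  }

  withr::with_seed(config$seed, {
    truth <- sample(universe, truth_size)
    ad_known <- sample(truth, config$ad_set_size)
    non_truth <- setdiff(universe, truth)

    m <- config$n_diseases - 1L
    u <- runif(m, 0.3, 1)
    sets <- vector("list", m)
    overlap_frac <- numeric(m)
    for (i in seq_len(m)) {
      k <- config$set_sizes[i]
      n_ov <- min(round(config$overlap_strength * u[i] * k), k, truth_size)
      n_rest <- k - n_ov
      if (n_rest > length(non_truth)) {
        abort("Infeasible sizes: not enough non-truth proteins")
      }
      sets[[i]] <- c(
        if (n_ov > 0) sample(truth, n_ov) else character(),
        if (n_rest > 0) sample(non_truth, n_rest) else character()
      )
      overlap_frac[i] <- n_ov / k
    }
    similarity <- pmin(pmax(
      overlap_frac * 0.7 + 0.3 + rnorm(m, 0, config$noise_sd),
      0.30), 0.99)

    diseases <- sprintf("Synthetic disease %02d", seq_len(m))
    ad_label <- "Alzheimer's Disease"
    all_sets <- c(sets, list(ad_known))
    names(all_sets) <- c(diseases, ad_label)

    membership <- matrix(0L, nrow = m + 1L, ncol = n,
                         dimnames = list(names(all_sets), universe))
    for (i in seq_along(all_sets)) {
      membership[i, match(all_sets[[i]], universe)] <- 1L
    }
    table <- disease_table(
      disease = names(all_sets),
      similarity = c(similarity, 1),
      proteins = all_sets,
      ad_name = ad_label
    )
    structure(
      list(
        data = new_ibds_data(table, membership, universe),
        truth = sort(truth),
        hidden = sort(setdiff(truth, ad_known)),
        config = config
      ),
      class = "ibds_synthetic"
    )
  })
}

#' @export
print.ibds_synthetic <- function(x, ...) {
  cat("<ibds_synthetic> ", x$config$n_diseases, " diseases x ",
      x$config$n_proteins, " proteins; truth set ", length(x$truth),
      " (", length(x$hidden), " hidden); rho = ",
      x$config$overlap_strength, "\n", sep = "")
  invisible(x)
}

#' Per-protein truth labels of a synthetic dataset
#'
#' @param dataset An `ibds_synthetic`.
#' @return A tibble with columns `accession`, `truth` (in the ground-truth
#'   AD set), `known` (annotated to the AD row), `hidden` (truth but not
#'   annotated).
#' @export
truth_labels <- function(dataset) {
  stopifnot(inherits(dataset, "ibds_synthetic"))
  universe <- dataset$data$universe
  ad_i <- ad_row_index(dataset$data)
  known <- universe[dataset$data$membership[ad_i, ] == 1]
  tibble::tibble(
    accession = universe,
    truth = universe %in% dataset$truth,
    known = universe %in% known,
    hidden = universe %in% dataset$hidden
  )
}

#' Write a synthetic dataset as the two TSV files the readers consume
#'
#' Emits `similarities.tsv` (disease_a = AD, disease_b, similarity; the AD
#' self-pair is included) and `associations.tsv` (disease, accession), in
#' the dialects read by [read_similarity_pairs()] and
#' [read_associations()], plus `truth.tsv` with the ground-truth labels.
#'
#' @param dataset An `ibds_synthetic`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic_tsvs <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ibds_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- dataset$data$table
  ad <- ad_name(tab)

  sims <- tibble::tibble(
    disease_a = ad,
    disease_b = tab$disease,
    similarity = tab$similarity
  )
  sim_path <- file.path(dir, "similarities.tsv")
  readr::write_tsv(sims, sim_path, col_names = FALSE, progress = FALSE)

  assoc <- tidyr::unnest(
    tibble::tibble(disease = tab$disease, accession = tab$proteins),
    "accession"
  )
  assoc_path <- file.path(dir, "associations.tsv")
  readr::write_tsv(assoc, assoc_path, progress = FALSE)

  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth_labels(dataset), truth_path, progress = FALSE)

  invisible(c(similarities = sim_path, associations = assoc_path,
              truth = truth_path))
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic dataset, runs the full iteration on it, and
#' measures how well the final weights separate the hidden ground-truth AD
#' proteins (positives: truth-set members not annotated to the AD row)
#' from proteins outside the truth set (negatives).
#'
#' @param config A [synthetic_config()].
#' @param opt_config An [ibds_config()] for the optimizer run.
#' @return The recovery AUC (a single number).
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                opt_config = ibds_config()) {
  dataset <- generate_synthetic(config)
  fit <- run_ibds(dataset$data, opt_config)
  negatives <- setdiff(dataset$data$universe, dataset$truth)
  eval_set <- c(dataset$hidden, negatives)
  auc(unname(fit$weights[eval_set]), eval_set %in% dataset$hidden)
}
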