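# From raw similarity pairs and association lists to the triple the
# optimizer consumes: a disease table, a binary disease-by-protein
# membership matrix, and the ordered protein universe.

#' Default disease exclusions
#'
#' Diseases dropped from the AD neighbourhood before model fitting:
#' Williams Syndrome (a gene-deletion disorder associated with over a
#' thousand proteins, which would swamp the one-hot design) and two
#' diseases with no retrievable associated proteins.
#'
#' @return Character vector of disease names.
#' @export
default_exclusions <- function() {
  c("Williams Syndrome", "Psychomotor Agitation", "Ischemic Attack Transient")
}

#' Extract similarities with one target disease from a pair list
#'
#' Reduces a tibble of similarity pairs to the diseases paired with a
#' target (on either side of the pair).  Self-pairs are dropped.  When the
#' same disease appears in several pairs with the target with conflicting
#' similarity values, the maximum is kept and a warning is raised; symptom
#' similarity files commonly store each pair in both orientations.
#'
#' @param pairs A data frame with columns `disease_a`, `disease_b`,
#'   `similarity` (see [read_similarity_pairs()]).
#' @param target_name The target disease (matching is case-insensitive with
#'   whitespace collapsed).
#' @return A tibble with columns `disease` (normalized names) and
#'   `similarity`, one row per disease paired with the target.
#' @export
extract_target_similarities <- function(pairs, target_name) {
  stopifnot(is.data.frame(pairs),
            all(c("disease_a", "disease_b", "similarity") %in% names(pairs)))
  target <- normalize_disease_name(target_name)
  a <- normalize_disease_name(pairs$disease_a)
  b <- normalize_disease_name(pairs$disease_b)
  hit <- a == target | b == target
  if (!any(hit)) {
    abort(paste0("Target disease '", target_name,
                 "' not found in any similarity pair"))
  }
  other <- ifelse(a[hit] == target, b[hit], a[hit])
  sim <- pairs$similarity[hit]
  keep <- other != target
  out <- tibble::tibble(disease = other[keep], similarity = sim[keep])
  dups <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(out, .data$disease),
                     n_vals = dplyr::n_distinct(.data$similarity),
                     .groups = "drop"),
    .data$n_vals > 1
  )
  if (nrow(dups) > 0) {
    warn(paste0("Conflicting similarity values for ",
                nrow(dups), " disease(s) (e.g. '", dups$disease[1],
                "'); keeping the maximum"))
  }
  dplyr::summarise(dplyr::group_by(out, .data$disease),
                   similarity = max(.data$similarity), .groups = "drop")
}

#' Filter diseases by similarity threshold
#'
#' Keeps diseases whose similarity to the target is at least `threshold`
#' (inclusive: the default 0.3 retains diseases printed at 0.30).
#'
#' @param simmap A data frame with columns `disease`, `similarity`.
#' @param threshold Minimum similarity retained. Default 0.3.
#' @return The filtered tibble.
#' @export
filter_by_threshold <- function(simmap, threshold = 0.3) {
  stopifnot(is.data.frame(simmap),
            all(c("disease", "similarity") %in% names(simmap)))
  dplyr::filter(tibble::as_tibble(simmap), .data$similarity >= threshold)
}

#' Remove excluded diseases
#'
#' Drops the named diseases from a similarity map, matching
#' case-insensitively with whitespace collapsed.  Names absent from the map
#' are ignored.
#'
#' @param simmap A data frame with columns `disease`, `similarity`.
#' @param excluded Character vector of disease names to remove; defaults to
#'   [default_exclusions()].
#' @return The filtered tibble.
#' @export
apply_exclusions <- function(simmap, excluded = default_exclusions()) {
  stopifnot(is.data.frame(simmap), "disease" %in% names(simmap))
  drop <- normalize_disease_name(excluded)
  dplyr::filter(tibble::as_tibble(simmap),
                !(normalize_disease_name(.data$disease) %in% drop))
}

#' Build the disease table, membership matrix and protein universe
#'
#' Assembles the model inputs from a similarity map and per-disease protein
#' sets.  The target disease (AD) is appended as a final row with
#' similarity 1 and its own known proteins.  The protein universe is the
#' union of all protein sets, ordered by first appearance (scanning
#' diseases in `simmap` order, then the AD row; within one disease,
#' accessions in lexicographic order) so that runs are reproducible.  The
#' membership matrix is binary with one row per disease in table order and
#' one column per universe protein.
#'
#' @param simmap A data frame with columns `disease`, `similarity`
#'   (similarities in (0, 1); the target must not be present).
#' @param associations Either a data frame with columns `disease`,
#'   `accession` (see [read_associations()]) or a named list of accession
#'   character vectors.  Every disease in `simmap` must have a non-empty
#'   protein set; diseases with no known proteins must be excluded first
#'   (see [apply_exclusions()]).
#' @param ad_name Name of the target disease.
#' @param ad_proteins Non-empty character vector of the target's known
#'   protein accessions.
#' @return An `ibds_data` object: a list with elements `table` (a
#'   [disease_table()]), `membership` (binary matrix, diseases by
#'   proteins), and `universe` (ordered character vector of accessions).
#' @export
build_membership <- function(simmap, associations, ad_name, ad_proteins) {
  stopifnot(is.data.frame(simmap),
            all(c("disease", "similarity") %in% names(simmap)))
  ad_proteins <- unique(as.character(ad_proteins))
  if (length(ad_proteins) == 0) {
    abort("ad_proteins must be non-empty")
  }
  if (is.data.frame(associations)) {
    assoc <- split(associations$accession,
                   normalize_disease_name(associations$disease))
  } else {
    assoc <- setNames(associations, normalize_disease_name(names(associations)))
  }
  assoc <- purrr::map(assoc, function(p) unique(as.character(p)))

  norm <- normalize_disease_name(simmap$disease)
  if (normalize_disease_name(ad_name) %in% norm) {
    abort("The target disease must not appear in simmap; it is appended")
  }
  sets <- assoc[norm]
  missing <- purrr::map_lgl(sets, function(s) is.null(s) || length(s) == 0)
  if (any(missing)) {
    abort(paste0(
      "Disease(s) with no known proteins: ",
      paste(simmap$disease[missing], collapse = ", "),
      ". Exclude them (see apply_exclusions) before building the matrix."
    ))
  }
  names(sets) <- simmap$disease

  all_sets <- c(sets, stats::setNames(list(ad_proteins), ad_name))
  universe <- unique(unlist(purrr::map(all_sets, sort), use.names = FALSE))
  n <- length(universe)

  P <- matrix(0L, nrow = length(all_sets), ncol = n,
              dimnames = list(names(all_sets), universe))
  for (i in seq_along(all_sets)) {
    P[i, match(all_sets[[i]], universe)] <- 1L
  }

  table <- disease_table(
    disease = names(all_sets),
    similarity = c(simmap$similarity, 1),
    proteins = all_sets,
    ad_name = ad_name
  )
  new_ibds_data(table, P, universe)
}

new_ibds_data <- function(table, membership, universe) {
  stopifnot(nrow(membership) == nrow(table),
            ncol(membership) == length(universe))
  counts <- as.integer(rowSums(membership))
  if (!all(counts == table$protein_count)) {
    warn("Membership row sums differ from stored protein counts; counts recomputed from sets")
    table$protein_count <- counts
  }
  structure(
    list(table = table, membership = membership, universe = universe),
    class = "ibds_data"
  )
}

#' @export
print.ibds_data <- function(x, ...) {
  cat("<ibds_data> ", nrow(x$table), " diseases x ", length(x$universe),
      " proteins; target: ", ad_name(x$table), "\n", sep = "")
  invisible(x)
}

# Row index of the target (AD) disease in an ibds_data object.
ad_row_index <- function(data) {
  which(normalize_disease_name(data$table$disease) ==
          normalize_disease_name(ad_name(data$table)))
}
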