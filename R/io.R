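# Readers and writers for the plain-text formats the pipeline touches:
# disease-disease similarity pairs, disease-protein association lists,
# the packaged reference disease table, and ranking output.

# Read non-comment, non-empty lines of a text file, keeping original line
# numbers so parse errors can point at the offending line.
read_data_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  tibble::tibble(line = seq_along(lines)[keep], text = lines[keep])
}

# Split one line on tabs; if that yields fewer than `min_fields` fields,
# fall back to splitting on runs of whitespace.
split_fields <- function(text, min_fields) {
  fields <- strsplit(text, "\t", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  fields <- fields[fields != ""]
  if (length(fields) < min_fields) {
    fields <- strsplit(trimws(text), "\\s+")[[1]]
  }
  fields
}

#' Read a disease-disease similarity pair file
#'
#' Parses a symptom-based disease-similarity file into a tibble of pairs.
#' The dialect is deliberately loose: lines starting with `#` are ignored,
#' fields are tab-separated (falling back to whitespace separation when a
#' line has fewer than three tab fields), at least three columns are
#' required and any extra columns are ignored.  The third column must parse
#' as a similarity in \[0, 1\].  A leading header line whose third field is
#' not numeric is skipped.
#'
#' @param path Path to the similarity file.
#' @return A tibble with columns `disease_a`, `disease_b` (character) and
#'   `similarity` (numeric in \[0, 1\]), one row per input row.
#' @seealso [extract_target_similarities()] for reducing pairs to
#'   similarities with one target disease.
#' @export
read_similarity_pairs <- function(path) {
  rows <- read_data_lines(path)
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      disease_a = character(), disease_b = character(), similarity = double()
    ))
  }
  parse_one <- function(line, text) {
    fields <- split_fields(text, 3L)
    if (length(fields) < 3L) {
      abort(paste0("Malformed similarity row at line ", line,
                   ": expected at least 3 columns, got ", length(fields)))
    }
    fields[1:3]
  }
  parsed <- purrr::map2(rows$line, rows$text, parse_one)
  mat <- do.call(rbind, parsed)
  sim <- suppressWarnings(as.numeric(mat[, 3]))

  # Tolerate a single header line at the top of the file.
  if (is.na(sim[1]) && nrow(rows) >= 1) {
    rows <- rows[-1, , drop = FALSE]
    mat <- mat[-1, , drop = FALSE]
    sim <- sim[-1]
    if (nrow(rows) == 0) {
      return(tibble::tibble(
        disease_a = character(), disease_b = character(), similarity = double()
      ))
    }
  }
  bad <- which(is.na(sim))
  if (length(bad) > 0) {
    abort(paste0("Non-numeric similarity at line ", rows$line[bad[1]],
                 ": '", mat[bad[1], 3], "'"))
  }
  out_of_range <- which(sim < 0 | sim > 1)
  if (length(out_of_range) > 0) {
    abort(paste0("Similarity out of [0, 1] at line ",
                 rows$line[out_of_range[1]], ": ", sim[out_of_range[1]]))
  }
  tibble::tibble(disease_a = mat[, 1], disease_b = mat[, 2], similarity = sim)
}

#' Read a disease-protein association file
#'
#' Parses a two-column, tab-separated file mapping diseases to protein
#' accessions.  Disease names are normalized (case-folded, whitespace
#' collapsed) and accessions are deduplicated within each disease.  Lines
#' starting with `#` are ignored; a header line reading
#' `disease<TAB>accession` (or `protein`) is skipped.
#'
#' @param path Path to the association file.
#' @return A tibble with columns `disease` (normalized name) and
#'   `accession`, one row per unique pair.
#' @export
read_associations <- function(path) {
  rows <- read_data_lines(path)
  empty <- tibble::tibble(disease = character(), accession = character())
  if (nrow(rows) == 0) {
    return(empty)
  }
  parse_one <- function(line, text) {
    fields <- strsplit(text, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 2L || any(fields[1:2] == "")) {
      abort(paste0("Malformed association row at line ", line,
                   ": expected 2 tab-separated columns (disease, accession)"))
    }
    fields[1:2]
  }
  parsed <- purrr::map2(rows$line, rows$text, parse_one)
  mat <- do.call(rbind, parsed)
  if (tolower(mat[1, 1]) == "disease" &&
      tolower(mat[1, 2]) %in% c("accession", "protein", "protein_accession")) {
    mat <- mat[-1, , drop = FALSE]
  }
  if (nrow(mat) == 0) {
    return(empty)
  }
  dplyr::distinct(
    tibble::tibble(
      disease = normalize_disease_name(mat[, 1]),
      accession = mat[, 2]
    )
  )
}

#' Construct a disease table
#'
#' A disease table is the container for the per-disease inputs of the
#' ranking method: one row per disease with its similarity to the target
#' disease (the mean of that disease's similarity distribution), its known
#' associated proteins, and the known-protein count.  Exactly one row — the
#' target itself — must have similarity 1.
#'
#' @param disease Character vector of unique disease names.
#' @param similarity Numeric vector of similarities in (0, 1\].
#' @param proteins List of character vectors of protein accessions (may be
#'   empty vectors when only counts are known).
#' @param protein_count Integer vector of known-protein counts; when
#'   `proteins` is non-empty it must equal the set size.
#' @param ad_name Name of the target (AD) row; must match the row with
#'   similarity 1 after name normalization.
#' @return A `disease_table`: a tibble with columns `disease`, `similarity`,
#'   `proteins` (list-column), `protein_count`, and attribute `ad_name`.
#' @export
disease_table <- function(disease, similarity, proteins = NULL,
                          protein_count = NULL, ad_name) {
  disease <- as.character(disease)
  if (anyDuplicated(normalize_disease_name(disease))) {
    abort("Disease names must be unique (after normalization)")
  }
  if (any(similarity <= 0 | similarity > 1)) {
    abort("Similarities must lie in (0, 1]")
  }
  if (is.null(proteins)) {
    proteins <- rep(list(character()), length(disease))
  }
  proteins <- purrr::map(proteins, function(p) unique(as.character(p)))
  if (is.null(protein_count)) {
    protein_count <- purrr::map_int(proteins, length)
  }
  protein_count <- as.integer(protein_count)
  set_sizes <- purrr::map_int(proteins, length)
  nonempty <- set_sizes > 0
  if (any(protein_count[nonempty] != set_sizes[nonempty])) {
    abort("protein_count must equal the protein set size where sets are given")
  }
  ad_idx <- which(normalize_disease_name(disease) ==
                    normalize_disease_name(ad_name))
  if (length(ad_idx) != 1) {
    abort(paste0("Target disease '", ad_name, "' must appear exactly once"))
  }
  if (sum(similarity == 1) != 1 || similarity[ad_idx] != 1) {
    abort("Exactly one row (the target disease) must have similarity 1")
  }
  out <- tibble::tibble(
    disease = disease,
    similarity = as.numeric(similarity),
    proteins = proteins,
    protein_count = protein_count
  )
  attr(out, "ad_name") <- disease[ad_idx]
  class(out) <- c("disease_table", class(out))
  out
}

#' Name of the target (AD) row of a disease table
#'
#' @param table A `disease_table`.
#' @return The target disease name as stored in the table.
#' @export
ad_name <- function(table) {
  attr(table, "ad_name")
}

#' Load the packaged reference disease table
#'
#' Returns the packaged table of 39 diseases (38 AD-related diseases plus
#' AD itself): for each, the symptom-based similarity to AD and the number
#' of known associated proteins.  Protein sets are empty in this fixture;
#' only the counts are known.  The known-protein counts total 2,088 over
#' the 39 rows, of which 184 belong to the AD row.
#'
#' @return A `disease_table` with 39 rows.
#' @examples
#' tab <- load_reference_disease_table()
#' sum(tab$protein_count)
#' @export
load_reference_disease_table <- function() {
  path <- system.file("extdata", "ad_disease_table.tsv", package = "ibds",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  disease_table(
    disease = raw$disease,
    similarity = raw$similarity,
    protein_count = raw$protein_count,
    ad_name = "Alzheimer's Disease"
  )
}

#' Rank proteins by weight
#'
#' Sorts proteins by weight (descending), breaking ties by accession in
#' lexicographic order, and flags candidates whose weight strictly exceeds
#' the candidate threshold.
#'
#' @param accession Character vector of protein accessions.
#' @param weight Numeric vector of protein weights.
#' @param candidate_threshold Weight above which (strictly) a protein is
#'   flagged as an AD-candidate. Default 0.001.
#' @return A tibble with columns `accession`, `weight`, `rank`, `candidate`,
#'   sorted by rank.
#' @export
rank_weights <- function(accession, weight, candidate_threshold = 0.001) {
  stopifnot(length(accession) == length(weight))
  ord <- order(-weight, accession, method = "radix")
  w_sorted <- weight[ord]
  tibble::tibble(
    accession = accession[ord],
    weight = w_sorted,
    rank = seq_along(ord),
    candidate = w_sorted > candidate_threshold
  )
}

#' Write a protein ranking to a TSV file
#'
#' Writes a ranking (as produced by [rank_weights()] or carried by an IBDS
#' fit) as a tab-separated file with a header, sorted by rank ascending.
#' Weights are printed with full precision (at least 6 significant digits),
#' so re-reading the file reproduces the ordering and weights.
#'
#' @param ranking A data frame with columns `accession`, `weight`, `rank`,
#'   `candidate`; `rank` must be a permutation of `1:nrow`.
#' @param path Output path.
#' @return The input `ranking`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(is.data.frame(ranking),
            all(c("accession", "weight", "rank", "candidate") %in%
                  names(ranking)))
  if (!all(is.finite(ranking$weight))) {
    abort("Ranking weights must be finite")
  }
  if (!setequal(ranking$rank, seq_len(nrow(ranking)))) {
    abort("Ranks must be a permutation of 1..N")
  }
  out <- dplyr::arrange(
    ranking[, c("accession", "weight", "rank", "candidate")], .data$rank
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(ranking)
}

#' Read a protein ranking written by [write_ranking()]
#'
#' @param path Path to a ranking TSV.
#' @return A tibble with columns `accession`, `weight`, `rank`, `candidate`.
#' @export
read_ranking <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    accession = readr::col_character(),
                    weight = readr::col_double(),
                    rank = readr::col_integer(),
                    candidate = readr::col_logical()
                  ))
}
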