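# Shared fixtures, built in code.

# A small ibds_data triple built by hand: three diseases plus the AD row.
toy_data <- function() {
  simmap <- tibble::tibble(
    disease = c("dementia", "brain injuries", "cadasil"),
    similarity = c(0.9, 0.48, 0.33)
  )
  assoc <- tibble::tibble(
    disease = c("dementia", "dementia", "brain injuries", "brain injuries",
                "cadasil"),
    accession = c("A1", "B1", "B1", "C1", "D1")
  )
  build_membership(simmap, assoc, ad_name = "alzheimer disease",
                   ad_proteins = c("A1", "E1"))
}

# A small synthetic dataset for optimizer-level tests.
small_synthetic <- function(seed = 7, rho = 0.8) {
  generate_synthetic(synthetic_config(
    n_diseases = 10L, n_proteins = 90L, ad_set_size = 15L,
    overlap_strength = rho, noise_sd = 0.03, seed = seed
  ))
}

# Write lines to a temp file and return its path.
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Row index of the target disease (similarity 1) in an ibds_data object.
ad_row_index_for_test <- function(data) {
  which(data$table$similarity == 1)
}

# Brute-force AUC over all positive-negative pairs (ties count 0.5).
pair_count_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}
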