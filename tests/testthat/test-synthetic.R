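test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_diseases = 10, n_proteins = 80, ad_set_size = 15,
                          seed = 5)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$data$membership, b$data$membership)
  expect_identical(a$data$table$similarity, b$data$table$similarity)
  expect_identical(a$truth, b$truth)

  c <- generate_synthetic(synthetic_config(
    n_diseases = 10, n_proteins = 80, ad_set_size = 15, seed = 6
  ))
  expect_false(identical(a$truth, c$truth))
})

test_that("default configuration mirrors the reference-table scale", {
  ds <- generate_synthetic(synthetic_config(seed = 1))
  expect_equal(nrow(ds$data$table), 39)
  expect_lte(length(ds$data$universe), 1481)
  ad <- ds$data$table[ds$data$table$disease == ad_name(ds$data$table), ]
  expect_equal(ad$similarity, 1)
  expect_equal(ad$protein_count, 184L)
  # non-AD set sizes are exactly the reference counts
  ref <- load_reference_disease_table()
  expect_equal(sort(ds$data$table$protein_count),
               sort(ref$protein_count))
})

test_that("generated structure obeys the advertised invariants", {
  cfg <- synthetic_config(n_diseases = 14, n_proteins = 150, ad_set_size = 25,
                          overlap_strength = 0.6, seed = 9)
  ds <- generate_synthetic(cfg)
  # membership row sums equal the configured sizes
  sizes <- unname(rowSums(ds$data$membership))
  expect_equal(sizes[seq_len(13)], as.numeric(cfg$set_sizes))
  expect_equal(sizes[14], 25)
  # similarities clipped to the operating range
  sims <- ds$data$table$similarity
  expect_true(all(sims >= 0.30 & sims <= 1))
  # AD row proteins are a subset of the truth set
  adr <- ad_row_index_for_test(ds$data)
  known <- ds$data$universe[ds$data$membership[adr, ] == 1]
  expect_true(all(known %in% ds$truth))
  expect_setequal(c(known, ds$hidden), ds$truth)

  lab <- truth_labels(ds)
  expect_equal(sum(lab$truth), length(ds$truth))
  expect_equal(sum(lab$hidden), length(ds$hidden))
  expect_false(any(lab$hidden & lab$known))
})

test_that("overlap with the truth set tracks the overlap strength", {
  overlap_stats <- function(rho, seed) {
    ds <- generate_synthetic(synthetic_config(
      n_diseases = 12, n_proteins = 150, ad_set_size = 25,
      overlap_strength = rho, noise_sd = 0.02, seed = seed
    ))
    adr <- ad_row_index_for_test(ds$data)
    sets <- ds$data$table$proteins[-adr]
    mean(vapply(sets, function(s) mean(s %in% ds$truth), numeric(1)))
  }
  seeds <- 1:20
  at0 <- vapply(seeds, function(s) overlap_stats(0, s), numeric(1))
  at45 <- vapply(seeds, function(s) overlap_stats(0.45, s), numeric(1))
  at9 <- vapply(seeds, function(s) overlap_stats(0.9, s), numeric(1))
  # no signal at rho = 0: no disease draws truth proteins
  expect_equal(mean(at0), 0)
  expect_gt(mean(at45), mean(at0))
  expect_gt(mean(at9), mean(at45))
})

test_that("similarity co-varies with overlap only when rho > 0", {
  ds <- generate_synthetic(synthetic_config(
    n_diseases = 30, n_proteins = 300, ad_set_size = 40,
    overlap_strength = 0.9, noise_sd = 0.02, seed = 13
  ))
  adr <- ad_row_index_for_test(ds$data)
  ovfrac <- vapply(ds$data$table$proteins[-adr],
                   function(s) mean(s %in% ds$truth), numeric(1))
  sims <- ds$data$table$similarity[-adr]
  expect_gt(stats::cor(ovfrac, sims), 0.8)

  ds0 <- generate_synthetic(synthetic_config(
    n_diseases = 30, n_proteins = 300, ad_set_size = 40,
    overlap_strength = 0, noise_sd = 0.02, seed = 13
  ))
  ov0 <- vapply(ds0$data$table$proteins[-adr],
                function(s) mean(s %in% ds0$truth), numeric(1))
  expect_equal(stats::sd(ov0), 0)   # overlap carries no information
})

test_that("synthetic TSVs round-trip through the readers", {
  ds <- generate_synthetic(synthetic_config(
    n_diseases = 9, n_proteins = 70, ad_set_size = 12, seed = 17
  ))
  dir <- tempfile()
  paths <- write_synthetic_tsvs(ds, dir)
  expect_true(all(file.exists(paths)))

  pairs <- read_similarity_pairs(paths[["similarities"]])
  sims <- extract_target_similarities(pairs, "Alzheimer's Disease")
  expect_equal(nrow(sims), 8)

  assoc <- read_associations(paths[["associations"]])
  adr <- ad_row_index_for_test(ds$data)
  ad_prot <- ds$data$table$proteins[[adr]]
  rebuilt <- build_membership(
    sims,
    dplyr::filter(assoc,
                  .data$disease != normalize_disease_name("Alzheimer's Disease")),
    ad_name = "Alzheimer's Disease", ad_proteins = ad_prot
  )
  # same diseases, same per-disease counts, same universe contents
  expect_setequal(rebuilt$universe,
                  ds$data$universe[colSums(ds$data$membership) > 0])
  orig_counts <- setNames(ds$data$table$protein_count,
                          normalize_disease_name(ds$data$table$disease))
  new_counts <- setNames(rebuilt$table$protein_count,
                         normalize_disease_name(rebuilt$table$disease))
  expect_equal(new_counts[names(orig_counts)], orig_counts)
})

test_that("recovery improves with overlap strength", {
  cfg <- function(rho, s) synthetic_config(
    n_diseases = 20, n_proteins = 400, ad_set_size = 50,
    overlap_strength = rho, noise_sd = 0.02, seed = s
  )
  seeds <- 1:3
  mean_auc <- function(rho) {
    mean(vapply(seeds, function(s) {
      recovery_experiment(cfg(rho, s), ibds_config(max_iter = 250, seed = s))
    }, numeric(1)))
  }
  a0 <- mean_auc(0)
  a45 <- mean_auc(0.45)
  a9 <- mean_auc(0.9)
  expect_lte(a0, a45)
  expect_lte(a45, a9)
  expect_gt(a9, 0.6)
  # no signal: chance level up to the optimizer's membership bias
  expect_gte(a0, 0.4)
  expect_lte(a0, 0.6)
})
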