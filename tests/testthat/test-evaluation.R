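test_that("auc follows the Mann-Whitney convention", {
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(1, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "positive and .* negative")
})

test_that("auc equals brute-force pair counting on random instances", {
  set.seed(51)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(round(runif(n), 2))  # rounded to force ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auc(scores, labels), pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("randomly permuted labels give chance-level auc", {
  set.seed(52)
  scores <- runif(500)
  aucs <- replicate(40, auc(scores, sample(rep(c(1, 0), c(100, 400)))))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("pooled sweep auc concatenates all runs", {
  ds <- generate_synthetic(synthetic_config(
    n_diseases = 8, n_proteins = 50, ad_set_size = 10, seed = 4
  ))
  fit <- run_ibds(ds$data, ibds_config(max_iter = 15, seed = 1))
  positives <- ds$hidden

  one <- pooled_sweep_auc(list(fit), positives)
  eval_auc <- auc(unname(fit$weights),
                  names(fit$weights) %in% positives)
  expect_equal(one, eval_auc)
  # duplicating the whole sample leaves the AUC unchanged
  expect_equal(pooled_sweep_auc(list(fit, fit, fit), positives), one)

  # pair-count oracle on a genuinely pooled pair of distinct runs
  fit2 <- run_ibds(ds$data, ibds_config(max_iter = 15, seed = 2,
                                        initial_mass = 0.3))
  scores <- c(unname(fit$weights), unname(fit2$weights))
  labels <- c(names(fit$weights), names(fit2$weights)) %in% positives
  expect_equal(pooled_sweep_auc(list(fit, fit2), positives),
               pair_count_auc(scores, labels))
})

test_that("rwr reproduces closed-form fixed points", {
  # single self-looped node holds all mass
  loop <- tibble::tibble(protein_a = "a", protein_b = "a")
  expect_equal(rwr(loop, "a")$score, 1)

  # two nodes joined by one edge, seed {a}, restart 1/2 -> (2/3, 1/3)
  two <- tibble::tibble(protein_a = "a", protein_b = "b")
  out <- rwr(two, "a", restart = 0.5)
  expect_equal(out$score[out$node == "a"], 2 / 3, tolerance = 1e-9)
  expect_equal(out$score[out$node == "b"], 1 / 3, tolerance = 1e-9)

  expect_error(rwr(two, "zz"), "not in graph")
})

test_that("rwr matches the direct linear solve on random graphs", {
  set.seed(53)
  for (rep in 1:15) {
    n <- sample(3:20, 1)
    m <- sample(n:(2 * n), 1)
    edges <- tibble::tibble(
      protein_a = paste0("n", sample(n, m, replace = TRUE)),
      protein_b = paste0("n", sample(n, m, replace = TRUE)),
      weight = runif(m, 0.1, 2)
    )
    nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
    seeds <- sample(nodes, sample(1:2, 1))
    r <- runif(1, 0.2, 0.8)
    out <- rwr(edges, seeds, restart = r, tol = 1e-14)
    expect_equal(sum(out$score), 1, tolerance = 1e-9)

    # direct solve of (I - (1-r) W) p = r e with the same normalization
    k <- length(nodes)
    a <- matrix(0, k, k, dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(edges))) {
      ia <- edges$protein_a[i]; ib <- edges$protein_b[i]
      if (ia == ib) {
        a[ia, ia] <- a[ia, ia] + edges$weight[i]
      } else {
        a[ia, ib] <- a[ia, ib] + edges$weight[i]
        a[ib, ia] <- a[ib, ia] + edges$weight[i]
      }
    }
    deg <- colSums(a)
    dang <- deg == 0
    diag(a)[dang] <- 1
    deg[dang] <- 1
    w_mat <- sweep(a, 2, deg, "/")
    e <- setNames(numeric(k), nodes)
    e[seeds] <- 1 / length(seeds)
    p <- solve(diag(k) - (1 - r) * w_mat, r * e)
    expect_equal(setNames(out$score, out$node)[nodes], p, tolerance = 1e-8)
  }
})

test_that("cross-validation is seeded, leakage-free and signal-sensitive", {
  strong <- generate_synthetic(synthetic_config(
    n_diseases = 12, n_proteins = 120, ad_set_size = 20,
    overlap_strength = 0.9, noise_sd = 0.02, seed = 21
  ))
  cfg <- ibds_config(max_iter = 100, seed = 21)
  ev <- cross_validated_auc(strong$data, cfg, k_folds = 4)
  expect_length(ev$fold_auc, 4)
  expect_equal(ev$auc, mean(ev$fold_auc))
  # every known protein lands in exactly one fold
  expect_setequal(ev$folds$accession, strong$data$universe[
    strong$data$membership[ad_row_index_for_test(strong$data), ] == 1
  ])

  # identical seed, identical report
  ev2 <- cross_validated_auc(strong$data, cfg, k_folds = 4)
  expect_identical(ev$fold_auc, ev2$fold_auc)
  expect_identical(ev$folds, ev2$folds)

  # no-signal data scores lower than strong-signal data
  null <- generate_synthetic(synthetic_config(
    n_diseases = 12, n_proteins = 120, ad_set_size = 20,
    overlap_strength = 0, noise_sd = 0.02, seed = 21
  ))
  ev0 <- cross_validated_auc(null$data, cfg, k_folds = 4)
  expect_gt(ev$auc, ev0$auc)
  expect_gt(ev$auc, 0.5)

  gl <- glance(ev)
  expect_equal(gl$auc, ev$auc)
  expect_equal(nrow(tidy(ev)), 4)
})

test_that("cross-validation is invariant to protein ordering", {
  ds <- generate_synthetic(synthetic_config(
    n_diseases = 8, n_proteins = 60, ad_set_size = 10,
    overlap_strength = 0.8, seed = 22
  ))
  cfg <- ibds_config(max_iter = 40, seed = 22)
  ev <- cross_validated_auc(ds$data, cfg, k_folds = 3)

  perm <- withr::with_seed(1, sample(60))
  shuffled <- ds$data
  shuffled$membership <- shuffled$membership[, perm]
  shuffled$universe <- shuffled$universe[perm]
  ev_perm <- cross_validated_auc(shuffled, cfg, k_folds = 3)
  # fold assignment is anchored to sorted accessions, not input order
  expect_identical(ev$folds, ev_perm$folds)
  # fold AUCs agree up to the selectors' tie-breaks among identical
  # one-hot columns, which follow column order
  expect_equal(ev$fold_auc, ev_perm$fold_auc, tolerance = 0.05)
  expect_equal(ev$auc, ev_perm$auc, tolerance = 0.05)
})
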