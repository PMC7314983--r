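test_that("initial weights split the mass as documented", {
  w <- init_weights(0.1, 1:184, 1481)
  expect_equal(w[1], 0.1 / 184)
  expect_equal(round(w[1], 6), 0.000543)
  expect_equal(w[200], 0.9 / (1481 - 184))
  expect_equal(round(w[200], 5), 0.00069)
  expect_equal(sum(w), 1)

  w6 <- init_weights(0.6, 1:184, 1481)
  expect_equal(w6[1], 3.2609e-3, tolerance = 1e-4)
  expect_equal(w6[1000], 3.0840e-4, tolerance = 1e-4)
  expect_equal(sum(w6), 1)

  expect_error(init_weights(0.5, integer(0), 10), "subset")
  expect_error(init_weights(0.5, 1:10, 10), "subset")
  expect_error(init_weights(1.2, 1:2, 10))
})

test_that("weight updates bump selected proteins and conserve mass", {
  w <- c(0.5, 0.3, 0.2)
  out <- update_weights(w, 1L)
  # delta = min(w)/10 = 0.02 added to w1, removed uniformly from the others
  expect_equal(out, c(0.52, 0.29, 0.19))
  expect_equal(sum(out), 1)

  expect_equal(update_weights(w, integer(0)), w)
  expect_error(update_weights(w, 1:3), "unselected")
  expect_error(update_weights(w, 5L), "range")
})

test_that("weight updates stay a probability vector under stress", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    w <- runif(n)
    w[sample(n, sample(0:2, 1))] <- 0
    w <- w / sum(w)
    sel <- sample(n, sample(1:(n - 1), 1))
    out <- update_weights(w, sel)
    expect_lt(abs(sum(out) - 1), 1e-9)
    expect_true(all(out >= 0))
    # selected entries never lose weight
    expect_true(all(out[sel] >= w[sel] - 1e-12))
  }
})

test_that("clamped updates re-spread the deficit over positive unselected mass", {
  # unselected entry near zero gets clamped; remainder comes from the rest
  w <- c(0.9, 1e-12, 0.09999999999)
  w <- w / sum(w)
  out <- update_weights(w, 1L)
  expect_lt(abs(sum(out) - 1), 1e-9)
  expect_true(all(out >= 0))
  expect_gt(out[1], w[1])
})

test_that("acceptance follows the Metropolis rule", {
  expect_equal(acceptance_probability(-0.5, 1), 1)
  expect_equal(acceptance_probability(0, 1), 1)
  expect_equal(acceptance_probability(1, 1), exp(-1))
  expect_equal(acceptance_probability(1, 1), 0.36788, tolerance = 1e-4)

  probs <- acceptance_probability(0.7, 2^-(0:40))
  expect_true(all(diff(probs) < 0 | probs[-1] == 0))
  expect_equal(probs[41], 0)
  expect_error(acceptance_probability(1, 0), "positive")
})

test_that("the iteration is deterministic given a seed", {
  ds <- small_synthetic(seed = 7)
  cfg <- ibds_config(max_iter = 40, seed = 99)
  fit1 <- run_ibds(ds$data, cfg)
  fit2 <- run_ibds(ds$data, cfg)
  expect_identical(fit1$ranking, fit2$ranking)
  expect_identical(fit1$log, fit2$log)
})

test_that("best loss never increases and mass is conserved after a run", {
  ds <- small_synthetic(seed = 8)
  fit <- run_ibds(ds$data, ibds_config(max_iter = 120, seed = 5))
  expect_true(all(diff(fit$log$best_loss) <= 0))
  expect_lt(abs(sum(fit$weights) - 1), 1e-9)
  expect_true(all(fit$weights >= 0))
  expect_lt(abs(sum(fit$state$weights) - 1), 1e-9)
  # the reported best loss is the loss of the reported weights
  expect_equal(total_loss(unname(fit$weights), ds$data$table,
                          ds$data$membership),
               fit$loss)
})

test_that("with instant cooling the iteration is greedy", {
  ds <- small_synthetic(seed = 9)
  fit <- run_ibds(ds$data, ibds_config(max_iter = 80, seed = 3,
                                       cooling = 1e-6))
  expect_equal(fit$state$accepted_worse_count, 0L)
  expect_true(all(diff(fit$log$loss) <= 0))
})

test_that("a protein shared by AD and its most similar disease ranks first", {
  # Six proteins; PA is exclusively shared by AD and the most similar
  # disease, so every selector step supports it and it accumulates the
  # known-protein mass advantage plus repeated bumps.
  simmap <- tibble::tibble(
    disease = c("d1", "d2", "d3"),
    similarity = c(0.95, 0.4, 0.33)
  )
  assoc <- tibble::tibble(
    disease = c("d1", "d2", "d2", "d3", "d3"),
    accession = c("PA", "PB", "PC", "PC", "PD")
  )
  data <- build_membership(simmap, assoc, "AD", c("PA", "PE"))
  fit <- run_ibds(data, ibds_config(max_iter = 60, seed = 1))
  expect_equal(fit$ranking$accession[1], "PA")
})

test_that("known proteins end above never-annotated proteins on signal data", {
  ds <- small_synthetic(seed = 10, rho = 0.8)
  fit <- run_ibds(ds$data, ibds_config(max_iter = 120, seed = 4))
  lab <- truth_labels(ds)
  in_no_set <- colSums(ds$data$membership) == 0
  never <- lab$accession[in_no_set]
  known <- lab$accession[lab$known]
  expect_gt(mean(fit$weights[known]), mean(fit$weights[never]))
})

test_that("candidate extraction applies a strict threshold", {
  w <- setNames(rep(1 / 1481, 1481), paste0("P", 1:1481))
  expect_length(candidates(w, 0.001), 0)
  expect_length(candidates(w, 0), 1481)

  w2 <- setNames(c(0.3, 0.2, 0.002, rep(0, 7)), paste0("Q", 1:10))
  expect_setequal(candidates(w2, 0.001), c("Q1", "Q2", "Q3"))
  expect_setequal(candidates(w2, 0), c("Q1", "Q2", "Q3"))
  df <- tibble::tibble(accession = names(w2), weight = unname(w2))
  expect_setequal(candidates(df), c("Q1", "Q2", "Q3"))
})

test_that("the initial-value sweep runs the full grid with distinct seeds", {
  ds <- generate_synthetic(synthetic_config(
    n_diseases = 8, n_proteins = 50, ad_set_size = 10, seed = 2
  ))
  sweep <- initial_value_sweep(ds$data, ibds_config(max_iter = 15, seed = 1))
  expect_length(sweep, 9)
  expect_equal(names(sweep), sprintf("%.1f", seq(0.1, 0.9, 0.1)))
  seeds <- vapply(sweep, function(f) f$config$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  masses <- vapply(sweep, function(f) f$config$initial_mass, numeric(1))
  expect_equal(unname(masses), seq(0.1, 0.9, 0.1))
  # pooling yields 9 x N (score, label) pairs
  pooled <- tidy(sweep)
  expect_equal(nrow(pooled), 9 * 50)
})

test_that("tidiers and glance expose the fit in tabular form", {
  ds <- small_synthetic(seed = 12)
  fit <- run_ibds(ds$data, ibds_config(max_iter = 25, seed = 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 90)
  expect_equal(sum(td$known), 15)
  expect_equal(td$rank, 1:90)
  gl <- glance(fit)
  expect_equal(gl$n_proteins, 90)
  expect_equal(gl$loss, fit$loss)
  expect_equal(gl$n_candidates, sum(td$candidate))
})
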