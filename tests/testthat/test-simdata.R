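test_that("cohort simulation is deterministic given the seed", {
  a <- simulate_cohort(small_config(seed = 5))
  b <- simulate_cohort(small_config(seed = 5))
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$true_coefficients, b$truth$true_coefficients)
  c2 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(a$table$counts, c2$table$counts))
})

test_that("cohort structure matches the configured design", {
  cfg <- small_config(seed = 2)
  sim <- simulate_cohort(cfg)
  n_subj <- 2 * cfg$n_subjects_per_arm
  expect_equal(nrow(sim$table$counts), n_subj * length(cfg$weeks))
  expect_equal(ncol(sim$table$counts), cfg$n_otus)
  expect_true(all(sim$table$counts >= 0))
  expect_true(all(sim$table$counts == round(sim$table$counts)))
  m <- sim$meta
  expect_setequal(unique(m$treatment), c("control", "STAT"))
  ## all subjects switch diet at the switch week
  expect_true(all(m$diet[m$week < cfg$diet_switch_week] == "NC"))
  expect_true(all(m$diet[m$week >= cfg$diet_switch_week] == "HFD"))
  ## per-sample totals fall in the simulated depth distribution's range
  tot <- rowSums(sim$table$counts)
  lo <- qlnorm(1e-6, cfg$depth_lognormal[1], cfg$depth_lognormal[2])
  hi <- qlnorm(1 - 1e-6, cfg$depth_lognormal[1], cfg$depth_lognormal[2])
  expect_true(all(tot >= lo - 1 & tot <= hi + 1))
  ## Weight+1 exists at every sampled week (post-study weighing)
  expect_false(anyNA(m[["Weight+1"]]))
  ## truth invariants
  tr <- sim$truth
  expect_identical(tr$true_support, tr$true_coefficients != 0)
  ev <- eigen(tr$true_precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(tr$true_precision, t(tr$true_precision), tolerance = 1e-10)
})

test_that("a null cohort has no planted coefficients", {
  sim <- simulate_cohort(small_config(seed = 3, n_assoc_otus = 0))
  expect_true(all(sim$truth$true_coefficients == 0))
  expect_length(sim$truth$assoc_otus, 0)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_otus = 5, n_assoc_otus = 9), "exceed")
  expect_error(sim_config(weeks = c(4, 4, 11)), "increasing")
  expect_error(simulate_network_counts(matrix(c(1, 2, 2, 1), 2), 10),
               "positive definite")
  expect_error(simulate_network_counts(matrix(c(1, 2, 3, 1), 2), 10),
               "symmetric")
})

test_that("planted precision matrices honor topology and conditioning", {
  for (topo in c("chain", "hub", "erdos_renyi")) {
    Om <- make_precision(30, topo, condition = 10)
    ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    ## covariance has unit diagonal by construction
    expect_equal(diag(solve(Om)), rep(1, 30), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  Omc <- make_precision(10, "chain")
  off <- abs(Omc) > 1e-10 & row(Omc) != col(Omc)
  expect_true(all(abs(row(Omc)[off] - col(Omc)[off]) == 1))
  Omh <- make_precision(10, "hub")
  expect_equal(sum(abs(Omh[1, -1]) > 1e-10), 9)
  Omh2 <- make_precision(20, "hub")
  expect_equal(sum(abs(Omh2[11, -11]) > 1e-10), 9)  # second hub at node 11
})

test_that("network count simulation reproduces the latent correlation", {
  Om <- make_precision(20, "chain", condition = 10)
  tab <- simulate_network_counts(Om, n_samples = 800, seed = 4)
  expect_identical(tab$counts,
                   simulate_network_counts(Om, 800, seed = 4)$counts)
  ## clr of the counts correlates along the chain, not at distance 2+
  X <- clr_transform(tab)$values
  C <- cor(X)
  near <- mean(abs(C[cbind(1:19, 2:20)]))
  far <- mean(abs(C[cbind(1:15, 5:19)]))
  expect_gt(near, far)
})

test_that("age series carries a learnable monotone signal in planted taxa", {
  cfg <- sim_config(n_subjects_per_arm = 10, n_otus = 60, n_age_taxa = 10,
                    seed = 12)
  s <- simulate_age_series(cfg)
  X <- clr_transform(s$table)$values
  rho <- apply(X, 2, function(x) suppressWarnings(cor(x, s$ages,
                                                      method = "spearman")))
  planted <- names(s$truth)
  expect_gt(mean(abs(rho[planted])), 2 * mean(abs(rho[setdiff(colnames(X),
                                                              planted)])))
  ## planted sign agrees with the observed trend direction
  expect_gt(mean(sign(rho[planted]) == sign(s$truth)), 0.8)
  expect_warning(simulate_age_series(sim_config(n_age_taxa = 0, seed = 1)),
                 "unlearnable")
})
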