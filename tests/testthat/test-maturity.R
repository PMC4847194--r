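age_cfg <- function(seed) {
  sim_config(n_subjects_per_arm = 10, n_otus = 60, n_age_taxa = 10,
             seed = seed)
}

test_that("the age model learns planted age taxa (and nothing from noise)", {
  s <- simulate_age_series(age_cfg(21))
  m <- fit_age_model(s$table, s$ages, n_trees = 500, seed = 2)
  rho <- cor(m$oob_predictions, s$ages, method = "spearman")
  expect_gte(rho, 0.8)

  ## deterministic given seed
  m2 <- fit_age_model(s$table, s$ages, n_trees = 500, seed = 2)
  expect_identical(m$oob_predictions, m2$oob_predictions)

  ## shuffled ages carry no signal
  set.seed(5)
  m0 <- fit_age_model(s$table, sample(s$ages), n_trees = 500, seed = 3)
  expect_lt(abs(cor(m0$oob_predictions, s$ages, method = "spearman")), 0.2)

  expect_error(fit_age_model(s$table, rep(4, length(s$ages))), "constant")
})

test_that("MM and MAZ follow their defining formulas", {
  ## hand-built model: three controls with OOB predictions 7, 8, 9 in one
  ## bin (median 8, SD 1) and a case predicted at 10 -> MM = 2, MAZ = 2
  counts <- matrix(10L, 4, 3,
                   dimnames = list(c("c1", "c2", "c3", "x1"),
                                   c("o1", "o2", "o3")))
  tab <- otu_table(counts)
  model <- structure(list(forest = NULL,
                          oob_predictions = c(c1 = 7, c2 = 8, c3 = 9,
                                              x1 = 10),
                          training_ids = c("c1", "c2", "c3", "x1"),
                          n_trees = 0L),
                     class = "age_model")
  res <- maz_scores(model, tab, ages = rep(4, 4),
                    control_mask = c(TRUE, TRUE, TRUE, FALSE))
  sc <- res$scores
  expect_equal(sc$MM[sc$sample == "x1"], 2)
  expect_equal(sc$MAZ[sc$sample == "x1"], 2)
  ## control at the bin median scores 0 / 0
  expect_equal(sc$MM[sc$sample == "c2"], 0)
  expect_equal(sc$MAZ[sc$sample == "c2"], 0)
  ## control median MM is 0 by construction
  expect_equal(median(sc$MM[sc$sample != "x1"]), 0)
})

test_that("control MM medians are exactly zero per bin on simulated data", {
  s <- simulate_age_series(age_cfg(31))
  ctrl <- rep(TRUE, length(s$ages))
  m <- fit_age_model(s$table, s$ages, n_trees = 300, seed = 4)
  res <- maz_scores(m, s$table, s$ages, ctrl)
  sc <- res$scores
  for (b in unique(sc$bin))
    expect_equal(median(sc$MM[sc$bin == b]), 0)
  ## control MAZ spread is near unit scale (median-vs-mean centering slack)
  sds <- tapply(sc$MAZ, sc$bin, sd)
  expect_true(all(abs(sds - 1) < 0.25))
})

test_that("a damped-maturation arm scores negative MAZ early in life", {
  cfg <- age_cfg(41)
  ctrl_sim <- simulate_age_series(cfg)
  n <- length(ctrl_sim$ages)
  ## cases: community develops at 60% of chronological speed
  case_sim <- simulate_age_series(
    sim_config(n_subjects_per_arm = 10, n_otus = 60, n_age_taxa = 10,
               seed = 41),
    ages_effective = 0.6 * ctrl_sim$ages)
  joint <- otu_table(rbind(ctrl_sim$table$counts,
                           `rownames<-`(case_sim$table$counts,
                                        paste0("case_", rownames(case_sim$table$counts)))))
  ages <- c(ctrl_sim$ages, case_sim$ages)
  ctrl <- rep(c(TRUE, FALSE), each = n)
  m <- fit_age_model(ctrl_sim$table, ctrl_sim$ages, n_trees = 400, seed = 6)
  res <- maz_scores(m, joint, ages, ctrl)
  sc <- res$scores
  early <- sc$bin <= sort(unique(sc$bin))[2]
  expect_lt(mean(sc$MAZ[!sc$control & early]), 0)
  ## and the deficit is substantial, not marginal
  expect_lt(mean(sc$MAZ[!sc$control & early]), -1)
})

test_that("bins without enough controls are flagged and excluded", {
  s <- simulate_age_series(age_cfg(51))
  ctrl <- rep(TRUE, length(s$ages))
  ctrl[s$ages == max(s$ages)] <- FALSE       # last bin loses its controls
  m <- fit_age_model(s$table[ctrl, ], s$ages[ctrl], n_trees = 200, seed = 1)
  res <- maz_scores(m, s$table, s$ages, ctrl)
  sc <- res$scores
  expect_true(all(sc$flagged[sc$bin == max(s$ages)]))
  expect_true(all(is.na(sc$MAZ[sc$flagged])))
})

test_that("planted discriminative OTUs beat the random baseline 2-fold", {
  d <- planted_disease(seed = 61)
  rep_ <- classify_disease(d$table, d$labels, weeks = rep(4, 40),
                           n_trees = 200, depth = 1000, n_trials = 2,
                           seed = 7)
  expect_lt(rep_$mean_error[["week4"]], 0.25)
  ## planted OTUs rank in the top decile of importance
  imp <- rep_$importance[, "week4"]
  cut <- quantile(imp, 0.9)
  expect_gte(mean(imp[d$disc] >= cut), 0.8)
})

test_that("permuted labels give chance-level leave-one-out error", {
  d <- planted_disease(seed = 71)
  set.seed(9)
  rep0 <- classify_disease(d$table, sample(d$labels), weeks = rep(4, 40),
                           n_trees = 200, depth = 1000, n_trials = 2,
                           seed = 8)
  se2 <- 2 * sqrt(0.25 / 40)
  expect_lt(abs(rep0$mean_error[["week4"]] - 0.5), se2 + 0.1)
})

test_that("weeks with a single class are skipped, others still scored", {
  d <- planted_disease(n_per = 10, seed = 81)
  wk <- c(rep(4, 10), rep(11, 10))          # week 4 all healthy
  labels <- c(rep(FALSE, 10), rep(c(FALSE, TRUE), 5))
  expect_message(
    rep_ <- classify_disease(d$table, labels, weeks = wk, n_trees = 100,
                             depth = 1000, n_trials = 1, seed = 3),
    "single class")
  expect_true(is.na(rep_$error["week4", 1]))
  expect_false(is.na(rep_$error["week11", 1]))
})
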