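#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort]: two
#' treatment arms (control / STAT) sampled repeatedly over weeks, a diet
#' switch from normal chow to high-fat diet applying to every subject, a
#' sparse overdispersed OTU count table generated by a logistic-normal
#' multinomial model with a planted sparse inverse-covariance structure,
#' a small planted set of OTU-phenotype associations, and age-graded taxa.
#'
#' @param n_subjects_per_arm subjects per treatment arm; default 20.
#' @param weeks strictly increasing sampling weeks; default 4, 11, 16, 30.
#' @param diet_switch_week all subjects switch NC -> HFD at this week;
#'   default 13.
#' @param n_otus number of OTUs; default 200.
#' @param n_assoc_otus OTUs with planted phenotype associations; default 10.
#' @param assoc_effect_size latent log-scale coefficient magnitude per unit
#'   phenotype; default 1.0.
#' @param subject_sd sd of the per-subject random effect on log-abundance;
#'   default 0.5.
#' @param depth_lognormal (meanlog, sdlog) of the library-size
#'   distribution; default (log(2e4), 0.3).
#' @param precision_spec list: \code{topology} in chain / hub /
#'   erdos_renyi, \code{condition} target condition number (default 100),
#'   \code{edge_value} partial-covariance magnitude (default 0.3).
#' @param n_age_taxa number of age-graded taxa; default 20.
#' @param age_slope log-abundance change per week for age taxa; default
#'   0.15.
#' @param treatment_effect,diet_effect latent log-scale shifts applied to
#'   \code{n_treat_otus} / \code{n_diet_otus} random OTUs; defaults 1.0,
#'   1.0, 20, 20.
#' @param n_treat_otus,n_diet_otus see above.
#' @param baseline_sd sd of per-OTU baseline log-abundance; default 1.0.
#' @param pheno_noise_sd residual sd of phenotype responses; default 0.5.
#' @param pheno_subject_sd sd of the per-subject phenotype random effect;
#'   default 1.0.
#' @param seed integer master seed; default 1.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_subjects_per_arm = 20,
                       weeks = c(4, 11, 16, 30),
                       diet_switch_week = 13,
                       n_otus = 200,
                       n_assoc_otus = 10,
                       assoc_effect_size = 1.0,
                       subject_sd = 0.5,
                       depth_lognormal = c(log(2e4), 0.3),
                       precision_spec = list(topology = "erdos_renyi",
                                             condition = 100,
                                             edge_value = 0.3),
                       n_age_taxa = 20,
                       age_slope = 0.15,
                       treatment_effect = 1.0,
                       diet_effect = 1.0,
                       n_treat_otus = 20,
                       n_diet_otus = 20,
                       baseline_sd = 1.0,
                       pheno_noise_sd = 0.5,
                       pheno_subject_sd = 1.0,
                       seed = 1L) {
  if (n_assoc_otus > n_otus) stop("n_assoc_otus must not exceed n_otus")
  if (is.unsorted(weeks, strictly = TRUE)) stop("weeks must be strictly increasing")
  if (subject_sd < 0 || baseline_sd < 0) stop("sds must be non-negative")
  if (any(depth_lognormal <= 0) && depth_lognormal[1] <= 0)
    stop("depth parameters must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

phyla_pool <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                "Actinobacteria", "Tenericutes", "Verrucomicrobia")

#' Planted precision matrix
#'
#' Builds a symmetric positive-definite precision (inverse-covariance)
#' matrix with a given sparsity topology, rescaled so the implied
#' covariance has unit diagonal, with the condition number adjusted by a
#' uniform diagonal shift.
#'
#' @param p dimension.
#' @param topology \code{"chain"} (tridiagonal), \code{"hub"} (stars of
#'   ~10 nodes each) or \code{"erdos_renyi"} (random edges, expected
#'   degree 2).
#' @param condition target condition number; default 100.
#' @param edge_value magnitude of off-diagonal entries; default 0.3.
#' @param seed integer seed (erdos_renyi placement).
#' @return precision matrix (p x p), PD, unit-diagonal covariance inverse.
#' @export
make_precision <- function(p, topology = c("chain", "hub", "erdos_renyi"),
                           condition = 100, edge_value = 0.3, seed = 1L) {
  topology <- match.arg(topology)
  E <- matrix(0, p, p)
  if (topology == "chain") {
    for (i in seq_len(p - 1L)) E[i, i + 1L] <- E[i + 1L, i] <- 1
  } else if (topology == "hub") {
    ## hubs of ~10 nodes each: a single giant star caps the attainable
    ## partial correlation at 1/sqrt(p-1), too weak to be a usable fixture
    starts <- seq(1L, p, by = 10L)
    for (h in starts) {
      leaves <- seq(h + 1L, min(h + 9L, p))
      if (length(leaves)) { E[h, leaves] <- 1; E[leaves, h] <- 1 }
    }
  } else {
    restore <- local_rng(seed)
    pr <- min(1, 2 / (p - 1))
    up <- which(upper.tri(E))
    on <- up[stats::runif(length(up)) < pr]
    E[on] <- 1
    E <- E + t(E)
    restore()
  }
  signs <- matrix(1, p, p)
  Om <- E * edge_value * signs
  ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev); lmax <- max(ev)
  ## diagonal shift c solving (lmax + c)/(lmin + c) = condition
  cshift <- (lmax - condition * lmin) / (condition - 1)
  cshift <- max(cshift, -lmin + 1e-3)
  Om <- Om + diag(cshift, p)
  ## rescale so the covariance has unit diagonal
  S <- solve(Om)
  d <- sqrt(diag(S))
  S <- t(S / d) / d
  Om <- solve(S)
  Om <- (Om + t(Om)) / 2
  dimnames(Om) <- list(paste0("OTU", seq_len(p)), paste0("OTU", seq_len(p)))
  Om
}

check_pd <- function(precision) {
  precision <- as.matrix(precision)
  if (!isTRUE(all.equal(precision, t(precision), tolerance = 1e-8)))
    stop("precision must be symmetric")
  ev <- eigen((precision + t(precision)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("precision must be positive definite (min eigenvalue ",
         format(min(ev)), ")")
  (precision + t(precision)) / 2
}

## logistic-normal multinomial counts from latent log-abundances
lnm_counts <- function(Z, depth_lognormal) {
  n <- nrow(Z)
  depths <- pmax(1, round(stats::rlnorm(n, depth_lognormal[1],
                                        depth_lognormal[2])))
  P <- exp(Z - apply(Z, 1L, max))
  P <- P / rowSums(P)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1L, depths[i], P[i, ])[, 1L],
                     integer(ncol(Z))))
  dimnames(counts) <- dimnames(Z)
  counts
}

#' Simulate a longitudinal two-arm cohort
#'
#' Latent log-abundances are baseline + subject random effect + treatment
#' effect (STAT arm) + diet effect (all subjects after the switch week) +
#' age trend + correlated Gaussian noise with covariance equal to the
#' inverse of the planted precision matrix; counts are multinomial draws
#' with lognormal library sizes (logistic-normal multinomial). Phenotypes
#' are linear in the latent abundances of the planted associated OTUs plus
#' a subject effect and noise; "Weight+1" is the next-timepoint weight.
#' Sex is simulated but has no effect.
#'
#' @param config a [sim_config].
#' @return list with \code{table} ([otu_table] with taxonomy),
#'   \code{meta} (per-sample data.frame: sample_id, subject_id, week,
#'   treatment, diet, sex, the seven phenotype columns, glucose, insulin)
#'   and \code{truth} (class \code{sim_truth}: \code{true_support},
#'   \code{true_precision}, \code{true_age_taxa}, \code{true_coefficients},
#'   \code{latent}).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  restore <- local_rng(cfg$seed)
  on.exit(restore())
  p <- cfg$n_otus
  Om <- make_precision(p, cfg$precision_spec$topology,
                       condition = cfg$precision_spec$condition %||% 100,
                       edge_value = cfg$precision_spec$edge_value %||% 0.3,
                       seed = sample.int(2^31 - 1L, 1L))
  Om <- check_pd(Om)
  Sigma <- solve(Om)
  n_subj <- 2L * cfg$n_subjects_per_arm
  subjects <- sprintf("M%02d", seq_len(n_subj))
  treatment <- rep(c("control", "STAT"), each = cfg$n_subjects_per_arm)
  sex <- rep_len(c("M", "F"), n_subj)
  grid <- expand.grid(subject = seq_len(n_subj), week = cfg$weeks)
  grid <- grid[order(grid$subject, grid$week), ]
  n <- nrow(grid)
  otus <- paste0("OTU", seq_len(p))

  baseline <- stats::rnorm(p, 0, cfg$baseline_sd)
  subj_eff <- matrix(stats::rnorm(n_subj * p, 0, cfg$subject_sd), n_subj, p)
  treat_otus <- sample.int(p, min(cfg$n_treat_otus, p))
  treat_vec <- numeric(p)
  treat_vec[treat_otus] <- sample(c(-1, 1), length(treat_otus),
                                  replace = TRUE) * cfg$treatment_effect
  diet_otus <- sample.int(p, min(cfg$n_diet_otus, p))
  diet_vec <- numeric(p)
  diet_vec[diet_otus] <- sample(c(-1, 1), length(diet_otus),
                                replace = TRUE) * cfg$diet_effect
  age_otus <- if (cfg$n_age_taxa > 0) sample.int(p, min(cfg$n_age_taxa, p))
              else integer()
  age_vec <- numeric(p)
  age_vec[age_otus] <- sample(c(-1, 1), length(age_otus),
                              replace = TRUE) * cfg$age_slope

  eps <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
  wk <- grid$week
  hfd <- as.numeric(wk >= cfg$diet_switch_week)
  stat <- as.numeric(treatment[grid$subject] == "STAT")
  wk_c <- wk - mean(cfg$weeks)
  Z <- matrix(baseline, n, p, byrow = TRUE) +
    subj_eff[grid$subject, , drop = FALSE] +
    outer(stat, treat_vec) +
    outer(hfd, diet_vec) +
    outer(wk_c, age_vec) +
    eps
  sample_id <- sprintf("%s_w%02d", subjects[grid$subject], wk)
  dimnames(Z) <- list(sample_id, otus)

  base_phen <- c("Fat", "BMC", "Lean", "DMI", "Weight", "NAFLD")
  phen_names <- c("Fat", "BMC", "Lean", "DMI", "Weight", "Weight+1", "NAFLD")
  Bt <- matrix(0, p, length(phen_names), dimnames = list(otus, phen_names))
  assoc_otus <- if (cfg$n_assoc_otus > 0) sample.int(p, cfg$n_assoc_otus)
                else integer()
  for (o in assoc_otus) {
    picks <- sample(base_phen, 3L)
    Bt[o, picks] <- sample(c(-1, 1), 3L, replace = TRUE) *
      cfg$assoc_effect_size
  }
  subj_phen <- matrix(stats::rnorm(n_subj * length(base_phen), 0,
                                   cfg$pheno_subject_sd),
                      n_subj, length(base_phen))
  Y <- Z %*% Bt[, base_phen] +
    subj_phen[grid$subject, , drop = FALSE] +
    matrix(stats::rnorm(n * length(base_phen), 0, cfg$pheno_noise_sd),
           n, length(base_phen))
  colnames(Y) <- base_phen
  ## an auxiliary post-study weighing (weights are measured beyond the last
  ## stool sample), so "Weight+1" exists at the final sampled week too
  wk_aux <- max(cfg$weeks) + 1L
  eps_aux <- MASS::mvrnorm(n_subj, mu = rep(0, p), Sigma = Sigma)
  Z_aux <- matrix(baseline, n_subj, p, byrow = TRUE) + subj_eff +
    outer(as.numeric(treatment == "STAT"), treat_vec) +
    outer(rep(as.numeric(wk_aux >= cfg$diet_switch_week), n_subj), diet_vec) +
    outer(rep(wk_aux - mean(cfg$weeks), n_subj), age_vec) + eps_aux
  w_aux <- drop(Z_aux %*% Bt[, "Weight"]) +
    subj_phen[, which(base_phen == "Weight")] +
    stats::rnorm(n_subj, 0, cfg$pheno_noise_sd)
  wplus <- weight_plus_one(c(Y[, "Weight"], w_aux),
                           c(subjects[grid$subject], subjects),
                           c(wk, rep(wk_aux, n_subj)))[seq_len(n)]

  meta <- data.frame(sample_id = sample_id,
                     subject_id = subjects[grid$subject],
                     week = wk,
                     treatment = treatment[grid$subject],
                     diet = ifelse(hfd == 1, "HFD", "NC"),
                     sex = sex[grid$subject],
                     stringsAsFactors = FALSE, check.names = FALSE)
  meta <- cbind(meta, as.data.frame(Y, check.names = FALSE))
  meta[["Weight+1"]] <- wplus
  meta$glucose <- pmax(50, stats::rnorm(n, 180, 40))
  meta$insulin <- stats::rlnorm(n, log(15), 0.5)
  meta <- meta[, c("sample_id", "subject_id", "week", "treatment", "diet",
                   "sex", phen_names, "glucose", "insulin")]
  rownames(meta) <- sample_id

  taxonomy <- sprintf("k__Bacteria;p__%s;g__g%d",
                      sample(phyla_pool, p, replace = TRUE), seq_len(p))
  counts <- lnm_counts(Z, cfg$depth_lognormal)
  truth <- structure(list(
    true_support = Bt != 0,
    true_precision = Om,
    true_age_taxa = stats::setNames(age_vec[age_otus], otus[age_otus]),
    true_coefficients = Bt,
    assoc_otus = otus[assoc_otus],
    treat_otus = otus[treat_otus],
    diet_otus = otus[diet_otus],
    latent = Z), class = "sim_truth")
  list(table = otu_table(counts, taxonomy), meta = meta, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate counts with a planted network structure
#'
#' Logistic-normal multinomial counts whose latent covariance is the
#' inverse of the supplied precision matrix (per-OTU baselines drawn once).
#'
#' @param precision symmetric positive-definite matrix.
#' @param n_samples number of samples.
#' @param depth (meanlog, sdlog) of the lognormal library size;
#'   default (log(1e4), 0.25).
#' @param baseline_sd sd of per-OTU baseline log-abundance; default 1.
#' @param seed integer seed.
#' @return an [otu_table].
#' @export
simulate_network_counts <- function(precision, n_samples,
                                    depth = c(log(1e4), 0.25),
                                    baseline_sd = 1, seed = 1L) {
  Om <- check_pd(precision)
  p <- nrow(Om)
  restore <- local_rng(seed)
  on.exit(restore())
  Sigma <- solve(Om)
  baseline <- stats::rnorm(p, 0, baseline_sd)
  Z <- MASS::mvrnorm(n_samples, mu = baseline, Sigma = Sigma)
  if (is.null(colnames(Om))) colnames(Z) <- paste0("OTU", seq_len(p))
  else colnames(Z) <- colnames(Om)
  rownames(Z) <- paste0("S", seq_len(n_samples))
  otu_table(lnm_counts(Z, depth))
}

#' Simulate an age-graded community series
#'
#' Subjects sampled across the configured weeks; the planted age taxa
#' follow monotone log-linear trends in age while the other OTUs are
#' exchangeable noise. Supplying \code{ages_effective} decouples the age
#' driving community composition from the reported chronological age
#' (e.g. a delayed-maturation arm uses a damped effective age).
#'
#' @param config a [sim_config]; \code{n_age_taxa}, \code{age_slope},
#'   \code{n_subjects_per_arm} and \code{weeks} are used.
#' @param ages_effective optional per-sample effective age driving the
#'   community (default: the chronological sampling week).
#' @return list with \code{table} ([otu_table]), \code{ages}
#'   (chronological weeks), \code{subjects}, and \code{truth} (planted
#'   slopes by OTU).
#' @export
simulate_age_series <- function(config = sim_config(), ages_effective = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_age_taxa == 0)
    warning("n_age_taxa = 0: age is unlearnable from this series")
  restore <- local_rng(cfg$seed)
  on.exit(restore())
  p <- cfg$n_otus
  n_subj <- cfg$n_subjects_per_arm
  grid <- expand.grid(subject = seq_len(n_subj), week = cfg$weeks)
  grid <- grid[order(grid$subject, grid$week), ]
  n <- nrow(grid)
  ages <- grid$week
  eff <- if (is.null(ages_effective)) ages else ages_effective
  if (length(eff) != n) stop("ages_effective must have one value per sample")
  otus <- paste0("OTU", seq_len(p))
  age_otus <- if (cfg$n_age_taxa > 0) sample.int(p, min(cfg$n_age_taxa, p))
              else integer()
  age_vec <- numeric(p)
  age_vec[age_otus] <- sample(c(-1, 1), length(age_otus),
                              replace = TRUE) * cfg$age_slope
  baseline <- stats::rnorm(p, 0, cfg$baseline_sd)
  subj_eff <- matrix(stats::rnorm(n_subj * p, 0, cfg$subject_sd), n_subj, p)
  Z <- matrix(baseline, n, p, byrow = TRUE) +
    subj_eff[grid$subject, , drop = FALSE] +
    outer(eff - mean(cfg$weeks), age_vec) +
    matrix(stats::rnorm(n * p), n, p)
  subjects <- sprintf("A%02d", grid$subject)
  dimnames(Z) <- list(sprintf("%s_w%02d", subjects, ages), otus)
  list(table = otu_table(lnm_counts(Z, cfg$depth_lognormal)),
       ages = ages, subjects = subjects,
       truth = stats::setNames(age_vec[age_otus], otus[age_otus]))
}
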