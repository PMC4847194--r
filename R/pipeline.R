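#' Run the full analysis pipeline from a configuration file
#'
#' Orchestrates the stages — simulate (or read) -> prevalence filter ->
#' clr -> within-subject decomposition -> sPLS + StARS + significance ->
#' score clustering -> per-cluster association networks -> network
#' topology and attacks -> maturity (MAZ) -> disease classification ->
#' host metabolic flags — persisting every stage's artifact under
#' \code{out_dir}. A stage runs when its configuration block is present;
#' missing blocks are skipped with a notice. Every stage draws its seed
#' from the master seed plus a fixed per-stage offset (stage index x 1000),
#' so the whole run is a pure function of (inputs, config, seed).
#'
#' @param config path to a YAML configuration file, or an equivalent
#'   named list. Recognised blocks: \code{simulate} (sim_config fields) or
#'   \code{input} (\code{otu_table}, \code{metadata} paths), \code{filter},
#'   \code{clr}, \code{decompose}, \code{spls}, \code{cluster},
#'   \code{networks}, \code{topology}, \code{maz}, \code{classify},
#'   \code{homa}; plus top-level \code{seed} and \code{out_dir}.
#' @return invisibly, a list of stage results; artifacts are written to
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out_dir %||% file.path(tempdir(), "micropls_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(seed = seed, out_dir = out_dir)
  stage_seed <- function(i) seed + 1000L * i
  note <- function(...) message("[pipeline] ", ...)
  skip <- function(name) note("stage '", name, "' not configured; skipped")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  jsonlite::write_json(list(seed = seed), file.path(out_dir, "run.json"),
                       auto_unbox = TRUE)

  ## --- inputs ---
  if (!is.null(cfg$simulate)) {
    sc <- run_stage("simulate", do.call(sim_config,
      c(cfg$simulate, list(seed = stage_seed(1L)))))
    sim <- run_stage("simulate", simulate_cohort(sc))
    table <- sim$table; meta <- sim$meta
    write_otu_table(table, file.path(out_dir, "otu_table.tsv"))
    write_metadata(meta, file.path(out_dir, "metadata.tsv"))
    jsonlite::write_json(
      list(assoc_otus = sim$truth$assoc_otus,
           age_taxa = as.list(sim$truth$true_age_taxa)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE)
    res$truth <- sim$truth
  } else if (!is.null(cfg$input)) {
    table <- run_stage("input", read_otu_table(cfg$input$otu_table,
      format = cfg$input$format %||% "tsv"))
    meta <- run_stage("input", read_metadata(cfg$input$metadata, table))
  } else stop("config needs a 'simulate' or 'input' block")
  meta <- meta[sample_ids(table), , drop = FALSE]
  res$table <- table; res$meta <- meta

  ## --- filter + clr ---
  if (!is.null(cfg$filter)) {
    table <- run_stage("filter",
      filter_prevalence(table, cfg$filter$min_fraction %||% 0.10))
    write_otu_table(table, file.path(out_dir, "otu_filtered.tsv"))
  } else skip("filter")
  if (!is.null(cfg$clr)) {
    clr <- run_stage("clr", clr_transform(table, cfg$clr$pseudocount %||% 1))
    utils::write.table(clr$values, file.path(out_dir, "clr.tsv"),
                       sep = "\t", quote = FALSE)
    res$clr <- clr
  } else { skip("clr"); clr <- NULL }

  phen_cols <- intersect(c("Fat", "BMC", "Lean", "DMI", "Weight",
                           "Weight+1", "NAFLD"), names(meta))
  decomp <- NULL
  if (!is.null(cfg$decompose) && !is.null(clr)) {
    Y <- as.matrix(meta[, phen_cols, drop = FALSE])
    ok <- stats::complete.cases(Y)
    if (any(!ok)) note(sum(!ok), " samples dropped from responses (missing ",
                       "next-timepoint weight)")
    decomp <- run_stage("decompose", within_subject_split(
      clr$values[ok, , drop = FALSE], meta$subject_id[ok], meta$diet[ok],
      meta$treatment[ok]))
    ydec <- run_stage("decompose", within_subject_split(
      Y[ok, , drop = FALSE], meta$subject_id[ok], meta$diet[ok]))
    utils::write.table(decomp$within, file.path(out_dir, "within_X.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(ydec$within, file.path(out_dir, "within_Y.tsv"),
                       sep = "\t", quote = FALSE)
    res$decomp <- decomp; res$ydec <- ydec; res$rows_used <- which(ok)
  } else skip("decompose")

  ## --- sPLS + significance ---
  spls_fit <- NULL
  if (!is.null(cfg$spls) && !is.null(decomp)) {
    sp <- cfg$spls
    subj <- meta$subject_id[res$rows_used]
    prof <- run_stage("spls", stars_select_eta(
      decomp$within, res$ydec$within, subjects = subj,
      eta_grid = sp$eta_grid %||% seq(0.05, 0.95, by = 0.05),
      n_subsets = sp$n_subsets %||% 50,
      threshold = sp$threshold %||% 0.001,
      K = sp$K %||% 7, seed = stage_seed(2L)))
    assoc <- run_stage("spls", bootstrap_significance(
      decomp$within, res$ydec$within, prof$support, subjects = subj,
      B_boot = sp$B_boot %||% 2000, B_null = sp$B_null %||% sp$B_boot %||% 2000,
      alpha = sp$alpha %||% 0.01, K = sp$K %||% 7, seed = stage_seed(3L)))
    utils::write.table(
      data.frame(eta = prof$eta_grid, D = prof$D,
                 D_monotone = prof$D_monotone),
      file.path(out_dir, "stars_stability.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(assoc$associations,
                       file.path(out_dir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(eta = prof$eta_selected,
                              K = prof$fit$K,
                              support = names(which(prof$support))),
                         file.path(out_dir, "spls_model.json"),
                         auto_unbox = TRUE)
    spls_fit <- prof$fit
    res$stars <- prof; res$associations <- assoc
  } else skip("spls")

  ## --- clustering of scores ---
  gmm <- NULL
  if (!is.null(cfg$cluster) && !is.null(spls_fit)) {
    cl <- cfg$cluster
    gmm <- run_stage("cluster", cluster_scores(
      spls_fit$scores, k_range = cl$k_range %||% 1:9,
      seed = stage_seed(4L)))
    rows <- res$rows_used
    assign_df <- data.frame(sample = sample_ids(table)[rows],
                            cluster = gmm$assignment)
    utils::write.table(assign_df, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trans <- transition_diagram(gmm$assignment,
                                meta$subject_id[rows], meta$week[rows],
                                min_count = cl$min_count %||% 6)
    utils::write.table(trans$all_moves,
                       file.path(out_dir, "transitions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$gmm <- gmm; res$transitions <- trans
  } else skip("cluster")

  ## --- per-cluster networks + topology ---
  if (!is.null(cfg$networks) && !is.null(gmm)) {
    nw <- cfg$networks
    min_n <- nw$min_cluster_size %||% 20
    phy <- phylum_of(table$taxonomy %||% rep("", ncol(table$counts)))
    names(phy) <- otu_ids(table)
    nets <- list()
    rows <- res$rows_used
    for (k in sort(unique(gmm$assignment))) {
      sel <- rows[gmm$assignment == k]
      if (length(sel) < min_n) {
        note("cluster ", k, ": only ", length(sel), " samples; skipped")
        next
      }
      ## clr recomputed within the cluster's samples (cluster-local
      ## composition)
      Xk <- clr_transform(table[sel, ],
                          pseudocount = cfg$clr$pseudocount %||% 1)$values
      nets[[as.character(k)]] <- run_stage("networks", stars_network(
        Xk, n_subsets = nw$n_subsets %||% 50,
        threshold = nw$threshold %||% 0.0005, phylum = phy,
        seed = stage_seed(5L) + k))
      write_network(nets[[as.character(k)]],
                    file.path(out_dir, sprintf("network_c%s.tsv", k)))
    }
    res$networks <- nets
    if (!is.null(cfg$topology) && length(nets) >= 1L) {
      tp <- cfg$topology
      gcms <- lapply(nets, graphlet_correlation_matrix)
      if (length(nets) >= 2L) {
        Dm <- matrix(0, length(nets), length(nets),
                     dimnames = list(names(nets), names(nets)))
        for (i in seq_along(nets)) for (j in seq_along(nets))
          if (i < j) Dm[i, j] <- Dm[j, i] <- gcd(gcms[[i]], gcms[[j]])
        xy <- embed_networks(Dm)
        utils::write.table(cbind(network = names(nets), as.data.frame(xy)),
                           file.path(out_dir, "network_mds.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$gcd <- Dm
      }
      summ <- lapply(nets, summary_stats)
      jsonlite::write_json(summ, file.path(out_dir, "network_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      atk <- lapply(nets, function(g) {
        lapply(c("random", "degree", "betweenness"), function(s)
          attack_curve(g, s, n_rep = tp$n_rep %||% 50,
                       seed = stage_seed(6L)))
      })
      res$attacks <- atk
      res$keystones <- lapply(nets, top_keystones)
    } else if (!is.null(cfg$topology)) skip("topology")
  } else skip("networks")

  ## --- maturity ---
  if (!is.null(cfg$maz)) {
    ctrl <- meta$treatment == "control"
    am <- run_stage("maz", fit_age_model(table[ctrl, ], meta$week[ctrl],
      n_trees = cfg$maz$n_trees %||% 1000, seed = stage_seed(7L)))
    mz <- run_stage("maz", maz_scores(am, table, meta$week, ctrl))
    utils::write.table(mz$scores, file.path(out_dir, "maz.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$maz <- mz
  } else skip("maz")

  ## --- host flags + disease classification ---
  flags <- NULL
  if (!is.null(cfg$homa)) {
    h <- homa_ir(meta$glucose, meta$insulin)
    flags <- data.frame(sample = rownames(meta), homa_ir = h,
                        homa_elevated = h > HOMA_IR_THRESHOLD)
    utils::write.table(flags, file.path(out_dir, "homa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$homa <- flags
  } else skip("homa")
  if (!is.null(cfg$classify)) {
    cc <- cfg$classify
    labels <- if (!is.null(flags)) {
      ## subject is diseased if elevated HOMA-IR at its last sampled week
      last <- tapply(seq_len(nrow(meta)), meta$subject_id,
                     function(i) i[which.max(meta$week[i])])
      dz <- stats::setNames(flags$homa_elevated[unlist(last)], names(last))
      dz[meta$subject_id]
    } else rep(FALSE, nrow(meta))
    if (length(unique(labels)) < 2L) {
      note("classify: single disease class; skipped")
    } else {
      rep_ <- run_stage("classify", classify_disease(
        table, labels, meta$week,
        n_trees = cc$n_trees %||% 1000, depth = cc$depth %||% 1000,
        n_trials = cc$n_trials %||% 10, seed = stage_seed(8L)))
      utils::write.table(rep_$error, file.path(out_dir, "rf_error.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(rep_$importance,
                         file.path(out_dir, "rf_importance.tsv"),
                         sep = "\t", quote = FALSE)
      res$classifier <- rep_
    }
  } else skip("classify")

  invisible(res)
}
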