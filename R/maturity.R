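#' Random-forest microbiota age model
#'
#' Regresses host age on microbial composition (relative abundances) with a
#' random forest grown on control samples only; out-of-bag predictions for
#' the training samples are retained so downstream maturity scores of
#' controls are not optimistic.
#'
#' @param table_controls [otu_table] of control samples.
#' @param ages numeric age (weeks) per control sample.
#' @param n_trees trees per forest; default 1000.
#' @param seed integer seed.
#' @return object of class \code{age_model}: the forest (\code{mtry} =
#'   ceiling(d/3)), \code{oob_predictions} (named), \code{training_ids}.
#' @export
fit_age_model <- function(table_controls, ages, n_trees = 1000, seed = 1L) {
  stopifnot(inherits(table_controls, "otu_table"))
  if (length(unique(ages)) < 2L)
    stop("training ages are constant; age is unlearnable")
  X <- rel_abundance(table_controls)
  restore <- local_rng(seed)
  on.exit(restore())
  ## discrete sampling weeks as the regression response are expected here
  rf <- suppressWarnings(
    randomForest::randomForest(x = X, y = as.numeric(ages),
                               ntree = n_trees,
                               mtry = ceiling(ncol(X) / 3)))
  oob <- rf$predicted
  names(oob) <- rownames(X)
  structure(list(forest = rf, oob_predictions = oob,
                 training_ids = rownames(X), n_trees = n_trees),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("age_model: random forest, %d trees, %d training samples\n",
              x$n_trees, length(x$training_ids)))
  invisible(x)
}

#' @export
predict.age_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "otu_table")) rel_abundance(newdata)
       else as.matrix(newdata)
  stats::predict(object$forest, X)
}

rel_abundance <- function(table) {
  counts <- table$counts
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  counts / tot
}

#' Microbiota maturity and microbiota-by-age z-scores
#'
#' Per sample, with age bins defined by sampled week:
#' MM = predicted microbiota age - median predicted microbiota age of
#' control samples in the same bin; MAZ = MM / SD of predicted microbiota
#' age of those controls. Control predictions entering the bin statistics
#' are out-of-bag where the control was in the training set.
#'
#' @param model an [fit_age_model] fit.
#' @param table_all [otu_table] of all samples to score.
#' @param ages age (weeks) per sample; also the default binning variable.
#' @param control_mask logical: which samples are controls.
#' @param bins optional bin label per sample; default the sampled age.
#' @return object of class \code{maz_result}: data.frame with
#'   \code{sample}, \code{bin}, \code{predicted_age}, \code{MM},
#'   \code{MAZ}, \code{flagged} (bin had < 2 controls or zero SD).
#' @export
maz_scores <- function(model, table_all, ages, control_mask, bins = NULL) {
  stopifnot(inherits(model, "age_model"))
  ids <- sample_ids(table_all)
  if (is.null(bins)) bins <- ages
  in_train <- ids %in% model$training_ids
  pred <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (any(!in_train))
    pred[!in_train] <- predict(model, table_all[!in_train, ])
  pred[in_train] <- model$oob_predictions[ids[in_train]]
  mm <- maz <- rep(NA_real_, length(ids))
  flagged <- rep(FALSE, length(ids))
  for (b in unique(bins)) {
    sel <- bins == b
    ctrl <- sel & control_mask
    if (sum(ctrl) < 2L) {
      flagged[sel] <- TRUE
      next
    }
    med <- stats::median(pred[ctrl])
    sdv <- stats::sd(pred[ctrl])
    mm[sel] <- pred[sel] - med
    if (sdv > 0) maz[sel] <- mm[sel] / sdv else flagged[sel] <- TRUE
  }
  structure(list(scores = data.frame(sample = ids, bin = bins,
                                     predicted_age = unname(pred),
                                     MM = mm, MAZ = maz, flagged = flagged,
                                     control = control_mask,
                                     stringsAsFactors = FALSE)),
            class = "maz_result")
}

#' @export
print.maz_result <- function(x, ...) {
  s <- x$scores
  cat(sprintf("maz_result: %d samples, %d bins, %d flagged\n",
              nrow(s), length(unique(s$bin)), sum(s$flagged)))
  invisible(x)
}

#' Random-forest disease classification with leave-one-out error
#'
#' Per sampled week, classifies disease state from microbial composition.
#' Each of \code{n_trials} trials rarefies the table to even depth, then
#' fits a leave-one-out sequence of random forests per week (d/3 variables
#' per split); model error is the leave-one-out misclassification rate.
#' OTU importance is the mean increase in leave-one-out error (in %) when
#' that OTU's value in the held-out sample is replaced by a random draw
#' from the training samples.
#'
#' @param table [otu_table] of all samples.
#' @param labels binary disease labels (logical or two-level factor).
#' @param weeks week per sample; one model per week.
#' @param n_trees trees per forest; default 1000.
#' @param depth rarefaction depth; default 1000.
#' @param n_trials independent rarefaction trials; default 10.
#' @param seed integer seed.
#' @return object of class \code{rf_report}: \code{error} (week x trial
#'   matrix of LOO errors), \code{mean_error} per week, \code{importance}
#'   (OTU x week mean increase error, %), \code{params}.
#' @export
classify_disease <- function(table, labels, weeks, n_trees = 1000,
                             depth = 1000, n_trials = 10, seed = 1L) {
  stopifnot(inherits(table, "otu_table"))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must be binary")
  uweeks <- sort(unique(weeks))
  p <- ncol(table$counts)
  err <- matrix(NA_real_, length(uweeks), n_trials,
                dimnames = list(paste0("week", uweeks), NULL))
  imp <- matrix(0, p, length(uweeks),
                dimnames = list(otu_ids(table), paste0("week", uweeks)))
  imp_n <- integer(length(uweeks))
  restore <- local_rng(seed)
  on.exit(restore())
  for (tr in seq_len(n_trials)) {
    rt <- rarefy(table, depth = depth,
                 seed = sample.int(.Machine$integer.max, 1L))
    ids <- sample_ids(rt)
    keep <- match(ids, sample_ids(table))
    X <- rel_abundance(rt)
    y <- labels[keep]; wk <- weeks[keep]
    for (wi in seq_along(uweeks)) {
      sel <- which(wk == uweeks[wi])
      if (length(unique(y[sel])) < 2L ||
          min(table(droplevels(y[sel]))) < 2L) {
        message("week ", uweeks[wi],
                ": single class (or a class with one sample), skipped")
        next
      }
      Xw <- X[sel, , drop = FALSE]; yw <- droplevels(y[sel])
      nw <- length(sel)
      wrong <- logical(nw)
      dimp <- numeric(p)
      for (i in seq_len(nw)) {
        rf <- randomForest::randomForest(
          x = Xw[-i, , drop = FALSE], y = yw[-i], ntree = n_trees,
          mtry = max(1L, ceiling(p / 3)))
        pred <- stats::predict(rf, Xw[i, , drop = FALSE])
        wrong[i] <- pred != yw[i]
        ## permuted-feature predictions of the held-out sample
        Z <- Xw[rep(i, p), , drop = FALSE]
        donors <- sample(seq_len(nw - 1L), p, replace = TRUE)
        Z[cbind(seq_len(p), seq_len(p))] <-
          Xw[-i, , drop = FALSE][cbind(donors, seq_len(p))]
        predp <- stats::predict(rf, Z)
        dimp <- dimp + ((predp != yw[i]) - (pred != yw[i]))
      }
      err[wi, tr] <- mean(wrong)
      imp[, wi] <- imp[, wi] + 100 * dimp / nw
      imp_n[wi] <- imp_n[wi] + 1L
    }
  }
  imp <- sweep(imp, 2L, pmax(imp_n, 1L), "/")
  structure(list(error = err, mean_error = rowMeans(err, na.rm = TRUE),
                 importance = imp,
                 params = list(n_trees = n_trees, depth = depth,
                               n_trials = n_trials,
                               mtry = max(1L, ceiling(p / 3)))),
            class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat("rf_report: leave-one-out error by week\n")
  print(round(x$mean_error, 3))
  invisible(x)
}
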