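## Independent oracles used across tests.

## Exhaustive per-node orbit counts: enumerate ALL 3- and 4-subsets of the
## vertex set with combn, keep the connected ones (igraph), classify by
## induced degree sequence. Independent of the package's enumeration path.
oracle_count_orbits <- function(A) {
  A <- as.matrix(A); A[A != 0] <- 1
  n <- nrow(A)
  cnt <- matrix(0L, n, 15L, dimnames = list(NULL, paste0("o", 0:14)))
  cnt[, 1] <- as.integer(rowSums(A))
  connected <- function(S) {
    g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected")
    igraph::is_connected(g)
  }
  if (n >= 3) for (v in utils::combn(n, 3, simplify = FALSE)) {
    S <- A[v, v]
    if (!connected(S)) next
    ds <- rowSums(S)
    if (sum(ds) == 6) cnt[v, "o3"] <- cnt[v, "o3"] + 1L
    else {
      cnt[v[ds == 2], "o2"] <- cnt[v[ds == 2], "o2"] + 1L
      cnt[v[ds == 1], "o1"] <- cnt[v[ds == 1], "o1"] + 1L
    }
  }
  if (n >= 4) for (v in utils::combn(n, 4, simplify = FALSE)) {
    S <- A[v, v]
    if (!connected(S)) next
    ds <- rowSums(S); m <- sum(ds) / 2
    if (m == 6) cnt[v, "o14"] <- cnt[v, "o14"] + 1L
    else if (m == 5) {
      cnt[v[ds == 2], "o12"] <- cnt[v[ds == 2], "o12"] + 1L
      cnt[v[ds == 3], "o13"] <- cnt[v[ds == 3], "o13"] + 1L
    } else if (m == 4 && max(ds) == 2) cnt[v, "o8"] <- cnt[v, "o8"] + 1L
    else if (m == 4) {
      cnt[v[ds == 1], "o9"]  <- cnt[v[ds == 1], "o9"]  + 1L
      cnt[v[ds == 2], "o10"] <- cnt[v[ds == 2], "o10"] + 1L
      cnt[v[ds == 3], "o11"] <- cnt[v[ds == 3], "o11"] + 1L
    } else if (max(ds) == 3) {
      cnt[v[ds == 1], "o6"] <- cnt[v[ds == 1], "o6"] + 1L
      cnt[v[ds == 3], "o7"] <- cnt[v[ds == 3], "o7"] + 1L
    } else {
      cnt[v[ds == 1], "o4"] <- cnt[v[ds == 1], "o4"] + 1L
      cnt[v[ds == 2], "o5"] <- cnt[v[ds == 2], "o5"] + 1L
    }
  }
  cnt
}

random_adjacency <- function(n, p_edge, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p_edge)
  A + t(A)
}

## edge F1 against a precision matrix's off-diagonal pattern
edge_f1 <- function(adj_est, precision) {
  truth <- (abs(precision) > 1e-10) & upper.tri(precision)
  est <- (adj_est != 0) & upper.tri(adj_est)
  tp <- sum(truth & est)
  if (tp == 0) return(0)
  prec <- tp / sum(est)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

## tiny cohort config used by several tests
small_config <- function(seed = 1L, ...) {
  args <- list(...)
  base <- list(n_subjects_per_arm = 6, n_otus = 40, n_assoc_otus = 4,
               depth_lognormal = c(log(5000), 0.3), seed = seed)
  do.call(sim_config, utils::modifyList(base, args))
}

## Enumerate, from scratch, the automorphism orbits of all connected
## graphs on 2..4 vertices: returns a list with one entry per isomorphism
## class, each holding the adjacency and the vertex-orbit partition.
enumerate_graphlet_orbits <- function() {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  classes <- list()
  for (n in 2:4) {
    pairs <- t(utils::combn(n, 2))
    pp <- perms(seq_len(n))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      A <- matrix(0L, n, n)
      on <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) != 0)
      for (e in on) {
        A[pairs[e, 1], pairs[e, 2]] <- 1L
        A[pairs[e, 2], pairs[e, 1]] <- 1L
      }
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      if (!igraph::is_connected(g) || igraph::ecount(g) == 0) next
      ## already seen this isomorphism class?
      seen <- any(vapply(classes, function(cl)
        nrow(cl$A) == n && igraph::isomorphic(
          g, igraph::graph_from_adjacency_matrix(cl$A, mode = "undirected")),
        logical(1)))
      if (seen) next
      ## vertex orbits under the automorphism group
      autos <- Filter(function(p) all(A[p, p] == A), pp)
      orbit_of <- seq_len(n)
      for (p in autos)
        for (v in seq_len(n))
          orbit_of[p[v]] <- min(orbit_of[p[v]], orbit_of[v])
      ## iterate to closure
      repeat {
        prev <- orbit_of
        for (p in autos)
          for (v in seq_len(n))
            orbit_of[p[v]] <- min(orbit_of[p[v]], orbit_of[v])
        if (identical(prev, orbit_of)) break
      }
      classes[[length(classes) + 1]] <- list(A = A, orbits = orbit_of)
    }
  }
  classes
}

## binary disease cohort with a few discriminative OTUs (logistic-normal
## multinomial counts; planted effect on the latent log scale)
planted_disease <- function(n_per = 20, p = 60, effect = 1.5, seed = 1) {
  set.seed(seed)
  labels <- rep(c(FALSE, TRUE), each = n_per)
  disc <- 1:5
  base <- rnorm(p)
  Z <- matrix(base, 2 * n_per, p, byrow = TRUE) +
    matrix(rnorm(2 * n_per * p, sd = 1), 2 * n_per, p)
  Z[labels, disc] <- Z[labels, disc] + effect
  P <- exp(Z); P <- P / rowSums(P)
  counts <- t(apply(P, 1, function(pr) rmultinom(1, 5000, pr)[, 1]))
  rownames(counts) <- paste0("s", seq_len(2 * n_per))
  colnames(counts) <- paste0("OTU", seq_len(p))
  list(table = otu_table(counts), labels = labels, disc = paste0("OTU", disc))
}
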