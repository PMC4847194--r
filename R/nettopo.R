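## Graphlet-based topology: per-node orbit counts for all connected
## graphlets on <= 4 nodes (15 orbits, Przulj numbering: within each
## graphlet, orbits are ordered by node degree), graphlet correlation
## matrices over the 11 non-redundant orbits, graphlet correlation
## distance, MDS embedding, natural connectivity, attack curves, summary
## statistics and keystone ranking.

## Accept an igraph graph, an association_network, or an adjacency matrix;
## return a plain 0/1 symmetric adjacency matrix with zero diagonal.
as_adjacency <- function(graph) {
  if (inherits(graph, "association_network")) {
    n <- length(graph$nodes)
    A <- matrix(0L, n, n, dimnames = list(graph$nodes, graph$nodes))
    if (nrow(graph$edges)) {
      ia <- match(graph$edges$otu_a, graph$nodes)
      ib <- match(graph$edges$otu_b, graph$nodes)
      A[cbind(ia, ib)] <- 1L; A[cbind(ib, ia)] <- 1L
    }
    return(A)
  }
  if (inherits(graph, "igraph")) {
    if (any(igraph::which_loop(graph)) || any(igraph::which_multiple(graph)))
      stop("self-loops / multi-edges are not allowed")
    A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
    A[A != 0] <- 1L
    return(A)
  }
  A <- as.matrix(graph)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  A[A != 0] <- 1L
  storage.mode(A) <- "integer"
  if (is.null(rownames(A)) && nrow(A) > 0L)
    rownames(A) <- colnames(A) <- paste0("V", seq_len(nrow(A)))
  A
}

#' The non-redundant graphlet orbits on up to four nodes
#'
#' Of the 15 automorphism orbits of connected graphlets with at most four
#' nodes, four (3, 12, 13, 14) are linearly dependent on the others across
#' nodes; the remaining 11 form the signature used for graphlet
#' correlation distances.
#'
#' @return integer vector of the 11 orbit indices.
#' @export
nonredundant_orbits <- function() c(0L, 1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L)

#' Per-node graphlet orbit counts
#'
#' Exact induced-subgraph counts of the 15 orbits of connected graphlets on
#' at most 4 nodes, per node. Connected 3- and 4-node vertex subsets are
#' enumerated (each exactly once) and classified by their induced degree
#' sequence.
#'
#' @param graph simple undirected graph (igraph, [association_network], or
#'   adjacency matrix).
#' @return object of class \code{orbit_signature}: integer matrix, nodes x
#'   15 orbits (columns \code{o0}..\code{o14}).
#' @export
count_orbits <- function(graph) {
  A <- as_adjacency(graph)
  n <- nrow(A)
  cnt <- matrix(0L, n, 15L,
                dimnames = list(rownames(A), paste0("o", 0:14)))
  deg <- rowSums(A)
  cnt[, "o0"] <- as.integer(deg)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  ## connected triples: every connected 3-set has a node adjacent to both
  ## others; enumerate (center, pair-of-neighbors), dedupe
  trip <- NULL
  for (c0 in seq_len(n)) {
    nb <- nbr[[c0]]
    if (length(nb) >= 2L) {
      pr <- utils::combn(nb, 2L)
      trip <- rbind(trip, cbind(c0, t(pr)))
    }
  }
  if (!is.null(trip) && nrow(trip)) {
    trip <- t(apply(trip, 1L, sort))
    trip <- unique(trip)
    for (r in seq_len(nrow(trip))) {
      v <- trip[r, ]
      m <- A[v[1], v[2]] + A[v[1], v[3]] + A[v[2], v[3]]
      if (m == 3L) {
        cnt[v, "o3"] <- cnt[v, "o3"] + 1L
      } else {                               # path: center has degree 2
        dsub <- c(A[v[1], v[2]] + A[v[1], v[3]],
                  A[v[1], v[2]] + A[v[2], v[3]],
                  A[v[1], v[3]] + A[v[2], v[3]])
        cnt[v[dsub == 2L], "o2"] <- cnt[v[dsub == 2L], "o2"] + 1L
        cnt[v[dsub == 1L], "o1"] <- cnt[v[dsub == 1L], "o1"] + 1L
      }
    }
    ## connected quads: each contains a connected triple plus an adjacent node
    quad_keys <- new.env(hash = TRUE, parent = emptyenv())
    quads <- vector("list", 256L); nq <- 0L
    for (r in seq_len(nrow(trip))) {
      v <- trip[r, ]
      ext <- setdiff(which(A[v[1], ] | A[v[2], ] | A[v[3], ]), v)
      for (k in ext) {
        q <- sort(c(v, k))
        key <- paste(q, collapse = ".")
        if (is.null(quad_keys[[key]])) {
          quad_keys[[key]] <- TRUE
          nq <- nq + 1L
          if (nq > length(quads)) quads <- c(quads, vector("list", length(quads)))
          quads[[nq]] <- q
        }
      }
    }
    if (nq > 0L) for (r in seq_len(nq)) {
      q <- quads[[r]]
      S <- A[q, q]
      ds <- rowSums(S)
      m <- sum(ds) / 2L
      if (m == 6L) {                          # K4
        cnt[q, "o14"] <- cnt[q, "o14"] + 1L
      } else if (m == 5L) {                   # diamond
        cnt[q[ds == 2L], "o12"] <- cnt[q[ds == 2L], "o12"] + 1L
        cnt[q[ds == 3L], "o13"] <- cnt[q[ds == 3L], "o13"] + 1L
      } else if (m == 4L) {
        if (max(ds) == 2L) {                  # 4-cycle
          cnt[q, "o8"] <- cnt[q, "o8"] + 1L
        } else {                              # paw (tailed triangle)
          cnt[q[ds == 1L], "o9"]  <- cnt[q[ds == 1L], "o9"]  + 1L
          cnt[q[ds == 2L], "o10"] <- cnt[q[ds == 2L], "o10"] + 1L
          cnt[q[ds == 3L], "o11"] <- cnt[q[ds == 3L], "o11"] + 1L
        }
      } else {                                # m == 3: tree
        if (max(ds) == 3L) {                  # star
          cnt[q[ds == 1L], "o6"] <- cnt[q[ds == 1L], "o6"] + 1L
          cnt[q[ds == 3L], "o7"] <- cnt[q[ds == 3L], "o7"] + 1L
        } else {                              # path P4
          cnt[q[ds == 1L], "o4"] <- cnt[q[ds == 1L], "o4"] + 1L
          cnt[q[ds == 2L], "o5"] <- cnt[q[ds == 2L], "o5"] + 1L
        }
      }
    }
  }
  structure(cnt, class = c("orbit_signature", "matrix"))
}

#' @export
print.orbit_signature <- function(x, ...) {
  cat(sprintf("orbit_signature: %d nodes x 15 orbits\n", nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Graphlet correlation matrix
#'
#' Spearman correlation matrix across nodes of the 11 non-redundant orbit
#' counts. A single all-ones dummy row is appended before correlating so
#' that orbit columns constant across nodes remain well-defined.
#'
#' @param sig an \code{orbit_signature} from [count_orbits] (or a graph,
#'   which is counted first).
#' @return 11 x 11 symmetric correlation matrix with unit diagonal.
#' @export
graphlet_correlation_matrix <- function(sig) {
  if (!inherits(sig, "orbit_signature")) sig <- count_orbits(sig)
  if (nrow(sig) < 2L) stop("need at least 2 nodes")
  cols <- paste0("o", nonredundant_orbits())
  m <- rbind(unclass(sig)[, cols, drop = FALSE], 1)
  gcm <- suppressWarnings(stats::cor(m, method = "spearman"))
  gcm[is.na(gcm)] <- 0      # columns constant even after the dummy row
  diag(gcm) <- 1
  gcm
}

#' Graphlet correlation distance
#'
#' Frobenius norm of the difference of the upper triangles (diagonal
#' excluded) of two graphlet correlation matrices.
#'
#' @param gcm_a,gcm_b matrices from [graphlet_correlation_matrix] (or
#'   graphs, which are converted first).
#' @return non-negative scalar.
#' @export
gcd <- function(gcm_a, gcm_b) {
  if (!(is.matrix(gcm_a) && nrow(gcm_a) == ncol(gcm_a) &&
        isTRUE(all.equal(diag(gcm_a), rep(1, nrow(gcm_a)), check.attributes = FALSE))))
    gcm_a <- graphlet_correlation_matrix(gcm_a)
  if (!(is.matrix(gcm_b) && nrow(gcm_b) == ncol(gcm_b) &&
        isTRUE(all.equal(diag(gcm_b), rep(1, nrow(gcm_b)), check.attributes = FALSE))))
    gcm_b <- graphlet_correlation_matrix(gcm_b)
  d <- (gcm_a - gcm_b)[upper.tri(gcm_a)]
  sqrt(sum(d^2))
}

#' Classical MDS embedding of network distances
#'
#' Torgerson classical multidimensional scaling of a pairwise distance
#' matrix into 2-D. Coordinates are centered; each axis's sign is fixed so
#' the first network's coordinate is non-negative.
#'
#' @param distance_matrix symmetric non-negative distance matrix.
#' @return matrix, networks x 2 coordinates.
#' @export
embed_networks <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  k <- min(2L, nrow(D) - 1L)
  xy <- stats::cmdscale(D, k = k)
  if (ncol(xy) < 2L)
    xy <- cbind(xy, matrix(0, nrow(D), 2L - ncol(xy)))
  for (j in 1:2) if (xy[1L, j] < 0) xy[, j] <- -xy[, j]
  colnames(xy) <- c("MDS1", "MDS2")
  xy
}

#' Natural connectivity
#'
#' ln of the average of exp(eigenvalues) of the (unweighted, unsigned)
#' adjacency matrix; a spectral measure of route redundancy. An edgeless
#' graph scores 0; an empty node set is an error.
#'
#' @param graph simple undirected graph (any accepted form).
#' @return scalar.
#' @export
natural_connectivity <- function(graph) {
  A <- as_adjacency(graph)
  n <- nrow(A)
  if (n == 0L) stop("natural connectivity is undefined on an empty node set")
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(sum(exp(ev - m))) - log(n)        # log-mean-exp, overflow-safe
}

#' Attack-robustness curve
#'
#' Removes nodes one at a time — uniformly at random, by degree, or by
#' betweenness centrality — recording natural connectivity of the remaining
#' graph against the fraction of nodes removed. Targeted rankings are
#' recomputed after each removal by default (adaptive); random attacks are
#' averaged over \code{n_rep} repetitions.
#'
#' @param graph simple undirected graph.
#' @param strategy \code{"random"}, \code{"degree"} or \code{"betweenness"}.
#' @param n_rep repetitions for the random strategy; default 50.
#' @param adaptive recompute the target ranking after each removal
#'   (default TRUE); FALSE ranks once on the intact graph.
#' @param seed integer seed (random strategy).
#' @return object of class \code{attack_curve}: \code{fraction_removed}
#'   grid on [0, 1), \code{natural_connectivity} values (mean over
#'   repetitions for random attacks), \code{strategy}, \code{n_rep},
#'   \code{seed}, and for random attacks the per-repetition matrix
#'   \code{replicates}.
#' @export
attack_curve <- function(graph, strategy = c("random", "degree", "betweenness"),
                         n_rep = 50, adaptive = TRUE, seed = 1L) {
  strategy <- match.arg(strategy)
  A <- as_adjacency(graph)
  n <- nrow(A)
  if (n < 1L) stop("empty graph")
  frac <- (seq_len(n) - 1L) / n
  one_run <- function(order_fun) {
    keep <- seq_len(n)
    vals <- numeric(n)
    for (k in seq_len(n)) {
      vals[k] <- natural_connectivity(A[keep, keep, drop = FALSE])
      if (k == n) break
      keep <- keep[-order_fun(keep)]
    }
    vals
  }
  score_pick <- function(score) function(keep) {
    s <- score(keep)
    which.max(s)                            # ties: first (lowest index)
  }
  if (strategy == "random") {
    restore <- local_rng(seed)
    on.exit(restore())
    reps <- matrix(NA_real_, n, n_rep)
    for (r in seq_len(n_rep)) {
      ord <- sample(n)
      keep <- seq_len(n)
      for (k in seq_len(n)) {
        reps[k, r] <- natural_connectivity(A[keep, keep, drop = FALSE])
        if (k < n) keep <- setdiff(keep, ord[k])
      }
    }
    vals <- rowMeans(reps)
  } else if (strategy == "degree") {
    if (!adaptive) {
      d0 <- rowSums(A)
      picker <- function(keep) which.max(d0[keep])
    } else picker <- score_pick(function(keep) rowSums(A[keep, keep, drop = FALSE]))
    vals <- one_run(picker); reps <- NULL
  } else {
    bet <- function(keep) {
      g <- igraph::graph_from_adjacency_matrix(A[keep, keep, drop = FALSE],
                                               mode = "undirected")
      igraph::betweenness(g)
    }
    if (!adaptive) {
      b0 <- bet(seq_len(n))
      picker <- function(keep) which.max(b0[keep])
    } else picker <- score_pick(bet)
    vals <- one_run(picker); reps <- NULL
  }
  structure(list(strategy = strategy, fraction_removed = frac,
                 natural_connectivity = vals, n_rep = if (strategy == "random") n_rep else NA_integer_,
                 adaptive = adaptive, seed = seed, replicates = reps),
            class = "attack_curve")
}

#' @export
print.attack_curve <- function(x, ...) {
  cat(sprintf("attack_curve (%s%s): %d steps, connectivity %.3f -> %.3f\n",
              x$strategy, if (isTRUE(x$adaptive)) ", adaptive" else "",
              length(x$fraction_removed),
              x$natural_connectivity[1],
              x$natural_connectivity[length(x$natural_connectivity)]))
  invisible(x)
}

#' Global network summary statistics
#'
#' @param net an [association_network] (or igraph / adjacency; phylum
#'   assortativity requires labels).
#' @return list: node and edge counts, diameter of the largest connected
#'   component, mean degree, mean betweenness centrality, greedy-modularity
#'   community modularity, and categorical assortativity over phylum labels
#'   (NA when unavailable).
#' @export
summary_stats <- function(net) {
  g <- if (inherits(net, "association_network")) as_igraph(net)
       else igraph::graph_from_adjacency_matrix(as_adjacency(net),
                                                mode = "undirected")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  phy <- igraph::vertex_attr(g, "phylum")
  assort <- if (!is.null(phy) && length(unique(phy)) > 1L)
    igraph::assortativity_nominal(g, as.integer(factor(phy))) else NA_real_
  mod <- if (igraph::ecount(g) > 0)
    igraph::modularity(igraph::cluster_fast_greedy(g)) else NA_real_
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       diameter = if (igraph::vcount(sub) > 1L)
         igraph::diameter(sub, weights = NA) else 0,
       mean_degree = mean(igraph::degree(g)),
       mean_betweenness = mean(igraph::betweenness(g)),
       modularity = mod,
       phylum_assortativity = assort)
}

#' Keystone (hub + bottleneck) taxa
#'
#' Ranks nodes by the sum of their degree rank and betweenness-centrality
#' rank (1 = highest); ties are broken by betweenness, then node id.
#'
#' @param net graph in any accepted form.
#' @param k number of keystones to return; default 2 (all nodes if k
#'   exceeds the node count).
#' @return data.frame: \code{otu}, \code{degree}, \code{betweenness},
#'   \code{rank_score}, ordered best first.
#' @export
top_keystones <- function(net, k = 2) {
  A <- as_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  deg <- igraph::degree(g)
  bet <- igraph::betweenness(g)
  r_deg <- rank(-deg, ties.method = "min")
  r_bet <- rank(-bet, ties.method = "min")
  score <- r_deg + r_bet
  ord <- order(score, -bet, rownames(A))
  k <- min(k, nrow(A))
  out <- data.frame(otu = rownames(A)[ord], degree = deg[ord],
                    betweenness = bet[ord], rank_score = score[ord],
                    row.names = NULL)
  out[seq_len(k), ]
}
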