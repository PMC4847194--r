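test_that("orbit counts match the exhaustive-enumeration oracle", {
  ## small canonical graphs
  tri <- matrix(0L, 3, 3); tri[upper.tri(tri)] <- 1L; tri <- tri + t(tri)
  sig <- unclass(count_orbits(tri))
  expect_true(all(sig[, "o0"] == 2L))
  expect_true(all(sig[, "o3"] == 1L))
  expect_true(all(sig[, paste0("o", 4:14)] == 0L))

  p4 <- matrix(0L, 4, 4)
  p4[1, 2] <- p4[2, 3] <- p4[3, 4] <- 1L; p4 <- p4 + t(p4)
  expect_identical(unname(unclass(count_orbits(p4))),
                   unname(oracle_count_orbits(p4)))

  ## random graphs up to 8 nodes, many seeds, several densities
  for (s in 1:40) {
    n <- 4L + (s %% 5L)
    A <- random_adjacency(n, p_edge = 0.25 + 0.1 * (s %% 4L), seed = s)
    expect_identical(unname(unclass(count_orbits(A))),
                     unname(oracle_count_orbits(A)),
                     info = paste("seed", s))
  }

  ## handshake identity: sum of orbit-0 = 2 |E|
  A <- random_adjacency(12, 0.3, seed = 99)
  expect_equal(sum(count_orbits(A)[, "o0"]), sum(A))
  expect_error(count_orbits(diag(3)), "loops")
})

test_that("graphlet correlation matrix and distance behave as a signature", {
  A <- random_adjacency(15, 0.3, seed = 5)
  B <- random_adjacency(15, 0.7, seed = 6)
  ga <- graphlet_correlation_matrix(A)
  gb <- graphlet_correlation_matrix(B)
  expect_equal(dim(ga), c(11L, 11L))
  expect_equal(diag(ga), rep(1, 11), ignore_attr = TRUE)
  expect_equal(ga, t(ga))
  expect_equal(gcd(ga, ga), 0)
  expect_equal(gcd(ga, gb), gcd(gb, ga))
  expect_gt(gcd(ga, gb), 0)

  ## ring graph: all nodes identical, so orbit columns are constant and
  ## the dummy row makes co-constant orbits perfectly correlated
  ring <- matrix(0L, 8, 8)
  for (i in 1:8) { j <- i %% 8 + 1; ring[i, j] <- ring[j, i] <- 1L }
  gr <- graphlet_correlation_matrix(ring)
  sig <- unclass(count_orbits(ring))[, paste0("o", nonredundant_orbits())]
  ## columns constant at a common value above the dummy's 1 rank together
  co <- colnames(sig)[apply(sig, 2, function(x) all(x == x[1]) && x[1] > 1)]
  expect_true(all(gr[co, co] == 1))

  ## oracle value for gcd(K6, P6) scripted independently
  k6 <- matrix(1L, 6, 6); diag(k6) <- 0L
  p6 <- matrix(0L, 6, 6)
  for (i in 1:5) { p6[i, i + 1] <- p6[i + 1, i] <- 1L }
  ora <- local({
    spearman_dummy <- function(M) {
      cc <- suppressWarnings(
        stats::cor(rbind(M, 1), method = "spearman"))
      cc[is.na(cc)] <- 0; diag(cc) <- 1
      cc
    }
    ca <- spearman_dummy(oracle_count_orbits(k6)[, paste0("o", c(0:2, 4:11))])
    cb <- spearman_dummy(oracle_count_orbits(p6)[, paste0("o", c(0:2, 4:11))])
    sqrt(sum(((ca - cb)[upper.tri(ca)])^2))
  })
  expect_equal(gcd(k6, p6), ora, tolerance = 1e-12)
})

test_that("classical MDS embedding respects simple geometries", {
  ## three equidistant networks form an equilateral triangle
  D <- matrix(1, 3, 3); diag(D) <- 0
  xy <- embed_networks(D)
  d12 <- dist(xy)
  expect_equal(as.vector(d12), rep(1, 3), tolerance = 1e-8)
  expect_true(xy[1, 1] >= 0 && xy[1, 2] >= 0)

  ## duplicated network -> coincident points
  D2 <- rbind(c(0, 0, 2), c(0, 0, 2), c(2, 2, 0))
  xy2 <- embed_networks(D2)
  expect_lt(max(abs(xy2[1, ] - xy2[2, ])), 1e-6)

  ## embedding distances track input distances on random pseudo-distances
  set.seed(3)
  P <- matrix(runif(5 * 4), 5)
  Dm <- as.matrix(dist(P))
  xy3 <- embed_networks(Dm)
  expect_gt(cor(as.vector(dist(xy3)), as.vector(stats::as.dist(Dm))), 0.9)
})

test_that("natural connectivity matches direct eigendecomposition", {
  expect_equal(natural_connectivity(matrix(0, 4, 4)), 0)
  tri <- matrix(0L, 3, 3); tri[upper.tri(tri)] <- 1L; tri <- tri + t(tri)
  expect_equal(natural_connectivity(tri), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  for (s in 1:10) {
    n <- sample(20:200, 1)
    A <- random_adjacency(n, 2 / n, seed = s + 1000)
    direct <- log(mean(exp(eigen(A, symmetric = TRUE)$values)))
    expect_equal(natural_connectivity(A), direct, tolerance = 1e-9)
  }
  ## adding any edge strictly increases it
  for (s in 1:10) {
    A <- random_adjacency(8, 0.3, seed = s)
    off <- which(A == 0 & upper.tri(A))
    if (!length(off)) next
    pick <- off[1]
    A2 <- A; A2[pick] <- 1L; A2[cbind(col(A)[pick], row(A)[pick])] <- 1L
    A2 <- pmax(A2, t(A2))
    expect_gt(natural_connectivity(A2), natural_connectivity(A))
  }
  expect_error(natural_connectivity(matrix(0, 0, 0)), "empty")
})

test_that("attack curves expose hub fragility", {
  star <- matrix(0L, 8, 8)
  star[1, 2:8] <- star[2:8, 1] <- 1L
  deg <- attack_curve(star, "degree")
  ## removing the hub first disconnects everything
  expect_equal(deg$natural_connectivity[2], 0, tolerance = 1e-12)
  rnd <- attack_curve(star, "random", n_rep = 50, seed = 2L)
  expect_true(all(deg$natural_connectivity <=
                    rnd$natural_connectivity + 1e-12))
  ## reproducible given seed
  rnd2 <- attack_curve(star, "random", n_rep = 50, seed = 2L)
  expect_identical(rnd$natural_connectivity, rnd2$natural_connectivity)
  ## betweenness attack also takes the hub first
  bet <- attack_curve(star, "betweenness")
  expect_equal(bet$natural_connectivity[2], 0, tolerance = 1e-12)
  expect_equal(deg$fraction_removed, (0:7) / 8)
})

test_that("summary statistics and keystones match hand-computable graphs", {
  p4 <- matrix(0L, 4, 4)
  p4[1, 2] <- p4[2, 3] <- p4[3, 4] <- 1L; p4 <- p4 + t(p4)
  s <- summary_stats(p4)
  expect_equal(s$diameter, 3)
  expect_equal(s$n_edges, 3)

  ## two single-phylum cliques, disconnected: assortativity 1
  A <- matrix(0L, 6, 6)
  A[1:3, 1:3] <- 1L; A[4:6, 4:6] <- 1L; diag(A) <- 0L
  rownames(A) <- colnames(A) <- paste0("t", 1:6)
  net <- association_network(
    nodes = rownames(A),
    edges = data.frame(otu_a = c("t1", "t1", "t2", "t4", "t4", "t5"),
                       otu_b = c("t2", "t3", "t3", "t5", "t6", "t6"),
                       sign = 1, weight = 1, stars_frequency = 1),
    phylum = rep(c("Firmicutes", "Bacteroidetes"), each = 3))
  s2 <- summary_stats(net)
  expect_equal(s2$phylum_assortativity, 1)

  ## star center is the unique top keystone
  star <- matrix(0L, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1L
  rownames(star) <- colnames(star) <- paste0("v", 1:5)
  ks <- top_keystones(star, k = 1)
  expect_identical(ks$otu, "v1")

  ## barbell bridge outranks clique members on betweenness
  bb <- matrix(0L, 7, 7)
  bb[1:3, 1:3] <- 1L; bb[5:7, 5:7] <- 1L; diag(bb) <- 0L
  bb[3, 4] <- bb[4, 3] <- bb[4, 5] <- bb[5, 4] <- 1L
  rownames(bb) <- colnames(bb) <- paste0("n", 1:7)
  g <- igraph::graph_from_adjacency_matrix(bb, mode = "undirected")
  expect_gt(igraph::betweenness(g)["n4"], max(igraph::betweenness(g)[c("n1", "n2")]))
  ks2 <- top_keystones(bb, k = 3)
  expect_true("n4" %in% ks2$otu[1:3])

  ## k beyond node count returns all nodes
  expect_equal(nrow(top_keystones(star, k = 99)), 5L)
})
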