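# Contact counting, interaction strengths and network parameters.

test_that("contact counts match a brute-force atom-pair scan", {
  set.seed(3)
  for (trial in 1:5) {
    tm <- rand_toy_model(nres = 7, ncontacts = 3)
    n <- count_contacts(tm$model)
    # independent O(atoms^2) double loop
    A <- tm$model$atoms
    nres <- nchar(tm$model$sequence)
    ref <- matrix(0L, nres, nres)
    for (a in seq_len(nrow(A))) for (b in seq_len(nrow(A))) {
      if (a >= b) next
      ra <- A$res_index[a]; rb <- A$res_index[b]
      if (ra == rb || abs(ra - rb) == 1) next
      d <- sqrt((A$x[a] - A$x[b])^2 + (A$y[a] - A$y[b])^2 +
                  (A$z[a] - A$z[b])^2)
      if (d <= 4.5) {
        ref[ra, rb] <- ref[ra, rb] + 1L
        ref[rb, ra] <- ref[rb, ra] + 1L
      }
    }
    expect_equal(n, ref)
    # and equals the engineered spec
    for (r in seq_len(nrow(tm$contacts)))
      expect_equal(n[tm$contacts$i[r], tm$contacts$j[r]],
                   tm$contacts$n_pairs[r])
  }
})

test_that("sequence neighbours and distant pairs contribute no contacts", {
  # residues far apart: zero everywhere
  pdb <- tempfile(fileext = ".pdb")
  make_toy_structure("AVLIK", NULL, pdb)
  m <- read_structure(pdb)
  expect_true(all(count_contacts(m) == 0))
  # overlapping side chains of adjacent residues are ignored
  atoms <- data.frame(res_index = c(1, 2, 3), elety = "CB",
                      x = c(0, 1, 50), y = 0, z = 0)
  m2 <- structure_model("AVL", atoms)
  expect_equal(count_contacts(m2)[1, 2], 0L)
  # chain break: adjacent in order but numbering gap -> counted
  m3 <- structure_model("AVL", atoms, resno = c(1, 5, 9))
  expect_equal(count_contacts(m3)[1, 2], 1L)
})

test_that("interaction strength follows the normalized-contact formula", {
  expect_equal(interaction_strength(0, 100, 100), 0)
  expect_equal(interaction_strength(3, 100, 100), 3)
  expect_equal(interaction_strength(5, 50, 200), 5)
  # homogeneity: doubling the count doubles the strength
  set.seed(5)
  n <- sample(1:20, 10); Ni <- runif(10, 40, 110); Nj <- runif(10, 40, 110)
  expect_equal(interaction_strength(2 * n, Ni, Nj),
               2 * interaction_strength(n, Ni, Nj))
  expect_error(interaction_strength(1, 0, 50), "positive")
  expect_error(interaction_strength(1, -3, 50), "positive")
})

test_that("the I_min cutoff is strict and isolated nodes are kept", {
  # engineer I values via a custom normalization: N = 100 for all types
  norm <- setNames(rep(100, 21), c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X"))
  pdb <- tempfile(fileext = ".pdb")
  # n_pairs 2, 3, 5 -> I = 2, 3, 5 under N = 100
  make_toy_structure("AVLIKME", data.frame(i = c(1, 3, 5), j = c(3, 5, 7),
                                           n_pairs = c(2, 3, 5)), pdb)
  m <- read_structure(pdb)
  p2 <- build_psn(m, norm = norm, i_min = 2)
  expect_equal(nrow(p2$edges), 2L)       # I = 2 excluded: strict >
  expect_equal(sort(p2$edges$I_ij), c(3, 5))
  p0 <- build_psn(m, norm = norm, i_min = 0)
  expect_equal(nrow(p0$edges), 3L)
  expect_equal(p0$n_nodes, 7L)           # isolated residues still nodes
})

test_that("degrees, hubs and the degree-sum identity", {
  # star with 5 leaves
  atoms <- data.frame(res_index = 1:7, elety = "CB",
                      x = seq(0, 180, by = 30), y = 0, z = 0)
  m <- structure_model("AVLIKME", atoms)
  p <- build_psn(m, i_min = 0)
  p$edges <- data.frame(i = rep(1, 5), j = 3:7, n_ij = 1, I_ij = 5)
  d <- degrees(p)
  expect_equal(d[1], 5L)
  expect_equal(sum(d), 2L * nrow(p$edges))
  expect_equal(sum(is_hub(d)), 1L)
  expect_true(is_hub(4))
  expect_false(is_hub(3))
  expect_equal(hubs(p), 1L)
})

test_that("path and star betweenness match closed forms", {
  mk <- function(n, edges) {
    atoms <- data.frame(res_index = seq_len(n), elety = "CB",
                        x = 30 * seq_len(n), y = 0, z = 0)
    p <- build_psn(structure_model(strrep("A", n), atoms), i_min = 0)
    p$edges <- data.frame(i = edges[, 1], j = edges[, 2], n_ij = 1, I_ij = 5)
    p
  }
  path3 <- mk(3, cbind(c(1, 2), c(2, 3)))
  expect_equal(node_betweenness(path3), c(0, 1, 0))
  expect_equal(edge_betweenness(path3)$eb, c(2, 2))
  star4 <- mk(4, cbind(1, 2:4))
  expect_equal(node_betweenness(star4), c(3, 0, 0, 0))
  single <- mk(2, cbind(1, 2))
  expect_equal(edge_betweenness(single)$eb, 1)
})

test_that("betweenness equals exhaustive geodesic enumeration on random graphs", {
  set.seed(42)
  for (trial in 1:30) {
    n <- sample(5:12, 1)
    edges <- rand_edges(n, p = runif(1, 0.2, 0.5))
    if (nrow(edges) == 0) next
    atoms <- data.frame(res_index = seq_len(n), elety = "CB",
                        x = 30 * seq_len(n), y = 0, z = 0)
    p <- build_psn(structure_model(strrep("A", n), atoms), i_min = 0)
    p$edges <- data.frame(i = edges[, 1], j = edges[, 2], n_ij = 1, I_ij = 5)
    ref <- oracle_betweenness(n, edges)
    expect_equal(node_betweenness(p), ref$nb, tolerance = 1e-10)
    expect_equal(edge_betweenness(p)$eb, ref$eb, tolerance = 1e-10)
  }
})

test_that("largest-cluster sizes are non-increasing in I_min", {
  set.seed(9)
  for (trial in 1:5) {
    tm <- rand_toy_model(nres = 8, ncontacts = 5)
    scan <- largest_cluster_scan(tm$model, i_min_list = seq(0, 8, by = 0.5))
    expect_true(all(diff(scan$lclu) <= 0))
    expect_equal(scan$lclu[nrow(scan)], 1L)  # beyond every I: edgeless
  }
  # i_min = 0 on a fully connected fixture spans all residues
  pdb <- tempfile(fileext = ".pdb")
  make_toy_structure("AVLIK",
                     data.frame(i = c(1, 2, 3, 1), j = c(3, 4, 5, 4),
                                n_pairs = 2),
                     pdb)
  m <- read_structure(pdb)
  expect_equal(largest_cluster_scan(m, i_min_list = 0)$lclu, 5L)
})

test_that("dataset-derived normalization records its mode and covers types", {
  set.seed(21)
  models <- lapply(1:3, function(i) rand_toy_model(nres = 6)$model)
  expect_warning(norm <- derive_normalization(models), "fallback")
  expect_equal(attr(norm, "mode"), "derived")
  expect_true(all(norm > 0))
  expect_true(all(c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X") %in%
                    names(norm)))
})
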