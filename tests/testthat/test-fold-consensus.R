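# f-CAM construction, conserved edges, consensus parameters, hot spots.

# small helper: unweighted NAM from an explicit edge list
nam_from_edges <- function(id, L, edges, phantom = integer(0)) {
  if (nrow(edges)) {
    mat <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                                j = c(edges[, 2], edges[, 1]),
                                x = rep(1, 2 * nrow(edges)), dims = c(L, L))
  } else mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(L, L))
  psnfold:::new_nam(id, mat, L, phantom = phantom)
}

test_that("f-CAM counts edge occurrences and is order-invariant", {
  L <- 10
  e1 <- cbind(1, 5)
  nams <- c(lapply(1:7, function(s) nam_from_edges(paste0("s", s), L, e1)),
            lapply(8:10, function(s)
              nam_from_edges(paste0("s", s), L, cbind(2, 6))))
  f <- build_fcam(nams)
  expect_equal(f$mat[1, 5], 7)
  expect_equal(f$mat[2, 6], 3)
  expect_equal(f$n_structures, 10L)
  # permutation invariance
  f2 <- build_fcam(rev(nams))
  expect_equal(as.matrix(f$mat), as.matrix(f2$mat))
  # single NAM: f-CAM equals the NAM; empty NAMs: all zero
  f1 <- build_fcam(nams[1])
  expect_equal(as.matrix(f1$mat), as.matrix(nams[[1]]$mat))
  f0 <- build_fcam(list(nam_from_edges("e", L, cbind(integer(0), integer(0)))))
  expect_true(all(f0$mat == 0))
  # mixed lengths fatal
  expect_error(build_fcam(c(nams[1], list(nam_from_edges("x", 9, e1)))),
               "mixed")
})

test_that("conserved-edge selection honours threshold, ranking and percent", {
  L <- 10
  mk <- function(present, edge) lapply(seq_len(10), function(s)
    if (s <= present) edge else NULL)
  edges_per_s <- lapply(1:10, function(s) {
    e <- rbind(if (s <= 9) c(1, 5), if (s <= 7) c(2, 6), if (s <= 4) c(3, 7),
               if (s <= 9) c(1, 4))
    if (is.null(e)) matrix(integer(0), ncol = 2) else e
  })
  nams <- lapply(1:10, function(s)
    nam_from_edges(paste0("s", s), L, edges_per_s[[s]]))
  top <- top_conserved_edges(build_fcam(nams), min_frac = 0.5, top_k = 20)
  # the 40% edge is excluded; ties at count 9 break by ascending columns
  expect_equal(top$count, c(9L, 9L, 7L))
  expect_equal(top[1, c("col_i", "col_j")], data.frame(col_i = 1, col_j = 4),
               ignore_attr = TRUE)
  expect_equal(top$freq_pct, c(90L, 90L, 70L))
  top1 <- top_conserved_edges(build_fcam(nams), top_k = 1)
  expect_equal(nrow(top1), 1L)
})

test_that("hub weights use strict more-than-half for fold specificity", {
  L <- 12
  star <- cbind(1, 2:5)  # column 1 has degree 4
  nams <- lapply(1:10, function(s)
    nam_from_edges(paste0("s", s), L, if (s <= 5) star else
      matrix(integer(0), ncol = 2)))
  hw <- hub_weights(nams)
  expect_equal(hw[1], 5L)
  expect_equal(sum(hw), 5L)  # leaves have degree 1
  # hub in exactly half the structures is NOT fold-specific
  expect_length(fold_specific_hubs(hw, 10), 0)
  nams6 <- lapply(1:10, function(s)
    nam_from_edges(paste0("s", s), L, if (s <= 6) star else
      matrix(integer(0), ncol = 2)))
  expect_equal(fold_specific_hubs(hub_weights(nams6), 10), 1L)
})

test_that("top-k frequency positions behave on degenerate ensembles", {
  L <- 8
  path_edges <- cbind(1:4, 2:5)  # path over columns 1..5
  one <- nam_from_edges("s1", L, path_edges)
  # a single structure: frequency list is 0/1; significant = its top-k
  suppressWarnings(res <- topk_frequency_positions(list(one), "nb",
                                                   k = 3, m = 5))
  ref <- oracle_betweenness(L, path_edges)
  ord <- order(-ref$nb, seq_len(L))[1:3]
  expect_setequal(res$significant, ord)
  # ensemble of identical structures: same set, counts all equal n
  many <- lapply(1:6, function(s) one)
  suppressWarnings(res6 <- topk_frequency_positions(many, "nb", k = 3, m = 5))
  expect_setequal(res6$significant, ord)
  expect_true(all(res6$counts[as.character(ord)] == 6))
  # EB contributes both endpoint columns
  suppressWarnings(reb <- topk_frequency_positions(list(one), "eb",
                                                   k = 1, m = 4))
  eb_top <- order(-ref$eb, path_edges[, 1], path_edges[, 2])[1]
  expect_setequal(res$per_structure[[1]], ord)
  expect_setequal(reb$per_structure[[1]], path_edges[eb_top, ])
})

test_that("planted high-betweenness groups are recovered by counting", {
  L <- 30
  # group A: columns 1..5 chained through column 3 in structures 1..8;
  # group B: columns 11..15 chained through 13 in structures 9..10
  chainA <- cbind(c(1, 2, 3, 3), c(3, 3, 4, 5))
  chainB <- cbind(c(11, 12, 13, 13), c(13, 13, 14, 15))
  nams <- lapply(1:10, function(s)
    nam_from_edges(paste0("s", s), L, if (s <= 8) chainA else chainB))
  suppressWarnings(res <- topk_frequency_positions(nams, "nb", k = 1, m = 2))
  expect_equal(as.integer(res$counts["3"]), 8L)
  expect_equal(as.integer(res$counts["13"]), 2L)
  expect_setequal(res$significant, c(3, 13))
})

test_that("Venn regions partition the union and hot spots need three supports", {
  v <- venn_hot_spots(hub_cols = c(1, 2, 3, 4), nb_cols = c(1, 2, 3, 9),
                      eb_cols = c(1, 3), edge_cols = c(1, 2, 5))
  tab <- v$table
  expect_equal(tab$region[tab$column == 1], "Hubs+NB+EB+Edges")
  expect_equal(tab$region_id[tab$column == 1], 1L)
  expect_equal(tab$region[tab$column == 2], "Hubs+NB+Edges")
  expect_equal(tab$region_id[tab$column == 2], 2L)
  expect_equal(tab$region[tab$column == 3], "Hubs+NB+EB")
  expect_equal(tab$region_id[tab$column == 3], 4L)
  expect_false(tab$hot_spot[tab$column == 9])   # single parameter
  expect_setequal(v$hot_spots, c(1, 2, 3))
  # region assignment is a partition: each column exactly one region
  expect_equal(anyDuplicated(tab$column), 0L)
  # enlarging one parameter set never removes an all-four column
  v2 <- venn_hot_spots(c(1, 2, 3, 4, 9), c(1, 2, 3, 9), c(1, 3), c(1, 2, 5))
  expect_true(1 %in% v2$hot_spots)
  expect_true(all(intersect(v$table$column[v$table$region_id %in% 1L],
                            v2$table$column) %in% v2$hot_spots))
})

test_that("spatial motif components equal a union-find oracle", {
  set.seed(33)
  for (trial in 1:8) {
    cols <- sample(50, 14)
    e <- t(replicate(10, sample(cols, 2)))
    edges <- data.frame(col_i = pmin(e[, 1], e[, 2]),
                        col_j = pmax(e[, 1], e[, 2]))
    edges <- edges[!duplicated(paste(edges$col_i, edges$col_j)), ]
    motif <- spatial_motif(edges)
    nodes <- sort(unique(c(edges$col_i, edges$col_j)))
    ref <- oracle_components(nodes, as.matrix(edges))
    got <- lapply(motif, function(z) sort(z$columns))
    expect_setequal(lapply(ref, function(z) sort(unname(z))), got)
    # components sorted by edge count descending
    ecounts <- vapply(motif, function(z) nrow(z$edges), numeric(1))
    expect_true(all(diff(ecounts) <= 0))
  }
  # two disjoint triangles -> two components of 3 edges
  tri2 <- data.frame(col_i = c(1, 1, 2, 10, 10, 11),
                     col_j = c(2, 3, 3, 11, 12, 12))
  expect_length(spatial_motif(tri2), 2)
  # chain of 20 edges -> one component
  chain <- data.frame(col_i = 1:20, col_j = 2:21)
  expect_length(spatial_motif(chain), 1)
})

test_that("edge niches classify endpoints including strand termini", {
  pdb <- tempfile(fileext = ".pdb")
  # 12 residues: helix 1-3, strand 5-10 (6 residues), rest loop
  make_toy_structure("AVLIKMEFSTWY",
                     data.frame(i = c(1, 5, 7, 10), j = c(3, 12, 12, 7),
                                n_pairs = 2),
                     pdb, helix = list(c(1, 3)), sheet = list(c(5, 10)))
  m <- read_structure(pdb)
  cm <- map_columns(m, m$sequence)
  edges <- data.frame(col_i = c(1, 5, 7, 7), col_j = c(3, 12, 12, 10))
  niche <- edge_niche_histogram(edges, list(m), list(cm))
  expect_equal(as.integer(niche["HH"]), 1L)    # 1-3 both helix
  expect_equal(as.integer(niche["LE"]), 2L)    # strand-loop pairs
  # edge 7-10: 7 is mid-strand but 10 is the last strand residue -> EE_t
  expect_equal(as.integer(niche["EE_t"]), 1L)
  # widen the window: nothing changes here; shrink via mid-strand pair
  edges2 <- data.frame(col_i = 6, col_j = 8)   # positions 2 and 4 of 6
  niche2 <- edge_niche_histogram(edges2, list(m), list(cm))
  expect_equal(as.integer(niche2["EE_m"]), 1L)
  niche3 <- edge_niche_histogram(edges2, list(m), list(cm),
                                 terminus_window = 2)
  expect_equal(as.integer(niche3["EE_t"]), 1L)
})

test_that("hot spots are invariant across I_min when planted strengths exceed 4%", {
  spec <- planted_ensemble_spec(seed = 77)
  ens <- make_planted_ensemble(spec)
  suppressWarnings(sens <- imin_sensitivity(ens$nams, i_min_list = c(2, 3, 4)))
  expect_true(all(sens$jaccard == 1))
  expect_equal(sens$shared[1, 2], length(sens$hot_spots[[1]]))
  # identical I_min twice: Jaccard 1 trivially
  suppressWarnings(s2 <- imin_sensitivity(ens$nams, i_min_list = c(2, 2)))
  expect_equal(s2$jaccard[1, 2], 1)
  # I_min above all planted strengths: empty sets, overlap 0 with warning
  w <- capture_warnings(s3 <- imin_sensitivity(ens$nams,
                                               i_min_list = c(50, 60)))
  expect_true(any(grepl("empty hot-spot", w)))
  expect_equal(s3$jaccard[1, 2], 0)
})
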