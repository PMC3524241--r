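# The fixture generator must satisfy its own ground truth.

test_that("toy structures realize their contact specs exactly", {
  pdb <- tempfile(fileext = ".pdb")
  make_toy_structure("PIAHT", data.frame(i = 1, j = 4, n_pairs = 3), pdb)
  n <- count_contacts(read_structure(pdb))
  expect_equal(n[1, 4], 3L)
  n[1, 4] <- n[4, 1] <- 0L
  expect_true(all(n == 0))
  # empty spec: edgeless PSN at any positive cutoff
  pdb2 <- tempfile(fileext = ".pdb")
  make_toy_structure("PTYEVF", NULL, pdb2)
  expect_equal(nrow(build_psn(read_structure(pdb2), i_min = 0.01)$edges), 0L)
  # glycine contributes its single CA: a one-pair contact is possible ...
  pdb3 <- tempfile(fileext = ".pdb")
  make_toy_structure("GAVL", data.frame(i = 1, j = 3, n_pairs = 1), pdb3)
  expect_equal(count_contacts(read_structure(pdb3))[1, 3], 1L)
  # ... but multi-pair or multi-contact glycine requests are infeasible
  expect_error(make_toy_structure("AGVL", data.frame(i = c(2), j = c(4),
                                                     n_pairs = 3),
                                  tempfile()), NA)  # partner side, fine
  expect_error(make_toy_structure("GAVL",
                                  data.frame(i = c(1, 1), j = c(3, 4),
                                             n_pairs = 1),
                                  tempfile()), "glycine")
  expect_error(make_toy_structure("GAGL",
                                  data.frame(i = 1, j = 3, n_pairs = 2),
                                  tempfile()), "glycine")
})

test_that("toy structure output is deterministic byte for byte", {
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  spec <- data.frame(i = c(1, 2), j = c(4, 6), n_pairs = c(2, 4))
  make_toy_structure("PTYEVF", spec, p1, helix = list(c(2, 3)))
  make_toy_structure("PTYEVF", spec, p2, helix = list(c(2, 3)))
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted ensembles satisfy their ground-truth record", {
  ens <- make_planted_ensemble()
  gt <- ens$ground_truth
  nams <- planted_nams(ens)
  # re-derive every planted edge's frequency from the emitted NAMs
  for (e in seq_len(nrow(gt$edges))) {
    present <- vapply(nams, function(nm)
      nm$mat[gt$edges$col_i[e], gt$edges$col_j[e]] != 0, logical(1))
    expect_equal(which(present), gt$edges$present[[e]])
    expect_equal(sum(present), round(gt$edges$freq[e] * 10))
  }
  # hub columns reach degree >= 4 exactly in their planted structures
  for (h in seq_len(nrow(gt$hubs))) {
    deg <- vapply(nams, function(nm)
      sum(nm$mat[gt$hubs$col[h], ] != 0), numeric(1))
    expect_equal(which(deg >= 4), gt$hubs$present[[h]])
  }
  # phantom invariant: gaps only at zero-degree columns
  for (s in seq_along(nams)) {
    expect_equal(nams[[s]]$phantom, gt$gap_cols[[s]])
    expect_true(all(Matrix::rowSums(nams[[s]]$mat != 0)[gt$gap_cols[[s]]] == 0))
    # alignment gap structure matches
    expect_equal(which(ens$alignment$ali[s, ] == "-"), gt$gap_cols[[s]])
  }
})

test_that("the same seed reproduces the ensemble; different seeds differ", {
  e1 <- make_planted_ensemble(planted_ensemble_spec(seed = 42))
  e2 <- make_planted_ensemble(planted_ensemble_spec(seed = 42))
  expect_identical(e1$alignment$ali, e2$alignment$ali)
  expect_equal(lapply(e1$nams, nam_edges), lapply(e2$nams, nam_edges))
  e3 <- make_planted_ensemble(planted_ensemble_spec(seed = 43))
  expect_false(identical(e1$alignment$ali, e3$alignment$ali))
})

test_that("frequency-1 edges appear everywhere; bernoulli mode is random", {
  spec <- planted_ensemble_spec(
    planted_edges = data.frame(col_i = 1, col_j = 10, freq = 1),
    hub_freqs = numeric(0), clique_freqs = numeric(0), seed = 2)
  ens <- make_planted_ensemble(spec)
  expect_equal(ens$ground_truth$edges$count, 10L)
  for (nm in planted_nams(ens)) expect_equal(nm$mat[1, 10], 1)
  bspec <- planted_ensemble_spec(n_structures = 40, mode = "bernoulli",
                                 seed = 3)
  bens <- make_planted_ensemble(bspec)
  cnt <- bens$ground_truth$edges$count
  expect_true(any(cnt != round(bens$ground_truth$edges$freq * 40)))
})

test_that("ensembles round-trip through their on-disk form", {
  ens <- make_planted_ensemble(planted_ensemble_spec(seed = 12))
  dir <- tempfile()
  write_planted_ensemble(ens, dir)
  aln <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(aln$ali, ens$alignment$ali)
  nm1 <- read_nam(file.path(dir, "nam_S01.tsv"))
  expect_equal(nam_edges(nm1), nam_edges(ens$nams[[1]]), tolerance = 1e-8)
  gt <- readLines(file.path(dir, "ground_truth.txt"))
  expect_true(any(startsWith(gt, "edge=")))
  expect_true(any(startsWith(gt, "hub=")))
})

test_that("pipeline recovery on a zero-background ensemble is exact", {
  ens <- make_planted_ensemble()
  gt <- ens$ground_truth
  nams <- planted_nams(ens)
  cons <- suppressWarnings(consensus_report(nams))
  # every planted edge with frequency >= 0.5 and high-enough rank is found
  want <- gt$edges[gt$edges$count >= 5, c("col_i", "col_j", "count")]
  # include planted hub spokes and clique edges that also recur >= 5 times
  got <- cons$conserved_edges
  expect_true(all(got$count >= 5))
  key <- function(d) paste(d$col_i, d$col_j)
  top_want <- want[order(-want$count, want$col_i, want$col_j), ]
  # the 20 selected edges all come from the planted >= 50% pool
  pool <- c(key(want),
            unlist(lapply(seq_len(nrow(gt$hubs)), function(h) {
              if (gt$hubs$count[h] >= 5) {
                p <- gt$hubs$partners[[h]]
                paste(pmin(gt$hubs$col[h], p), pmax(gt$hubs$col[h], p))
              }
            })),
            unlist(lapply(seq_len(nrow(gt$cliques)), function(cc) {
              if (gt$cliques$count[cc] >= 5) {
                tri <- gt$cliques$cols[[cc]]
                c(paste(tri[1], tri[2]), paste(tri[1], tri[3]),
                  paste(tri[2], tri[3]))
              }
            })))
  expect_true(all(key(got) %in% pool))
  # reported frequencies equal planted counts exactly
  m <- match(key(got), key(gt$edges))
  hit <- !is.na(m)
  expect_equal(got$count[hit], gt$edges$count[m[hit]])
})
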