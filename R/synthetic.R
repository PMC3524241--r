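# Synthetic fixtures: toy coordinate files with engineered side-chain
# contacts, and planted alignment ensembles with known ground truth.

.TOY_ATOM_POOL <- c("CG", "CD", "CE", "CZ", "CH", "CN", "CP", "CQ", "CR",
                    "CS", "CT", "CU", "CV", "CW")

pad80 <- function(x) formatC(x, width = -80)

fmt_atom <- function(serial, name, res3, chain, resno, x, y, z) {
  name4 <- if (nchar(name) < 4) sprintf("%-4s", paste0(" ", name))
           else name
  pad80(sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                serial, name4, res3, chain, resno, x, y, z, 1, 0,
                substr(name, 1, 1)))
}

fmt_helix <- function(serial, chain, r1, r2, res3_1, res3_2) {
  pad80(sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d  1%30s %5d",
                serial, sprintf("%d", serial), res3_1, chain, r1,
                res3_2, chain, r2, "", r2 - r1 + 1L))
}

fmt_sheet <- function(serial, chain, r1, r2, res3_1, res3_2) {
  pad80(sprintf("SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d  0",
                serial, "A", 1L, res3_1, chain, r1, res3_2, chain, r2))
}

#' Write a toy peptide with engineered side-chain contacts
#'
#' Generates a PDB-format coordinate file for a short peptide in which each
#' requested residue pair (i, j) has exactly `n_pairs` side-chain atom pairs
#' within 4.5 Angstrom, and every unspecified pair keeps all interaction
#' atoms more than 6 Angstrom apart. The geometry is schematic, not
#' physically realistic: residues sit on a widely spaced line and each
#' engineered contact is realized at its own isolated "meeting point", where
#' one anchor atom of residue i is surrounded by `n_pairs` atoms of residue
#' j at 3 Angstrom. Glycine contributes only its C-alpha, so a glycine can
#' take part in at most one engineered contact (and a glycine contact
#' partner can supply only one atom pair); infeasible requests error. The
#' layout is fully deterministic, so identical arguments produce a
#' byte-identical file.
#'
#' @param sequence one-letter amino-acid string.
#' @param contacts data frame with columns `i`, `j`, `n_pairs`
#'   (`|i - j| >= 2`, `1 <= n_pairs <= 12`), or `NULL` for no contacts.
#' @param path output PDB path.
#' @param chain chain identifier.
#' @param helix,sheet optional lists of `c(start, end)` residue-number spans
#'   written as HELIX/SHEET records.
#' @return the path, invisibly.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' make_toy_structure("PIAHT", data.frame(i = 1, j = 4, n_pairs = 3), pdb)
#' count_contacts(read_structure(pdb))[1, 4]
#' @export
make_toy_structure <- function(sequence, contacts = NULL, path,
                               chain = "A", helix = NULL, sheet = NULL) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  stopifnot(n >= 1, all(aa %in% .AA1))
  res3 <- unname(.AA1TO3[aa])

  if (!is.null(contacts) && nrow(contacts)) {
    contacts <- as.data.frame(contacts)
    stopifnot(all(c("i", "j", "n_pairs") %in% names(contacts)))
    ii <- pmin(contacts$i, contacts$j)
    jj <- pmax(contacts$i, contacts$j)
    if (any(ii < 1 | jj > n)) stop("contact indices out of range")
    if (any(jj - ii < 2)) stop("contacts must satisfy |i - j| >= 2")
    if (anyDuplicated(paste(ii, jj))) stop("duplicate contact pairs")
    if (any(contacts$n_pairs < 1 | contacts$n_pairs > 12))
      stop("n_pairs must be in 1..12")
    contacts$i <- ii; contacts$j <- jj
    gly_uses <- table(factor(c(ii, jj)[c(aa[ii], aa[jj]) == "G"],
                             levels = seq_len(n)))
    if (any(gly_uses > 1))
      stop("infeasible contact spec: a glycine can take part in at most one contact")
  } else contacts <- data.frame(i = integer(0), j = integer(0),
                                n_pairs = integer(0))

  home <- function(r) c(30 * r, 0, 0)
  meet <- function(m) c(30 * m, 100, 0)

  lines <- character(0)
  hser <- 0L
  for (h in helix) {
    hser <- hser + 1L
    lines <- c(lines, fmt_helix(hser, chain, h[1], h[2],
                                res3[match(h[1], seq_len(n))],
                                res3[match(h[2], seq_len(n))]))
  }
  sser <- 0L
  for (s in sheet) {
    sser <- sser + 1L
    lines <- c(lines, fmt_sheet(sser, chain, s[1], s[2],
                                res3[match(s[1], seq_len(n))],
                                res3[match(s[2], seq_len(n))]))
  }

  # per-residue extra atoms: list of (name, xyz)
  extra <- vector("list", n)
  gly_at_meeting <- rep(NA_integer_, n)  # meeting index a Gly backbone moves to
  used <- integer(n)                      # atoms drawn from the name pool

  take_name <- function(r) {
    used[r] <<- used[r] + 1L
    if (used[r] > length(.TOY_ATOM_POOL))
      stop("infeasible contact spec: residue ", r, " needs too many atoms")
    .TOY_ATOM_POOL[used[r]]
  }

  for (m in seq_len(nrow(contacts))) {
    i <- contacts$i[m]; j <- contacts$j[m]; np <- contacts$n_pairs[m]
    M <- meet(m)
    # glycine (single CA) must be the one-atom anchor side
    if (aa[j] == "G" && aa[i] != "G") { tmp <- i; i <- j; j <- tmp }
    if (aa[j] == "G" && np > 1)
      stop("infeasible contact spec: glycine partner can supply only one atom pair")
    # anchor: one atom of residue i at M
    if (aa[i] == "G") {
      gly_at_meeting[i] <- m
    } else {
      extra[[i]] <- c(extra[[i]], list(list(name = take_name(i), xyz = M)))
    }
    # partner: np atoms of residue j at 3 A around M
    for (t in seq_len(np)) {
      th <- 2 * pi * (t - 1) / max(np, 1)
      xyz <- M + 3.0 * c(cos(th), sin(th), 0)
      if (aa[j] == "G") {
        gly_at_meeting[j] <- m + 0.5  # offset marker: CA at M + (3,0,0)
      } else {
        extra[[j]] <- c(extra[[j]], list(list(name = take_name(j), xyz = xyz)))
      }
    }
  }

  ser <- 0L
  for (r in seq_len(n)) {
    base <- if (is.na(gly_at_meeting[r])) home(r) else {
      m <- floor(gly_at_meeting[r])
      off <- if (gly_at_meeting[r] %% 1 > 0) c(3, 0, 0) else c(0, 0, 0)
      meet(m) + off
    }
    bb <- list(N = base + c(-0.5, 0.8, 0.2), CA = base,
               C = base + c(0.75, 0.9, -0.2), O = base + c(0.8, 2.1, -0.2))
    for (nmx in names(bb)) {
      ser <- ser + 1L
      lines <- c(lines, fmt_atom(ser, nmx, res3[r], chain, r,
                                 bb[[nmx]][1], bb[[nmx]][2], bb[[nmx]][3]))
    }
    if (aa[r] != "G") {
      h <- home(r)
      ser <- ser + 1L
      lines <- c(lines, fmt_atom(ser, "CB", res3[r], chain, r,
                                 h[1], h[2] - 1.5, h[3]))
      for (ex in extra[[r]]) {
        ser <- ser + 1L
        lines <- c(lines, fmt_atom(ser, ex$name, res3[r], chain, r,
                                   ex$xyz[1], ex$xyz[2], ex$xyz[3]))
      }
    }
  }
  lines <- c(lines, pad80("END"))
  writeLines(lines, path)
  invisible(path)
}

#' Specification of a planted alignment ensemble
#'
#' Collects the parameters of the synthetic ensemble generator. The defaults
#' describe the reference planted model used throughout validation: 10
#' structures over 100 alignment columns; 30 planted edges at occurrence
#' frequencies evenly spaced from 0.3 to 1.0 with no background edges; 5
#' planted hub columns (each wired to 4 private partner columns) at
#' frequencies 1, 0.9, 0.8, 0.6 and 0.4; 3 planted triangles at frequencies
#' 1, 0.8 and 0.6; a 10% per-structure gap rate (gaps only ever placed at
#' columns that carry no edge in that structure); planted interaction
#' strengths drawn uniformly from 5-10%, i.e. all above the 2-4% cutoff
#' range; and dominant-residue conservation planted at the hub columns with
#' dominance increasing with hub frequency.
#'
#' @param n_structures ensemble size.
#' @param n_columns alignment length.
#' @param planted_edges optional data frame `col_i`, `col_j`, `freq`
#'   overriding the automatic edge placement.
#' @param n_planted_edges,freq_range automatic edge placement parameters.
#' @param background_edge_rate per-pair probability of a random background
#'   edge (0 keeps recovery exact).
#' @param gap_rate fraction of columns gapped per structure.
#' @param hub_freqs occurrence frequencies of the planted hub columns.
#' @param clique_freqs occurrence frequencies of the planted triangles.
#' @param conserved_dominance base dominance of the planted conserved
#'   residue types.
#' @param i_range range the planted percent interaction strengths are drawn
#'   from.
#' @param mode `"deterministic"` plants each edge in exactly
#'   `round(freq * n_structures)` structures; `"bernoulli"` draws presence
#'   independently per structure with probability `freq`.
#' @param seed integer seed controlling every random choice.
#' @return object of class `planted_spec`.
#' @export
planted_ensemble_spec <- function(n_structures = 10, n_columns = 100,
                                  planted_edges = NULL, n_planted_edges = 30,
                                  freq_range = c(0.3, 1.0),
                                  background_edge_rate = 0, gap_rate = 0.1,
                                  hub_freqs = c(1, 0.9, 0.8, 0.6, 0.4),
                                  clique_freqs = c(1, 0.8, 0.6),
                                  conserved_dominance = 0.9,
                                  i_range = c(5, 10),
                                  mode = c("deterministic", "bernoulli"),
                                  seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_structures >= 1, n_columns >= 4,
            background_edge_rate >= 0, background_edge_rate <= 1,
            gap_rate >= 0, gap_rate < 1,
            all(hub_freqs >= 0 & hub_freqs <= 1),
            all(clique_freqs >= 0 & clique_freqs <= 1),
            i_range[1] > 0, diff(i_range) >= 0, seed == round(seed))
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("col_i", "col_j", "freq") %in% names(planted_edges)),
              all(planted_edges$freq >= 0 & planted_edges$freq <= 1))
    n_planted_edges <- nrow(planted_edges)
  }
  need <- 2L * n_planted_edges + 5L * length(hub_freqs) +
    3L * length(clique_freqs)
  if (is.null(planted_edges) && need > n_columns)
    stop("n_columns too small for the requested planted features (need ",
         need, ")")
  structure(list(n_structures = n_structures, n_columns = n_columns,
                 planted_edges = planted_edges,
                 n_planted_edges = n_planted_edges, freq_range = freq_range,
                 background_edge_rate = background_edge_rate,
                 gap_rate = gap_rate, hub_freqs = hub_freqs,
                 clique_freqs = clique_freqs,
                 conserved_dominance = conserved_dominance,
                 i_range = i_range, mode = mode, seed = as.integer(seed)),
            class = "planted_spec")
}

# realize presence: structures containing a planted feature of frequency f
.realize_presence <- function(f, n, mode) {
  if (mode == "deterministic") {
    cnt <- round(f * n)
    if (cnt == 0L) integer(0) else sort(sample.int(n, cnt))
  } else which(stats::runif(n) < f)
}

#' Generate a planted alignment ensemble
#'
#' Realizes a [planted_ensemble_spec()] into a list of weighted NAMs (edge
#' entries carry planted percent interaction strengths), a gapped alignment,
#' and a ground-truth record of everything that was planted. In
#' deterministic mode each planted feature of frequency f is present in
#' exactly `round(f * n_structures)` structures, so downstream frequency
#' recovery is exact rather than statistical. Gap columns are only ever
#' chosen among columns carrying no edge in that structure, which guarantees
#' the phantom-column invariant by construction.
#'
#' @param spec a `planted_spec` (default: the reference spec).
#' @return object of class `planted_ensemble`: list with `nams` (weighted
#'   `psn_nam` list), `alignment` (`psn_alignment`), `ground_truth` (list
#'   with realized `edges`, `hubs`, `cliques`, `gap_cols`,
#'   `conserved_types`) and `spec`.
#' @export
make_planted_ensemble <- function(spec = planted_ensemble_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  n <- spec$n_structures
  L <- spec$n_columns

  nhub <- length(spec$hub_freqs)
  ncl <- length(spec$clique_freqs)
  if (is.null(spec$planted_edges)) {
    perm <- sample.int(L)
    ecols <- perm[seq_len(2L * spec$n_planted_edges)]
    off <- 2L * spec$n_planted_edges
    hcols <- perm[off + seq_len(nhub)]
    pcols <- perm[off + nhub + seq_len(4L * nhub)]
    ccols <- perm[off + 5L * nhub + seq_len(3L * ncl)]
    em <- matrix(ecols, ncol = 2L, byrow = TRUE)
    edges <- data.frame(col_i = pmin(em[, 1L], em[, 2L]),
                        col_j = pmax(em[, 1L], em[, 2L]),
                        freq = seq(spec$freq_range[1], spec$freq_range[2],
                                   length.out = spec$n_planted_edges))
  } else {
    edges <- spec$planted_edges
    taken <- unique(c(edges$col_i, edges$col_j))
    rest <- sample(setdiff(seq_len(L), taken))
    if (length(rest) < 5L * nhub + 3L * ncl)
      stop("n_columns too small for hubs/cliques next to explicit edges")
    hcols <- rest[seq_len(nhub)]
    pcols <- rest[nhub + seq_len(4L * nhub)]
    ccols <- rest[5L * nhub + seq_len(3L * ncl)]
  }

  edges$i_val <- stats::runif(nrow(edges), spec$i_range[1], spec$i_range[2])
  edges$present <- lapply(edges$freq, .realize_presence, n, spec$mode)
  edges$count <- lengths(edges$present)

  hubsdf <- if (nhub) data.frame(col = hcols, freq = spec$hub_freqs) else
    data.frame(col = integer(0), freq = numeric(0))
  if (nhub) {
    hubsdf$partners <- lapply(seq_len(nhub), function(h)
      pcols[(h - 1L) * 4L + 1:4])
    hubsdf$present <- lapply(hubsdf$freq, .realize_presence, n, spec$mode)
    hubsdf$count <- lengths(hubsdf$present)
  }

  cliquesdf <- if (ncl) data.frame(freq = spec$clique_freqs) else
    data.frame(freq = numeric(0))
  if (ncl) {
    cliquesdf$cols <- lapply(seq_len(ncl), function(cix) {
      sort(ccols[(cix - 1L) * 3L + 1:3])
    })
    cliquesdf$present <- lapply(cliquesdf$freq, .realize_presence, n,
                                spec$mode)
    cliquesdf$count <- lengths(cliquesdf$present)
  }

  # per-structure edge lists
  s_edges <- replicate(n, list(ci = integer(0), cj = integer(0),
                               w = numeric(0)), simplify = FALSE)
  add_edge <- function(s, a, b, w) {
    s_edges[[s]]$ci <<- c(s_edges[[s]]$ci, min(a, b))
    s_edges[[s]]$cj <<- c(s_edges[[s]]$cj, max(a, b))
    s_edges[[s]]$w <<- c(s_edges[[s]]$w, w)
  }
  for (e in seq_len(nrow(edges)))
    for (s in edges$present[[e]])
      add_edge(s, edges$col_i[e], edges$col_j[e], edges$i_val[e])
  if (nhub) for (h in seq_len(nhub)) {
    wts <- stats::runif(4L, spec$i_range[1], spec$i_range[2])
    for (s in hubsdf$present[[h]])
      for (p in 1:4)
        add_edge(s, hubsdf$col[h], hubsdf$partners[[h]][p], wts[p])
  }
  if (ncl) for (cix in seq_len(ncl)) {
    tri <- cliquesdf$cols[[cix]]
    wts <- stats::runif(3L, spec$i_range[1], spec$i_range[2])
    pairs <- rbind(tri[c(1, 2)], tri[c(1, 3)], tri[c(2, 3)])
    for (s in cliquesdf$present[[cix]])
      for (p in 1:3) add_edge(s, pairs[p, 1L], pairs[p, 2L], wts[p])
  }
  if (spec$background_edge_rate > 0) {
    planted_keys <- unlist(lapply(seq_len(n), function(s)
      paste(s, s_edges[[s]]$ci, s_edges[[s]]$cj)))
    for (s in seq_len(n)) {
      npairs <- L * (L - 1L) / 2L
      nbg <- stats::rbinom(1L, npairs, spec$background_edge_rate)
      if (nbg == 0L) next
      pick <- sample.int(npairs, nbg)
      a <- ceiling((sqrt(8 * pick + 1) - 1) / 2)  # row of pair index
      ci <- pick - a * (a - 1L) / 2L
      cj <- a + 1L
      keep <- !(paste(s, pmin(ci, cj), pmax(ci, cj)) %in% planted_keys)
      for (q in which(keep))
        add_edge(s, ci[q], cj[q],
                 stats::runif(1L, spec$i_range[1], spec$i_range[2]))
    }
  }

  # gaps: only at columns with zero degree in the structure
  gap_cols <- vector("list", n)
  ngap <- round(spec$gap_rate * L)
  for (s in seq_len(n)) {
    touched <- unique(c(s_edges[[s]]$ci, s_edges[[s]]$cj))
    eligible <- setdiff(seq_len(L), touched)
    if (length(eligible) < ngap) {
      warning("structure ", s, ": only ", length(eligible),
              " gap-eligible columns (wanted ", ngap, ")")
      gap_cols[[s]] <- sort(eligible)
    } else gap_cols[[s]] <- sort(sample(eligible, ngap))
  }

  # conserved residue types at hub columns (dominance grows with frequency)
  conserved <- if (nhub) data.frame(
    col = hubsdf$col,
    aa = sample(.AA1, nhub, replace = TRUE),
    dominance = pmin(1, spec$conserved_dominance * (0.6 + 0.4 * hubsdf$freq))
  ) else data.frame(col = integer(0), aa = character(0),
                    dominance = numeric(0))

  ali <- matrix("-", n, L)
  ids <- sprintf("S%02d", seq_len(n))
  rownames(ali) <- ids
  for (s in seq_len(n)) {
    real <- setdiff(seq_len(L), gap_cols[[s]])
    draw <- sample(.AA1, length(real), replace = TRUE)
    names(draw) <- NULL
    ali[s, real] <- draw
    hit <- match(conserved$col, real)
    for (q in which(!is.na(hit))) {
      if (stats::runif(1) < conserved$dominance[q])
        ali[s, conserved$col[q]] <- conserved$aa[q]
    }
  }

  nams <- lapply(seq_len(n), function(s) {
    e <- s_edges[[s]]
    mat <- Matrix::sparseMatrix(i = c(e$ci, e$cj), j = c(e$cj, e$ci),
                                x = c(e$w, e$w), dims = c(L, L))
    new_nam(ids[s], mat, L, phantom = gap_cols[[s]], weighted = TRUE,
            i_min = 2)
  })

  structure(list(
    nams = nams,
    alignment = alignment_from_matrix(ali),
    ground_truth = list(edges = edges, hubs = hubsdf, cliques = cliquesdf,
                        gap_cols = gap_cols, conserved_types = conserved),
    spec = spec
  ), class = "planted_ensemble")
}

#' @export
print.planted_ensemble <- function(x, ...) {
  cat("planted_ensemble: ", x$spec$n_structures, " structures x ",
      x$spec$n_columns, " columns; ", nrow(x$ground_truth$edges),
      " planted edges, ", nrow(x$ground_truth$hubs), " hubs, ",
      nrow(x$ground_truth$cliques), " cliques (seed ", x$spec$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Unweighted NAMs of a planted ensemble at a cutoff
#'
#' @param ensemble a `planted_ensemble`.
#' @param i_min percent cutoff (default 2).
#' @return list of unweighted `psn_nam` objects.
#' @export
planted_nams <- function(ensemble, i_min = 2) {
  lapply(ensemble$nams, nam_at, i_min = i_min)
}

#' Write a planted ensemble to disk
#'
#' Emits the gapped alignment as FASTA, each weighted NAM as sparse triplet
#' TSV, and the ground truth as a key-value text record.
#'
#' @param ensemble a `planted_ensemble`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_planted_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::BStringSet(apply(ensemble$alignment$ali, 1L, paste,
                                       collapse = ""))
  Biostrings::writeXStringSet(seqs, file.path(dir, "alignment.fasta"))
  for (nm in ensemble$nams)
    write_nam(nm, file.path(dir, paste0("nam_", nm$structure_id, ".tsv")))
  gt <- ensemble$ground_truth
  ln <- c(paste0("seed=", ensemble$spec$seed),
          paste0("mode=", ensemble$spec$mode),
          paste0("n_structures=", ensemble$spec$n_structures),
          paste0("n_columns=", ensemble$spec$n_columns),
          vapply(seq_len(nrow(gt$edges)), function(e) paste0(
            "edge=", gt$edges$col_i[e], ",", gt$edges$col_j[e],
            ";freq=", gt$edges$freq[e], ";count=", gt$edges$count[e],
            ";present=", paste(gt$edges$present[[e]], collapse = ",")),
            character(1)),
          vapply(seq_len(nrow(gt$hubs)), function(h) paste0(
            "hub=", gt$hubs$col[h], ";freq=", gt$hubs$freq[h],
            ";count=", gt$hubs$count[h],
            ";partners=", paste(gt$hubs$partners[[h]], collapse = ",")),
            character(1)),
          vapply(seq_len(nrow(gt$cliques)), function(cc) paste0(
            "clique=", paste(gt$cliques$cols[[cc]], collapse = ","),
            ";freq=", gt$cliques$freq[cc], ";count=", gt$cliques$count[cc]),
            character(1)))
  writeLines(ln, file.path(dir, "ground_truth.txt"))
  invisible(dir)
}
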