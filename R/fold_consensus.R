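#' Combine NAMs into a fold-specific combined adjacency matrix (f-CAM)
#'
#' Elementwise sum of the ensemble's 0/1 NAMs: entry (i, j) counts the number
#' of structures whose networks contain the column-pair edge (i, j), i.e.
#' every edge is weighed by its frequency of occurrence across the dataset.
#'
#' @param nams list of unweighted `psn_nam` objects with a common alignment
#'   length.
#' @return object of class `psn_fcam`: list with `mat` (sparse symmetric
#'   count matrix), `n_structures`, `alignment_length`.
#' @export
build_fcam <- function(nams) {
  stopifnot(is.list(nams), length(nams) >= 1,
            all(vapply(nams, inherits, logical(1), "psn_nam")))
  L <- unique(vapply(nams, `[[`, numeric(1), "alignment_length"))
  if (length(L) != 1L)
    stop("NAMs have mixed alignment lengths: ", paste(L, collapse = ", "))
  if (any(vapply(nams, `[[`, logical(1), "weighted")))
    stop("f-CAM requires unweighted (0/1) NAMs; threshold with nam_at() first")
  mat <- Reduce(`+`, lapply(nams, `[[`, "mat"))
  structure(list(mat = mat, n_structures = length(nams),
                 alignment_length = L),
            class = "psn_fcam")
}

#' @export
print.psn_fcam <- function(x, ...) {
  cat("psn_fcam: ", x$alignment_length, " columns, ", x$n_structures,
      " structures, ", nrow(fcam_edges(x)), " distinct edges\n", sep = "")
  invisible(x)
}

# All f-CAM edges as a data frame (col_i < col_j, count)
fcam_edges <- function(fcam) {
  tm <- methods::as(fcam$mat, "TsparseMatrix")
  keep <- tm@i < tm@j & tm@x != 0
  out <- data.frame(col_i = tm@i[keep] + 1L, col_j = tm@j[keep] + 1L,
                    count = as.integer(tm@x[keep]))
  out[order(out$col_i, out$col_j), , drop = FALSE]
}

#' Top fold-conserved edges of an f-CAM
#'
#' Selects the column-pair interactions present in at least
#' `min_frac * n_structures` structures, ranks them by occurrence count
#' (descending, ties by ascending column pair) and keeps the `top_k` first.
#' Frequencies are additionally reported as integer percent of the ensemble.
#'
#' @param fcam a `psn_fcam`.
#' @param min_frac minimum fraction of structures an edge must appear in
#'   (default 0.5, i.e. at least half the dataset).
#' @param top_k number of edges kept (default 20).
#' @return data frame with `col_i`, `col_j`, `count`, `freq_pct`, ordered by
#'   rank.
#' @export
top_conserved_edges <- function(fcam, min_frac = 0.5, top_k = 20) {
  stopifnot(inherits(fcam, "psn_fcam"), fcam$n_structures >= 1)
  e <- fcam_edges(fcam)
  e <- e[e$count >= min_frac * fcam$n_structures, , drop = FALSE]
  e <- e[order(-e$count, e$col_i, e$col_j), , drop = FALSE]
  if (nrow(e) > top_k) e <- e[seq_len(top_k), , drop = FALSE]
  e$freq_pct <- as.integer(round(100 * e$count / fcam$n_structures))
  rownames(e) <- NULL
  e
}

#' Hub weights and fold-specific hubs across an ensemble
#'
#' The hub weight of an alignment column is the number of structures in
#' which the residue occupying that column is a hub (degree >= 4) of its
#' network. Columns that are hubs in strictly more than `frac` of the
#' structures are the fold-specific hub residues.
#'
#' @param nams list of unweighted `psn_nam` objects.
#' @param hub_degree minimum degree for hub status.
#' @param hw integer vector of hub weights.
#' @param n_structures ensemble size.
#' @param frac strict fraction threshold (default 0.5: more than half).
#' @return `hub_weights()`: integer vector over alignment columns;
#'   `fold_specific_hubs()`: integer vector of column indices.
#' @export
hub_weights <- function(nams, hub_degree = 4) {
  stopifnot(length(nams) >= 1)
  L <- nams[[1L]]$alignment_length
  hw <- integer(L)
  for (nm in nams) {
    deg <- Matrix::rowSums(nm$mat != 0)
    hw <- hw + as.integer(deg >= hub_degree)
  }
  hw
}

#' @rdname hub_weights
#' @export
fold_specific_hubs <- function(hw, n_structures, frac = 0.5) {
  which(hw > frac * n_structures)
}

# top-k selection: value descending, ties by ascending index; exactly k kept
top_k_by_value <- function(values, candidates, k) {
  if (length(candidates) == 0L) return(integer(0))
  if (k > length(candidates)) {
    warning("fewer candidates (", length(candidates), ") than k = ", k,
            "; keeping all")
    k <- length(candidates)
  }
  ord <- candidates[order(-values[candidates], candidates)]
  ord[seq_len(k)]
}

#' Consensus positions from per-structure betweenness rankings
#'
#' For each structure the `k` alignment columns with the highest node
#' betweenness (`measure = "nb"`), or the endpoints of the `k` edges with the
#' highest edge betweenness (`measure = "eb"`), are recorded. Occurrences are
#' counted across structures, and the columns occupying the top `m` ranks of
#' that frequency list are the significant set. All ties break
#' deterministically: by value descending then ascending column (or column
#' pair) within a structure, and by count descending then ascending column
#' across structures. Phantom columns have degree zero and never enter the
#' rankings.
#'
#' @param nams list of unweighted `psn_nam` objects.
#' @param measure `"nb"` or `"eb"`.
#' @param k per-structure list length (default 20).
#' @param m number of significant ranks kept from the frequency list
#'   (default 30).
#' @return list with `significant` (integer columns), `counts` (named
#'   integer vector over columns with nonzero counts) and `per_structure`
#'   (list of per-structure column sets).
#' @export
topk_frequency_positions <- function(nams, measure = c("nb", "eb"),
                                     k = 20, m = 30) {
  measure <- match.arg(measure)
  stopifnot(length(nams) >= 1)
  L <- nams[[1L]]$alignment_length
  counts <- integer(L)
  per_structure <- vector("list", length(nams))
  for (s in seq_along(nams)) {
    nm <- nams[[s]]
    g <- nam_graph(nm)
    real <- setdiff(seq_len(L), nm$phantom)
    if (measure == "nb") {
      nb <- as.numeric(igraph::betweenness(g, directed = FALSE, weights = NA))
      cols <- top_k_by_value(nb, real, k)
    } else {
      e <- nam_edges(nm)
      if (nrow(e) == 0L) {
        cols <- integer(0)
      } else {
        eb <- as.numeric(igraph::edge_betweenness(g, directed = FALSE,
                                                  weights = NA))
        ord <- order(-eb, e$col_i, e$col_j)
        kk <- min(k, nrow(e))
        if (kk < k) warning("structure ", nm$structure_id, " has only ",
                            nrow(e), " edges (< k = ", k, ")")
        top <- ord[seq_len(kk)]
        cols <- sort(unique(c(e$col_i[top], e$col_j[top])))
      }
    }
    per_structure[[s]] <- cols
    counts[cols] <- counts[cols] + 1L
  }
  nz <- which(counts > 0L)
  significant <- top_k_by_value(counts, nz, min(m, length(nz)))
  if (length(nz) < m)
    warning("only ", length(nz), " columns ever ranked; m = ", m, " capped")
  list(significant = sort(significant),
       counts = stats::setNames(counts[nz], nz),
       per_structure = per_structure)
}

# Canonical parameter order used in all Venn reports
.VENN_PARAMS <- c("Hubs", "NB", "EB", "Edges")

# Region labels 1-5: intersection of all four, then the four triples,
# numbered in the report convention (1 = all four; 2 = Hubs+NB+Edges;
# 3 = NB+EB+Edges; 4 = Hubs+NB+EB; 5 = Hubs+EB+Edges).
.FIG5_REGIONS <- c(
  "Hubs+NB+EB+Edges" = 1L,
  "Hubs+NB+Edges"    = 2L,
  "NB+EB+Edges"      = 3L,
  "Hubs+NB+EB"       = 4L,
  "Hubs+EB+Edges"    = 5L
)

#' Intersect the four network parameters into fold-specific hot spots
#'
#' Assigns every alignment column in the union of the four parameter sets
#' (fold-specific hubs, significant node-betweenness columns, significant
#' edge-betweenness columns, endpoints of the top conserved edges) to exactly
#' one of the 15 intersection regions of the four-set Venn diagram. Columns
#' supported by all four parameters, or by any three, are the fold-specific
#' hot spots.
#'
#' @param hub_cols,nb_cols,eb_cols,edge_cols integer column sets over the
#'   same alignment.
#' @param hub_weight optional hub-weight vector used to order hot spots
#'   (support count descending, then hub weight descending, then column).
#' @return object of class `psn_consensus_venn`: list with `table` (one row
#'   per column in the union: membership flags, `n_params`, `region`,
#'   `region_id` in 1-5 or NA, `hot_spot`) and `hot_spots` (ordered integer
#'   vector).
#' @export
venn_hot_spots <- function(hub_cols, nb_cols, eb_cols, edge_cols,
                           hub_weight = NULL) {
  sets <- list(Hubs = as.integer(hub_cols), NB = as.integer(nb_cols),
               EB = as.integer(eb_cols), Edges = as.integer(edge_cols))
  all_cols <- sort(unique(unlist(sets)))
  if (length(all_cols) == 0L) {
    tab <- data.frame(column = integer(0), Hubs = logical(0), NB = logical(0),
                      EB = logical(0), Edges = logical(0),
                      n_params = integer(0), region = character(0),
                      region_id = integer(0), hot_spot = logical(0))
    return(structure(list(table = tab, hot_spots = integer(0)),
                     class = "psn_consensus_venn"))
  }
  memb <- vapply(sets, function(s) all_cols %in% s,
                 logical(length(all_cols)))
  if (length(all_cols) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, .VENN_PARAMS))
  n_params <- rowSums(memb)
  region <- apply(memb, 1L, function(r)
    paste(.VENN_PARAMS[r], collapse = "+"))
  region_id <- unname(.FIG5_REGIONS[region])
  hot <- n_params >= 3
  tab <- data.frame(column = all_cols, memb, n_params = n_params,
                    region = region, region_id = region_id,
                    hot_spot = hot)
  hw <- if (is.null(hub_weight)) rep(0, length(all_cols))
        else hub_weight[all_cols]
  ord <- order(-tab$n_params, -hw, tab$column)
  hot_spots <- tab$column[ord][tab$hot_spot[ord]]
  structure(list(table = tab, hot_spots = hot_spots),
            class = "psn_consensus_venn")
}

#' @export
print.psn_consensus_venn <- function(x, ...) {
  cat("psn_consensus_venn: ", nrow(x$table), " columns in union, ",
      length(x$hot_spots), " fold-specific hot spots\n", sep = "")
  invisible(x)
}

#' Full consensus analysis of a NAM ensemble
#'
#' Runs the complete consensus stage: builds the f-CAM, extracts the top
#' conserved edges, computes hub weights and fold-specific hubs, the
#' significant node- and edge-betweenness columns, and intersects the four
#' parameter sets into fold-specific hot spots.
#'
#' @param nams list of unweighted `psn_nam` objects.
#' @param min_frac conserved-edge occurrence threshold (fraction of
#'   structures, default 0.5).
#' @param top_k_edges number of conserved edges kept (default 20).
#' @param hub_frac strict hub-weight fraction for fold-specific hubs
#'   (default 0.5).
#' @param hub_degree hub degree cutoff (default 4).
#' @param k per-structure betweenness list length (default 20).
#' @param m significant frequency ranks kept (default 30).
#' @return object of class `psn_consensus`: list with `fcam`,
#'   `conserved_edges`, `hub_weights`, `fold_hubs`, `nb`, `eb`, `venn`,
#'   `hot_spots` and the parameters used.
#' @export
consensus_report <- function(nams, min_frac = 0.5, top_k_edges = 20,
                             hub_frac = 0.5, hub_degree = 4, k = 20, m = 30) {
  fcam <- build_fcam(nams)
  edges <- top_conserved_edges(fcam, min_frac = min_frac, top_k = top_k_edges)
  hw <- hub_weights(nams, hub_degree = hub_degree)
  fh <- fold_specific_hubs(hw, fcam$n_structures, frac = hub_frac)
  nb <- topk_frequency_positions(nams, "nb", k = k, m = m)
  eb <- topk_frequency_positions(nams, "eb", k = k, m = m)
  edge_cols <- sort(unique(c(edges$col_i, edges$col_j)))
  venn <- venn_hot_spots(fh, nb$significant, eb$significant, edge_cols,
                         hub_weight = hw)
  structure(list(
    fcam = fcam, conserved_edges = edges, hub_weights = hw,
    fold_hubs = fh, nb = nb, eb = eb, venn = venn,
    hot_spots = venn$hot_spots,
    params = list(min_frac = min_frac, top_k_edges = top_k_edges,
                  hub_frac = hub_frac, hub_degree = hub_degree,
                  k = k, m = m)
  ), class = "psn_consensus")
}

#' @export
print.psn_consensus <- function(x, ...) {
  cat("psn_consensus: ", x$fcam$n_structures, " structures, ",
      nrow(x$conserved_edges), " conserved edges, ",
      length(x$fold_hubs), " fold-specific hubs, ",
      length(x$hot_spots), " hot spots\n", sep = "")
  invisible(x)
}

#' Spatial motif from the conserved-edge graph
#'
#' Builds a graph whose vertices are the endpoint columns of the top
#' conserved edges and whose edges are those conserved edges, and returns its
#' connected components sorted by edge count (descending). The largest
#' component is the candidate spatial motif. When the ensemble alignment is
#' supplied, each component also carries the amino acid observed at each of
#' its columns in every structure, exposing the residue-type composition of
#' the motif.
#'
#' @param conserved_edges data frame with `col_i`, `col_j` (e.g. from
#'   [top_conserved_edges()]).
#' @param alignment optional `psn_alignment` for residue composition.
#' @return list of components; each is a list with `columns`, `edges`
#'   (data frame) and optionally `composition` (structures x columns
#'   character matrix). The first component is the candidate motif.
#' @export
spatial_motif <- function(conserved_edges, alignment = NULL) {
  stopifnot(nrow(conserved_edges) >= 1)
  cols <- sort(unique(c(conserved_edges$col_i, conserved_edges$col_j)))
  g <- igraph::make_empty_graph(n = length(cols), directed = FALSE)
  g <- igraph::add_edges(g, rbind(match(conserved_edges$col_i, cols),
                                  match(conserved_edges$col_j, cols)))
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(ci) {
    vcols <- cols[comp$membership == ci]
    e <- conserved_edges[conserved_edges$col_i %in% vcols &
                           conserved_edges$col_j %in% vcols, , drop = FALSE]
    res <- list(columns = vcols, edges = e)
    if (!is.null(alignment)) {
      res$composition <- alignment$ali[, vcols, drop = FALSE]
      colnames(res$composition) <- vcols
    }
    res
  })
  out[order(-vapply(out, function(z) nrow(z$edges), numeric(1)),
            vapply(out, function(z) min(z$columns), numeric(1)))]
}

# Classify one label pair into a niche class
.niche_class <- function(l1, l2, term1, term2, terminus_window) {
  key <- paste(sort(c(l1, l2)), collapse = "")
  switch(key,
    "HL" = "LH", "EL" = "LE", "EH" = "EH", "LL" = "LL", "HH" = "HH",
    "EE" = if ((!is.na(term1) && term1 < terminus_window) ||
               (!is.na(term2) && term2 < terminus_window)) "EE_t" else "EE_m"
  )
}

#' Secondary-structure niche histogram of conserved edges
#'
#' Classifies each conserved edge, in each structure that contains it, by the
#' secondary-structure labels of its two endpoint residues: loop-helix (LH),
#' loop-sheet (LE), sheet-helix (EH), loop-loop (LL), helix-helix (HH), and
#' sheet-sheet split into mid-strand (EE_m) versus strand-terminus (EE_t)
#' contacts. A sheet-sheet edge is EE_t when either endpoint lies within
#' `terminus_window` residues of the end of its strand run.
#'
#' @param conserved_edges data frame with `col_i`, `col_j`.
#' @param models list of `psn_structure` objects with `secstruct` set.
#' @param cmaps list of matching `psn_colmap` objects.
#' @param nams optional list of matching unweighted NAMs; when given, an
#'   edge is only classified in structures whose network actually contains
#'   it (otherwise in every structure where both endpoints are real
#'   residues).
#' @param terminus_window strand-terminus window in residues (default 1:
#'   the first/last residue of a strand).
#' @return named integer vector of counts over
#'   `c(LH, LE, EH, EE_m, EE_t, LL, HH)`.
#' @export
edge_niche_histogram <- function(conserved_edges, models, cmaps, nams = NULL,
                                 terminus_window = 1) {
  stopifnot(length(models) == length(cmaps))
  classes <- c("LH", "LE", "EH", "EE_m", "EE_t", "LL", "HH")
  counts <- stats::setNames(integer(length(classes)), classes)
  for (s in seq_along(models)) {
    m <- models[[s]]
    if (is.null(m$secstruct)) {
      warning("structure ", m$structure_id,
              " lacks secondary-structure annotation; skipped")
      next
    }
    ann <- data.frame(label = m$secstruct)
    # strand terminus distances recomputed from the labels
    full <- structure_ann_from_labels(m)
    cm <- cmaps[[s]]
    inv <- integer(cm$alignment_length)
    inv[cm$columns] <- seq_along(cm$columns)
    present <- if (!is.null(nams)) {
      nm <- nams[[s]]$mat
      vapply(seq_len(nrow(conserved_edges)), function(r)
        nm[conserved_edges$col_i[r], conserved_edges$col_j[r]] != 0,
        logical(1))
    } else rep(TRUE, nrow(conserved_edges))
    for (r in which(present)) {
      ri <- inv[conserved_edges$col_i[r]]
      rj <- inv[conserved_edges$col_j[r]]
      if (ri == 0L || rj == 0L) next
      cl <- .niche_class(full$label[ri], full$label[rj],
                         full$from_terminus[ri], full$from_terminus[rj],
                         terminus_window)
      counts[cl] <- counts[cl] + 1L
    }
  }
  counts
}

# Rebuild strand-run annotation from a model's stored labels.
structure_ann_from_labels <- function(model) {
  n <- length(model$secstruct)
  label <- model$secstruct
  from_term <- rep(NA_integer_, n)
  i <- 1L
  while (i <= n) {
    if (label[i] == "E") {
      j <- i
      while (j < n && label[j + 1L] == "E" &&
             model$residues$chain[j + 1L] == model$residues$chain[i]) j <- j + 1L
      len <- j - i + 1L
      pos <- seq_len(len)
      from_term[i:j] <- pmin(pos - 1L, len - pos)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(label = label, from_terminus = from_term)
}

#' Sensitivity of the hot-spot consensus to the interaction cutoff
#'
#' Reruns the full consensus pipeline at each cutoff in `i_min_list` and
#' reports the hot-spot set per cutoff together with the pairwise overlap
#' (shared counts and Jaccard index). The ensemble may be given either as a
#' list of weighted NAMs (re-thresholded with [nam_at()]) or as a list with
#' `models`, `norm` and `cmaps` (PSNs rebuilt from coordinates at each
#' cutoff).
#'
#' @param ensemble list of weighted `psn_nam` objects, or a list with
#'   elements `models`, `norm`, `cmaps`.
#' @param i_min_list percent cutoffs (default `c(2, 3, 4)`).
#' @param ... further arguments passed to [consensus_report()].
#' @return list with `hot_spots` (named list per cutoff), `jaccard` and
#'   `shared` (matrices), `reports` (the per-cutoff `psn_consensus`
#'   objects).
#' @export
imin_sensitivity <- function(ensemble, i_min_list = c(2, 3, 4), ...) {
  stopifnot(length(i_min_list) >= 1)
  nam_lists <- lapply(i_min_list, function(im) {
    if (!is.null(ensemble$models)) {
      mapply(function(mo, cm) {
        build_nam(build_psn(mo, norm = ensemble$norm, i_min = im), cm)
      }, ensemble$models, ensemble$cmaps, SIMPLIFY = FALSE)
    } else {
      lapply(ensemble, nam_at, i_min = im)
    }
  })
  reports <- lapply(nam_lists, consensus_report, ...)
  hs <- lapply(reports, `[[`, "hot_spots")
  names(hs) <- paste0("i_min_", i_min_list)
  nI <- length(i_min_list)
  jac <- shared <- matrix(NA_real_, nI, nI,
                          dimnames = list(names(hs), names(hs)))
  for (a in seq_len(nI)) for (b in seq_len(nI)) {
    inter <- length(intersect(hs[[a]], hs[[b]]))
    uni <- length(union(hs[[a]], hs[[b]]))
    shared[a, b] <- inter
    if (uni == 0L) {
      warning("empty hot-spot sets at ", names(hs)[a], " and ", names(hs)[b],
              "; overlap reported as 0")
      jac[a, b] <- 0
    } else jac[a, b] <- inter / uni
  }
  list(hot_spots = hs, jaccard = jac, shared = shared, reports = reports)
}

#' Write the consensus report as a directory of TSV tables
#'
#' Emits `conserved_edges.tsv`, `hub_weights.tsv`, `nb_significant.tsv`,
#' `eb_significant.tsv` and `hot_spots.tsv` (with Venn region labels).
#'
#' @param report a `psn_consensus`.
#' @param dir output directory (created if needed).
#' @param header optional `#`-prefixed header lines for every file.
#' @return the directory, invisibly.
#' @export
write_consensus_report <- function(report, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_with_header(report$conserved_edges,
                        file.path(dir, "conserved_edges.tsv"), header)
  hw <- report$hub_weights
  write_tsv_with_header(
    data.frame(column = which(hw > 0), hub_weight = hw[hw > 0],
               fold_specific = which(hw > 0) %in% report$fold_hubs),
    file.path(dir, "hub_weights.tsv"), header)
  write_tsv_with_header(
    data.frame(column = report$nb$significant,
               count = as.integer(report$nb$counts[
                 as.character(report$nb$significant)])),
    file.path(dir, "nb_significant.tsv"), header)
  write_tsv_with_header(
    data.frame(column = report$eb$significant,
               count = as.integer(report$eb$counts[
                 as.character(report$eb$significant)])),
    file.path(dir, "eb_significant.tsv"), header)
  vt <- report$venn$table
  vt$region_id <- ifelse(is.na(vt$region_id), "other", vt$region_id)
  write_tsv_with_header(vt, file.path(dir, "hot_spots.tsv"), header)
  invisible(dir)
}

#' Write the f-CAM as sparse triplet TSV
#'
#' @param fcam a `psn_fcam`.
#' @param path output path.
#' @param header optional extra header lines.
#' @return the path, invisibly.
#' @export
write_fcam <- function(fcam, path, header = NULL) {
  hdr <- c(paste0("n_structures=", fcam$n_structures),
           paste0("alignment_length=", fcam$alignment_length), header)
  write_tsv_with_header(fcam_edges(fcam), path, hdr)
}
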