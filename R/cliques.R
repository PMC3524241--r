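#' Enumerate k-cliques of a network
#'
#' A k-clique is a set of k nodes that are pairwise connected. Side-chain
#' networks are dominated by k = 3 cliques (triangles); higher orders are
#' rare and not supported here.
#'
#' @param x a `psn` or `psn_nam`.
#' @param k clique size (only `k = 3` is supported).
#' @return integer matrix with one sorted triple per row (rows in
#'   lexicographic order); zero rows when the graph has no triangles. For a
#'   NAM the entries are alignment columns.
#' @export
k_cliques <- function(x, k = 3) {
  if (k != 3) stop("only k = 3 cliques are supported")
  g <- if (inherits(x, "psn")) psn_graph(x)
       else if (inherits(x, "psn_nam")) nam_graph(x)
       else stop("expected a psn or psn_nam")
  cl <- igraph::cliques(g, min = k, max = k)
  if (length(cl) == 0L)
    return(matrix(integer(0), ncol = k,
                  dimnames = list(NULL, paste0("n", seq_len(k)))))
  m <- t(vapply(cl, function(v) sort(as.integer(v)), integer(k)))
  m <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
  colnames(m) <- paste0("n", seq_len(k))
  m
}

#' Clique-percolation communities
#'
#' Two k-cliques are adjacent when they share k - 1 nodes (for triangles: an
#' edge); a k-clique community is a connected component of that
#' clique-adjacency relation, reported as the union of its member cliques'
#' nodes.
#'
#' @param cliques matrix of sorted triples from [k_cliques()].
#' @param k clique size (3).
#' @return list of communities; each is a list with `nodes` (sorted) and
#'   `clique_idx` (row indices of member cliques). Ordered by node count
#'   descending, then smallest node.
#' @export
clique_communities <- function(cliques, k = 3) {
  if (k != 3) stop("only k = 3 communities are supported")
  nc <- nrow(cliques)
  if (nc == 0L) return(list())
  # adjacency via shared edges: each triangle contributes its 3 edges
  edge_key <- rbind(
    paste(cliques[, 1L], cliques[, 2L]),
    paste(cliques[, 1L], cliques[, 3L]),
    paste(cliques[, 2L], cliques[, 3L])
  )
  cg <- igraph::make_empty_graph(n = nc, directed = FALSE)
  for (grp in split(rep(seq_len(nc), each = 3L), as.vector(edge_key))) {
    if (length(grp) > 1L)
      cg <- igraph::add_edges(cg, rbind(grp[-length(grp)], grp[-1L]))
  }
  comp <- igraph::components(cg)
  out <- lapply(seq_len(comp$no), function(ci) {
    idx <- which(comp$membership == ci)
    list(nodes = sort(unique(as.integer(cliques[idx, , drop = FALSE]))),
         clique_idx = idx)
  })
  out[order(-vapply(out, function(z) length(z$nodes), numeric(1)),
            vapply(out, function(z) min(z$nodes), numeric(1)))]
}

#' Clique participation across an ensemble
#'
#' An alignment column participates in cliques in a structure when its
#' residue belongs to at least one triangle of that structure's network. The
#' participation count of a column is the number of structures in which it
#' participates; columns reaching `min_frac` of the ensemble form the
#' clique-participation set.
#'
#' @param nams list of unweighted `psn_nam` objects.
#' @param min_frac fraction-of-structures threshold (default 0.5; columns
#'   with `count >= min_frac * n_structures` are kept).
#' @return list with `counts` (integer vector over alignment columns) and
#'   `columns` (integer vector meeting the threshold).
#' @export
clique_participation <- function(nams, min_frac = 0.5) {
  stopifnot(length(nams) >= 1)
  L <- nams[[1L]]$alignment_length
  counts <- integer(L)
  for (nm in nams) {
    cl <- k_cliques(nm)
    cols <- unique(as.integer(cl))
    counts[cols] <- counts[cols] + 1L
  }
  list(counts = counts,
       columns = which(counts >= min_frac * length(nams)))
}

#' Overlap of top hot spots with clique-participating columns
#'
#' @param hot_spots ordered hot-spot columns (best first).
#' @param clique_columns clique-participation column set.
#' @param top_n number of leading hot spots considered (default 25; capped
#'   at the available number with a note in the result).
#' @return list with `percent` (100 x overlap / n_used), `n_used`,
#'   `overlap` (the shared columns).
#' @export
hotspot_clique_overlap <- function(hot_spots, clique_columns, top_n = 25) {
  n_used <- min(top_n, length(hot_spots))
  if (n_used < top_n)
    warning("only ", n_used, " hot spots available (top_n = ", top_n, ")")
  top <- hot_spots[seq_len(n_used)]
  ov <- intersect(top, clique_columns)
  list(percent = if (n_used) 100 * length(ov) / n_used else NA_real_,
       n_used = n_used, overlap = sort(ov))
}

#' Write clique tables
#'
#' @param cliques matrix from [k_cliques()].
#' @param communities list from [clique_communities()].
#' @param participation list from [clique_participation()].
#' @param path output TSV path.
#' @param header optional header lines.
#' @return the path, invisibly.
#' @export
write_cliques <- function(cliques, path, header = NULL) {
  write_tsv_with_header(as.data.frame(cliques), path, header)
}

#' @rdname write_cliques
#' @export
write_communities <- function(communities, path, header = NULL) {
  df <- if (length(communities)) data.frame(
    community = rep(seq_along(communities),
                    vapply(communities, function(z) length(z$nodes), numeric(1))),
    node = unlist(lapply(communities, `[[`, "nodes"))
  ) else data.frame(community = integer(0), node = integer(0))
  write_tsv_with_header(df, path, header)
}

#' @rdname write_cliques
#' @export
write_participation <- function(participation, path, header = NULL) {
  nz <- which(participation$counts > 0L)
  write_tsv_with_header(
    data.frame(column = nz, count = participation$counts[nz],
               selected = nz %in% participation$columns),
    path, header)
}
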