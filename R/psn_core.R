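#' Count side-chain heavy-atom contacts between residues
#'
#' For every unordered residue pair (i, j) counts the number of distinct
#' (atom-of-i, atom-of-j) pairs among their interaction atoms whose Euclidean
#' distance is at most `distance_cutoff` (4.5 Angstrom by default, compared
#' inclusively). Self pairs and covalent sequence neighbours contribute zero:
#' two residues are sequence neighbours when they are adjacent in chain
#' order, lie on the same chain, and their author numbering differs by at
#' most one (so chain breaks and chain boundaries never suppress a contact).
#'
#' @param model a `psn_structure`.
#' @param distance_cutoff contact distance in Angstrom (inclusive).
#' @return symmetric integer matrix `n` with `n[i, j]` the raw contact count.
#' @export
count_contacts <- function(model, distance_cutoff = 4.5) {
  nres <- nrow(model$residues)
  if (nres < 2) stop("model must contain at least 2 residues")
  n <- matrix(0L, nres, nres)
  A <- model$atoms
  if (nrow(A) >= 2) {
    d <- as.matrix(stats::dist(A[, c("x", "y", "z")]))
    hit <- which(d <= distance_cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit)) {
      ri <- A$res_index[hit[, 1L]]
      rj <- A$res_index[hit[, 2L]]
      keep <- ri != rj
      if (any(keep)) {
        i <- pmin(ri[keep], rj[keep])
        j <- pmax(ri[keep], rj[keep])
        tab <- table(factor(paste(i, j), levels = unique(paste(i, j))))
        ij <- do.call(rbind, strsplit(names(tab), " "))
        ii <- as.integer(ij[, 1L]); jj <- as.integer(ij[, 2L])
        n[cbind(ii, jj)] <- as.integer(tab)
        n[cbind(jj, ii)] <- as.integer(tab)
      }
    }
  }
  # zero out covalent sequence neighbours
  if (nres >= 2) {
    k <- seq_len(nres - 1L)
    nb <- model$residues$chain[k] == model$residues$chain[k + 1L] &
      abs(model$residues$resno[k + 1L] - model$residues$resno[k]) <= 1L
    nbk <- k[nb]
    n[cbind(nbk, nbk + 1L)] <- 0L
    n[cbind(nbk + 1L, nbk)] <- 0L
  }
  diag(n) <- 0L
  n
}

#' Percent interaction strength between two residues
#'
#' The strength of the non-covalent interaction between residues i and j is
#' the raw side-chain contact count normalized by the residue types:
#' \deqn{I_{ij} = \frac{n_{ij}}{\sqrt{N_i N_j}} \times 100}
#' where \eqn{N_i}, \eqn{N_j} are the residue-type normalization factors
#' (see [default_normalization()]). Vectorized over its arguments.
#'
#' @param n_ij raw contact count(s).
#' @param N_i,N_j positive normalization factors.
#' @return interaction strength(s) in percent.
#' @export
interaction_strength <- function(n_ij, N_i, N_j) {
  if (any(!is.finite(N_i)) || any(!is.finite(N_j)) ||
      any(N_i <= 0) || any(N_j <= 0))
    stop("normalization factors must be positive")
  100 * n_ij / sqrt(N_i * N_j)
}

# Full percent interaction-strength matrix for a model.
interaction_matrix <- function(model, norm = default_normalization(),
                               distance_cutoff = 4.5, n = NULL) {
  norm <- check_normalization(norm)
  if (is.null(n)) n <- count_contacts(model, distance_cutoff)
  aa <- strsplit(model$sequence, "")[[1]]
  Nv <- unname(norm[aa])
  interaction_strength(n, outer(Nv, rep(1, length(Nv))),
                       outer(rep(1, length(Nv)), Nv))
}

#' Build a protein structure network
#'
#' Connects residue pairs whose interaction strength strictly exceeds the
#' cutoff `i_min` (2% by default). All residues are nodes, including
#' isolated ones; sequence neighbours are never connected.
#'
#' @param model a `psn_structure`.
#' @param norm normalization table (see [default_normalization()]).
#' @param i_min percent interaction-strength cutoff; an edge requires
#'   `I_ij > i_min` (strict).
#' @param distance_cutoff contact distance in Angstrom.
#' @return an object of class `psn`: list with `structure_id`, `n_nodes`,
#'   `edges` (data frame `i`, `j`, `n_ij`, `I_ij` with `i < j`), `i_min`,
#'   `distance_cutoff`, `norm_mode` and the source `model`.
#' @export
build_psn <- function(model, norm = default_normalization(), i_min = 2,
                      distance_cutoff = 4.5) {
  stopifnot(i_min >= 0)
  norm <- check_normalization(norm)
  n <- count_contacts(model, distance_cutoff)
  I <- interaction_matrix(model, norm, distance_cutoff, n = n)
  sel <- which(I > i_min & upper.tri(I), arr.ind = TRUE)
  edges <- data.frame(
    i = sel[, 1L], j = sel[, 2L],
    n_ij = n[sel], I_ij = I[sel]
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    structure_id = model$structure_id,
    n_nodes = nrow(model$residues),
    edges = edges,
    i_min = i_min,
    distance_cutoff = distance_cutoff,
    norm_mode = attr(norm, "mode") %||% "custom",
    model = model
  ), class = "psn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psn <- function(x, ...) {
  cat("psn '", x$structure_id, "': ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges (I_min = ", x$i_min, "%)\n", sep = "")
  invisible(x)
}

# igraph view of a psn (or of an edge list over 1..n_nodes)
psn_graph <- function(x) {
  if (inherits(x, "psn")) {
    g <- igraph::make_empty_graph(n = x$n_nodes, directed = FALSE)
    if (nrow(x$edges))
      g <- igraph::add_edges(g, rbind(x$edges$i, x$edges$j))
    g
  } else stop("psn_graph expects a psn")
}

#' Node degrees and hub status
#'
#' A hub is a node with four or more connections; the degree-4 cutoff
#' reflects the steric packing limit of side chains in folded proteins.
#'
#' @param psn a `psn` object.
#' @param degree integer degree(s).
#' @param hub_degree minimum degree for hub status (default 4).
#' @return `degrees()`: integer vector over nodes; `is_hub()`: logical;
#'   `hubs()`: integer node indices of the hubs.
#' @export
degrees <- function(psn) {
  d <- integer(psn$n_nodes)
  if (nrow(psn$edges)) {
    t1 <- tabulate(psn$edges$i, nbins = psn$n_nodes)
    t2 <- tabulate(psn$edges$j, nbins = psn$n_nodes)
    d <- t1 + t2
  }
  d
}

#' @rdname degrees
#' @export
is_hub <- function(degree, hub_degree = 4) degree >= hub_degree

#' @rdname degrees
#' @export
hubs <- function(psn, hub_degree = 4) which(is_hub(degrees(psn), hub_degree))

#' Node and edge betweenness
#'
#' Node betweenness of v is the sum over unordered node pairs (s, t), both
#' distinct from v, of the fraction of shortest paths between s and t that
#' pass through v; edge betweenness of an edge is the same sum over all
#' unordered pairs (paths through the edge, endpoint pairs included). Both
#' are computed on the unweighted graph, as raw sums without any
#' normalization by pair count; pairs in different components contribute
#' zero.
#'
#' @param psn a `psn` object.
#' @return `node_betweenness()`: numeric vector over nodes;
#'   `edge_betweenness()`: the psn edge data frame with an `eb` column.
#' @export
node_betweenness <- function(psn) {
  g <- psn_graph(psn)
  as.numeric(igraph::betweenness(g, directed = FALSE, weights = NA))
}

#' @rdname node_betweenness
#' @export
edge_betweenness <- function(psn) {
  g <- psn_graph(psn)
  eb <- if (igraph::ecount(g))
    as.numeric(igraph::edge_betweenness(g, directed = FALSE, weights = NA))
  else numeric(0)
  out <- psn$edges[, c("i", "j"), drop = FALSE]
  out$eb <- eb
  out
}

#' Largest-cluster size as a function of the interaction cutoff
#'
#' Rebuilds the PSN of one model at each cutoff in `i_min_list` and records
#' the size of the largest connected component (LClu). The LClu profile
#' locates the connectivity transition that motivates working near
#' I_min = 2-5%: below the transition the network is densely connected,
#' above it it fragments.
#'
#' @param model a `psn_structure`.
#' @param norm normalization table.
#' @param i_min_list numeric vector of percent cutoffs.
#' @param distance_cutoff contact distance in Angstrom.
#' @return data frame with columns `i_min`, `lclu` (sizes non-increasing in
#'   `i_min`).
#' @export
largest_cluster_scan <- function(model, norm = default_normalization(),
                                 i_min_list = seq(1, 6, by = 0.5),
                                 distance_cutoff = 4.5) {
  stopifnot(length(i_min_list) >= 1)
  norm <- check_normalization(norm)
  n <- count_contacts(model, distance_cutoff)
  I <- interaction_matrix(model, norm, distance_cutoff, n = n)
  nres <- nrow(model$residues)
  lclu <- vapply(i_min_list, function(im) {
    sel <- which(I > im & upper.tri(I), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = nres, directed = FALSE)
    if (nrow(sel)) g <- igraph::add_edges(g, t(sel))
    max(igraph::components(g)$csize)
  }, numeric(1))
  data.frame(i_min = i_min_list, lclu = as.integer(lclu))
}

#' Write PSN edge and node tables
#'
#' @param psn a `psn` object.
#' @param path output TSV path.
#' @param header optional character vector of `#`-prefixed header lines.
#' @return the path, invisibly.
#' @export
write_psn_edges <- function(psn, path, header = NULL) {
  res <- psn$model$residues
  e <- psn$edges
  out <- data.frame(
    res_i = paste0(res$chain[e$i], res$resno[e$i], res$insert[e$i]),
    res_j = paste0(res$chain[e$j], res$resno[e$j], res$insert[e$j]),
    aa_i = res$aa[e$i], aa_j = res$aa[e$j],
    n_ij = e$n_ij, I_ij = round(e$I_ij, 4)
  )
  write_tsv_with_header(out, path, header)
}

#' @rdname write_psn_edges
#' @export
write_psn_nodes <- function(psn, path, header = NULL) {
  res <- psn$model$residues
  d <- degrees(psn)
  out <- data.frame(
    res = paste0(res$chain, res$resno, res$insert), aa = res$aa,
    degree = d, is_hub = is_hub(d), nb = node_betweenness(psn)
  )
  write_tsv_with_header(out, path, header)
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
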