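#' Read a gapped multiple alignment
#'
#' Reads an aligned FASTA file (e.g. the sequence view of a multiple
#' structure alignment) into a character matrix with one row per structure.
#' Gap characters `-` and `.` are accepted; sequences are upper-cased. All
#' records must have identical length; when `ids` is supplied, every id must
#' be present in the alignment.
#'
#' @param path FASTA file with gap characters.
#' @param ids optional character vector of required structure ids.
#' @return an object of class `psn_alignment`: list with `ids`, `ali`
#'   (character matrix, rows named by id) and `alignment_length`.
#' @export
read_alignment <- function(path, ids = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty alignment: ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: record lengths ", paste(unique(w), collapse = ", "))
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicated record identifiers in alignment")
  if (!is.null(ids)) {
    miss <- setdiff(ids, nm)
    if (length(miss))
      stop("alignment is missing structure id(s): ", paste(miss, collapse = ", "))
  }
  ali <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(ali) <- nm
  structure(list(ids = nm, ali = ali, alignment_length = w[1L]),
            class = "psn_alignment")
}

#' @export
print.psn_alignment <- function(x, ...) {
  cat("psn_alignment: ", length(x$ids), " sequences, length ",
      x$alignment_length, "\n", sep = "")
  invisible(x)
}

# Build a psn_alignment from a plain character matrix (rows named by id).
alignment_from_matrix <- function(ali) {
  structure(list(ids = rownames(ali), ali = ali,
                 alignment_length = ncol(ali)),
            class = "psn_alignment")
}

#' Map a structure's residues to alignment columns
#'
#' The k-th non-gap character of the structure's gapped alignment row maps
#' its k-th residue to that column (1-based). The degapped row must equal the
#' model sequence (case-insensitive); the first discrepancy is reported on
#' mismatch.
#'
#' @param model a `psn_structure`.
#' @param gapped_seq the structure's gapped row: a single string, a character
#'   vector of single characters, or a `psn_alignment` (the row matching
#'   `model$structure_id` is used).
#' @return an object of class `psn_colmap`: list with `structure_id`,
#'   `columns` (integer per residue), `alignment_length`.
#' @export
map_columns <- function(model, gapped_seq) {
  if (inherits(gapped_seq, "psn_alignment")) {
    if (!model$structure_id %in% gapped_seq$ids)
      stop("alignment has no record for ", model$structure_id)
    chars <- gapped_seq$ali[model$structure_id, ]
  } else if (length(gapped_seq) == 1L && nchar(gapped_seq[1L]) > 1L) {
    chars <- strsplit(gapped_seq, "")[[1]]
  } else chars <- gapped_seq
  chars <- toupper(chars)
  cols <- which(!.is_gap(chars))
  got <- chars[cols]
  want <- strsplit(toupper(model$sequence), "")[[1]]
  if (length(got) != length(want))
    stop("sequence/alignment mismatch for ", model$structure_id,
         ": alignment has ", length(got), " residues, structure has ",
         length(want))
  bad <- which(got != want)
  if (length(bad))
    stop("sequence/alignment mismatch for ", model$structure_id,
         " at residue ", bad[1L], " (alignment '", got[bad[1L]],
         "' vs structure '", want[bad[1L]], "')")
  structure(list(structure_id = model$structure_id,
                 columns = cols,
                 alignment_length = length(chars)),
            class = "psn_colmap")
}

#' Project a PSN onto alignment columns (NAM)
#'
#' Builds the length-normalized adjacency matrix of one structure: a
#' symmetric alignment-length x alignment-length matrix with a nonzero entry
#' at (c(i), c(j)) for every PSN edge (i, j), where c is the residue-to-
#' column map. Columns at which the structure has a gap ("phantom residues")
#' have all-zero rows and columns, so they never perturb the real
#' interactions. With `weighted = TRUE` the entries carry the percent
#' interaction strengths instead of 1, which allows re-thresholding at a
#' higher cutoff later (see [nam_at()]).
#'
#' @param psn a `psn` object.
#' @param cmap the structure's `psn_colmap`.
#' @param weighted store `I_ij` instead of 1.
#' @return an object of class `psn_nam`: list with `structure_id`, `mat`
#'   (sparse symmetric matrix), `alignment_length`, `phantom` (gap columns),
#'   `weighted`, `i_min`.
#' @export
build_nam <- function(psn, cmap, weighted = FALSE) {
  stopifnot(inherits(psn, "psn"), inherits(cmap, "psn_colmap"))
  if (psn$structure_id != cmap$structure_id)
    stop("psn and column map come from different structures")
  if (psn$n_nodes != length(cmap$columns))
    stop("column map covers ", length(cmap$columns),
         " residues but PSN has ", psn$n_nodes)
  L <- cmap$alignment_length
  e <- psn$edges
  ci <- cmap$columns[e$i]
  cj <- cmap$columns[e$j]
  x <- if (weighted) e$I_ij else rep(1, nrow(e))
  mat <- Matrix::sparseMatrix(i = c(ci, cj), j = c(cj, ci), x = c(x, x),
                              dims = c(L, L))
  new_nam(psn$structure_id, mat, L,
          phantom = setdiff(seq_len(L), cmap$columns),
          weighted = weighted, i_min = psn$i_min)
}

new_nam <- function(structure_id, mat, alignment_length, phantom,
                    weighted = FALSE, i_min = NA_real_) {
  structure(list(structure_id = structure_id, mat = mat,
                 alignment_length = alignment_length,
                 phantom = as.integer(phantom),
                 weighted = weighted, i_min = i_min),
            class = "psn_nam")
}

#' @export
print.psn_nam <- function(x, ...) {
  cat("psn_nam '", x$structure_id, "': ", x$alignment_length, " columns (",
      length(x$phantom), " phantom), ", nrow(nam_edges(x)), " edges",
      if (x$weighted) ", weighted", "\n", sep = "")
  invisible(x)
}

#' NAM edge list
#'
#' @param nam a `psn_nam`.
#' @return data frame `col_i < col_j`, `w` (1 or the interaction strength).
#' @export
nam_edges <- function(nam) {
  tm <- methods::as(nam$mat, "TsparseMatrix")
  keep <- tm@i < tm@j
  out <- data.frame(col_i = tm@i[keep] + 1L, col_j = tm@j[keep] + 1L,
                    w = tm@x[keep])
  out <- out[out$w != 0, , drop = FALSE]
  out <- out[order(out$col_i, out$col_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold a weighted NAM at a higher interaction cutoff
#'
#' Keeps the edges whose stored interaction strength strictly exceeds
#' `i_min` and returns an unweighted (0/1) NAM. The new cutoff cannot be
#' below the cutoff the weighted NAM was built at, since edges below that
#' were never stored.
#'
#' @param nam a weighted `psn_nam`.
#' @param i_min percent cutoff.
#' @return an unweighted `psn_nam`.
#' @export
nam_at <- function(nam, i_min) {
  stopifnot(inherits(nam, "psn_nam"))
  if (!nam$weighted) {
    if (!is.na(nam$i_min) && i_min < nam$i_min)
      stop("cannot lower i_min on an unweighted NAM")
    if (!is.na(nam$i_min) && i_min == nam$i_min) return(nam)
    stop("NAM carries no interaction strengths; rebuild from the PSN")
  }
  if (!is.na(nam$i_min) && i_min < nam$i_min)
    stop("i_min below the cutoff the weighted NAM was built at")
  e <- nam_edges(nam)
  e <- e[e$w > i_min, , drop = FALSE]
  L <- nam$alignment_length
  mat <- Matrix::sparseMatrix(i = c(e$col_i, e$col_j),
                              j = c(e$col_j, e$col_i),
                              x = rep(1, 2L * nrow(e)), dims = c(L, L))
  new_nam(nam$structure_id, mat, L, nam$phantom, weighted = FALSE,
          i_min = i_min)
}

# igraph over alignment columns (vertices 1..L, isolated phantoms included)
nam_graph <- function(nam) {
  e <- nam_edges(nam)
  g <- igraph::make_empty_graph(n = nam$alignment_length, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, rbind(e$col_i, e$col_j))
  g
}

#' Recover residue-level edges from a NAM
#'
#' Inverse projection: maps NAM column pairs back to residue indices of the
#' source structure through its column map.
#'
#' @param nam a `psn_nam`.
#' @param cmap the structure's `psn_colmap`.
#' @return data frame with `i`, `j` residue indices (`i < j`).
#' @export
nam_to_residue_edges <- function(nam, cmap) {
  stopifnot(nam$structure_id == cmap$structure_id)
  e <- nam_edges(nam)
  inv <- integer(nam$alignment_length)
  inv[cmap$columns] <- seq_along(cmap$columns)
  if (nrow(e) && any(inv[e$col_i] == 0L | inv[e$col_j] == 0L))
    stop("NAM has edges at phantom columns")
  data.frame(i = pmin(inv[e$col_i], inv[e$col_j]),
             j = pmax(inv[e$col_i], inv[e$col_j]))
}

#' Write / read a NAM as sparse triplet TSV
#'
#' The header records the structure id, alignment length, weighting and the
#' cutoff, so files round-trip losslessly.
#'
#' @param nam a `psn_nam`.
#' @param path TSV path.
#' @return `write_nam()`: the path invisibly; `read_nam()`: a `psn_nam`.
#' @export
write_nam <- function(nam, path) {
  e <- nam_edges(nam)
  hdr <- c(paste0("structure_id=", nam$structure_id),
           paste0("alignment_length=", nam$alignment_length),
           paste0("weighted=", nam$weighted),
           paste0("i_min=", nam$i_min),
           paste0("phantom=", paste(nam$phantom, collapse = ",")))
  write_tsv_with_header(e, path, hdr)
}

#' @rdname write_nam
#' @export
read_nam <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, "="), "",
                           grep(paste0("^# ", key, "="), hdr, value = TRUE))
  L <- as.integer(get("alignment_length"))
  weighted <- as.logical(get("weighted"))
  i_min <- as.numeric(get("i_min"))
  ph <- get("phantom")
  phantom <- if (nzchar(ph)) as.integer(strsplit(ph, ",")[[1]]) else integer(0)
  e <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                         header = TRUE, sep = "\t")
  mat <- Matrix::sparseMatrix(i = c(e$col_i, e$col_j),
                              j = c(e$col_j, e$col_i),
                              x = c(e$w, e$w), dims = c(L, L))
  new_nam(get("structure_id"), mat, L, phantom, weighted, i_min)
}
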