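#' Read a domain structure for network construction
#'
#' Parses a PDB-format coordinate file (via [bio3d::read.pdb()]) and reduces
#' it to the residue-level model used throughout the package: one record per
#' amino-acid residue, carrying the side-chain heavy atoms that participate
#' in interaction counting. Glycine, which has no side chain, contributes
#' exactly its C-alpha atom; every other residue contributes its side-chain
#' heavy atoms (backbone N/CA/C/O and the terminal OXT are excluded, as are
#' hydrogens). Only the first model of a multi-model file is used; alternate
#' locations are resolved to the highest-occupancy conformer (ties broken by
#' altloc identifier); selenomethionine (MSE) is read as MET; waters, ligands
#' and nucleic acids are dropped. Any other chemically modified (HETATM)
#' amino acid is excluded with a warning.
#'
#' @param path PDB file path.
#' @param chain chain identifier(s) to keep, or `NULL` for all chains.
#' @param structure_id identifier stored in the model (default: file base
#'   name without extension).
#' @return an object of class `psn_structure`: a list with `structure_id`,
#'   `residues` (data frame with `chain`, `resno`, `insert`, `aa`),
#'   `atoms` (data frame with `res_index`, `elety`, `x`, `y`, `z`; the
#'   interaction atoms), `sequence` (one-letter string), `secstruct`
#'   (per-residue `H`/`E`/`L` labels from HELIX/SHEET records) and `sse`
#'   (the raw parsed spans).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' make_toy_structure("PIAHT", data.frame(i = 1, j = 4, n_pairs = 3), pdb)
#' m <- read_structure(pdb)
#' m$sequence
#' @export
read_structure <- function(path, chain = NULL, structure_id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]

  is_std  <- at$type == "ATOM" & at$resid %in% .AA3
  is_mse  <- at$resid == "MSE"
  # other modified amino acids: recognizable three-letter codes that bio3d
  # can map to a residue letter but that we do not model
  other_mod <- !(is_std | is_mse) &
    suppressWarnings(bio3d::aa321(at$resid)) != "X"
  if (any(other_mod)) {
    warning("excluding nonstandard amino-acid residues: ",
            paste(unique(at$resid[other_mod]), collapse = ", "))
  }
  at <- at[is_std | is_mse, , drop = FALSE]
  if (nrow(at) == 0L) stop("no amino-acid residues found in ", path)
  at$resid[at$resid == "MSE"] <- "MET"

  # drop hydrogens / deuterium
  ele <- at$elesy
  ele[is.na(ele) | ele == ""] <- substr(gsub("[0-9]", "", at$elety[is.na(ele) | ele == ""]), 1, 1)
  at <- at[!(toupper(ele) %in% c("H", "D")), , drop = FALSE]

  # alternate locations: keep highest occupancy per (chain, resno, insert, elety)
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o;   occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    o <- occ[idx]
    idx <- idx[o == max(o)]
    idx[order(alt[idx])][1L]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  # residues in file order
  rkey <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert), sep = "\r")
  ukey <- unique(rkey)
  ridx <- match(rkey, ukey)
  first <- match(ukey, rkey)
  residues <- data.frame(
    chain  = at$chain[first],
    resno  = at$resno[first],
    insert = ifelse(is.na(at$insert[first]), "", at$insert[first]),
    aa     = unname(.AA3TO1[at$resid[first]]),
    stringsAsFactors = FALSE
  )

  # interaction atoms: Gly -> CA only; others -> non-backbone heavy atoms
  gly <- residues$aa[ridx] == "G"
  keep_atom <- ifelse(gly, at$elety == "CA", !(at$elety %in% .BACKBONE_ATOMS))
  atoms <- data.frame(
    res_index = ridx[keep_atom],
    elety = at$elety[keep_atom],
    x = at$x[keep_atom], y = at$y[keep_atom], z = at$z[keep_atom],
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  bare <- setdiff(which(residues$aa != "G"), unique(atoms$res_index))
  bare <- union(bare, setdiff(seq_len(nrow(residues)), unique(atoms$res_index)))
  if (length(bare)) {
    warning("residue(s) with no side-chain heavy atoms retained with empty ",
            "interaction-atom set: ",
            paste(residues$chain[bare], residues$resno[bare], collapse = ", "))
  }

  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))

  model <- structure(list(
    structure_id = structure_id,
    residues = residues,
    atoms = atoms,
    sequence = paste(residues$aa, collapse = ""),
    secstruct = NULL,
    sse = list(helix = pdb$helix, sheet = pdb$sheet),
    path = path
  ), class = "psn_structure")
  model$secstruct <- read_secondary_structure(model)$label
  model
}

#' Low-level structure model constructor
#'
#' Builds a `psn_structure` directly from a sequence and interaction-atom
#' coordinates, bypassing file I/O. Mainly useful for simulation and testing.
#'
#' @param sequence one-letter amino-acid string.
#' @param atoms data frame with columns `res_index`, `elety`, `x`, `y`, `z`
#'   (interaction atoms only).
#' @param structure_id identifier.
#' @param chain chain identifier applied to all residues.
#' @param resno author residue numbers (default `1:n`).
#' @param secstruct per-residue labels in `H`/`E`/`L` (default all `L`).
#' @return a `psn_structure` object.
#' @export
structure_model <- function(sequence, atoms, structure_id = "model",
                            chain = "A", resno = NULL, secstruct = NULL) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  stopifnot(n >= 1, all(aa %in% c(.AA1, "X")))
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(secstruct)) secstruct <- rep("L", n)
  stopifnot(length(resno) == n, length(secstruct) == n,
            all(secstruct %in% c("H", "E", "L")))
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("res_index", "elety", "x", "y", "z") %in% names(atoms)),
            all(atoms$res_index %in% seq_len(n)))
  structure(list(
    structure_id = structure_id,
    residues = data.frame(chain = chain, resno = resno, insert = "",
                          aa = aa, stringsAsFactors = FALSE),
    atoms = atoms,
    sequence = paste(aa, collapse = ""),
    secstruct = secstruct,
    sse = list(helix = NULL, sheet = NULL),
    path = NA_character_
  ), class = "psn_structure")
}

#' @export
print.psn_structure <- function(x, ...) {
  cat("psn_structure '", x$structure_id, "': ", nrow(x$residues),
      " residues, ", nrow(x$atoms), " interaction atoms\n", sep = "")
  cat("  sequence: ",
      if (nchar(x$sequence) > 60) paste0(substr(x$sequence, 1, 57), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Secondary-structure annotation
#'
#' Assigns each residue a label in `{H, E, L}` (helix, strand, everything
#' else). By default labels come from the HELIX/SHEET records of the parsed
#' coordinate file; an external two-column annotation can override them. For
#' strand residues the annotation also records which strand run the residue
#' belongs to, its position within the run, and its distance from the nearest
#' strand terminus, which drives the classification of strand-strand contacts
#' into mid-strand versus terminus classes.
#'
#' @param model a `psn_structure`.
#' @param source `"pdb_records"` (HELIX/SHEET spans captured at read time) or
#'   `"file"` (external TSV).
#' @param file for `source = "file"`: TSV with columns `structure_id`,
#'   `chain`, `resnum`, `label`.
#' @return data frame with one row per residue: `label`, `strand_id`,
#'   `strand_pos`, `strand_len`, `from_terminus` (NA outside strands).
#' @export
read_secondary_structure <- function(model,
                                     source = c("pdb_records", "file"),
                                     file = NULL) {
  source <- match.arg(source)
  n <- nrow(model$residues)
  label <- rep("L", n)

  if (source == "pdb_records") {
    apply_span <- function(span, lab) {
      if (is.null(span) || length(span$start) == 0L) return()
      for (s in seq_along(span$start)) {
        st <- suppressWarnings(as.integer(span$start[s]))
        en <- suppressWarnings(as.integer(span$end[s]))
        ch <- span$chain[s]
        if (is.na(st) || is.na(en) || en < st) {
          warning("malformed secondary-structure span skipped")
          next
        }
        hit <- model$residues$chain == ch &
          model$residues$resno >= st & model$residues$resno <= en
        label[hit] <<- lab
      }
    }
    apply_span(model$sse$helix, "H")
    apply_span(model$sse$sheet, "E")
  } else {
    stopifnot(!is.null(file))
    ann <- utils::read.table(file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    ann <- ann[ann$structure_id == model$structure_id, , drop = FALSE]
    ok <- ann$label %in% c("H", "E", "L")
    if (any(!ok)) {
      warning("skipping annotation rows with labels outside {H,E,L}")
      ann <- ann[ok, , drop = FALSE]
    }
    idx <- match(paste(ann$chain, ann$resnum),
                 paste(model$residues$chain, model$residues$resno))
    label[idx[!is.na(idx)]] <- ann$label[!is.na(idx)]
  }

  # strand runs: consecutive E residues on the same chain
  strand_id <- strand_pos <- strand_len <- from_term <- rep(NA_integer_, n)
  run <- 0L
  i <- 1L
  while (i <= n) {
    if (label[i] == "E") {
      j <- i
      while (j < n && label[j + 1L] == "E" &&
             model$residues$chain[j + 1L] == model$residues$chain[i]) j <- j + 1L
      run <- run + 1L
      len <- j - i + 1L
      pos <- seq_len(len)
      strand_id[i:j] <- run
      strand_pos[i:j] <- pos
      strand_len[i:j] <- len
      from_term[i:j] <- pmin(pos - 1L, len - pos)
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(label = label, strand_id = strand_id, strand_pos = strand_pos,
             strand_len = strand_len, from_terminus = from_term,
             stringsAsFactors = FALSE)
}

#' Apply a secondary-structure annotation to a model
#'
#' @param model a `psn_structure`.
#' @param annotation as returned by [read_secondary_structure()].
#' @return the model with `secstruct` replaced.
#' @export
set_secondary_structure <- function(model, annotation) {
  stopifnot(nrow(annotation) == nrow(model$residues))
  model$secstruct <- annotation$label
  model
}
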