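#' Residue-type normalization factors
#'
#' The interaction strength between two residues divides the raw side-chain
#' atom-pair count by the geometric mean of residue-type normalization
#' factors \eqn{N_i}, which express how many side-chain contacts a residue
#' type can typically sustain. `default_normalization()` returns the standard
#' side-chain normalization table of the PSN literature, derived from a
#' statistical survey of contact capacities in protein structures.
#' `derive_normalization()` instead computes a
#' dataset-derived table as the maximum raw contact count \eqn{n_{ij}}
#' observed per residue type across an input ensemble, which makes the
#' normalization self-contained for unusual datasets.
#'
#' Both return a named numeric vector over the 20 one-letter residue codes
#' with a `"mode"` attribute (`"default"` or `"derived"`) that is propagated
#' into all downstream reports. The unknown residue code `"X"` is assigned
#' the median of the table.
#'
#' @param models list of [structure_model] objects (one per domain).
#' @param distance_cutoff side-chain heavy-atom contact cutoff in Angstrom.
#' @param fallback table supplying values for residue types never observed
#'   in the ensemble (default: `default_normalization()`).
#' @return named numeric vector of length 21 (20 residues plus `"X"`).
#' @seealso [interaction_strength()], [build_psn()]
#' @export
default_normalization <- function() {
  tab <- c(
    A = 55.7551, R = 93.7891, N = 73.4097, D = 75.1507, C = 54.9528,
    Q = 78.1301, E = 78.8288, G = 47.3129, H = 83.7357, I = 67.9452,
    L = 72.2517, K = 69.6096, M = 69.2569, F = 93.3082, P = 51.3310,
    S = 61.3946, T = 63.7075, W = 106.7030, Y = 100.7190, V = 62.3673
  )
  tab <- c(tab, X = unname(stats::median(tab)))
  attr(tab, "mode") <- "default"
  tab
}

#' @rdname default_normalization
#' @export
derive_normalization <- function(models, distance_cutoff = 4.5,
                                 fallback = default_normalization()) {
  stopifnot(is.list(models), length(models) >= 1)
  maxn <- stats::setNames(rep(0, length(.AA1)), .AA1)
  for (m in models) {
    n <- count_contacts(m, distance_cutoff = distance_cutoff)
    per_res <- apply(n, 1, max)
    aa <- strsplit(m$sequence, "")[[1]]
    for (a in .AA1) {
      hit <- aa == a
      if (any(hit)) maxn[a] <- max(maxn[a], per_res[hit])
    }
  }
  missing <- names(maxn)[maxn <= 0]
  if (length(missing)) {
    warning("residue types never observed in ensemble, using fallback N: ",
            paste(missing, collapse = ", "))
    maxn[missing] <- fallback[missing]
  }
  tab <- c(maxn, X = unname(stats::median(maxn)))
  attr(tab, "mode") <- "derived"
  tab
}

# Validate a normalization table: the 20 standard types present, all > 0.
check_normalization <- function(norm) {
  if (!is.numeric(norm) || !all(.AA1 %in% names(norm)))
    stop("normalization table must be a named numeric vector covering the 20 standard residue types")
  if (any(!is.finite(norm)) || any(norm <= 0))
    stop("normalization factors must be positive and finite")
  if (!"X" %in% names(norm)) norm <- c(norm, X = unname(stats::median(norm[.AA1])))
  norm
}
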