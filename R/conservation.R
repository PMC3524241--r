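#' Per-column amino-acid propensities of an alignment
#'
#' Counts the amino-acid types observed in each alignment column and
#' converts them to propensities normalized by the non-gap count, so the
#' propensities over amino acids sum to one for every column that is not all
#' gaps. Gaps are tracked separately; columns with a gap fraction above
#' `gap_flag` are flagged as gap-heavy (but never dropped).
#'
#' @param alignment a `psn_alignment`.
#' @param gap_flag gap-fraction above which a column is flagged (default
#'   0.7).
#' @return object of class `psn_colprofile`: list with `counts` (residues x
#'   columns integer matrix over the 20 types plus `X`), `propensity` (same
#'   shape, columns summing to 1), `gap_fraction`, `all_gap` (logical),
#'   `gap_heavy` (logical), `n_sequences`.
#' @export
column_propensities <- function(alignment, gap_flag = 0.7) {
  stopifnot(inherits(alignment, "psn_alignment"))
  ali <- alignment$ali
  L <- ncol(ali)
  types <- c(.AA1, "X")
  counts <- matrix(0L, length(types), L, dimnames = list(types, NULL))
  gap_n <- integer(L)
  for (cc in seq_len(L)) {
    col <- ali[, cc]
    gap <- .is_gap(col)
    gap_n[cc] <- sum(gap)
    col <- col[!gap]
    col[!col %in% .AA1] <- "X"
    if (length(col)) {
      t0 <- table(factor(col, levels = types))
      counts[, cc] <- as.integer(t0)
    }
  }
  nseq <- nrow(ali)
  nongap <- nseq - gap_n
  prop <- sweep(counts, 2L, pmax(nongap, 1L), "/")
  prop[, nongap == 0L] <- NA_real_
  structure(list(counts = counts, propensity = prop,
                 gap_fraction = gap_n / nseq,
                 all_gap = nongap == 0L,
                 gap_heavy = gap_n / nseq > gap_flag,
                 n_sequences = nseq),
            class = "psn_colprofile")
}

#' Shannon-entropy conservation score
#'
#' For a column with amino-acid frequencies \eqn{p_a} (gaps excluded), the
#' normalized Shannon entropy is
#' \eqn{H = -\sum_a p_a \log(p_a) / \log(A)} with alphabet size
#' \eqn{A = 20}, so \eqn{H} ranges from 0 (a single residue type) to 1
#' (uniform over the alphabet). The conservation score is \eqn{1 - H}:
#' higher means more conserved.
#'
#' @param counts integer vector of per-type counts for one column (gaps
#'   excluded), or a vector of frequencies.
#' @param alphabet_size entropy log base (default 20).
#' @return score in `[0, 1]`; `NA` for an all-gap (empty) column.
#' @export
conservation_score <- function(counts, alphabet_size = 20) {
  tot <- sum(counts)
  if (tot <= 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  H <- -sum(p * log(p)) / log(alphabet_size)
  1 - H
}

#' @rdname conservation_score
#' @param profile a `psn_colprofile` (or `psn_alignment`, profiled first).
#' @return `conservation_scores()`: numeric vector over columns (`NA` at
#'   all-gap columns).
#' @export
conservation_scores <- function(profile, alphabet_size = 20) {
  if (inherits(profile, "psn_alignment"))
    profile <- column_propensities(profile)
  apply(profile$counts, 2L, conservation_score,
        alphabet_size = alphabet_size)
}

#' Correlation between hub weight and sequence conservation
#'
#' @param hub_weights integer vector over alignment columns (see
#'   [hub_weights()]).
#' @param scores conservation scores over the same columns.
#' @param columns optional column selection (default: columns where both
#'   values are defined).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return the correlation coefficient.
#' @export
hubweight_conservation_correlation <- function(hub_weights, scores,
                                               columns = NULL,
                                               method = c("pearson",
                                                          "spearman")) {
  method <- match.arg(method)
  if (is.null(columns)) columns <- seq_along(scores)
  hw <- hub_weights[columns]
  sc <- scores[columns]
  ok <- is.finite(hw) & is.finite(sc)
  hw <- hw[ok]; sc <- sc[ok]
  if (length(hw) < 3) stop("need at least 3 columns with defined values")
  if (stats::sd(hw) == 0 || stats::sd(sc) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(hw, sc, method = method)
}

#' Conservation contrast between hot spots and control columns
#'
#' Summarizes the conservation-score distribution of the hot-spot columns
#' against a control set, reporting for each set the size, mean, median and
#' the fraction of columns whose score exceeds `threshold`.
#'
#' @param hot_spots,control integer column sets.
#' @param scores conservation scores over alignment columns.
#' @param threshold score threshold (default 0.2).
#' @return data frame with one row per set (`hot_spots`, `control`).
#' @export
hotspot_conservation_contrast <- function(hot_spots, control, scores,
                                          threshold = 0.2) {
  stopifnot(length(hot_spots) >= 1, length(control) >= 1)
  summarize <- function(cols) {
    sc <- scores[cols]
    sc <- sc[is.finite(sc)]
    data.frame(n = length(sc), mean = mean(sc), median = stats::median(sc),
               min = min(sc), max = max(sc),
               frac_above = mean(sc > threshold))
  }
  out <- rbind(summarize(hot_spots), summarize(control))
  out <- cbind(set = c("hot_spots", "control"), out, threshold = threshold)
  rownames(out) <- NULL
  out
}

#' Write conservation tables
#'
#' @param profile a `psn_colprofile`.
#' @param scores conservation scores over columns.
#' @param path output TSV path.
#' @param header optional header lines.
#' @return the path, invisibly.
#' @export
write_conservation <- function(profile, scores, path, header = NULL) {
  write_tsv_with_header(
    data.frame(column = seq_along(scores), score = round(scores, 4),
               gap_fraction = round(profile$gap_fraction, 4),
               gap_heavy = profile$gap_heavy),
    path, header)
}

#' @rdname write_conservation
#' @export
write_propensities <- function(profile, path, header = NULL) {
  df <- cbind(data.frame(column = seq_len(ncol(profile$propensity))),
              as.data.frame(t(round(profile$propensity, 4))))
  write_tsv_with_header(df, path, header)
}
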