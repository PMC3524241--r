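# Run configuration and command-line surface tying the stages together.

.DEFAULT_CONFIG <- list(
  structures = list(),      # list of list(path=, chain=, id=)
  alignment = NULL,         # gapped FASTA path
  secstruct_file = NULL,    # optional TSV override
  i_min = 2.0,
  distance_cutoff = 4.5,
  normalization = "default",  # "default", "derived", or a TSV path
  min_frac_edges = 0.5,
  hub_frac = 0.5,
  hub_degree = 4,
  k = 20,
  m = 30,
  top_k_edges = 20,
  clique_min_frac = 0.5,
  top_n_hot_spots = 25,
  terminus_window = 1,
  i_min_list = c(2, 3, 4),
  seed = 1,
  out_dir = "psnfold_out"
)

#' Read and validate a pipeline run configuration
#'
#' The configuration is a single declarative YAML file whose keys mirror the
#' analysis defaults (cutoffs of 2% interaction strength and 4.5 Angstrom,
#' half-the-dataset conservation thresholds, top-20 lists and top-30
#' frequency ranks), so a bare configuration reproduces the reference
#' settings. `validate_run_config()` reports every violated field at once.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return `read_run_config()`: validated configuration list;
#'   `validate_run_config()`: the config, invisibly (errors list all
#'   violations).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(.DEFAULT_CONFIG))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config <- merge_config(user)
  validate_run_config(config)
  config
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(config$i_min) && config$i_min >= 0, "i_min must be >= 0")
  chk(num1(config$distance_cutoff) && config$distance_cutoff > 0,
      "distance_cutoff must be > 0")
  for (key in c("min_frac_edges", "hub_frac", "clique_min_frac"))
    chk(num1(config[[key]]) && config[[key]] >= 0 && config[[key]] <= 1,
        paste(key, "must be in [0, 1]"))
  for (key in c("hub_degree", "k", "m", "top_k_edges", "top_n_hot_spots"))
    chk(num1(config[[key]]) && config[[key]] >= 1,
        paste(key, "must be >= 1"))
  chk(num1(config$terminus_window) && config$terminus_window >= 0,
      "terminus_window must be >= 0")
  chk(is.numeric(config$i_min_list) && length(config$i_min_list) >= 1,
      "i_min_list must be a nonempty numeric vector")
  chk(num1(config$seed), "seed must be a number")
  for (s in config$structures)
    chk(!is.null(s$path) && file.exists(s$path),
        paste("structure file not found:", s$path %||% "<missing path>"))
  if (!is.null(config$alignment))
    chk(file.exists(config$alignment),
        paste("alignment file not found:", config$alignment))
  if (length(bad))
    stop("invalid configuration:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(config)
}

# Shallow merge of user keys over the defaults (top-level replacement only,
# so list-valued keys like `structures` are taken as given).
merge_config <- function(user) {
  config <- .DEFAULT_CONFIG
  for (key in names(user)) config[[key]] <- user[[key]]
  config
}

# Load models, alignment, column maps and normalization for a config.
load_ensemble <- function(config) {
  if (length(config$structures) == 0L)
    stop("config lists no input structures")
  models <- lapply(config$structures, function(s)
    read_structure(s$path, chain = s$chain, structure_id = s$id))
  if (!is.null(config$secstruct_file)) {
    models <- lapply(models, function(m)
      set_secondary_structure(m, read_secondary_structure(
        m, source = "file", file = config$secstruct_file)))
  }
  norm <- if (identical(config$normalization, "default")) {
    default_normalization()
  } else if (identical(config$normalization, "derived")) {
    derive_normalization(models, config$distance_cutoff)
  } else {
    tab <- utils::read.table(config$normalization, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    v <- stats::setNames(tab[[2L]], tab[[1L]])
    attr(v, "mode") <- "table"
    check_normalization(v)
  }
  out <- list(models = models, norm = norm)
  if (!is.null(config$alignment)) {
    ids <- vapply(models, `[[`, character(1), "structure_id")
    out$alignment <- read_alignment(config$alignment, ids = ids)
    out$cmaps <- lapply(models, map_columns, out$alignment)
  }
  out
}

run_header <- function(config, norm) {
  c(paste0("psnfold ", as.character(utils::packageVersion("psnfold"))),
    paste0("normalization_mode=", attr(norm, "mode") %||% "custom"),
    paste0("i_min=", config$i_min,
           " distance_cutoff=", config$distance_cutoff,
           " seed=", config$seed))
}

#' Run one pipeline command
#'
#' Dispatches the pipeline stages: `psn` (per-structure edge/node tables),
#' `nam` (per-structure NAM triplet files), `fcam`, `consensus` (conserved
#' edges, hub weights, betweenness consensus, hot spots, spatial motif,
#' niche histogram), `cliques` (cliques, communities, participation,
#' hot-spot overlap), `conserve` (propensities and conservation scores),
#' `sensitivity` (hot spots across `i_min_list`), and `synth` (write the
#' reference planted ensemble). All outputs are TSV files under
#' `config$out_dir` carrying a header with the package version and
#' normalization mode; identical inputs and configuration yield identical
#' outputs.
#'
#' @param command one of `"psn"`, `"nam"`, `"fcam"`, `"consensus"`,
#'   `"cliques"`, `"conserve"`, `"sensitivity"`, `"synth"`.
#' @param config configuration list (see [read_run_config()]).
#' @return the output directory, invisibly.
#' @export
run_command <- function(command, config) {
  command <- match.arg(command, c("psn", "nam", "fcam", "consensus",
                                  "cliques", "conserve", "sensitivity",
                                  "synth"))
  config <- merge_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command == "synth") {
    ens <- make_planted_ensemble(planted_ensemble_spec(seed = config$seed))
    write_planted_ensemble(ens, file.path(config$out_dir, "planted"))
    return(invisible(config$out_dir))
  }

  ens <- load_ensemble(config)
  hdr <- run_header(config, ens$norm)
  psns <- lapply(ens$models, build_psn, norm = ens$norm,
                 i_min = config$i_min,
                 distance_cutoff = config$distance_cutoff)

  if (command == "psn") {
    for (p in psns) {
      write_psn_edges(p, file.path(config$out_dir,
                                   paste0(p$structure_id, "_edges.tsv")), hdr)
      write_psn_nodes(p, file.path(config$out_dir,
                                   paste0(p$structure_id, "_nodes.tsv")), hdr)
    }
    return(invisible(config$out_dir))
  }

  if (is.null(ens$cmaps))
    stop("command '", command, "' requires an alignment in the config")
  nams <- mapply(build_nam, psns, ens$cmaps, SIMPLIFY = FALSE)

  if (command == "nam") {
    for (nm in nams)
      write_nam(nm, file.path(config$out_dir,
                              paste0("nam_", nm$structure_id, ".tsv")))
    return(invisible(config$out_dir))
  }
  if (command == "fcam") {
    write_fcam(build_fcam(nams), file.path(config$out_dir, "fcam.tsv"), hdr)
    return(invisible(config$out_dir))
  }
  if (command == "consensus") {
    cons <- consensus_report(nams, min_frac = config$min_frac_edges,
                            top_k_edges = config$top_k_edges,
                            hub_frac = config$hub_frac,
                            hub_degree = config$hub_degree,
                            k = config$k, m = config$m)
    write_consensus_report(cons, config$out_dir, hdr)
    write_fcam(cons$fcam, file.path(config$out_dir, "fcam.tsv"), hdr)
    if (nrow(cons$conserved_edges)) {
      motif <- spatial_motif(cons$conserved_edges, ens$alignment)
      write_tsv_with_header(
        data.frame(component = rep(seq_along(motif),
                                   lengths(lapply(motif, `[[`, "columns"))),
                   column = unlist(lapply(motif, `[[`, "columns"))),
        file.path(config$out_dir, "spatial_motif.tsv"), hdr)
      niche <- edge_niche_histogram(cons$conserved_edges, ens$models,
                                    ens$cmaps, nams,
                                    terminus_window = config$terminus_window)
      write_tsv_with_header(
        data.frame(class = names(niche), count = as.integer(niche)),
        file.path(config$out_dir, "edge_niches.tsv"), hdr)
    }
    return(invisible(config$out_dir))
  }
  if (command == "cliques") {
    for (nm in nams)
      write_cliques(k_cliques(nm),
                    file.path(config$out_dir,
                              paste0("cliques_", nm$structure_id, ".tsv")),
                    hdr)
    part <- clique_participation(nams, min_frac = config$clique_min_frac)
    write_participation(part, file.path(config$out_dir, "participation.tsv"),
                        hdr)
    cons <- consensus_report(nams, min_frac = config$min_frac_edges,
                            top_k_edges = config$top_k_edges,
                            hub_frac = config$hub_frac,
                            hub_degree = config$hub_degree,
                            k = config$k, m = config$m)
    ov <- hotspot_clique_overlap(cons$hot_spots, part$columns,
                                 top_n = config$top_n_hot_spots)
    write_tsv_with_header(
      data.frame(percent = ov$percent, n_used = ov$n_used),
      file.path(config$out_dir, "hotspot_clique_overlap.tsv"), hdr)
    return(invisible(config$out_dir))
  }
  if (command == "conserve") {
    prof <- column_propensities(ens$alignment)
    sc <- conservation_scores(prof)
    write_conservation(prof, sc, file.path(config$out_dir,
                                           "conservation.tsv"), hdr)
    write_propensities(prof, file.path(config$out_dir, "propensities.tsv"),
                       hdr)
    return(invisible(config$out_dir))
  }
  # sensitivity
  sens <- imin_sensitivity(list(models = ens$models, norm = ens$norm,
                                cmaps = ens$cmaps),
                           i_min_list = config$i_min_list,
                           min_frac = config$min_frac_edges,
                           top_k_edges = config$top_k_edges,
                           hub_frac = config$hub_frac,
                           hub_degree = config$hub_degree,
                           k = config$k, m = config$m)
  hs <- sens$hot_spots
  write_tsv_with_header(
    data.frame(i_min = rep(config$i_min_list, lengths(hs)),
               column = unlist(hs)),
    file.path(config$out_dir, "hot_spots_by_imin.tsv"), hdr)
  ov <- as.data.frame(as.table(sens$jaccard))
  names(ov) <- c("a", "b", "jaccard")
  ov$shared <- as.data.frame(as.table(sens$shared))$Freq
  write_tsv_with_header(ov, file.path(config$out_dir, "imin_overlap.tsv"),
                        hdr)
  invisible(config$out_dir)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the `psnfold` executable script
#' (`system.file("exec", "psnfold", package = "psnfold")`): the first
#' argument is the command, `--config <file>` supplies the YAML
#' configuration, and `--out <dir>` optionally overrides the output
#' directory.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
psnfold_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: psnfold <command> --config <config.yaml> [--out <dir>]\n",
    "commands: psn nam fcam consensus cliques conserve sensitivity synth")
  if (length(args) < 1L || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args) < 1L) 1L else 0L))
  }
  command <- args[1L]
  rest <- args[-1L]
  getopt <- function(flag) {
    i <- which(rest == flag)
    if (length(i) == 1L && i < length(rest)) rest[i + 1L] else NULL
  }
  cfg_path <- getopt("--config")
  config <- if (is.null(cfg_path)) .DEFAULT_CONFIG else
    tryCatch(read_run_config(cfg_path), error = function(e) {
      message(conditionMessage(e)); NULL
    })
  if (is.null(config)) return(invisible(1L))
  out <- getopt("--out")
  if (!is.null(out)) config$out_dir <- out
  status <- tryCatch({
    run_command(command, config)
    0L
  }, error = function(e) {
    message("psnfold ", command, " failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
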