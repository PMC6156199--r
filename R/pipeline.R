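#' Top-level run configuration
#'
#' Bundles the per-stage configurations and the input/output locations for
#' [run_pipeline()]. Either `sim` is set (inputs are simulated) or `paths`
#' names on-disk inputs laid out as written by [write_simulation()].
#'
#' @param out_dir Run directory (created; effective config, catalog,
#'   provenance and logs are written there).
#' @param detection A [detection_config()].
#' @param enrichment An [enrichment_config()].
#' @param stability A [stability_config()].
#' @param sim Optional [sim_config()]; when set, inputs are simulated.
#' @param paths Optional list: `coverage_dir`, `annotation`, `genome`,
#'   `library_sizes`, optional `end_sites`, plus `timepoints` and
#'   `n_replicates` describing the library grid.
#' @param seed Master seed, propagated to every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, detection = detection_config(),
                       enrichment = enrichment_config(),
                       stability = stability_config(), sim = NULL,
                       paths = NULL, seed = 1) {
  if (is.null(sim) && is.null(paths)) stopf("supply either sim or paths")
  structure(list(out_dir = out_dir, detection = detection,
                 enrichment = enrichment, stability = stability,
                 sim = sim, paths = paths, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a decay experiment from bedGraph files on disk
#'
#' Expects the layout written by [write_simulation()]: per-library strand
#' bedGraphs named `t<min>_rep<r>_{fwd,rev}.bedgraph` and a
#' `library_sizes.tsv` sidecar.
#'
#' @param dir Coverage directory.
#' @param timepoints Numeric minutes (first 0).
#' @param n_replicates Replicate count.
#' @param genome_len Replicon length in nt.
#' @param replicon_id Replicon name.
#' @return A `decay_experiment` (raw tracks, no truth table).
#' @export
read_experiment <- function(dir, timepoints, n_replicates, genome_len,
                            replicon_id = "chr") {
  sizes <- read_library_sizes(file.path(dir, "library_sizes.tsv"))
  tracks <- lapply(seq_len(n_replicates), function(r) {
    lapply(seq_along(timepoints), function(ti) {
      lib <- sprintf("t%g_rep%d", timepoints[ti], r)
      tr <- lapply(c("+" = "fwd", "-" = "rev"), function(tag) {
        path <- file.path(dir, sprintf("%s_%s.bedgraph", lib, tag))
        if (!file.exists(path)) stopf("missing coverage file: %s", path)
        read_bedgraph(path, genome_len,
                      strand = if (tag == "fwd") "+" else "-",
                      library_total = sizes[[lib]], replicon_id = replicon_id)
      })
      names(tr) <- c("+", "-")
      tr
    })
  })
  structure(list(replicon_id = replicon_id, genome_len = genome_len,
                 timepoints = as.numeric(timepoints),
                 n_replicates = as.integer(n_replicates),
                 tracks = tracks, truth = NULL, config = NULL),
            class = "decay_experiment")
}

#' Run the full decRNA pipeline
#'
#' Simulates or loads inputs, detects decRNAs, scores fold stability
#' against random genomic segments, and writes the catalog (TSV + BED6), a
#' stability summary JSON, the effective configuration, and a provenance
#' record (config hash, package version) into the run directory. The run
#' is deterministic given the configuration and seed.
#'
#' @param config A [run_config()].
#' @return Invisible list with `calls`, `stability`, `experiment`, `genes`,
#'   `genome`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$sim)) {
    sim <- simulate_annotation(config$sim)
    genes <- sim$genes; genome <- sim$genome
    segments <- attr(config$sim, "segments")
    experiment <- simulate_decay_experiment(genome, genes, segments, config$sim)
    end_sites <- NULL
  } else {
    p <- config$paths
    for (f in c("annotation", "genome", "library_sizes")) {
      if (!file.exists(p[[f]])) stopf("missing %s file: %s", f, p[[f]])
    }
    gset <- read_genome_fasta(p$genome)
    genome <- stats::setNames(as.character(gset), names(gset))
    genes <- read_gff3(p$annotation)
    experiment <- read_experiment(p$coverage_dir, p$timepoints,
                                  p$n_replicates, Biostrings::width(gset)[1],
                                  replicon_id = names(gset)[1] %||% "chr")
    end_sites <- if (!is.null(p$end_sites)) read_end_sites(p$end_sites) else NULL
  }
  calls <- detect_decrnas(experiment, genes, genome, config$detection,
                          end_sites = end_sites)
  write_catalog(calls, file.path(config$out_dir, "catalog.tsv"),
                bed_path = file.path(config$out_dir, "calls.bed"))
  stab <- NULL
  if (nrow(calls)) {
    seqs <- stats::setNames(calls$sequence, calls$id)
    stab <- compare_stability(seqs, NULL, genome, config$stability,
                              engine = folding_engine("auto"))
    med <- tapply(stab$records$per_nt, stab$records$set, stats::median)
    jsonlite::write_json(
      list(engine = stab$engine, n_random = stab$n_random,
           p_vs_random = stab$p_vs_random,
           median_per_nt = as.list(med)),
      file.path(config$out_dir, "stability.json"),
      auto_unbox = TRUE, digits = NA)
  }
  cfg_file <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_file)
  input_md5 <- if (!is.null(config$paths)) {
    files <- unlist(config$paths[c("annotation", "genome", "library_sizes",
                                   "end_sites")], use.names = TRUE)
    as.list(tools::md5sum(files[!is.na(files) & file.exists(files)]))
  } else NULL
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("decarve")),
         config_md5 = unname(tools::md5sum(cfg_file)),
         input_md5 = input_md5,
         n_calls = nrow(calls), seed = config$seed),
    file.path(config$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, stability = stab, experiment = experiment,
                 genes = genes, genome = genome, out_dir = config$out_dir))
}

serializable_config <- function(config) {
  rapply(unclass(config), function(x) x, how = "replace")
}

#' Export per-timepoint coverage over a region for plotting
#'
#' Long-format table (position, timepoint, replicate, coverage) of
#' library-size-normalized coverage restricted to a region, the data behind
#' coverage-overlay figures of a decay time course.
#'
#' @param experiment A `decay_experiment` (raw tracks).
#' @param start,end Region, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return Data frame with `position` (0-based), `timepoint`, `replicate`,
#'   `coverage` (RPM).
#' @export
export_coverage_views <- function(experiment, start, end, strand = "+") {
  if (start < 0 || end > experiment$genome_len || end <= start) {
    stopf("region [%d, %d) outside replicon of length %d",
          start, end, experiment$genome_len)
  }
  rows <- list()
  for (r in seq_len(experiment$n_replicates)) {
    for (ti in seq_along(experiment$timepoints)) {
      tr <- normalize_by_library_size(get_track(experiment, r, ti, strand))
      rows[[length(rows) + 1L]] <- data.frame(
        position = start:(end - 1L),
        timepoint = experiment$timepoints[ti], replicate = r,
        coverage = track_slice(tr, start, end))
    }
  }
  do.call(rbind, rows)
}
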