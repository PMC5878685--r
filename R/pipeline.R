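# Staged simulate -> pileup -> scan -> call driver with a reproducibility
# manifest. One RNG stream per run: the run seed deterministically derives
# the per-stage seeds, so a manifest identifies the run completely.

#' Assemble a run configuration
#'
#' @param variant Reference variant for [build_mat_region()].
#' @param n_molecules,imprint_fraction,mean_fragment_len,weakened_window,opposite_break_prob,read_length
#'   Simulation parameters, see [sonication_params()].
#' @param flank_len Reference flank length, nt.
#' @param min_mapq Optional unique-mapper filter before counting (`NULL`:
#'   count all reads, the default for repeat-free donor-less references).
#' @param alpha Significance level for the caller.
#' @param max_size Largest scanned window size.
#' @param seed Run seed; stage seeds are derived from it.
#' @param out Output path prefix (directories are created).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(variant = "M_donorless", n_molecules = 100000,
                       imprint_fraction = 0.3, mean_fragment_len = 300,
                       weakened_window = 20L, opposite_break_prob = 0.8,
                       read_length = 130L, flank_len = 5000L, min_mapq = NULL,
                       alpha = 0.05, max_size = 40L, seed = 1L,
                       out = "nickscan_run") {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [run_config()]; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `"run_config"` object.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Run the full simulate -> pileup -> scan -> call pipeline
#'
#' Builds the reference, simulates the library, computes the 5'-count
#' profile, fits genome-wide null models, calls nicks, and writes the
#' reference (FASTA + BED), profile (TSV + bedGraph), null models (JSON),
#' calls (TSV + BED) and a JSON manifest recording inputs, parameters,
#' seeds, outputs and a call summary.
#'
#' @param config A [run_config()] (or a YAML path accepted by
#'   [load_run_config()]).
#' @return Invisibly, the manifest as a list (also written to
#'   `<out>.manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(dirname(config$out), showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(i) (config$seed * 1000L + i) %% .Machine$integer.max

  g <- build_mat_region(config$variant, flank_len = config$flank_len,
                        seed = stage_seed(1L))
  params <- sonication_params(
    n_molecules = config$n_molecules,
    imprint_fraction = config$imprint_fraction,
    mean_fragment_len = config$mean_fragment_len,
    weakened_window = config$weakened_window,
    opposite_break_prob = config$opposite_break_prob,
    read_length = config$read_length, seed = stage_seed(2L))
  reads <- simulate_library(g, params)
  profile <- compute_five_prime_counts(reads, g, min_mapq = config$min_mapq)
  models <- list(watson = fit_null(profile, "watson"),
                 crick = fit_null(profile, "crick"))
  calls <- call_nicks(profile, models, alpha = config$alpha,
                      max_size = config$max_size)

  files <- c(write_genome(g, config$out),
             write_profile(profile, config$out))
  for (s in c("watson", "crick")) {
    f <- paste0(config$out, ".null.", s, ".json")
    write_null_model(models[[s]], f)
    files <- c(files, f)
  }
  files <- c(files, write_nick_calls(calls, config$out))

  manifest <- list(
    package = "nickscan",
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    stage_seeds = list(genome = stage_seed(1L), library = stage_seed(2L)),
    genome = list(name = g$name, length = g$length,
                  true_nicks = g$nick_sites),
    library_size = profile$library_size,
    n_calls = nrow(calls),
    calls = as.data.frame(calls),
    outputs = unname(files))
  manifest_path <- paste0(config$out, ".manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
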