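#' Build a pipeline configuration
#'
#' Three profiles scale the same end-to-end pipeline: \code{smoke} (64 px
#' quadrants, 50 pairs, 2 epochs, 30 Monte Carlo trials) for wiring tests,
#' \code{scaled} (128 px quadrants, 200 pairs, 10 epochs, 32 channels) for
#' desk-scale study, and \code{full} (256 px quadrants, 1000 pairs, 50
#' epochs, 64 channels) matching the full study conditions. Every stage
#' receives a seed derived deterministically from the global seed.
#'
#' @param profile One of \code{"smoke"}, \code{"scaled"}, \code{"full"}.
#' @param seed Global integer seed.
#' @param out_dir Output directory for run artifacts.
#' @param ... Named overrides of individual fields.
#' @return List of class \code{run_config}.
#' @export
pipeline_config <- function(profile = c("smoke", "scaled", "full"),
                            seed = 1, out_dir = tempfile("sprphase_run_"),
                            ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    smoke = list(size_px = 128, n_pairs = 50, channels = 8, epochs = 2,
                 learning_rate = 2e-3, batch_size = 4, norm = "instance",
                 n_trials = 30, energies_pJ = c(500, 2000)),
    scaled = list(size_px = 256, n_pairs = 223, channels = 32, epochs = 10,
                  learning_rate = c(rep(2e-3, 6), rep(5e-4, 3), 2e-4),
                  batch_size = 1, norm = "instance", n_trials = 200,
                  energies_pJ = c(500, 1000, 2000, 2600)),
    full = list(size_px = 512, n_pairs = 1000, channels = 64, epochs = 50,
                 learning_rate = 1e-4, batch_size = 4, norm = "affine", n_trials = 500,
                 energies_pJ = round(exp(seq(log(90), log(2600),
                                             length.out = 12)))))
  cfg <- utils::modifyList(
    c(base, list(profile = profile, seed = seed, out_dir = out_dir,
                 methods = c("poly3", "azimuthal", "dl"),
                 test_dm = 50, test_ns = 1.33)),
    list(...))
  # per-stage seeds, all below 2^31
  cfg$stage_seeds <- list(dataset = (seed * 7L + 11L) %% 2000000011L,
                          train = (seed * 13L + 29L) %% 2000000011L,
                          mc = (seed * 17L + 47L) %% 2000000011L)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  x <- cfg
  x$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x[order(names(x))]), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline
#'
#' Executes dataset generation, network training, clean test-case
#' measurement with the three estimators, and the Monte Carlo LOD
#' benchmark, writing all artifacts plus a manifest (config echo, derived
#' seeds, config hash) to the configured output directory.
#'
#' @param cfg A \code{run_config} from \code{\link{pipeline_config}}.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the artifact paths and the in-memory
#'   results (\code{dataset}, \code{model}, \code{estimates},
#'   \code{benchmark}).
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[sprphase] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage dataset: ", cfg$n_pairs, " pairs at ", cfg$size_px, " px")
  dataset <- stage("dataset",
    generate_dataset(cfg$n_pairs, seed = cfg$stage_seeds$dataset,
                     size_px = cfg$size_px))
  dataset_path <- file.path(cfg$out_dir, "dataset.rds")
  write_dataset(dataset, dataset_path)

  say("stage train: ", cfg$epochs, " epochs, ", cfg$channels, " channels")
  model <- stage("train", {
    net_cfg <- can_config(input_size = cfg$size_px / 2,
                          base_channels = cfg$channels,
                          learning_rate = cfg$learning_rate,
                          epochs = cfg$epochs, batch_size = cfg$batch_size,
                          norm = cfg$norm, seed = cfg$stage_seeds$train)
    train_can(build_can(net_cfg), dataset)
  })
  model_path <- file.path(cfg$out_dir, "model.rds")
  save_can(model, model_path)

  say("stage measure: clean test case dm = ", cfg$test_dm,
      " nm, ns = ", cfg$test_ns)
  grid <- pupil_grid(cfg$size_px)
  stack <- gold_stack(cfg$test_dm, cfg$test_ns)
  estimates <- stage("measure", {
    ests <- lapply(c(poly3 = "poly3", azimuthal = "azimuthal", dl = "dl"),
                   function(m) {
                     e <- clean_beta_p(stack, m, grid,
                                       model = if (m == "dl") model)
                     list(beta_p = e$beta_p, method = e$method,
                          low_confidence = e$low_confidence)
                   })
    c(ests, list(config_hash = config_hash(cfg)))
  })
  estimates_path <- file.path(cfg$out_dir, "estimates.json")
  jsonlite::write_json(estimates, estimates_path, auto_unbox = TRUE,
                       digits = NA)

  say("stage benchmark: ", length(cfg$energies_pJ), " energies x ",
      length(cfg$methods), " methods, ", cfg$n_trials, " trials")
  benchmark <- stage("benchmark",
    suppressWarnings(
      lod_curve(stack, methods = cfg$methods, energies_pJ = cfg$energies_pJ,
                n_trials = cfg$n_trials, grid = grid, model = model,
                seed = cfg$stage_seeds$mc, on_failure = "na")))
  benchmark_path <- file.path(cfg$out_dir, "lod_benchmark.csv")
  utils::write.csv(benchmark, benchmark_path, row.names = FALSE)

  manifest <- list(package = "sprphase", profile = cfg$profile,
                   seed = cfg$seed, stage_seeds = cfg$stage_seeds,
                   config_hash = config_hash(cfg),
                   artifacts = basename(c(dataset_path, model_path,
                                          estimates_path, benchmark_path)))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  say("done: ", cfg$out_dir)
  invisible(list(paths = c(dataset = dataset_path, model = model_path,
                           estimates = estimates_path,
                           benchmark = benchmark_path,
                           manifest = manifest_path),
                 dataset = dataset, model = model, estimates = estimates,
                 benchmark = benchmark))
}

#' Load a pipeline configuration from a YAML file
#'
#' The file may set \code{profile}, \code{seed}, \code{out_dir} and any
#' field override accepted by \code{\link{pipeline_config}} (for example
#' \code{n_pairs}, \code{size_px}, \code{energies_pJ}).
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "smoke"
  seed <- y$seed %||% 1
  out_dir <- y$out_dir %||% tempfile("sprphase_run_")
  y$profile <- NULL; y$seed <- NULL; y$out_dir <- NULL
  do.call(pipeline_config,
          c(list(profile = profile, seed = seed, out_dir = out_dir), y))
}
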