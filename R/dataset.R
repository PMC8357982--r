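#' Draw one random simulation parameter set
#'
#' Samples the randomized material and illumination parameters used to
#' generalize the SPR training data: gold thickness uniform on [20, 60] nm,
#' wavelength uniform on [550, 650] nm, gold index 0.18 + 3.44i with
#' independent uniform \eqn{\pm 10\%} errors on the real and imaginary part,
#' and sample index uniform on [1.0, 1.4].
#'
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return List of class \code{parameter_sample}: \code{dm_nm},
#'   \code{wavelength_nm}, \code{nm} (complex), \code{ns}, \code{seed}.
#' @export
sample_parameters <- function(seed = NULL) {
  draw <- function() {
    u <- stats::runif(5)
    structure(list(
      dm_nm = 20 + 40 * u[1],
      wavelength_nm = 550 + 100 * u[2],
      nm = complex(real = 0.18 * (0.9 + 0.2 * u[3]),
                   imaginary = 3.44 * (0.9 + 0.2 * u[4])),
      ns = 1.0 + 0.4 * u[5],
      seed = seed),
      class = "parameter_sample")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Test-grid exclusion: a draw is rejected when it falls into the joint cell
# (thickness within +-0.5 nm of a held-out test thickness) AND (wavelength
# within +-1 nm of 633 nm). Excluding whole thickness bands would gut the
# 20-60 nm training range.
test_thicknesses <- c(30, 40, 45, 50)

#' Does a parameter draw collide with the held-out test configuration?
#'
#' @param params A \code{parameter_sample}.
#' @param dm_tol Thickness tolerance in nm (default 0.5).
#' @param wl_tol Wavelength tolerance in nm (default 1).
#' @return TRUE if the draw must be excluded from training/validation.
#' @export
is_test_configuration <- function(params, dm_tol = 0.5, wl_tol = 1) {
  any(abs(params$dm_nm - test_thicknesses) <= dm_tol) &&
    abs(params$wavelength_nm - 633) <= wl_tol
}

stack_from_params <- function(params, n0 = 1.52, na = 1.49) {
  layer_stack(n0 = n0,
              layers = list(list(n = params$nm, d = params$dm_nm)),
              ns = params$ns, wavelength_nm = params$wavelength_nm, na = na)
}

make_record <- function(params, grid, split, input = "amplitude") {
  field <- synthesize_bfp(stack_from_params(params), grid)
  q <- crop_quadrant(field, 1)
  inp <- if (input == "intensity") q$amplitude^2 else q$amplitude
  list(input = inp / max(inp), label = q$phase, params = params,
       split = split)
}

#' Generate a randomized training/validation dataset
#'
#' Draws \code{n_pairs} parameter sets (rejecting any draw that collides
#' with the held-out test grid), synthesizes the quadrant amplitude/phase
#' pair for each, and tags the first 90\% as training and the remainder as
#' validation.
#'
#' @param n_pairs Number of image pairs (>= 10).
#' @param seed Integer RNG seed; regeneration is bit-identical.
#' @param size_px Side of the full BFP image; the stored quadrants have side
#'   \code{size_px/2} (default 512, giving the standard 256 px quadrants).
#' @param input \code{"amplitude"} (default) or \code{"intensity"} network
#'   input.
#' @param na Numerical aperture of the simulated objective.
#' @return Object of class \code{spr_dataset}: list with \code{records}
#'   (each \code{list(input, label, params, split)}), \code{size_px},
#'   \code{input}, \code{seed}.
#' @export
generate_dataset <- function(n_pairs, seed = 1, size_px = 512,
                             input = c("amplitude", "intensity"),
                             na = 1.49) {
  stopifnot(n_pairs >= 10)
  input <- match.arg(input)
  grid <- pupil_grid(size_px, na)
  n_train <- floor(0.9 * n_pairs)
  records <- with_seed(seed, {
    lapply(seq_len(n_pairs), function(i) {
      repeat {
        p <- sample_parameters()
        if (!is_test_configuration(p)) break
      }
      make_record(p, grid, if (i <= n_train) "train" else "val", input)
    })
  })
  structure(list(records = records, size_px = size_px, input = input,
                 seed = seed),
            class = "spr_dataset")
}

#' Build the deterministic held-out test set
#'
#' The grid of configurations excluded from training: gold thicknesses
#' \{30, 40, 45, 50\} nm at 633 nm with the nominal gold index
#' 0.18 + 3.44i, over a set of sample indices spanning 1.00 (air) to 1.372
#' (liquid BSA protein).
#'
#' @param size_px Side of the full BFP image (default 512).
#' @param dm_nm Thickness grid in nm.
#' @param ns Sample-index grid; \code{dense_ns = TRUE} replaces it with a
#'   0.002-step grid over [1.00, 1.372].
#' @param dense_ns Use the dense sample-index grid.
#' @param na Numerical aperture.
#' @return An \code{spr_dataset} whose records are all tagged \code{test}.
#' @export
build_test_set <- function(size_px = 512, dm_nm = c(30, 40, 45, 50),
                           ns = c(1.00, 1.33, 1.34, 1.372),
                           dense_ns = FALSE, na = 1.49) {
  if (dense_ns) ns <- seq(1.00, 1.372, by = 0.002)
  grid <- pupil_grid(size_px, na)
  cases <- expand.grid(dm = dm_nm, ns = ns)
  records <- lapply(seq_len(nrow(cases)), function(i) {
    p <- structure(list(dm_nm = cases$dm[i], wavelength_nm = 633,
                        nm = 0.18 + 3.44i, ns = cases$ns[i], seed = NULL),
                   class = "parameter_sample")
    make_record(p, grid, "test")
  })
  structure(list(records = records, size_px = size_px, input = "amplitude",
                 seed = NULL),
            class = "spr_dataset")
}

#' @export
print.spr_dataset <- function(x, ...) {
  sp <- table(factor(vapply(x$records, `[[`, character(1), "split"),
                     levels = c("train", "val", "test")))
  cat("SPR BFP dataset:", length(x$records), "records (",
      paste(names(sp), sp, collapse = ", "), ") |",
      x$size_px / 2, "px quadrants |", x$input, "input\n")
  invisible(x)
}

#' Subset a dataset by split tag
#'
#' @param dataset An \code{spr_dataset}.
#' @param split One of \code{"train"}, \code{"val"}, \code{"test"}.
#' @return List of records carrying that tag.
#' @export
dataset_split <- function(dataset, split) {
  stopifnot(inherits(dataset, "spr_dataset"))
  Filter(function(r) r$split == split, dataset$records)
}

#' Write or read a dataset container
#'
#' Datasets are serialized with R's native binary serialization; reading
#' back restores bit-identical images and parameters.
#'
#' @param dataset An \code{spr_dataset}.
#' @param path File path (conventionally \code{.rds}).
#' @return \code{read_dataset} returns the \code{spr_dataset};
#'   \code{write_dataset} returns \code{path} invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spr_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "spr_dataset"))
  x
}
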