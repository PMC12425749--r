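#' Add background events, rescale to a target count total, draw Poisson noise
#'
#' Two-stage noise model for dynamic sinograms. First a spatially
#' uniform background of random and scatter events is added to every
#' frame, apportioned across frames proportionally to each frame's true
#' counts so that in total (and per frame)
#' `sum(background) = background_fraction * sum(trues)`. Second, all
#' frames are globally rescaled so the total expected count over the
#' whole scan equals `total_counts`, and one Poisson realization is
#' drawn with the scaled expectations as means.
#'
#' @param trues Noise-free sinogram counts, bins x frames matrix, >= 0.
#' @param background_fraction Background-to-trues ratio (default 0.20).
#' @param total_counts Target total expected counts (default 8e6).
#' @param seed Integer seed for the Poisson draw.
#' @return List: `expected` (scaled trues + background, bins x frames),
#'   `trues` (scaled trues), `r` (scaled background means, for use as
#'   the additive term in MLEM), `noisy` (one Poisson realization),
#'   `scale` (the global scale factor applied).
#' @export
corrupt <- function(trues, background_fraction = 0.20, total_counts = 8e6,
                    seed = NULL) {
  trues <- as.matrix(trues)
  if (any(trues < 0)) stop("noise-free sinograms must be nonnegative")
  tot <- sum(trues)
  if (tot <= 0) stop("cannot scale an all-zero sinogram sequence")
  frame_tot <- colSums(trues)
  r <- matrix(rep(background_fraction * frame_tot / nrow(trues),
                  each = nrow(trues)), nrow(trues), ncol(trues))
  expected <- trues + r
  scale <- total_counts / sum(expected)
  expected <- expected * scale
  trues_s <- trues * scale
  r_s <- r * scale
  if (!is.null(seed)) set.seed(as.integer(seed))
  noisy <- matrix(stats::rpois(length(expected), lambda = expected),
                  nrow(expected), ncol(expected))
  list(expected = expected, trues = trues_s, r = r_s,
       noisy = noisy, scale = scale)
}

#' Simulate a complete seeded dynamic-PET dataset
#'
#' Runs the full simulation protocol: phantom construction, regional
#' TACs from the two-tissue compartment model, frame integration over
#' the dynamic schedule, forward projection of the count-scaled
#' ground-truth images, two-stage noise corruption and `n_realizations`
#' independent Poisson realizations sharing one expected sinogram.
#' Per-realization sub-seeds are derived deterministically from `seed`.
#'
#' Ground-truth images are stored in count-scaled units (activity x
#' frame duration x global scale), the scale in which MLEM estimates
#' them from the noisy counts.
#'
#' @param phantom A `pet_phantom` (default 111 x 111, 5 x 5 lesion).
#' @param kinetics Per-region kinetic parameters (see
#'   [default_kinetics()]).
#' @param input_params Input-function parameters (see
#'   [default_input_params()]).
#' @param schedule A `frame_schedule` (default 24-frame protocol).
#' @param system A `pet_system`; default built to match the phantom
#'   side.
#' @param background_fraction,total_counts Noise-stage parameters.
#' @param n_realizations Number of independent noisy datasets
#'   (default 20).
#' @param seed Master seed.
#' @return Object of class `pet_dataset`: list with `truth_images`
#'   (pixels x frames, count-scaled), `activity` (pixels x frames,
#'   activity units), `expected`, `trues`, `r` (bins x frames),
#'   `noisy` (list of bins x frames matrices), `region_frames`,
#'   `phantom`, `schedule`, `system_geometry`, `seeds`, `scale`,
#'   `config`, `version`.
#' @export
simulate_dataset <- function(phantom = make_phantom(),
                             kinetics = default_kinetics(),
                             input_params = default_input_params(),
                             schedule = frame_schedule(),
                             system = NULL,
                             background_fraction = 0.20,
                             total_counts = 8e6,
                             n_realizations = 20L,
                             seed = 1L) {
  stopifnot(inherits(phantom, "pet_phantom"), inherits(schedule, "frame_schedule"))
  if (is.null(system)) system <- build_system_matrix(phantom$side)
  if (ncol(system$H) != phantom$side^2)
    stop("system geometry does not match the phantom side")

  cp <- function(t) input_function(t, input_params)
  tmax_min <- schedule$total / 60
  region_frames <- lapply(kinetics, function(par) {
    tac_times <- seq(0, tmax_min, by = 0.01)
    tac_vals <- solve_tissue_tac(par, cp, tac_times)
    frame_integrate(list(times = tac_times, values = tac_vals), schedule)
  })

  activity <- build_activity_frames(phantom, region_frames)
  # counts accumulate over the frame duration (durations in minutes)
  truth_counts <- activity * matrix(schedule$dur / 60, nrow(activity),
                                    schedule$n_frames, byrow = TRUE)
  trues_sino <- as.matrix(system$H %*% truth_counts)

  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_realizations)
  if (anyDuplicated(seeds)) warning("duplicate per-realization seeds")

  first <- corrupt(trues_sino, background_fraction, total_counts, seed = seeds[1])
  noisy <- vector("list", n_realizations)
  noisy[[1]] <- first$noisy
  if (n_realizations > 1L) {
    for (i in 2:n_realizations) {
      set.seed(seeds[i])
      noisy[[i]] <- matrix(stats::rpois(length(first$expected), first$expected),
                           nrow(first$expected), ncol(first$expected))
    }
  }

  structure(list(
    truth_images = truth_counts * first$scale,
    activity = activity,
    expected = first$expected,
    trues = first$trues,
    r = first$r,
    noisy = noisy,
    region_frames = region_frames,
    phantom = phantom,
    schedule = schedule,
    system_geometry = list(image_side = system$image_side,
                           n_angles = system$n_angles,
                           n_radial = system$n_radial),
    seeds = seeds,
    scale = first$scale,
    config = list(background_fraction = background_fraction,
                  total_counts = total_counts,
                  n_realizations = n_realizations,
                  seed = as.integer(seed),
                  kinetics = kinetics,
                  input_params = input_params),
    version = dataset_schema_version()
  ), class = "pet_dataset")
}

#' @export
print.pet_dataset <- function(x, ...) {
  cat(sprintf("Dynamic PET dataset: %d x %d phantom, %d frames, %d realization(s)\n",
              x$phantom$side, x$phantom$side, x$schedule$n_frames,
              length(x$noisy)))
  cat(sprintf("  total expected counts %.4g, background fraction %.3f\n",
              sum(x$expected), sum(x$r) / sum(x$trues)))
  invisible(x)
}
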