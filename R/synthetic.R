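apply_noise <- function(x, noise) {
  eps <- stats::rnorm(length(x), 0, noise$sigma_mult)
  bg <- stats::rnorm(length(x), noise$background, noise$background_sd)
  x * exp(eps) + bg
}

pop_to_long <- function(pop) {
  tr <- pop$traces
  data.frame(
    cell_id = rep(tr$cell, 3L),
    time_h = rep(tr$time, 3L),
    channel = rep(c("N", "G", "G_X"), each = nrow(tr)),
    intensity = c(tr$N, tr$G, tr$G_X))
}

#' Generate a synthetic single-cell time-lapse experiment
#'
#' Emulates time-lapse imaging of reporter cells during and after an
#' induction pulse: a heterogeneous population is simulated with
#' [simulate_population()], the three channels (`N`, `G`, `G_X`) are
#' sampled at frame boundaries, multiplicative log-normal measurement
#' noise plus additive background is applied, and end-point fate labels
#' are recorded (optionally flipped with probability `label_flip` to
#' emulate staining errors). Both the noisy and the noise-free tables are
#' returned so downstream analyses can be tested against a clean oracle.
#'
#' @inheritParams simulate_population
#' @param noise A [noise_model()].
#' @param frame_interval Imaging cadence \[h\].
#' @param seed Integer master seed; deterministically spawns independent
#'   child seeds for doses, noise and label flips.
#' @return An object of class `"timelapse_data"`: list with `noisy` and
#'   `clean` long trace tables (`cell_id`, `time_h`, `channel`,
#'   `intensity`), `labels` (data frame `cell_id`, `fate`, `true_fate`),
#'   `doses`, `population` (the underlying [simulate_population()] result)
#'   and `times`.
#' @examples
#' \donttest{
#' tl <- generate_timelapse(n = 20, seed = 1)
#' head(tl$noisy)
#' table(tl$labels$fate)
#' }
#' @export
generate_timelapse <- function(params = fate_model(),
                               protocol = pulse_protocol(),
                               dist = dose_distribution(), n = 200,
                               noise = noise_model(),
                               frame_interval = NULL, seed = NULL) {
  check_flag_class(noise, "noise_model")
  check_number(n, "n", lower = 2)
  frame_interval <- frame_interval %||%
    default_config_raw()$analysis$frame_interval
  check_number(frame_interval, "frame_interval", lower = 0,
               strict_lower = TRUE)
  times <- seq(0, protocol$t_final, by = frame_interval)
  if (length(times) < 2L) stop("zero frames in protocol", call. = FALSE)
  seeds <- child_seeds(seed, 3L)
  pop <- simulate_population(params, protocol, dist, n = n,
                             seed = seeds[[1L]], times = times)
  clean <- pop_to_long(pop)
  noisy <- clean
  noisy$intensity <- with_seed(seeds[[2L]], apply_noise(clean$intensity, noise))
  true_fate <- as.character(pop$fates)
  fate <- with_seed(seeds[[3L]], {
    flip <- stats::runif(length(true_fate)) < noise$label_flip
    ifelse(flip & !is.na(true_fate),
           ifelse(true_fate == "GATA_high", "NANOG_high", "GATA_high"),
           true_fate)
  })
  structure(list(
    noisy = noisy, clean = clean,
    labels = data.frame(cell_id = seq_len(n), fate = fate,
                        true_fate = true_fate),
    doses = pop$doses, population = pop, times = times,
    noise = noise, seed = seed),
    class = "timelapse_data")
}

#' @export
print.timelapse_data <- function(x, ...) {
  cat(sprintf(
    "Synthetic time-lapse: %d cells x %d frames (%.3g h cadence)\n",
    length(x$doses), length(x$times), diff(x$times[1:2])))
  tb <- table(x$labels$fate, useNA = "ifany")
  cat("  recorded fates:", paste(sprintf("%s = %d", names(tb), tb),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic flow-cytometry-like snapshot
#'
#' Single-timepoint noisy intensity samples per channel for a simulated
#' population, emulating a flow-cytometry measurement taken `t_sample`
#' hours after the start of the protocol (default: end of the chase).
#'
#' @inheritParams generate_timelapse
#' @param t_sample Sampling time \[h\], `<= t_final`.
#' @return List with `channels` (named list of noisy intensity vectors for
#'   `N`, `G`, `G_X`), `clean` (noise-free counterparts), `fates`, and
#'   `doses`.
#' @examples
#' \donttest{
#' fs <- generate_flow_snapshot(n = 100, seed = 1)
#' histogram_peaks(fs$channels$G)
#' }
#' @export
generate_flow_snapshot <- function(params = fate_model(),
                                   protocol = pulse_protocol(),
                                   dist = dose_distribution(), n = 200,
                                   t_sample = NULL, noise = noise_model(),
                                   seed = NULL) {
  check_flag_class(noise, "noise_model")
  t_sample <- t_sample %||% protocol$t_final
  check_number(t_sample, "t_sample", lower = 0, upper = protocol$t_final)
  seeds <- child_seeds(seed, 2L)
  grid <- sort(unique(c(0, t_sample, protocol$t_final)))
  if (length(grid) < 2L) grid <- c(0, protocol$t_final)
  pop <- simulate_population(params, protocol, dist, n = n,
                             seed = seeds[[1L]], times = grid)
  fin <- pop$traces[abs(pop$traces$time - t_sample) < 1e-9, ]
  clean <- list(N = fin$N, G = fin$G, G_X = fin$G_X)
  channels <- with_seed(seeds[[2L]], lapply(clean, apply_noise, noise = noise))
  list(channels = channels, clean = clean, fates = pop$fates,
       doses = pop$doses, t_sample = t_sample, population = pop)
}

#' Generate a binormal labeled toy sample
#'
#' Two unit-variance normal classes with a given mean separation — the
#' standard fixture for exercising the ROC stack, whose true AUC is the
#' closed-form binormal value `pnorm(separation / sqrt(2))`.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param separation Mean gap between the positive and negative class.
#' @param seed Optional integer seed.
#' @return List with `values` and logical `labels` (`TRUE` = positive).
#' @examples
#' toy <- generate_labeled_toy(50, 50, separation = 2, seed = 1)
#' roc_frame(toy$values, toy$labels)$auc
#' @export
generate_labeled_toy <- function(n_pos, n_neg, separation, seed = NULL) {
  check_number(n_pos, "n_pos", lower = 1)
  check_number(n_neg, "n_neg", lower = 1)
  check_number(separation, "separation")
  with_seed(seed, list(
    values = c(stats::rnorm(n_neg, 0, 1), stats::rnorm(n_pos, separation, 1)),
    labels = c(rep(FALSE, n_neg), rep(TRUE, n_pos))))
}
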