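# Synthetic ring-flip ensembles and noisy coupling observations. The
# generator emulates the statistical structure the analysis assumes: a
# stationary two/three-state flip process, per-state idealised geometry with
# Gaussian coordinate jitter, and additive Gaussian measurement noise on
# couplings.

#' Specify a ring-flip model
#'
#' A discrete-time Markov chain over the three basis conformers with a
#' prescribed stationary distribution. Real flip kinetics are on the
#' microsecond scale but the rates are not known; the chain is parameterised
#' instead by `mean_dwell`, the expected dwell (in frames) of the most
#' populated state. Less populated states dwell proportionally shorter
#' (`d_i = mean_dwell * pi_i / max(pi)`), which is the unique reversible
#' chain with the requested stationary distribution and equal jump flow
#' between all populated states.
#'
#' @param stationary population vector (the stationary distribution).
#' @param mean_dwell expected dwell of the most populated state, frames
#'   (>= 1 after scaling for every populated state). Default 50.
#' @param seed integer seed used by [simulate_flip_trajectory()];
#'   `NULL` leaves the RNG stream alone.
#' @return list of class `flip_model` with the transition matrix in `trans`.
#' @export
flip_model <- function(stationary, mean_dwell = 50, seed = NULL) {
  p <- validate_population(stationary)
  pop <- which(p > 0)
  dwell <- mean_dwell * p / max(p)
  if (any(dwell[pop] < 1)) {
    stopf("populated state %s has mean dwell %.2f < 1 frame; increase mean_dwell",
          FIT_BASIS[pop][which.min(dwell[pop])], min(dwell[pop]))
  }
  trans <- diag(3)
  if (length(pop) > 1) {
    esc <- 1 / dwell[pop]  # escape probability per frame
    for (a in seq_along(pop)) {
      i <- pop[a]
      trans[i, i] <- 1 - esc[a]
      others <- pop[-a]
      trans[i, others] <- esc[a] / length(others)
    }
  }
  structure(list(stationary = p, mean_dwell = mean_dwell, dwell = dwell,
                 trans = trans, seed = seed),
            class = "flip_model")
}

#' Simulate a conformer-state trajectory
#'
#' Runs the flip chain for `n_frames` steps, starting from a draw of the
#' stationary distribution. Seeded runs are bit-reproducible.
#'
#' @param model a [flip_model()].
#' @param n_frames number of frames (>= 1).
#' @return character vector of conformer labels, length `n_frames`.
#' @export
simulate_flip_trajectory <- function(model, n_frames) {
  stopifnot(inherits(model, "flip_model"))
  if (n_frames < 1) stopf("n_frames must be at least 1")
  n_frames <- as.integer(n_frames)
  with_seed(model$seed, {
    states <- integer(n_frames)
    states[1] <- sample.int(3, 1, prob = model$stationary)
    if (n_frames > 1) {
      u <- stats::runif(n_frames - 1)
      cum <- apply(model$trans, 1, cumsum)  # 3 x 3, column = from-state
      for (t in 2:n_frames) {
        states[t] <- findInterval(u[t - 1], cum[, states[t - 1]],
                                  left.open = TRUE) + 1L
      }
    }
    FIT_BASIS[states]
  })
}

#' Map conformer states to jittered ideal-geometry frames
#'
#' Each state becomes its idealised ring ([build_ideal_ring()], with ring
#' protons) plus isotropic Gaussian coordinate jitter of standard deviation
#' `jitter_sd` on every atom; `jitter_sd = 0` reproduces the ideal geometry
#' exactly.
#'
#' @param states character vector of labels in `1C4`, `2SO`, `4C1`.
#' @param jitter_sd coordinate noise, Angstrom (>= 0). Default 0.
#' @param seed integer seed, or `NULL`.
#' @return a [ring_trajectory] with 11 atoms per frame (empty-state input
#'   gives a 0-frame trajectory).
#' @export
states_to_frames <- function(states, jitter_sd = 0, seed = NULL) {
  if (jitter_sd < 0) stopf("jitter_sd must be nonnegative")
  bad <- setdiff(unique(states), FIT_BASIS)
  if (length(bad)) stopf("cannot build geometry for state '%s'", bad[1])
  ideal <- lapply(FIT_BASIS, function(l) {
    f <- build_ideal_ring(l, include_protons = TRUE)
    as.matrix(f[, c("x", "y", "z")])
  })
  names(ideal) <- FIT_BASIS
  tmpl <- build_ideal_ring("1C4")
  n <- length(states)
  coords <- array(0, c(n, nrow(tmpl), 3))
  if (n > 0) {
    idx <- match(states, FIT_BASIS)
    for (l in seq_along(FIT_BASIS)) {
      sel <- which(idx == l)
      if (length(sel)) {
        coords[sel, , ] <- rep(ideal[[l]], each = length(sel))
      }
    }
    if (jitter_sd > 0) {
      coords <- coords + with_seed(seed, array(stats::rnorm(length(coords), 0, jitter_sd),
                                               dim(coords)))
    }
  }
  ring_trajectory(tmpl$name, coords, elements = tmpl$elem)
}

#' Synthesise a noisy observed coupling vector
#'
#' The exact population mixture of the reference couplings plus independent
#' Gaussian noise per coupling -- a synthetic stand-in for a measured
#' coupling row. The default noise (0.1 Hz) is roughly the one-decimal
#' resolution at which couplings are reported.
#'
#' @param p generating population vector.
#' @param refs a [conformer_refs] object.
#' @param noise_sd measurement noise, Hz (>= 0). Default 0.1.
#' @param seed integer seed, or `NULL`.
#' @return named coupling vector (Hz), clamped to the physical range.
#' @export
synth_observed_couplings <- function(p, refs = builtin_reference_set(),
                                     noise_sd = 0.1, seed = NULL) {
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  j <- back_calculate(p, refs)
  if (noise_sd > 0) {
    j <- j + with_seed(seed, stats::rnorm(4, 0, noise_sd))
  }
  coupling_vector(pmin(pmax(j, 0), 15))
}
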