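#' Simulation-to-haptics force channel
#'
#' Deterministic model of the asynchronous path from the simulation loop
#' (tens of Hz) to the haptic device loop (hundreds to 1000 Hz): the device
#' holds the last force delivered by the simulation (zeroth-order hold),
#' optionally smoothed by a causal moving average in the haptic-rate
#' domain to soften the staircase discontinuities the hold introduces.
#'
#' @param times strictly increasing simulation sample times (s).
#' @param forces n x 3 matrix of force samples (N).
#' @param haptic_rate device rate (Hz).
#' @param smoothing_window moving-average window in haptic-rate samples
#'   (>= 1; 1 = no smoothing).
#' @return An object of class `force_channel`.
#' @export
force_channel <- function(times, forces, haptic_rate = 1000,
                          smoothing_window = 1L) {
  forces <- as.matrix(forces)
  if (ncol(forces) == 1L) forces <- cbind(forces, 0, 0)
  stopifnot(length(times) == nrow(forces), ncol(forces) == 3L)
  if (length(times) < 1L) stopf("channel needs at least one sample")
  if (any(diff(times) <= 0)) stopf("timestamps must be strictly increasing")
  if (haptic_rate <= 0) stopf("haptic_rate must be > 0")
  if (smoothing_window < 1L) stopf("smoothing window must be >= 1")
  structure(list(times = as.numeric(times), forces = forces,
                 haptic_rate = haptic_rate,
                 smoothing_window = as.integer(smoothing_window)),
            class = "force_channel")
}

#' Zeroth-order-hold sample of the force channel
#'
#' Returns the force of the latest simulation sample with timestamp
#' `<= t` (the hold is inclusive at sample instants).
#'
#' @param channel a [force_channel()].
#' @param t query times (s); must not precede the first sample.
#' @return length(t) x 3 matrix of forces (N).
#' @export
sample_zoh <- function(channel, t) {
  stopifnot(inherits(channel, "force_channel"))
  if (any(t < channel$times[1L]))
    stopf("query time %.6g precedes first sample %.6g", min(t), channel$times[1L])
  ix <- findInterval(t, channel$times)
  channel$forces[ix, , drop = FALSE]
}

#' Causal moving-average smoothing
#'
#' Mean of the last `window` samples (fewer at the start of the sequence);
#' `window = 1` is the identity. Operates per column.
#'
#' @param samples numeric vector or matrix (samples in rows).
#' @param window integer >= 1.
#' @return smoothed samples, same shape as the input.
#' @export
smooth_moving_average <- function(samples, window) {
  if (window < 1L) stopf("window must be >= 1")
  window <- as.integer(window)
  vec_in <- is.null(dim(samples))
  x <- as.matrix(samples)
  if (window == 1L) return(if (vec_in) as.numeric(x) else x)
  n <- nrow(x)
  cs <- apply(x, 2L, cumsum)
  cs <- rbind(0, cs)
  i <- seq_len(n)
  lo <- pmax(i - window + 1L, 1L)
  out <- (cs[i + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (i - lo + 1)
  if (vec_in) as.numeric(out) else out
}

#' Resample a simulation force log to the haptic rate
#'
#' Zeroth-order hold at the haptic rate over the span of the simulation
#' log, then the channel's moving-average smoothing.
#'
#' @param channel a [force_channel()].
#' @return `data.frame` with columns `t`, `fx`, `fy`, `fz`, `f_mag`.
#' @export
resample_haptic <- function(channel) {
  stopifnot(inherits(channel, "force_channel"))
  t0 <- channel$times[1L]
  t1 <- channel$times[length(channel$times)]
  th <- seq(t0, t1, by = 1 / channel$haptic_rate)
  f <- sample_zoh(channel, th)
  f <- smooth_moving_average(f, channel$smoothing_window)
  data.frame(t = th, fx = f[, 1L], fy = f[, 2L], fz = f[, 3L],
             f_mag = sqrt(rowSums(f^2)))
}
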