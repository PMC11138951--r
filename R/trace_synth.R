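interp_to_length <- function(x, new_len) {
  if (length(x) == new_len) return(x)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = new_len))$y
}

#' Resample a segment to 75-125% of its length
#'
#' Linear interpolation onto `round(length * factor)` samples (at least 2);
#' endpoints are preserved, so zero-corrected segments stay zero-corrected.
#'
#' @param segment an `egm_segment`.
#' @param factor length factor in `[0.75, 1.25]`.
#' @return the resampled segment, re-normalized to unit max-abs.
#' @export
resample_segment <- function(segment, factor) {
  stopifnot(inherits(segment, "egm_segment"))
  if (factor < 0.75 || factor > 1.25)
    stop("resampling factor must lie in [0.75, 1.25], got ", factor)
  n <- length(segment$samples)
  new_len <- max(2L, round(n * factor))
  out <- segment
  out$samples <- interp_to_length(segment$samples, new_len)
  peak <- max(abs(out$samples))
  if (peak > 0) out$samples <- out$samples / peak
  out
}

#' Mixup of two segments
#'
#' Convex combination `lambda * a + (1 - lambda) * b` of two same-kind
#' segments; `b` is first interpolated to the length of `a`. The result is
#' re-normalized to unit max-abs. If the combination cancels to (near) zero,
#' the first segment is returned unchanged.
#'
#' @param a,b `egm_segment`s of the same kind.
#' @param lambda mixing coefficient in `[0, 1]`.
#' @return mixed `egm_segment`.
#' @export
mixup <- function(a, b, lambda) {
  stopifnot(inherits(a, "egm_segment"), inherits(b, "egm_segment"))
  if (a$kind != b$kind)
    stop("mixup requires segments of the same kind (", a$kind, " vs ", b$kind, ")")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  bs <- interp_to_length(b$samples, length(a$samples))
  mixed <- lambda * a$samples + (1 - lambda) * bs
  peak <- max(abs(mixed))
  if (peak < 1e-9) return(a)  # degenerate cancellation
  out <- a
  out$samples <- mixed / peak
  out
}

label_channel <- function(kind, merge_ff_into_lf) {
  switch(kind, STIM = "STIM", LF = "LF", LP = "LF",
         FF = if (merge_ff_into_lf) "LF" else "FF")
}

#' Compose one cardiac cycle from its rules
#'
#' Builds the baseline by concatenating amplitude-scaled rest segments to
#' the cycle length, then adds each placed segment (scaled by its amplitude,
#' optionally resampled and mixed up) at the index determined by its
#' position percentage, `round(position/100 * (rr - len))`, so placements
#' always fall inside the cycle. The placed index ranges are recorded as
#' ground-truth intervals (late potentials are labeled on the local-field
#' channel).
#'
#' @param rules a `cycle_rules`.
#' @param pools a `segment_pools`.
#' @param rr_samples cycle length in samples.
#' @return list with `signal` (numeric of length `rr_samples`, mV) and
#'   `intervals` (data.frame `kind`, `onset`, `offset`).
#' @export
compose_cycle <- function(rules, pools, rr_samples) {
  baseline <- numeric(0)
  for (i in seq_along(rules$rest$indices)) {
    seg <- pools$REST[[rules$rest$indices[i]]]
    baseline <- c(baseline, seg$samples * rules$rest$amplitudes[i])
  }
  if (length(baseline) < rr_samples)
    baseline <- c(baseline, numeric(rr_samples - length(baseline)))
  signal <- baseline[seq_len(rr_samples)]
  ints <- list()
  for (p in rules$placements) {
    seg <- pools[[p$kind]][[p$pool_index]]
    if (!is.na(p$mixup_partner))
      seg <- mixup(seg, pools[[p$kind]][[p$mixup_partner]], p$mixup_lambda)
    if (p$resample_factor != 1)
      seg <- resample_segment(seg, p$resample_factor)
    len <- length(seg$samples)
    if (len > rr_samples) {
      warning("skipping ", p$kind, " placement longer than the cycle")
      next
    }
    start <- round(p$position_pct / 100 * (rr_samples - len))
    idx <- (start + 1):(start + len)
    signal[idx] <- signal[idx] + seg$samples * p$amplitude
    ints <- c(ints, list(data.frame(
      kind = label_channel(p$kind, isTRUE(rules$merge_ff_into_lf)),
      onset = start, offset = start + len)))
  }
  intervals <- if (length(ints)) do.call(rbind, ints) else
    data.frame(kind = character(0), onset = numeric(0), offset = numeric(0))
  list(signal = signal, intervals = intervals)
}

#' Assemble a labeled trace from three composed cycles
#'
#' Concatenates the tail of the left cycle (its last `left_keep_pct`
#' percent), the full central cycle and the head of the right cycle, adds
#' white noise (relative to the central-cycle peak) and a sub-hertz
#' sinusoidal baseline wander with random phase, shifts all ground-truth
#' intervals into the cropped frame (clipping at the borders) and rebuilds
#' the 3xN mask. Overlapping same-channel intervals are fused so mask runs
#' and intervals stay in bijection.
#'
#' @param cycles list of three `compose_cycle()` results.
#' @param registry the `registry_rules` the cycles were drawn under.
#' @return object of class `egm_trace`: `signal`, `mask` (3xN), `intervals`
#'   (`egm_intervals`), `n`, `fs`, `registry`.
#' @export
assemble_trace <- function(cycles, registry) {
  n1 <- length(cycles[[1]]$signal)
  n2 <- length(cycles[[2]]$signal)
  n3 <- length(cycles[[3]]$signal)
  left_n <- round(registry$left_keep_pct / 100 * n1)
  right_n <- round(registry$right_keep_pct / 100 * n3)
  signal <- c(if (left_n > 0) cycles[[1]]$signal[(n1 - left_n + 1):n1],
              cycles[[2]]$signal,
              if (right_n > 0) cycles[[3]]$signal[seq_len(right_n)])
  n <- length(signal)
  ints <- rbind(
    shift_intervals(cycles[[1]]$intervals, left_n - n1),
    shift_intervals(cycles[[2]]$intervals, left_n),
    shift_intervals(cycles[[3]]$intervals, left_n + n2))
  ints <- clip_intervals(ints, 0, n)
  central_peak <- max(abs(cycles[[2]]$signal))
  if (registry$noise_sigma > 0)
    signal <- signal + stats::rnorm(n, sd = registry$noise_sigma * central_peak)
  if (registry$wander_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    t <- (seq_len(n) - 1) / 1000
    signal <- signal + registry$wander_amp * central_peak *
      sin(2 * pi * registry$wander_freq * t + phase)
  }
  intervals <- canonicalize_intervals(as_egm_intervals(ints, n))
  structure(list(signal = signal, mask = intervals_to_mask(intervals, n),
                 intervals = intervals, n = n, fs = 1000,
                 registry = registry),
            class = "egm_trace")
}

#' @export
print.egm_trace <- function(x, ...) {
  cat(sprintf("<egm_trace> %d samples @ %g Hz, %d labeled intervals\n",
              x$n, x$fs, nrow(x$intervals)))
  invisible(x)
}

#' Plot a labeled synthetic trace
#'
#' Signal with the ground-truth components shaded (stimulation grey, local
#' field green, far field magenta).
#'
#' @param x an `egm_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.egm_trace <- function(x, ...) {
  t <- (seq_len(x$n) - 1) / x$fs
  graphics::plot(t, x$signal, type = "l", xlab = "time (s)",
                 ylab = "voltage (mV)", ...)
  cols <- c(STIM = grDevices::adjustcolor("grey40", 0.3),
            LF = grDevices::adjustcolor("forestgreen", 0.3),
            FF = grDevices::adjustcolor("magenta", 0.3))
  usr <- graphics::par("usr")
  for (i in seq_len(nrow(x$intervals)))
    graphics::rect(x$intervals$onset[i] / x$fs, usr[3],
                   x$intervals$offset[i] / x$fs, usr[4],
                   col = cols[[x$intervals$kind[i]]], border = NA)
  invisible(x)
}

#' Generate a reproducible synthetic dataset
#'
#' Draws `n_traces` labeled traces under the generator's study conditions.
#' Traces are grouped into synthetic patients (consecutive blocks) so that
#' patient-wise splitting can be exercised downstream.
#'
#' @param n_traces number of traces.
#' @param seed integer seed; the dataset is byte-identical across runs for
#'   a given seed and configuration.
#' @param config a [synth_config()].
#' @param pools optional `segment_pools`; built (seeded) when missing.
#' @param amp_model optional `amplitude_model`; defaults to
#'   [default_amplitude_model()].
#' @param traces_per_patient traces per synthetic patient, default 4.
#' @return list of `egm_trace`s, each with a `patient` element.
#' @export
generate_dataset <- function(n_traces, seed, config = synth_config(),
                             pools = NULL, amp_model = NULL,
                             traces_per_patient = 4) {
  set.seed(seed)
  if (is.null(pools)) pools <- build_segment_pools()
  if (is.null(amp_model)) amp_model <- default_amplitude_model()
  lapply(seq_len(n_traces), function(i) {
    registry <- draw_registry_rules(config)
    rules <- draw_cycle_rules(registry, pools, amp_model, config)
    cycles <- lapply(rules, compose_cycle, pools = pools,
                     rr_samples = round(registry$rr_ms))
    trace <- assemble_trace(cycles, registry)
    trace$patient <- sprintf("P%03d", (i - 1) %/% traces_per_patient + 1)
    trace
  })
}
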