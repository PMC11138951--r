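#' Waveform segment kinds
#'
#' The five fundamental component classes of a bipolar intracavitary
#' electrogram: stimulation artifact (`STIM`), local-field activation (`LF`),
#' late potential (`LP`, operationally a local activation shorter than 25
#' samples), far-field activation (`FF`) and inactive baseline (`REST`).
#' @export
SEGMENT_KINDS <- c("STIM", "LF", "LP", "FF", "REST")

#' Mask channel order: stimulation, local field, far field
#' @export
MASK_CHANNELS <- c("STIM", "LF", "FF")

#' Construct a waveform segment
#'
#' A segment is a single cropped or synthesized waveform fragment sampled at
#' 1000 Hz. Segments separate morphology from voltage: samples are stored
#' max-abs normalized and the original peak voltage is kept in
#' `native_amplitude` (mV).
#'
#' @param samples numeric vector of samples.
#' @param kind one of [SEGMENT_KINDS].
#' @param fs sampling rate in Hz (the pipeline assumes 1000 Hz throughout).
#' @param native_amplitude original max-abs voltage in mV before
#'   normalization; defaults to `max(abs(samples))`.
#' @param normalize if `TRUE` (default), scale samples to unit max-abs.
#' @return an object of class `egm_segment`.
#' @export
egm_segment <- function(samples, kind, fs = 1000, native_amplitude = NULL,
                        normalize = TRUE) {
  kind <- match.arg(kind, SEGMENT_KINDS)
  samples <- as.numeric(samples)
  peak <- max(abs(samples))
  if (is.null(native_amplitude)) native_amplitude <- peak
  if (normalize && peak > 0) samples <- samples / peak
  structure(list(samples = samples, kind = kind, fs = fs,
                 native_amplitude = native_amplitude),
            class = "egm_segment")
}

#' @export
length.egm_segment <- function(x) length(x$samples)

#' @export
print.egm_segment <- function(x, ...) {
  cat(sprintf("<egm_segment> %s, %d samples @ %g Hz, native amplitude %.4g mV\n",
              x$kind, length(x$samples), x$fs, x$native_amplitude))
  invisible(x)
}

#' Validate the segment invariants
#'
#' Checks max-abs normalization (within 1e-9, except all-zero REST), the
#' 25-sample LP/LF length rule and zero start/end voltage for non-REST
#' segments.
#'
#' @param seg an `egm_segment`.
#' @param tol numeric tolerance.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_segment <- function(seg, tol = 1e-9) {
  stopifnot(inherits(seg, "egm_segment"))
  s <- seg$samples
  peak <- max(abs(s))
  if (!(seg$kind == "REST" && peak == 0) && abs(peak - 1) > tol)
    stop("segment not max-abs normalized (peak = ", peak, ")")
  if (seg$kind == "LP" && length(s) >= 25)
    stop("LP segment must be shorter than 25 samples")
  if (seg$kind == "LF" && length(s) < 25)
    stop("LF segment must be at least 25 samples long")
  if (seg$kind != "REST" &&
      (abs(s[1]) > tol || abs(s[length(s)]) > tol))
    stop("non-REST segment must start and end at zero voltage")
  invisible(TRUE)
}

run_lengths <- function(x) {
  # maximal runs of 1s in a 0/1 vector -> data.frame(onset, offset), 0-based
  # half-open sample coordinates
  r <- rle(as.integer(x) != 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(onset = starts[r$values], offset = ends[r$values])
}

#' Crop a signal into its fundamental segments
#'
#' Reads the maximal runs of every channel of a 3xN binary mask (channel
#' order stimulation / local field / far field) and cuts the corresponding
#' stretches of the signal into raw (unnormalized) segments; the complement
#' of all annotated runs becomes `REST` segments. Overlap between the
#' stimulation and local-field channels is resolved in favour of the
#' stimulation artifact with a warning.
#'
#' Segments are returned raw so that concatenating all cropped segments in
#' temporal order reconstructs the input signal exactly; normalization
#' happens when a segment pool is finalized.
#'
#' @param signal single-lead numeric vector of length N.
#' @param mask 3xN binary matrix, rows `STIM`, `LF`, `FF`.
#' @return named list with one list of `egm_segment`s per kind
#'   (`STIM`, `LF`, `FF`, `REST`); each segment carries a `start` attribute
#'   (0-based sample index into the input).
#' @export
crop_segments <- function(signal, mask) {
  if (!is.matrix(mask) || nrow(mask) != 3L)
    stop("mask must be a 3xN matrix (channels STIM, LF, FF)")
  n <- length(signal)
  if (ncol(mask) != n)
    stop("signal length (", n, ") does not match mask length (", ncol(mask), ")")
  mask <- mask != 0
  if (any(mask[1, ] & mask[2, ])) {
    warning("overlapping STIM/LF annotations; stimulation takes precedence")
    mask[2, mask[1, ]] <- FALSE
  }
  out <- list(STIM = list(), LF = list(), FF = list(), REST = list())
  for (ch in seq_len(3)) {
    kind <- MASK_CHANNELS[ch]
    runs <- run_lengths(mask[ch, ])
    for (i in seq_len(nrow(runs))) {
      idx <- (runs$onset[i] + 1L):runs$offset[i]
      seg <- egm_segment(signal[idx], kind, normalize = FALSE)
      attr(seg, "start") <- runs$onset[i]
      out[[kind]] <- c(out[[kind]], list(seg))
    }
  }
  covered <- colSums(mask) > 0
  rest_runs <- run_lengths(!covered)
  for (i in seq_len(nrow(rest_runs))) {
    idx <- (rest_runs$onset[i] + 1L):rest_runs$offset[i]
    seg <- egm_segment(signal[idx], "REST", normalize = FALSE)
    attr(seg, "start") <- rest_runs$onset[i]
    out$REST <- c(out$REST, list(seg))
  }
  out
}

#' Low-pass filter a far-field or rest segment
#'
#' Applies a single-pass (causal) 2nd-order Butterworth low-pass at 100 Hz to
#' suppress any unannotated late potential riding on the segment. Only
#' far-field and rest segments are eligible.
#'
#' @param segment an `egm_segment` of kind `FF` or `REST`.
#' @param cutoff_hz cutoff frequency, default 100 Hz.
#' @param order filter order, default 2.
#' @return the filtered segment (same length, same kind).
#' @export
lowpass_ff_rest <- function(segment, cutoff_hz = 100, order = 2) {
  stopifnot(inherits(segment, "egm_segment"))
  if (!segment$kind %in% c("FF", "REST"))
    stop("lowpass_ff_rest applies only to FF and REST segments, got ", segment$kind)
  bf <- signal::butter(order, cutoff_hz / (segment$fs / 2), type = "low")
  filtered <- as.numeric(signal::filter(bf, segment$samples))
  out <- segment
  out$samples <- filtered
  out
}

#' Zero-correct a segment's endpoints
#'
#' Subtracts the straight line joining the first and last sample so that the
#' segment starts and ends at exactly zero voltage, which makes additive
#' composition of synthetic traces seamless. Interior morphology is modified
#' only by that linear trend.
#'
#' @param segment an `egm_segment` (length >= 2).
#' @return the corrected segment.
#' @export
zero_correct <- function(segment) {
  stopifnot(inherits(segment, "egm_segment"))
  s <- segment$samples
  n <- length(s)
  if (n < 2) stop("cannot zero-correct a segment with fewer than 2 samples")
  out <- segment
  out$samples <- s - seq(s[1], s[n], length.out = n)
  out
}

#' Split local activations into LF and LP pools
#'
#' Local activations shorter than 25 samples are re-labelled late potentials
#' (`LP`); those of 25 samples or more remain local fields (`LF`). The rule
#' is strict: a 24-sample activation is an LP, a 25-sample one an LF.
#'
#' @param segments list of `egm_segment`s annotated as local activations.
#' @param threshold length threshold in samples, default 25.
#' @return list with elements `lf` and `lp`, two disjoint and jointly
#'   exhaustive pools.
#' @export
split_lf_lp <- function(segments, threshold = 25) {
  lf <- list(); lp <- list()
  for (seg in segments) {
    if (length(seg$samples) < threshold) {
      seg$kind <- "LP"
      lp <- c(lp, list(seg))
    } else {
      seg$kind <- "LF"
      lf <- c(lf, list(seg))
    }
  }
  list(lf = lf, lp = lp)
}
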