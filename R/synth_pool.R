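#' Morphology generator configuration
#'
#' Duration and frequency ranges for the parametric waveform families used to
#' populate segment pools when annotated clinical segments are unavailable.
#' Local activations are amplitude-modulated oscillatory bursts with dominant
#' content in 80-300 Hz; far fields are smooth mono- or biphasic lobes below
#' 100 Hz; stimulation artifacts are biphasic near-impulses of a few
#' milliseconds; rest segments are low-amplitude colored noise.
#'
#' @param lf_len_range LF duration range in samples (>= 25).
#' @param lp_len_range LP duration range in samples (< 25).
#' @param ff_len_range FF duration range in samples.
#' @param stim_len_range stimulation artifact duration range in samples.
#' @param rest_len_range rest duration range in samples.
#' @param local_freq_range oscillation band for local activations, Hz.
#' @param rest_native_range native amplitude range for rest segments,
#'   relative to millivolt scale (kept small: baseline noise).
#' @param fs sampling rate, Hz.
#' @return a list of class `morph_config`.
#' @export
morph_config <- function(lf_len_range = c(25, 80), lp_len_range = c(8, 24),
                         ff_len_range = c(40, 160), stim_len_range = c(3, 5),
                         rest_len_range = c(50, 400),
                         local_freq_range = c(80, 300),
                         rest_native_range = c(0.005, 0.05), fs = 1000) {
  structure(as.list(environment()), class = "morph_config")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

synth_one_segment <- function(kind, cfg) {
  fs <- cfg$fs
  s <- switch(kind,
    LF = , LP = {
      len <- round(runif1(if (kind == "LF") cfg$lf_len_range else cfg$lp_len_range))
      # oscillation must complete at least one cycle within the burst
      fmin <- max(cfg$local_freq_range[1], fs / len)
      f1 <- stats::runif(1, fmin, cfg$local_freq_range[2])
      f2 <- stats::runif(1, fmin, cfg$local_freq_range[2])
      t <- (0:(len - 1)) / fs
      w <- hann_window(len)
      w * (sin(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi)) +
           stats::runif(1, 0.2, 0.8) *
             sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi)))
    },
    FF = {
      len <- round(runif1(cfg$ff_len_range))
      t <- seq_len(len)
      centre <- len * stats::runif(1, 0.35, 0.65)
      width <- len / stats::runif(1, 6, 10)
      lobe <- exp(-((t - centre)^2) / (2 * width^2))
      if (stats::runif(1) < 0.5) {
        # biphasic: derivative-of-Gaussian shape
        lobe <- -(t - centre) / width * lobe
      }
      lobe * hann_window(len)^0.25
    },
    STIM = {
      len <- max(3L, round(runif1(cfg$stim_len_range)))
      up <- ceiling((len - 1) / 2)
      c(rep(1, up), rep(-stats::runif(1, 0.5, 0.9), len - up))
    },
    REST = {
      len <- round(runif1(cfg$rest_len_range))
      bf <- signal::butter(2, 80 / (fs / 2), type = "low")
      as.numeric(signal::filter(bf, stats::rnorm(len)))
    },
    stop("unknown segment kind: ", kind))
  native <- if (kind == "REST") runif1(cfg$rest_native_range) else max(abs(s))
  seg <- egm_segment(s, kind, fs = fs, native_amplitude = native,
                     normalize = FALSE)
  seg <- zero_correct(seg)
  peak <- max(abs(seg$samples))
  if (peak > 0) seg$samples <- seg$samples / peak
  seg
}

#' Synthesize a pool of waveform segments
#'
#' Generates `n` segments of one kind from the parametric morphology
#' families of [morph_config()]. Every generated segment is zero-corrected,
#' max-abs normalized and satisfies the segment invariants (LP shorter than
#' 25 samples, LF at least 25 samples).
#'
#' @param kind one of [SEGMENT_KINDS].
#' @param n number of segments (> 0).
#' @param config a [morph_config()].
#' @return list of `egm_segment`s. Deterministic given the RNG state.
#' @export
synth_segment_pool <- function(kind, n, config = morph_config()) {
  kind <- match.arg(kind, SEGMENT_KINDS)
  stopifnot(n > 0)
  lapply(seq_len(n), function(i) synth_one_segment(kind, config))
}

#' Build the full set of segment pools
#'
#' @param n_per_kind named integer vector of pool sizes.
#' @param config a [morph_config()].
#' @return named list of pools (`STIM`, `LF`, `LP`, `FF`, `REST`), class
#'   `segment_pools`.
#' @export
build_segment_pools <- function(n_per_kind = c(STIM = 12, LF = 48, LP = 32,
                                               FF = 48, REST = 48),
                                config = morph_config()) {
  pools <- lapply(SEGMENT_KINDS, function(k)
    synth_segment_pool(k, n_per_kind[[k]], config))
  names(pools) <- SEGMENT_KINDS
  structure(pools, class = "segment_pools", config = config)
}

#' @export
print.segment_pools <- function(x, ...) {
  cat("<segment_pools>",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}
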