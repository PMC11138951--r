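#' Binarize a probability map
#'
#' Elementwise `>= threshold` (so a threshold of 0 marks everything).
#'
#' @param probmap 3xN matrix in `[0, 1]`.
#' @param threshold decision threshold, default 0.5.
#' @return 3xN integer 0/1 mask.
#' @export
binarize <- function(probmap, threshold = 0.5) {
  m <- (probmap >= threshold) + 0L
  dimnames(m) <- dimnames(probmap)
  m
}

#' Extract typed intervals from a binary mask
#'
#' Reads each channel's maximal runs of 1s, merges runs separated by a gap
#' strictly smaller than `merge_gap` samples, and drops intervals shorter
#' than `min_len` samples. With interval sets already respecting these
#' cleanups this is the exact inverse of [intervals_to_mask()].
#'
#' @param mask 3xN binary matrix (rows STIM, LF, FF).
#' @param min_len minimum interval length kept, default 3.
#' @param merge_gap gaps of fewer than this many samples are closed,
#'   default 2.
#' @param lead optional lead id stamped on the intervals.
#' @return an `egm_intervals` table.
#' @export
mask_to_intervals <- function(mask, min_len = 3, merge_gap = 2, lead = NA) {
  stopifnot(is.matrix(mask), nrow(mask) == 3)
  n <- ncol(mask)
  out <- list()
  for (ch in 1:3) {
    runs <- run_lengths(mask[ch, ])
    if (nrow(runs) > 1) {
      keep <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- runs$onset[i] - keep$offset[nrow(keep)]
        if (gap < merge_gap) {
          keep$offset[nrow(keep)] <- runs$offset[i]
        } else {
          keep <- rbind(keep, runs[i, , drop = FALSE])
        }
      }
      runs <- keep
    }
    runs <- runs[runs$offset - runs$onset >= min_len, , drop = FALSE]
    if (nrow(runs))
      out <- c(out, list(data.frame(kind = MASK_CHANNELS[ch], runs)))
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(0), onset = numeric(0), offset = numeric(0))
  df$lead <- rep(lead, length.out = nrow(df))
  as_egm_intervals(df, n)
}

#' Remove detections that are pacing-spike artifacts
#'
#' Local- and far-field intervals overlapping a stimulation interval by more
#' than half of their own length are discarded; they are fragments of the
#' pacing artifact, not physiological activations. The stimulation support
#' is dilated by a small margin before the overlap test, because artifact
#' fragments typically hug the spike's flanks (the decaying tail of the
#' pacing transient) without strictly overlapping the detected spike.
#'
#' @param intervals an interval table.
#' @param stim_margin_ms dilation of the stimulation support on each side
#'   before the overlap test, default 5 ms.
#' @return the cleaned table.
#' @export
clean_pacing_spikes <- function(intervals, stim_margin_ms = 5) {
  stim <- intervals[intervals$kind == "STIM", , drop = FALSE]
  if (nrow(stim) == 0 || nrow(intervals) == 0) return(intervals)
  keep <- vapply(seq_len(nrow(intervals)), function(i) {
    if (intervals$kind[i] == "STIM") return(TRUE)
    len <- intervals$offset[i] - intervals$onset[i]
    ov <- pmin(intervals$offset[i], stim$offset + stim_margin_ms) -
          pmax(intervals$onset[i], stim$onset - stim_margin_ms)
    max(c(ov, 0)) <= 0.5 * len
  }, logical(1))
  out <- intervals[keep, , drop = FALSE]
  as_egm_intervals(out, attr(intervals, "frame"))
}

#' Detect QRS barycenters on a surface lead
#'
#' A simple amplitude-envelope detector for when no external fiducials are
#' supplied: the rectified surface signal is smoothed with a 50 ms moving
#' average, peaks above 30% of the global maximum are selected with a
#' 200 ms refractory period, and each fiducial is placed at the barycenter
#' of the envelope within +/-100 ms of the peak.
#'
#' @param surface numeric surface-ECG lead.
#' @param fs sampling rate, default 1000.
#' @return increasing integer vector of barycenter sample indices (0-based).
#' @export
detect_qrs <- function(surface, fs = 1000) {
  env <- stats::filter(abs(surface), rep(1 / 51, 51), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- 0.3 * max(env)
  n <- length(env)
  peaks <- integer(0)
  i <- 2
  while (i < n) {
    if (env[i] >= thr && env[i] >= env[i - 1] && env[i] >= env[i + 1]) {
      peaks <- c(peaks, i)
      i <- i + round(0.2 * fs)
    } else i <- i + 1
  }
  vapply(peaks, function(p) {
    idx <- max(1, p - round(0.1 * fs)):min(n, p + round(0.1 * fs))
    w <- env[idx]
    round(sum((idx - 1) * w) / sum(w))
  }, numeric(1))
}

#' Crop a recording into per-cycle analysis windows
#'
#' Each window is `window_len` samples centered on a QRS barycenter
#' (`[b - window_len/2, b + window_len/2)`); windows crossing the recording
#' edges are zero-padded and the pad extents recorded, so window-local
#' intervals map back to recording coordinates exactly.
#'
#' @param signals T x L matrix of lead samples.
#' @param barycenters 0-based QRS barycenter sample indices.
#' @param window_len window length, default 1024.
#' @return list of windows: each has `data` (window_len x L), `offset`
#'   (0-based recording index of window sample 0, may be negative),
#'   `pad_left`, `pad_right`.
#' @export
window_by_qrs <- function(signals, barycenters, window_len = 1024) {
  if (length(barycenters) == 0)
    stop("no QRS barycenters available; supply external fiducials")
  signals <- as.matrix(signals)
  total <- nrow(signals)
  half <- window_len %/% 2
  lapply(barycenters, function(b) {
    start <- b - half                       # 0-based
    idx <- (start + 1):(start + window_len) # 1-based source rows
    ok <- idx >= 1 & idx <= total
    data <- matrix(0, window_len, ncol(signals))
    data[ok, ] <- signals[idx[ok], , drop = FALSE]
    list(data = data, offset = start,
         pad_left = sum(idx < 1), pad_right = sum(idx > total))
  })
}

#' Majority voting of detections across catheter leads
#'
#' The decapolar catheter's lead geometry makes true activations nearly
#' synchronous across leads, so per-lead detections of one kind are fused:
#' onsets are clustered greedily (a new cluster starts when the next sorted
#' onset lies more than `tolerance_ms` from the previous one), and every
#' cluster supported by at least `min_leads` distinct leads emits one
#' consensus interval at the median onset and median offset of its members.
#' Unsupported detections are dropped. Voting is invariant to lead order
#' and the consensus onset always lies within the range of its members.
#'
#' @param per_lead list of interval tables (one per lead, `lead` column
#'   set) or a single combined table.
#' @param kind which component kind to vote on.
#' @param tolerance_ms clustering linkage tolerance, default 20.
#' @param min_leads minimum distinct leads per consensus, default 3.
#' @return consensus `egm_intervals` (lead `NA`).
#' @export
vote_across_leads <- function(per_lead, kind, tolerance_ms = 20,
                              min_leads = 3) {
  df <- if (is.data.frame(per_lead)) per_lead else do.call(rbind, per_lead)
  frame <- if (is.data.frame(per_lead)) attr(per_lead, "frame") else
    attr(per_lead[[1]], "frame")
  df <- df[df$kind == kind, , drop = FALSE]
  if (nrow(df) == 0) return(egm_intervals(frame = frame))
  df <- df[order(df$onset), , drop = FALSE]
  cluster <- cumsum(c(1, diff(df$onset) > tolerance_ms))
  out <- list()
  for (cl in unique(cluster)) {
    members <- df[cluster == cl, , drop = FALSE]
    if (length(unique(members$lead)) < min_leads) next
    out <- c(out, list(data.frame(
      kind = kind, onset = round(stats::median(members$onset)),
      offset = round(stats::median(members$offset)), lead = NA)))
  }
  if (!length(out)) return(egm_intervals(frame = frame))
  as_egm_intervals(do.call(rbind, out), frame)
}
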