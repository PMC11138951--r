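#' Decrement classification configuration
#'
#' @param decrement_threshold_ms a response is decremental when the
#'   corrected delay increase after S2 strictly exceeds this, default 10.
#' @param max_response_delay_ms responses farther than this from their
#'   stimulus are not matched, default 300.
#' @param morphology_min_xcorr minimum normalized cross-correlation between
#'   the last two response waveforms, default 0.5.
#' @param xcorr_max_lag_ms lag search range of the correction, default 40.
#' @param origin_latency_ms adjacency window used to locate the paced
#'   chamber (the paced chamber's component intersects this window after
#'   the stimulus; conducted responses arrive later), default 60.
#' @param drive_latency_tol_ms tolerance around the drive-train
#'   stimulus-to-response latency used by the matcher, default 15.
#' @return list of class `decrement_config`.
#' @export
decrement_config <- function(decrement_threshold_ms = 10,
                             max_response_delay_ms = 300,
                             morphology_min_xcorr = 0.5,
                             xcorr_max_lag_ms = 40,
                             origin_latency_ms = 60,
                             drive_latency_tol_ms = 15) {
  stopifnot(decrement_threshold_ms > 0, max_response_delay_ms > 0,
            morphology_min_xcorr > 0, xcorr_max_lag_ms > 0)
  structure(as.list(environment()), class = "decrement_config")
}

exclusion <- function(reason, delta_t = numeric(0)) {
  structure(list(label = "excluded", exclusion_reason = reason,
                 delta_t_series = delta_t, raw_decrement_ms = NA_real_,
                 corrected_decrement_ms = NA_real_),
            class = "decrement_report")
}

#' Match each stimulus to its response
#'
#' Ties every stimulus to one response using the structure of the pacing
#' protocol. Candidate responses of stimulus i are those with onset in
#' `(stim_i, min(stim_{i+1}, stim_i + max_response_delay_ms)]`, so a
#' response can serve only one stimulus. Because the drive train conducts
#' at a constant latency, the matcher estimates that latency as the value
#' supported by the most drive beats (a candidate within
#' `drive_latency_tol_ms` counts as support) and picks, per drive beat,
#' the candidate closest to it; this makes the matching robust to isolated
#' spurious detections between far field and response. The extrastimulus
#' response may be delayed (that delay is the decrement), so the last
#' stimulus takes its first candidate at or beyond the drive latency minus
#' the tolerance.
#'
#' Clinical exclusions: fewer than two stimuli (the protocol needs a drive
#' beat plus S2) or a drive train with no common latency are uncoordinated
#' excerpts; a stimulus with no following response is an absent response
#' (which is how loss of capture after S2 manifests); one whose nearest
#' following response lies beyond the delay limit is too distant.
#'
#' @param stims consensus stimulation intervals (sorted).
#' @param responses consensus response intervals (sorted).
#' @param config a [decrement_config()].
#' @return matched pairs (`data.frame` with `stim_onset`, `resp_onset`,
#'   `resp_offset`, `delta_t`) or a `decrement_report` with the exclusion
#'   reason.
#' @export
match_stim_response <- function(stims, responses, config = decrement_config()) {
  n <- nrow(stims)
  if (n < 2) return(exclusion("uncoordinated"))
  tol <- config$drive_latency_tol_ms
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    s <- stims$onset[i]
    hi <- s + config$max_response_delay_ms
    next_s <- if (i < n) stims$onset[i + 1] else Inf
    idx <- which(responses$onset > s & responses$onset <= min(hi, next_s))
    if (!length(idx)) {
      beyond <- any(responses$onset > hi & responses$onset <= next_s)
      return(exclusion(if (beyond) "too_distant" else "no_response"))
    }
    cand[[i]] <- responses$onset[idx] - s
  }
  # drive-train latency: the candidate delay supported by most drive beats
  drive <- seq_len(n - 1)
  proposals <- sort(unique(unlist(cand[drive])))
  support <- vapply(proposals, function(v)
    sum(vapply(cand[drive], function(d) any(abs(d - v) <= tol), logical(1))),
    numeric(1))
  if (max(support) < length(drive)) return(exclusion("uncoordinated"))
  latency <- proposals[which.max(support)]
  pick <- numeric(n)
  for (i in drive) pick[i] <- cand[[i]][which.min(abs(cand[[i]] - latency))]
  late <- cand[[n]][cand[[n]] >= latency - tol]
  pick[n] <- if (length(late)) late[1] else
    cand[[n]][which.min(abs(cand[[n]] - latency))]
  resp_onset <- stims$onset + pick
  j <- match(resp_onset, responses$onset)
  data.frame(stim_onset = stims$onset, resp_onset = resp_onset,
             resp_offset = responses$offset[j], delta_t = pick)
}

#' Locate the pacing origin
#'
#' The paced chamber is the one whose component immediately follows each
#' stimulus: a local field (atrial signal in the coronary sinus) within the
#' adjacency latency means atrial pacing with far-field responses; an
#' adjacent far field (ventricular activation) means ventricular pacing
#' with local-field responses. Ambiguity (both or neither adjacent over the
#' majority of stimuli) excludes the excerpt as uncoordinated.
#'
#' @param stims consensus stimulation intervals.
#' @param lf_intervals,ff_intervals consensus LF and FF intervals.
#' @param config a [decrement_config()].
#' @return `"atrial_pacing"` or `"ventricular_pacing"`, or a
#'   `decrement_report` exclusion.
#' @export
stim_origin <- function(stims, lf_intervals, ff_intervals,
                        config = decrement_config()) {
  if (nrow(stims) == 0) return(exclusion("uncoordinated"))
  first_kind <- function(s) {
    # class of the earliest component intersecting the adjacency window
    lat <- config$origin_latency_ms
    pick <- function(resp) {
      hit <- resp$offset > s & resp$onset <= s + lat
      if (any(hit)) min(pmax(resp$onset[hit], s)) else Inf
    }
    t_lf <- pick(lf_intervals)
    t_ff <- pick(ff_intervals)
    if (t_lf == Inf && t_ff == Inf) return(NA_character_)
    if (t_lf == t_ff) return(NA_character_)
    if (t_lf < t_ff) "LF" else "FF"
  }
  votes <- vapply(stims$onset, first_kind, character(1))
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return(exclusion("uncoordinated"))
  lf_major <- mean(votes == "LF") > 0.5
  ff_major <- mean(votes == "FF") > 0.5
  if (lf_major) return("atrial_pacing")
  if (ff_major) return("ventricular_pacing")
  exclusion("uncoordinated")
}

#' Cross-correlation lag between two response waveforms
#'
#' Both waveforms are max-abs normalized and compared at integer lags in
#' `[-max_lag, +max_lag]`; the returned lag maximizes the normalized
#' cross-correlation `sum(a[t] * b[t + lag]) / (||a|| ||b||)`, so for
#' `b = a` delayed by `k` samples (zero-filled) the lag is exactly `k`. An
#' all-zero waveform yields lag 0 with peak 0.
#'
#' @param resp_a,resp_b numeric waveforms.
#' @param max_lag_ms search half-range in ms (= samples at 1000 Hz).
#' @return list with `lag_ms` and `peak` (in `[-1, 1]`).
#' @export
xcorr_lag <- function(resp_a, resp_b, max_lag_ms = 40) {
  a <- as.numeric(resp_a); b <- as.numeric(resp_b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(list(lag_ms = 0, peak = 0))
  a <- a / max(abs(a)); b <- b / max(abs(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  lags <- -max_lag_ms:max_lag_ms
  r <- vapply(lags, function(l) {
    ia <- seq_along(a)
    ib <- ia + l
    ok <- ib >= 1 & ib <= length(b)
    if (!any(ok)) return(0)
    sum(a[ok] * b[ib[ok]]) / (na * nb)
  }, numeric(1))
  best <- which.max(abs(r))
  list(lag_ms = lags[best], peak = r[best])
}

#' Classify decremental response from matched pairs
#'
#' The raw decrement is the increase of the stimulus-to-response delay at
#' the extrastimulus, `delta_t[N] - delta_t[N-1]`. Because both onsets are
#' detected (and detection jitter enters the difference), the value is
#' corrected by the lag of the highest cross-correlation between the last
#' two response waveforms after aligning each at its own detected onset;
#' a peak correlation below the morphology threshold excludes the excerpt
#' (too different response morphology). The label is decremental iff the
#' corrected decrement strictly exceeds the 10 ms threshold.
#'
#' @param pairs matched pairs from [match_stim_response()].
#' @param config a [decrement_config()].
#' @param waveforms optional list of the last two response waveforms
#'   extracted at the detected onsets: numeric vectors, or samples-x-leads
#'   matrices (then lag and peak are medians of the per-lead
#'   cross-correlations); without them the correction is 0.
#' @return a `decrement_report`.
#' @export
classify_decrement <- function(pairs, config = decrement_config(),
                               waveforms = NULL) {
  if (inherits(pairs, "decrement_report")) return(pairs)
  if (is.null(pairs) || nrow(pairs) < 2) return(exclusion("uncoordinated"))
  dt <- pairs$delta_t
  n <- length(dt)
  raw <- dt[n] - dt[n - 1]
  lag <- 0; peak <- NA_real_
  if (!is.null(waveforms) && length(waveforms) == 2) {
    w1 <- waveforms[[1]]; w2 <- waveforms[[2]]
    if (is.matrix(w1)) {
      # per-lead comparison, fused by the median: lead-averaging first
      # would let differently-jittered far-field interference decorrelate
      # two responses that every single lead sees as the same morphology
      xcs <- lapply(seq_len(ncol(w1)), function(l)
        xcorr_lag(w1[, l], w2[, l], config$xcorr_max_lag_ms))
      peak <- stats::median(vapply(xcs, `[[`, numeric(1), "peak"))
      lag <- round(stats::median(vapply(xcs, `[[`, numeric(1), "lag_ms")))
    } else {
      xc <- xcorr_lag(w1, w2, config$xcorr_max_lag_ms)
      peak <- xc$peak
      lag <- xc$lag_ms
    }
    if (abs(peak) < config$morphology_min_xcorr)
      return(exclusion("morphology_mismatch", dt))
  }
  corrected <- raw + lag
  structure(list(
    label = if (corrected > config$decrement_threshold_ms) "decremental"
            else "non_decremental",
    exclusion_reason = NULL, delta_t_series = dt,
    raw_decrement_ms = raw, corrected_decrement_ms = corrected,
    xcorr_peak = peak, xcorr_lag_ms = lag), class = "decrement_report")
}

#' @export
print.decrement_report <- function(x, ...) {
  cat("<decrement_report>", x$label)
  if (!is.null(x$exclusion_reason)) cat(" (", x$exclusion_reason, ")", sep = "")
  cat("\n")
  if (length(x$delta_t_series))
    cat("  delta_t (ms):", paste(round(x$delta_t_series, 1), collapse = ", "),
        "\n")
  if (!is.na(x$raw_decrement_ms))
    cat(sprintf("  decrement: raw %.1f ms, corrected %.1f ms\n",
                x$raw_decrement_ms, x$corrected_decrement_ms))
  invisible(x)
}

extract_response_waveform <- function(recording, onset, offset) {
  idx <- (onset + 1):offset
  idx <- idx[idx >= 1 & idx <= nrow(recording$signals)]
  recording$signals[idx, , drop = FALSE]   # samples x leads
}

#' Run the full decrement quantification pipeline
#'
#' Chains the five pipeline stages on a multi-lead recording: QRS windowing
#' (using the recording's barycenters, external fiducials, or the built-in
#' surface detector), per-lead per-window prediction (or ground-truth
#' oracle intervals), binarization and interval extraction, pacing-spike
#' cleanup, across-lead majority voting, pacing-origin location,
#' stimulus-response matching and decrement classification. Any stage may
#' abort with a typed exclusion, which is reported rather than raised.
#'
#' @param recording an `egm_recording` (or compatible list with `signals`,
#'   `fs`, and fiducials).
#' @param model a fitted `egm_segmenter`, or `NULL` when `use_oracle`.
#' @param use_oracle use the recording's ground-truth per-lead intervals
#'   instead of model predictions.
#' @param config a [decrement_config()].
#' @param vote_tolerance_ms,vote_min_leads majority-voting parameters.
#' @param threshold binarization threshold for model predictions.
#' @return a `decrement_report`; intermediate artifacts (consensus interval
#'   tables, pacing origin, matched pairs) are attached as attribute
#'   `"stages"` for audit.
#' @export
run_decrement_pipeline <- function(recording, model = NULL,
                                   use_oracle = FALSE,
                                   config = decrement_config(),
                                   vote_tolerance_ms = 20,
                                   vote_min_leads = 3, threshold = 0.5) {
  n_leads <- ncol(recording$signals)
  total <- nrow(recording$signals)
  if (use_oracle) {
    per_lead <- recording$oracle_intervals
  } else {
    if (is.null(model)) stop("supply a fitted model or set use_oracle = TRUE")
    bary <- recording$qrs_barycenters
    if (is.null(bary) || length(bary) == 0)
      bary <- detect_qrs(recording$surface, recording$fs)
    windows <- window_by_qrs(recording$signals, bary,
                             window_len = model$window_len)
    # batch all lead-windows through the network at once
    xs <- do.call(rbind, lapply(windows, function(w) t(w$data)))
    probs <- net_predict(model$net, prepare_windows(model, xs))
    per_lead <- vector("list", n_leads)
    k <- 0
    acc <- rep(list(list()), n_leads)
    for (w in windows) {
      for (lead in seq_len(n_leads)) {
        k <- k + 1
        ints <- mask_to_intervals(binarize(probs[[k]], threshold), lead = lead)
        # discard detections inside the zero padding, then map to the
        # recording frame
        ints <- clip_intervals(ints, w$pad_left,
                               model$window_len - w$pad_right)
        ints <- shift_intervals(ints, w$offset)
        acc[[lead]] <- c(acc[[lead]], list(ints))
      }
    }
    per_lead <- lapply(seq_len(n_leads), function(lead) {
      df <- do.call(rbind, acc[[lead]])
      if (is.null(df) || nrow(df) == 0) return(egm_intervals(frame = total))
      df$lead <- lead
      clean_pacing_spikes(canonicalize_intervals(as_egm_intervals(df, total)))
    })
  }
  consensus <- lapply(MASK_CHANNELS, function(k)
    vote_across_leads(per_lead, k, vote_tolerance_ms, vote_min_leads))
  names(consensus) <- MASK_CHANNELS
  stages <- list(per_lead = per_lead, consensus = consensus)
  origin <- stim_origin(consensus$STIM, consensus$LF, consensus$FF, config)
  if (inherits(origin, "decrement_report"))
    return(structure_stages(origin, stages))
  stages$origin <- origin
  responses <- if (origin == "ventricular_pacing") consensus$LF else consensus$FF
  if (origin == "ventricular_pacing") {
    # short local-field detections fully contained in a far-field interval
    # are high-frequency content of the ventricular far field, not the
    # atrial response (the containment rule the evaluation metrics apply to
    # LF false positives, restricted to late-potential-length detections:
    # a genuine response can legitimately overlap a long far field)
    ff <- consensus$FF
    contained <- vapply(seq_len(nrow(responses)), function(i)
      any(ff$onset <= responses$onset[i] & responses$offset[i] <= ff$offset),
      logical(1))
    short <- responses$offset - responses$onset < 25
    responses <- as_egm_intervals(
      responses[!(contained & short), , drop = FALSE],
      attr(responses, "frame"))
    stages$responses <- responses
  }
  pairs <- match_stim_response(consensus$STIM, responses, config)
  if (inherits(pairs, "decrement_report"))
    return(structure_stages(pairs, stages))
  stages$pairs <- pairs
  n <- nrow(pairs)
  waveforms <- lapply(c(n - 1, n), function(i)
    extract_response_waveform(recording, pairs$resp_onset[i],
                              pairs$resp_offset[i]))
  report <- classify_decrement(pairs, config, waveforms)
  structure_stages(report, stages)
}

structure_stages <- function(report, stages) {
  attr(report, "stages") <- stages
  report
}
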