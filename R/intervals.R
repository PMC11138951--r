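#' Typed onset/offset interval sets
#'
#' Delineation results and ground truth are exchanged as interval tables:
#' data frames with columns `kind` (one of `STIM`, `LF`, `FF`), `onset`,
#' `offset` and optionally `lead`. Coordinates are 0-based, half-open
#' `[onset, offset)` sample indices at 1000 Hz, so sample counts and
#' milliseconds coincide numerically.
#'
#' @param kind character vector of channel kinds.
#' @param onset,offset integer sample coordinates, `0 <= onset < offset <= frame`.
#' @param lead optional lead identifier.
#' @param frame window length the coordinates live in (samples), or `NA`.
#' @return a data.frame of class `egm_intervals`, sorted by kind then onset,
#'   with attribute `frame`.
#' @export
egm_intervals <- function(kind = character(0), onset = integer(0),
                          offset = integer(0), lead = NA, frame = NA_real_) {
  df <- data.frame(kind = as.character(kind), onset = as.numeric(onset),
                   offset = as.numeric(offset),
                   lead = rep(lead, length.out = length(kind)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$onset < 0) || any(df$offset <= df$onset))
      stop("intervals must satisfy 0 <= onset < offset (half-open convention)")
    if (!is.na(frame) && any(df$offset > frame))
      stop("interval offset exceeds the frame length")
    df <- df[order(df$kind, df$onset, df$offset), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, frame = frame, class = c("egm_intervals", "data.frame"))
}

as_egm_intervals <- function(df, frame = NA_real_) {
  if (is.null(df$lead)) df$lead <- rep(NA, nrow(df))
  egm_intervals(df$kind, df$onset, df$offset, df$lead, frame)
}

#' Render an interval set as a 3xN binary mask
#'
#' Channel order is stimulation / local field / far field (rows 1-3).
#'
#' @param intervals an interval table (`kind`, `onset`, `offset`).
#' @param n frame length in samples.
#' @return 3xN integer matrix with rownames `STIM`, `LF`, `FF`.
#' @export
intervals_to_mask <- function(intervals, n) {
  mask <- matrix(0L, 3, n, dimnames = list(MASK_CHANNELS, NULL))
  for (i in seq_len(nrow(intervals))) {
    ch <- match(intervals$kind[i], MASK_CHANNELS)
    if (is.na(ch)) stop("unknown interval kind: ", intervals$kind[i])
    a <- max(0, intervals$onset[i]); b <- min(n, intervals$offset[i])
    if (b > a) mask[ch, (a + 1):b] <- 1L
  }
  mask
}

#' Merge overlapping or touching intervals of the same kind and lead
#'
#' Canonical form used by the generator and pipeline: within each
#' (kind, lead) group, intervals whose supports overlap or touch are fused
#' into one, so that the interval table and its rendered mask are in
#' bijection (every mask run corresponds to exactly one interval).
#'
#' @param intervals interval table.
#' @param frame frame length carried through.
#' @return canonicalized `egm_intervals`.
#' @export
canonicalize_intervals <- function(intervals, frame = attr(intervals, "frame")) {
  if (nrow(intervals) == 0) return(as_egm_intervals(intervals, frame))
  groups <- split(seq_len(nrow(intervals)),
                  paste(intervals$kind, intervals$lead, sep = "\r"))
  out <- list()
  for (idx in groups) {
    g <- intervals[idx, , drop = FALSE]
    g <- g[order(g$onset, g$offset), , drop = FALSE]
    merged <- g[1, , drop = FALSE]
    for (i in seq_len(nrow(g))[-1]) {
      last <- nrow(merged)
      if (g$onset[i] <= merged$offset[last]) {
        merged$offset[last] <- max(merged$offset[last], g$offset[i])
      } else {
        merged <- rbind(merged, g[i, , drop = FALSE])
      }
    }
    out <- c(out, list(merged))
  }
  as_egm_intervals(do.call(rbind, out), frame)
}

shift_intervals <- function(intervals, by) {
  intervals$onset <- intervals$onset + by
  intervals$offset <- intervals$offset + by
  intervals
}

clip_intervals <- function(intervals, lo, hi) {
  intervals$onset <- pmax(intervals$onset, lo)
  intervals$offset <- pmin(intervals$offset, hi)
  intervals[intervals$offset > intervals$onset, , drop = FALSE]
}
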