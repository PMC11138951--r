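interval_overlap <- function(a_on, a_off, b_on, b_off) {
  pmax(0, pmin(a_off, b_off) - pmax(a_on, b_on))
}

# exact maximum matching on one connected component of the bipartite
# overlap graph: maximize (number of matched pairs, total overlap), ties
# resolved toward lexicographically earliest ground-truth assignment.
solve_component <- function(ov) {
  np <- nrow(ov); ng <- ncol(ov)
  best <- list(count = -1, overlap = -Inf, assign = rep(NA_integer_, np))
  assign <- rep(NA_integer_, np)
  used <- rep(FALSE, ng)
  recurse <- function(p, count, overlap) {
    if (count + (np - p + 1) < best$count) return(invisible())  # bound
    if (p > np) {
      better <- count > best$count ||
        (count == best$count && overlap > best$overlap + 1e-12) ||
        (count == best$count && abs(overlap - best$overlap) <= 1e-12 &&
           lex_less(assign, best$assign))
      if (better) best <<- list(count = count, overlap = overlap,
                                assign = assign)
      return(invisible())
    }
    for (g in seq_len(ng)) {
      if (!used[g] && ov[p, g] > 0) {
        used[g] <<- TRUE; assign[p] <<- g
        recurse(p + 1, count + 1, overlap + ov[p, g])
        used[g] <<- FALSE; assign[p] <<- NA_integer_
      }
    }
    recurse(p + 1, count, overlap)
  }
  recurse(1, 0, 0)
  best$assign
}

lex_less <- function(a, b) {
  a[is.na(a)] <- Inf; b[is.na(b)] <- Inf
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

greedy_match <- function(ov) {
  # fallback for very large components: repeatedly take the largest overlap
  assign <- rep(NA_integer_, nrow(ov))
  repeat {
    m <- which(ov == max(ov), arr.ind = TRUE)
    if (max(ov) <= 0) break
    m <- m[order(m[, 2]), , drop = FALSE][1, ]
    assign[m[1]] <- m[2]
    ov[m[1], ] <- 0; ov[, m[2]] <- 0
  }
  assign
}

#' Match predicted against reference detections
#'
#' Detection metrics count localized matches: a predicted interval counts
#' as a true positive when it can be paired one-to-one with a reference
#' interval it overlaps in time (any overlap qualifies). The pairing is the
#' optimal assignment maximizing first the number of matched pairs, then
#' the total overlap (computed exactly per connected component of the
#' overlap graph). Unmatched predictions are false positives; unmatched
#' references false negatives.
#'
#' @param pred,gt interval tables.
#' @param kind component kind to evaluate.
#' @return list with `tp` (data.frame of pairs with onsets/offsets of both
#'   sides and the overlap), `fp` and `fn` (interval subsets), and counts.
#' @export
match_detections <- function(pred, gt, kind) {
  p <- pred[pred$kind == kind, , drop = FALSE]
  g <- gt[gt$kind == kind, , drop = FALSE]
  p <- p[order(p$onset, p$offset), , drop = FALSE]
  g <- g[order(g$onset, g$offset), , drop = FALSE]
  np <- nrow(p); ng <- nrow(g)
  assign <- rep(NA_integer_, np)
  if (np > 0 && ng > 0) {
    ov <- outer(seq_len(np), seq_len(ng), function(i, j)
      interval_overlap(p$onset[i], p$offset[i], g$onset[j], g$offset[j]))
    # connected components of the bipartite overlap graph
    pcomp <- rep(NA_integer_, np); gcomp <- rep(NA_integer_, ng); nc <- 0
    for (i in seq_len(np)) {
      if (!is.na(pcomp[i])) next
      nc <- nc + 1
      queue <- i
      while (length(queue)) {
        pi <- queue[1]; queue <- queue[-1]
        if (!is.na(pcomp[pi])) next
        pcomp[pi] <- nc
        gs <- which(ov[pi, ] > 0 & is.na(gcomp))
        gcomp[gs] <- nc
        for (gj in gs) queue <- c(queue, which(ov[, gj] > 0 & is.na(pcomp)))
      }
    }
    for (comp in seq_len(nc)) {
      pi <- which(pcomp == comp); gi <- which(gcomp == comp)
      if (!length(gi)) next
      sub <- ov[pi, gi, drop = FALSE]
      sol <- if (length(pi) <= 8) solve_component(sub) else greedy_match(sub)
      assign[pi] <- gi[sol]
    }
  }
  tp_idx <- which(!is.na(assign))
  tp <- if (length(tp_idx)) data.frame(
    pred_onset = p$onset[tp_idx], pred_offset = p$offset[tp_idx],
    gt_onset = g$onset[assign[tp_idx]], gt_offset = g$offset[assign[tp_idx]],
    overlap = interval_overlap(p$onset[tp_idx], p$offset[tp_idx],
                               g$onset[assign[tp_idx]],
                               g$offset[assign[tp_idx]])) else
    data.frame(pred_onset = numeric(0), pred_offset = numeric(0),
               gt_onset = numeric(0), gt_offset = numeric(0),
               overlap = numeric(0))
  list(tp = tp,
       fp = p[is.na(assign), , drop = FALSE],
       fn = g[setdiff(seq_len(ng), assign[tp_idx]), , drop = FALSE],
       counts = c(TP = length(tp_idx), FP = np - length(tp_idx),
                  FN = ng - length(tp_idx)))
}

#' Discard local-field false positives inside far-field references
#'
#' Small local-field detections frequently fall within annotated far-field
#' activations (high-frequency content riding on the ventricular far
#' field); these are removed from the false-positive pool (they are not
#' converted to true positives). Containment is full containment within a
#' reference far-field interval. Filtering can only raise precision and
#' leaves recall untouched.
#'
#' @param fp_list data.frame of LF false positives.
#' @param ff_gt reference far-field intervals.
#' @return the reduced false-positive data.frame.
#' @export
filter_lf_within_ff <- function(fp_list, ff_gt) {
  ff <- ff_gt[ff_gt$kind == "FF", , drop = FALSE]
  if (nrow(fp_list) == 0 || nrow(ff) == 0) return(fp_list)
  contained <- vapply(seq_len(nrow(fp_list)), function(i)
    any(ff$onset <= fp_list$onset[i] & fp_list$offset[i] <= ff$offset),
    logical(1))
  fp_list[!contained, , drop = FALSE]
}

#' Onset and offset delineation errors of matched pairs
#'
#' Errors are `predicted - reference` in ms (positive = late). Standard
#' deviations use the population (n) convention. Empty input yields `NA`
#' summaries, never zeros.
#'
#' @param tp_pairs the `tp` data.frame from [match_detections()].
#' @return list with `onset_errors`, `offset_errors` and the `summary`
#'   named vector (means and SDs).
#' @export
delineation_errors <- function(tp_pairs) {
  pop_sd <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
  on_err <- tp_pairs$pred_onset - tp_pairs$gt_onset
  off_err <- tp_pairs$pred_offset - tp_pairs$gt_offset
  if (!nrow(tp_pairs)) { on_err <- numeric(0); off_err <- numeric(0) }
  list(onset_errors = on_err, offset_errors = off_err,
       summary = c(onset_mean = if (length(on_err)) mean(on_err) else NA_real_,
                   onset_sd = pop_sd(on_err),
                   offset_mean = if (length(off_err)) mean(off_err) else NA_real_,
                   offset_sd = pop_sd(off_err)))
}

#' Per-channel hard Dice between two binary masks
#'
#' `2|A n B| / (|A| + |B|)` per channel, in percent; a channel empty on
#' both sides scores 100 by convention.
#'
#' @param pred_mask,gt_mask binary matrices of equal shape (channels in
#'   rows).
#' @return named numeric vector of Dice percentages.
#' @export
sample_dice <- function(pred_mask, gt_mask) {
  stopifnot(all(dim(pred_mask) == dim(gt_mask)))
  out <- vapply(seq_len(nrow(pred_mask)), function(ch) {
    a <- pred_mask[ch, ] != 0; b <- gt_mask[ch, ] != 0
    denom <- sum(a) + sum(b)
    if (denom == 0) return(100)
    200 * sum(a & b) / denom
  }, numeric(1))
  names(out) <- rownames(pred_mask)
  if (is.null(rownames(pred_mask)) && nrow(pred_mask) == 3)
    names(out) <- MASK_CHANNELS
  out
}

merge_lf_ff <- function(intervals) {
  m <- intervals[intervals$kind %in% c("LF", "FF"), , drop = FALSE]
  if (nrow(m)) m$kind <- "LFFF"
  canonicalize_intervals(as_egm_intervals(m, attr(intervals, "frame")))
}

metrics_row <- function(md, kind) {
  cnt <- md$counts
  err <- delineation_errors(md$tp)$summary
  data.frame(kind = kind, TP = cnt[["TP"]], FP = cnt[["FP"]], FN = cnt[["FN"]],
             precision = if (cnt[["TP"]] + cnt[["FP"]] > 0)
               100 * cnt[["TP"]] / (cnt[["TP"]] + cnt[["FP"]]) else NA_real_,
             recall = if (cnt[["TP"]] + cnt[["FN"]] > 0)
               100 * cnt[["TP"]] / (cnt[["TP"]] + cnt[["FN"]]) else NA_real_,
             onset_mean = err[["onset_mean"]], onset_sd = err[["onset_sd"]],
             offset_mean = err[["offset_mean"]], offset_sd = err[["offset_sd"]])
}

#' Detection and delineation metrics report
#'
#' Computes per-kind precision, recall, Dice, and onset/offset error
#' statistics between a predicted and a reference interval table, in three
#' variants: `raw` (as matched), `filtered` (LF false positives fully
#' contained in reference far fields discarded) and `merged` (LF and FF
#' pooled into one class by OR-ing their masks, which absorbs
#' LF-versus-FF labeling ambiguity).
#'
#' @param pred,gt interval tables sharing a frame.
#' @param frame frame length in samples (for mask-based Dice); taken from
#'   the tables when missing.
#' @param variant one or more of `"raw"`, `"filtered"`, `"merged"`.
#' @return object of class `egm_metrics`: a data.frame with one row per
#'   kind and variant.
#' @export
delineation_metrics <- function(pred, gt, frame = NULL,
                                variant = c("raw", "filtered", "merged")) {
  variant <- match.arg(variant, several.ok = TRUE)
  if (is.null(frame)) frame <- attr(gt, "frame")
  if (is.null(frame) || is.na(frame))
    frame <- max(pred$offset, gt$offset, 0)
  pm <- intervals_to_mask(pred[pred$kind %in% MASK_CHANNELS, , drop = FALSE],
                          frame)
  gm <- intervals_to_mask(gt[gt$kind %in% MASK_CHANNELS, , drop = FALSE],
                          frame)
  dice <- sample_dice(pm, gm)
  rows <- list()
  if ("raw" %in% variant || "filtered" %in% variant) {
    mds <- lapply(MASK_CHANNELS, function(k) match_detections(pred, gt, k))
    names(mds) <- MASK_CHANNELS
    if ("raw" %in% variant) {
      for (k in MASK_CHANNELS) {
        r <- metrics_row(mds[[k]], k)
        r$dice <- dice[[k]]; r$variant <- "raw"
        rows <- c(rows, list(r))
      }
    }
    if ("filtered" %in% variant) {
      md <- mds$LF
      kept_fp <- filter_lf_within_ff(md$fp, gt)
      md$counts[["FP"]] <- nrow(kept_fp)
      md$fp <- kept_fp
      r <- metrics_row(md, "LF")
      r$dice <- dice[["LF"]]; r$variant <- "filtered"
      rows <- c(rows, list(r))
    }
  }
  if ("merged" %in% variant) {
    mp <- merge_lf_ff(pred); mg <- merge_lf_ff(gt)
    md <- match_detections(mp, mg, "LFFF")
    r <- metrics_row(md, "LF+FF")
    pm2 <- matrix(pmin(pm[2, ] + pm[3, ], 1), 1)
    gm2 <- matrix(pmin(gm[2, ] + gm[3, ], 1), 1)
    r$dice <- unname(sample_dice(pm2, gm2)); r$variant <- "merged"
    rows <- c(rows, list(r))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out[, c("variant", "kind", "TP", "FP", "FN", "precision",
                    "recall", "dice", "onset_mean", "onset_sd",
                    "offset_mean", "offset_sd")],
            class = c("egm_metrics", "data.frame"))
}

#' @export
print.egm_metrics <- function(x, digits = 2, ...) {
  cat("Detection / delineation metrics\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
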