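brute_force_match <- function(pred, gt, kind) {
  # independent oracle: enumerate every one-to-one assignment over the whole
  # instance and keep the one maximizing (pair count, total overlap)
  p <- pred[pred$kind == kind, , drop = FALSE]
  p <- p[order(p$onset, p$offset), , drop = FALSE]
  g <- gt[gt$kind == kind, , drop = FALSE]
  g <- g[order(g$onset, g$offset), , drop = FALSE]
  np <- nrow(p); ng <- nrow(g)
  best <- list(count = -1, overlap = -Inf)
  explore <- function(i, used, count, overlap) {
    if (i > np) {
      if (count > best$count ||
          (count == best$count && overlap > best$overlap + 1e-12))
        best <<- list(count = count, overlap = overlap)
      return(invisible())
    }
    explore(i + 1, used, count, overlap)
    for (j in seq_len(ng)) {
      ov <- min(p$offset[i], g$offset[j]) - max(p$onset[i], g$onset[j])
      if (!used[j] && ov > 0) {
        used[j] <- TRUE
        explore(i + 1, used, count + 1, overlap + ov)
        used[j] <- FALSE
      }
    }
  }
  explore(1, rep(FALSE, ng), 0, 0)
  best
}

random_instance <- function(max_n = 6, frame = 300) {
  mk <- function(n) {
    onset <- sort(sample(0:(frame - 45), n))
    iv(rep("LF", n), onset, onset + sample(5:40, n, replace = TRUE),
       frame = frame)
  }
  list(pred = mk(sample(0:max_n, 1) + 1), gt = mk(sample(0:max_n, 1) + 1))
}
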