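# Shared fixtures, built in code. Pools are small but exercise every kind.
local_pools <- local({
  pools <- NULL
  function() {
    if (is.null(pools)) {
      set.seed(424242)
      pools <<- build_segment_pools(c(STIM = 6, LF = 12, LP = 8, FF = 12,
                                      REST = 12))
    }
    pools
  }
})

make_mask <- function(n, stim = NULL, lf = NULL, ff = NULL) {
  # each of stim/lf/ff: list of c(onset, offset) half-open 0-based pairs
  m <- matrix(0L, 3, n)
  fill <- function(ch, iv) for (p in iv) m[ch, (p[1] + 1):p[2]] <<- 1L
  if (!is.null(stim)) fill(1, stim)
  if (!is.null(lf)) fill(2, lf)
  if (!is.null(ff)) fill(3, ff)
  m
}

iv <- function(kind = character(0), onset = numeric(0), offset = numeric(0),
               lead = NA, frame = NA_real_)
  egm_intervals(kind, onset, offset, lead, frame)
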