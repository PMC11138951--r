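#' Conditional log-normal amplitude model
#'
#' The voltage of far-field and rest segments depends strongly on the
#' amplitude of the local field of the same cardiac cycle: small local fields
#' come with relatively larger far fields. The model therefore splits the
#' local-field amplitude into 10 bins over the \[0,100\]% amplitude interval
#' (increments of 10%) and fits, per bin, one log-normal distribution to the
#' amplitude ratios `amplitude_segment / amplitude_LF` of the accompanying
#' far-field and rest segments. Local-field and late-potential amplitudes are
#' fitted unconditionally with log-normals of their own.
#'
#' @name amplitude_model
NULL

fit_lognormal <- function(x, clip = 1e-9) {
  # closed-form maximum likelihood on log-transformed values
  lx <- log(pmax(x, clip))
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  c(meanlog = mu, sdlog = max(sigma, 1e-6))
}

#' Map a local-field amplitude percentage to its bin
#'
#' @param pct amplitude as percentage of the reference range, in \[0, 100\].
#' @param n_bins number of bins, default 10.
#' @return integer bin index in `1..n_bins` (the last bin is closed above).
#' @export
amplitude_bin <- function(pct, n_bins = 10) {
  pmin(pmax(floor(pct / (100 / n_bins)), 0) + 1L, n_bins)
}

#' Fit the amplitude model
#'
#' @param cycles list of cycle observations; each element is a list with
#'   `lf_amplitude` (native mV of the cycle's local field), `ff_amplitudes`
#'   and `rest_amplitudes` (native mV of accompanying segments; may be
#'   empty).
#' @param lf_amps numeric vector of local-field native amplitudes (mV).
#' @param lp_amps numeric vector of late-potential native amplitudes (mV).
#' @param n_bins number of local-field amplitude bins, default 10.
#' @param lf_ref normalizer for the \[0,100\]% amplitude interval; defaults
#'   to the maximum local-field amplitude seen during fitting.
#' @details Bins with fewer than 3 observations inherit the parameters of the
#'   nearest populated bin so that small pools never break fitting. If no
#'   late-potential amplitudes are given they inherit the local-field fit.
#' @return an object of class `amplitude_model` with elements `lf_params`,
#'   `lp_params`, `ff_bins` and `rest_bins` (n_bins x 2 matrices of
#'   `meanlog`/`sdlog`), `bin_edges` and `lf_ref`.
#' @export
fit_amplitude_model <- function(cycles, lf_amps, lp_amps = numeric(0),
                                n_bins = 10, lf_ref = NULL) {
  all_lf <- c(lf_amps, vapply(cycles, function(cy) cy$lf_amplitude, numeric(1)))
  if (length(all_lf) == 0 && length(lp_amps) == 0)
    stop("cannot fit an amplitude model without any observations")
  if (is.null(lf_ref)) lf_ref <- max(all_lf)
  ff_obs <- vector("list", n_bins)
  rest_obs <- vector("list", n_bins)
  for (cy in cycles) {
    pct <- 100 * cy$lf_amplitude / lf_ref
    b <- amplitude_bin(pct, n_bins)
    if (length(cy$ff_amplitudes))
      ff_obs[[b]] <- c(ff_obs[[b]], cy$ff_amplitudes / cy$lf_amplitude)
    if (length(cy$rest_amplitudes))
      rest_obs[[b]] <- c(rest_obs[[b]], cy$rest_amplitudes / cy$lf_amplitude)
  }
  fit_bins <- function(obs) {
    pars <- matrix(NA_real_, n_bins, 2,
                   dimnames = list(NULL, c("meanlog", "sdlog")))
    populated <- which(vapply(obs, function(x) length(x) >= 3, logical(1)))
    if (length(populated) == 0)
      stop("no bin holds enough observations (need >= 3 in at least one bin)")
    for (b in populated) pars[b, ] <- fit_lognormal(obs[[b]])
    for (b in setdiff(seq_len(n_bins), populated)) {
      nearest <- populated[which.min(abs(populated - b))]
      pars[b, ] <- pars[nearest, ]
    }
    pars
  }
  lf_params <- if (length(lf_amps)) fit_lognormal(lf_amps) else
    fit_lognormal(vapply(cycles, function(cy) cy$lf_amplitude, numeric(1)))
  lp_params <- if (length(lp_amps)) fit_lognormal(lp_amps) else lf_params
  structure(list(lf_params = lf_params, lp_params = lp_params,
                 ff_bins = fit_bins(ff_obs), rest_bins = fit_bins(rest_obs),
                 bin_edges = seq(0, 100, length.out = n_bins + 1),
                 lf_ref = lf_ref, n_bins = n_bins),
            class = "amplitude_model")
}

#' @export
print.amplitude_model <- function(x, ...) {
  cat("<amplitude_model>\n")
  cat(sprintf("  LF:  log-normal(meanlog=%.3f, sdlog=%.3f)\n",
              x$lf_params[1], x$lf_params[2]))
  cat(sprintf("  LP:  log-normal(meanlog=%.3f, sdlog=%.3f)\n",
              x$lp_params[1], x$lp_params[2]))
  cat(sprintf("  FF/rest ratios: %d bins over [0,100]%% of LF range (ref %.3g mV)\n",
              x$n_bins, x$lf_ref))
  invisible(x)
}

#' Draw one amplitude from the model
#'
#' For `LF` and `LP` the draw is an absolute amplitude in mV; for `FF` and
#' `REST` it is a ratio relative to the cycle's local-field amplitude, drawn
#' from the bin selected by `lf_amplitude_pct`.
#'
#' @param model an `amplitude_model`.
#' @param kind one of `LF`, `LP`, `FF`, `REST`.
#' @param lf_amplitude_pct local-field amplitude as a percentage of the
#'   model's reference range; required for `FF`/`REST`, ignored otherwise.
#' @return a strictly positive draw (deterministic given the RNG state).
#' @export
sample_amplitude <- function(model, kind, lf_amplitude_pct = NULL) {
  stopifnot(inherits(model, "amplitude_model"))
  kind <- match.arg(kind, c("LF", "LP", "FF", "REST"))
  pars <- switch(kind,
    LF = model$lf_params,
    LP = model$lp_params,
    FF = , REST = {
      if (is.null(lf_amplitude_pct))
        stop(kind, " amplitudes are conditional on the LF amplitude; ",
             "supply lf_amplitude_pct")
      bins <- if (kind == "FF") model$ff_bins else model$rest_bins
      bins[amplitude_bin(lf_amplitude_pct, model$n_bins), ]
    })
  stats::rlnorm(1, meanlog = pars[1], sdlog = pars[2])
}

#' Reference amplitude model used by the synthetic generator
#'
#' A parametric stand-in for a model fitted on annotated clinical data (which
#' is not distributable). Local fields follow a log-normal around 1.5 mV and
#' late potentials around 0.45 mV; far-field and rest relative amplitudes
#' decrease across the 10 local-field amplitude bins, emulating the inverse
#' dependence seen in bipolar coronary-sinus recordings (relatively larger
#' far fields when the local field is small).
#'
#' @param n_bins number of conditional bins, default 10.
#' @return an `amplitude_model`.
#' @export
default_amplitude_model <- function(n_bins = 10) {
  mk <- function(mus, sd) cbind(meanlog = mus, sdlog = rep(sd, n_bins))
  structure(list(
    lf_params = c(meanlog = log(1.5), sdlog = 0.5),
    lp_params = c(meanlog = log(0.45), sdlog = 0.5),
    ff_bins = mk(log(seq(1.6, 0.25, length.out = n_bins)), 0.4),
    rest_bins = mk(log(seq(0.08, 0.015, length.out = n_bins)), 0.4),
    bin_edges = seq(0, 100, length.out = n_bins + 1),
    lf_ref = 5, n_bins = n_bins), class = "amplitude_model")
}
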