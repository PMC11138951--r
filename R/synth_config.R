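#' Synthetic-trace generator configuration
#'
#' All probabilities and ranges of the rule-based trace generator. The
#' generator works in two stages: per-registry rules (conditions shared by
#' all three composed cardiac cycles of a trace) and per-cycle rules (which
#' segments are drawn, where they are placed and at what amplitude).
#'
#' Defaults define the generator's study conditions: a registry contains
#' stimulation artifacts with probability 0.3 and shares one morphology
#' across its cycles with probability 0.5; cycle length is uniform in
#' 400-1000 ms; 10-50% of the flanking cycles are preserved around the
#' central one; local and far fields are each present with probability 0.9
#' (their absence emulates, e.g., AV block); the number of extra late
#' potentials is Poisson(0.3); every placed segment has a 0.5 chance of
#' being resampled to 75-125% of its length and a 0.3 chance of being mixed
#' up with a pool mate (Mixup coefficient from Beta(0.2, 0.2)); with
#' probability 0.1 the far field is merged into the local-field label.
#' Additive white noise has a relative sigma uniform in 0.01-0.1 of the
#' central-cycle peak and the sinusoidal baseline wander stays below 1 Hz.
#'
#' @param p_stim probability that a registry contains stimulation artifacts.
#' @param p_same_morphology probability that all cycles share segments.
#' @param rr_range_ms cycle length range (ms).
#' @param keep_range_pct range of the flanking-cycle percentage preserved.
#' @param noise_sigma_range relative white-noise sigma range.
#' @param wander_amp_range relative baseline-wander amplitude range.
#' @param wander_freq_range baseline-wander frequency range (Hz, < 1).
#' @param p_lf,p_ff per-cycle presence probabilities of LF and FF.
#' @param lp_rate Poisson mean of the per-cycle late-potential count.
#' @param p_resample chance a placement is length-resampled (75-125%).
#' @param p_mixup chance a placement is mixed up with another pool segment.
#' @param mixup_beta shape parameters of the Beta distribution of the Mixup
#'   coefficient.
#' @param p_merge_ff_lf chance the far field is labeled as local field
#'   (fused components).
#' @param stim_lognormal meanlog/sdlog of the stimulation-artifact amplitude
#'   (mV); stimulation spikes dwarf the physiological components.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(p_stim = 0.3, p_same_morphology = 0.5,
                         rr_range_ms = c(400, 1000),
                         keep_range_pct = c(10, 50),
                         noise_sigma_range = c(0.01, 0.1),
                         wander_amp_range = c(0, 0.3),
                         wander_freq_range = c(0.1, 0.8),
                         p_lf = 0.9, p_ff = 0.9, lp_rate = 0.3,
                         p_resample = 0.5, p_mixup = 0.3,
                         mixup_beta = c(0.2, 0.2), p_merge_ff_lf = 0.1,
                         stim_lognormal = c(meanlog = log(4), sdlog = 0.3)) {
  structure(as.list(environment()), class = "synth_config")
}

#' Draw registry-wide generation rules
#'
#' Registry rules hold for all three cardiac cycles of one synthetic trace:
#' whether the registry is stimulated, whether cycles share one morphology,
#' the cycle length, how much of the flanking cycles survives the final
#' crop, and the noise/wander levels.
#'
#' @param config a [synth_config()].
#' @return list of class `registry_rules`. Deterministic given RNG state.
#' @export
draw_registry_rules <- function(config = synth_config()) {
  structure(list(
    has_stimulation = stats::runif(1) < config$p_stim,
    same_morphology = stats::runif(1) < config$p_same_morphology,
    rr_ms = runif1(config$rr_range_ms),
    left_keep_pct = runif1(config$keep_range_pct),
    right_keep_pct = runif1(config$keep_range_pct),
    noise_sigma = runif1(config$noise_sigma_range),
    wander_amp = runif1(config$wander_amp_range),
    wander_freq = runif1(config$wander_freq_range)
  ), class = "registry_rules")
}

draw_placement <- function(kind, pool_index, amplitude, pools, config) {
  list(kind = kind, pool_index = pool_index, amplitude = amplitude,
       position_pct = stats::runif(1, 0, 100),
       resample_factor = if (stats::runif(1) < config$p_resample)
         stats::runif(1, 0.75, 1.25) else 1,
       mixup_partner = if (stats::runif(1) < config$p_mixup &&
                           length(pools[[kind]]) > 1)
         sample(setdiff(seq_along(pools[[kind]]), pool_index), 1) else NA,
       mixup_lambda = stats::rbeta(1, config$mixup_beta[1], config$mixup_beta[2]))
}

draw_rest_plan <- function(pools, amp_model, lf_pct, lf_amp, rr_samples) {
  idx <- integer(0); amps <- numeric(0); total <- 0
  while (total < rr_samples) {
    i <- sample(length(pools$REST), 1)
    idx <- c(idx, i)
    amps <- c(amps, lf_amp * sample_amplitude(amp_model, "REST", lf_pct))
    total <- total + length(pools$REST[[i]]$samples)
  }
  list(indices = idx, amplitudes = amps)
}

#' Draw the per-cycle rules of one trace
#'
#' Generates rules for the left, central and right cardiac cycles: which
#' pool segments are placed, where, at what amplitude, and whether they are
#' resampled or mixed up. If the registry shares one morphology, all three
#' cycles reference the same pool segments and positions while amplitudes
#' are redrawn per cycle. Far-field and rest amplitudes are drawn
#' conditional on the cycle's local-field amplitude bin.
#'
#' @param registry a `registry_rules`.
#' @param pools a `segment_pools`.
#' @param amp_model an `amplitude_model`.
#' @param config a [synth_config()].
#' @return list of three `cycle_rules`.
#' @export
draw_cycle_rules <- function(registry, pools, amp_model,
                             config = synth_config()) {
  rr_samples <- round(registry$rr_ms)
  need <- function(kind) {
    if (length(pools[[kind]]) == 0) stop("segment pool for ", kind, " is empty")
  }
  draw_one <- function() {
    lf_amp <- sample_amplitude(amp_model, "LF")
    lf_pct <- min(100, 100 * lf_amp / amp_model$lf_ref)
    placements <- list()
    if (stats::runif(1) < config$p_lf) {
      need("LF")
      placements <- c(placements, list(draw_placement(
        "LF", sample(length(pools$LF), 1), lf_amp, pools, config)))
    }
    if (stats::runif(1) < config$p_ff) {
      need("FF")
      ff_amp <- lf_amp * sample_amplitude(amp_model, "FF", lf_pct)
      placements <- c(placements, list(draw_placement(
        "FF", sample(length(pools$FF), 1), ff_amp, pools, config)))
    }
    n_lp <- stats::rpois(1, config$lp_rate)
    for (i in seq_len(n_lp)) {
      need("LP")
      placements <- c(placements, list(draw_placement(
        "LP", sample(length(pools$LP), 1),
        sample_amplitude(amp_model, "LP"), pools, config)))
    }
    if (registry$has_stimulation) {
      need("STIM")
      placements <- c(placements, list(draw_placement(
        "STIM", sample(length(pools$STIM), 1),
        stats::rlnorm(1, config$stim_lognormal[1], config$stim_lognormal[2]),
        pools, config)))
    }
    structure(list(placements = placements,
                   rest = draw_rest_plan(pools, amp_model, lf_pct, lf_amp,
                                         rr_samples),
                   merge_ff_into_lf = stats::runif(1) < config$p_merge_ff_lf,
                   lf_amplitude = lf_amp),
              class = "cycle_rules")
  }
  redraw_amplitudes <- function(rules) {
    lf_amp <- sample_amplitude(amp_model, "LF")
    lf_pct <- min(100, 100 * lf_amp / amp_model$lf_ref)
    rules$lf_amplitude <- lf_amp
    rules$placements <- lapply(rules$placements, function(p) {
      p$amplitude <- switch(p$kind,
        LF = lf_amp,
        FF = lf_amp * sample_amplitude(amp_model, "FF", lf_pct),
        LP = sample_amplitude(amp_model, "LP"),
        STIM = stats::rlnorm(1, config$stim_lognormal[1],
                             config$stim_lognormal[2]))
      p
    })
    rules$rest$amplitudes <- vapply(rules$rest$amplitudes, function(a)
      lf_amp * sample_amplitude(amp_model, "REST", lf_pct), numeric(1))
    rules
  }
  if (registry$same_morphology) {
    base <- draw_one()
    list(redraw_amplitudes(base), redraw_amplitudes(base), redraw_amplitudes(base))
  } else {
    list(draw_one(), draw_one(), draw_one())
  }
}
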