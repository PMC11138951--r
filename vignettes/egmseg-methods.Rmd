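---
title: "Delineating intracavitary electrograms and quantifying decrement-evoked potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating intracavitary electrograms and quantifying decrement-evoked potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egmseg)
```

## The problem

During electrophysiological studies of accessory pathways (AP) and
atrioventricular re-entrant tachycardias (AVRT), the operator paces the
heart with a drive train (coupling interval S in 400--600 ms) followed by a
premature extrastimulus S2 timed at the effective refractory period plus
20--60 ms, and watches how the latency between each stimulus and its
response in the coronary sinus (CS) changes. If the stimulus-to-response
delay after S2 grows by more than 10 ms the conduction is *decremental* --
a hallmark of AV-nodal behaviour that helps disambiguate AP from AVRT.
Measuring those latencies requires locating, on each of the five bipolar
CS leads, three component classes per cardiac cycle:

* **stimulation artifacts** (STIM) -- near-impulsive pacing spikes;
* **local fields** (LF) -- high-frequency deflections of the tissue under
  the electrode (atrial signals in the CS); local activations shorter than
  25 samples are termed **late potentials** (LP) and are labeled on the LF
  channel;
* **far fields** (FF) -- smoother, low-frequency deflections propagated
  from the remote (ventricular) chamber.

`egmseg` frames this as 1D semantic segmentation: a network maps a
1000 Hz single-lead window to per-sample probabilities of the three
classes (a $\{0,1\}^{3\times N}$ mask with channels STIM/LF/FF), and a
rule-based pipeline turns the per-lead masks into one clinical decision
per recording.

## Synthetic training data

Clinical recordings with delineation annotations are scarce and cannot be
redistributed, so the models are trained entirely on synthetic traces.
The generator mirrors clinical data only in its *semantics* -- frequency
content, durations, amplitude dependences, pacing structure -- and makes
no claim of physiological realism; its purpose is coverage of morphology
variability, not replication.

**Segment pools.** Waveform fragments of each class come from parametric
morphology families (`synth_segment_pool()`): LF/LP are windowed
oscillatory bursts with content in 80--300 Hz (LF 25--80 samples, LP 8--24
samples), FF are smooth mono- or biphasic lobes of 40--160 samples with
more than 90% of their power below 100 Hz, STIM are biphasic
near-impulses of 3--5 ms, and REST segments are low-pass-filtered noise.
When annotated data *are* available the same pools can be built with
`crop_segments()`: far-field and rest fragments are low-pass filtered
(100 Hz, 2nd-order Butterworth, single-pass causal -- the attenuation
oracle in the tests assumes the causal choice), every fragment is
zero-corrected by subtracting the line joining its endpoints, local
activations are split at the strict 25-sample threshold, and all fragments
are max-abs normalized with the original voltage kept in
`native_amplitude`.

**Amplitude model.** Far-field and rest voltages depend strongly on the
local-field voltage of the same cycle, so a single distribution will not
do: the LF amplitude range is cut into 10 bins (increments of 10% of the
reference range) and one log-normal is fitted per bin to the ratios
`amplitude_segment / amplitude_LF`, with LF and LP amplitudes fitted
unconditionally. Fitting is closed-form maximum likelihood on logs; bins
with fewer than 3 observations inherit the nearest populated bin so small
pools never break the fit. The normalizer of the "[0,100]%" interval is
the maximum LF amplitude seen during fitting -- a concrete choice the
interface leaves adjustable (`lf_ref`). The packaged reference model
(`default_amplitude_model()`) encodes LF around 1.5 mV, LP around
0.45 mV, and FF/rest relative amplitudes that *decrease* across LF bins,
reproducing the inverse dependence seen in bipolar CS data.

**Trace composition.** Each trace is three cardiac cycles: per-registry
rules are drawn first (stimulated with probability 0.3, one shared
morphology with probability 0.5, cycle length uniform in 400--1000 ms,
10--50% of each flanking cycle preserved, noise and sub-hertz sinusoidal
wander levels), then per-cycle rules (LF and FF each present with
probability 0.9, Poisson(0.3) extra late potentials, positions uniform in
[0,100]% of the cycle, a 0.5 chance of resampling to 75--125% length, a
0.3 chance of Mixup with a pool mate using a Beta(0.2, 0.2) coefficient --
the conventional concentration for that augmentation -- and a 0.1 chance
of labeling the FF on the LF channel to emulate fused components). Rest
segments are concatenated into a baseline, placements are added on top,
and the recorded indices become the ground truth, so mask runs and
interval tables are bijective by construction. The published rule table
for these probabilities is not available; the values above are the
generator's declared study conditions and every one is overridable through
`synth_config()`. Where the flanking-cycle crop clips an interval we keep
the clipped remainder labeled (the alternative -- dropping it -- would
teach the model to ignore real activations at window borders).

**Clinical protocol emulation.** `generate_clinical_recording()` builds
full five-lead recordings under ventricular pacing: each stimulus is
followed by a ventricular far field at 15 ms and the atrial local-field
response at a baseline latency of 100--160 ms; after S2 the response
latency grows by the programmed `decrement_ms`. Per-beat, per-lead onset
jitter is a permutation of {-2,-1,0,1,2} ms: each lead moves by up to
3 ms while the across-lead *median* is exactly zero, so the consensus
fiducial reflects the programmed timing and a programmed margin of 5 ms
from the 10-ms threshold cannot be crossed by jitter -- which is what
makes the 100/100 oracle-recovery check meaningful rather than flaky.
The truth label applies the strict rule: decremental iff
`decrement_ms > 10`.

## Architectures

`build_model()` instantiates 1D U-Nets and W-Nets: `depth` resolution
levels (5 or 6 in the configurations this package targets), 32 base
channels doubled
at each max-pooling (kernel 2) and halved at each nearest-neighbour
upsampling, two convolutional blocks per level (kernel 3, leaky ReLU with
slope 0.01), encoder-decoder skip connections by concatenation, and a
final 1x1 convolution squashed to [0,1] by a sigmoid. The W-Net feeds the
first U-Net's output into a second U-Net and additionally concatenates
each level of the first decoder into the matching level of the second
encoder. Efficient channel attention (ECA) can be inserted after each
convolutional block: per-channel gates are computed from globally averaged
channel descriptors through a 1D convolution across channels whose kernel
is the nearest odd integer to $\log_2(C)/2 + 1/2$.

Choices the architecture description leaves open, fixed here: convolution
kernel 3 with two blocks per level; nearest-neighbour-then-convolution
upsampling (avoids checkerboard artifacts); channel-wise (spatial)
dropout at rate 0.25 inside convolutional blocks as the regularizer;
per-window channel (instance) normalization with a learnable affine after
every convolution; input windows max-abs standardized to [-1,1] to match
the segment normalization. The normalization is load-bearing: without it
the region-overlap loss rewards growing the cascade's overall gain
(confidence sharpening), the unnormalized activations grow exponentially
over training until the output sigmoid saturates, and learning dies.
Normalizing each conv block's output makes the forward pass invariant to
weight scale and removes that attractor. Windows are 1024 samples (about one second at 1000 Hz,
divisible by $2^5$ and $2^6$); shorter cycles are zero-padded
symmetrically with the padding excluded from the loss, longer ones are
linearly resampled.

The networks are implemented directly on BLAS matrix products with
compiled kernels (`src/nn_kernels.cpp`): activations are channels-first
matrices whose columns are concatenated per-window time blocks, and each
convolution is one `dgemm` per kernel tap accumulated in place with
boundary corrections. Backpropagation is analytic throughout and verified
against finite differences in the test suite.

## Training

The training protocol is fixed and fully seeded: Adam (learning rate
$4\times10^{-3}$, batch 16; the rate was selected on short training
probes as the fastest stable setting for the normalized network), seed
123456, leaky ReLUs, and synthetic data only. The main loss is soft Dice per channel
and per window,
$D_c = (2\sum pt + \varepsilon)/(\sum p + \sum t + \varepsilon)$ with
$\varepsilon = 1$, averaged over windows and channels; computing the
Dice per window (rather than pooled over the batch) is what lets the
$\varepsilon$ smoothing stabilize windows whose channel is empty
(stimulation is absent from most cycles) and keeps gradient scales
comparable across windows. An optional edge-sensitivity loss
targets $Se = TP/(TP+FN)$ on segment boundaries: edge maps are absolute
first differences, reference edges are dilated by a +/-10-sample
tolerance, and the soft counts make the loss differentiable; it is
non-increasing as a predicted edge approaches a reference edge within the
tolerance. The best-performing configuration trains with the Dice loss alone,
so the default weights are `c(dice = 1, sens = 0)`. The step size is
annealed with a cosine schedule from the peak rate down to 5% of it over
the run, which sharpens the late-training fit. Two further numerical
safeguards: gradients are clipped to unit global norm, and pre-sigmoid
activations are clamped to +/-12 so that even a saturated output retains
a small nonzero gradient and training can recover from transient
all-background collapses.
Patient-wise splitting (`split_by_patient()`, fraction applied to
patients) keeps all traces of a patient on one side; an optional
validation carve-out selects the checkpoint by validation Dice.

## The clinical pipeline

`run_decrement_pipeline()` chains five stages. (1) Analysis windows of
1024 samples are centred on QRS barycenters -- supplied fiducials, or the
built-in amplitude-envelope detector on the surface lead (QRS detection is
deliberately pluggable; recordings without discernible QRS, e.g. in AF,
are out of scope). (2) Each lead of each window is predicted
independently; probability maps are binarized at 0.5 and runs become
intervals (runs closer than 2 samples merged, runs shorter than 3 samples
dropped), predictions overlapping a stimulation detection by more than
half their length are removed as pacing artifacts, and duplicate
detections of one event from overlapping windows are fused per lead.
(3) Majority voting across the five leads: onsets of one class are
clustered greedily with a 20 ms linkage and clusters supported by at
least 3 leads emit the median onset/offset -- the decapolar catheter's
geometry makes true events nearly synchronous across leads, while
spurious single-lead detections lose the vote. The voting parameters are
not specified by the source method and are configurable. (4) The paced
chamber is located per stimulus by the class of the earliest component
intersecting a 60 ms adjacency window (conducted responses arrive at
100 ms or later, so the window separates cleanly even under a few
milliseconds of onset-detection drift), with a majority vote across
stimuli; the response class is the other component. Under ventricular
pacing, late-potential-length (under 25 samples) local-field detections
fully contained in a consensus far field are discarded before matching --
the same containment rule the evaluation metrics apply to false
positives, length-restricted because a genuine atrial response may
legitimately overlap a long far field. Matching then exploits the
protocol's structure: candidates of stimulus i lie strictly between
stimulus i and stimulus i+1 (within 300 ms), the drive-train latency is
estimated as the delay supported by the most drive beats (15 ms
tolerance), each drive beat takes its consistent candidate, and the
extrastimulus takes its first candidate at or beyond that latency (its
surplus is the decrement). Typed exclusions: `uncoordinated` (fewer than
two stimuli, or no common drive latency), `no_response` (which is how
loss of capture after S2 manifests), `too_distant`, and
`morphology_mismatch` (normalized cross-correlation of the last two
response waveforms below 0.5; the correlation is computed per lead and
fused by the median, because averaging leads first lets
differently-jittered far-field interference decorrelate two responses
that every single lead sees as the same morphology).
(5) The raw decrement is $\Delta t_N - \Delta t_{N-1}$ over the last two
stimuli; it is corrected by the lag of the highest cross-correlation
between the last two response waveforms after aligning each at its own
detected onset, which cancels onset-detection jitter (the alternative
reading -- correcting with a pure cross-correlation delay -- is available
by calling `xcorr_lag()` directly). The final label applies the strict
rule: decremental iff the corrected decrement exceeds 10 ms. The
exclusion thresholds (300 ms, 0.5, 40 ms) are clinical-scale defaults,
all configurable via `decrement_config()`.

## Evaluation

`delineation_metrics()` reports per-class precision, recall, hard Dice,
and onset/offset errors (signed, predicted minus reference, population-SD
convention) in three variants: *raw*; *filtered*, where LF false
positives fully contained in a reference FF are discarded (they are
usually high-frequency content riding on the ventricular far field, not
errors worth counting -- the filter touches only false positives, so
precision can only rise and recall is untouched); and *merged*, where LF
and FF masks are OR-ed into one class to absorb cross-class labeling
ambiguity. Detection matching pairs predicted and reference intervals
one-to-one by temporal overlap (any overlap qualifies). The matching is
computed as the exact assignment maximizing first the number of pairs and
then the total overlap, solved per connected component of the overlap
graph; a greedy fallback covers pathologically large components. An
exhaustive whole-instance enumeration serves as the independent oracle in
the tests. Channels empty on both sides score Dice 100% by convention;
empty error summaries are `NA`, never zeros.

## What the tests show -- and what they do not

All acceptance checks are property-based, at these problem sizes: 1000
generated traces for labeling invariants; 5000 cycles per bin for
amplitude recovery within 5%; filter attenuation within 1% of the closed
form at 10/100/400 Hz; 500 random instances for matching-oracle
equivalence; a depth-5 U-Net overfitted on 32 windows for 200 epochs
(seed 123456, dropout disabled -- the experiment probes fit capacity,
which regularization deliberately impedes) to merged-class Dice above
0.9; and 100 programmed
recordings (decrements 0/5/15/20/40 ms) recovered exactly with oracle
intervals and to at least 90% agreement with the smoke-trained model.
Determinism is asserted by regenerating datasets and pipeline reports
byte-identically and by re-running the first epochs of the smoke
configuration twice; repeating the full 200-epoch run adds no information
beyond those identical opening epochs, since every later step is the same
deterministic code path.

Passing these checks demonstrates that the machinery is sound, that the
training loop can fit the synthetic distribution, and that the clinical
rule logic is exact. It does *not* demonstrate clinical performance: the
generator's morphologies are idealized, its noise is Gaussian plus a
single sinusoid, real inter-patient variability is far richer, and clinical-grade
accuracy figures can only be established on real recordings with expert
annotations, which are not distributable. A model intended for real use must be trained on
a generator fitted to real annotated pools (via `crop_segments()` and
`fit_amplitude_model()`) and validated clinically.

## Known limitations

* No ERP estimation: S2 timing is taken from detected stimuli.
* Windowing assumes a detectable QRS; atrial fibrillation without
  discernible QRS is unsupported.
* The weight-loading hook (`load_weights()`) accepts external pretrained
  encoders when shapes match, but no pretraining is shipped.
* Training runs on one CPU thread through BLAS; it is deliberately sized
  (window 1024, base 32) so the overfit experiment completes in minutes,
  not hours, and no GPU path is provided.
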