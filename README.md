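# megpac

Cross-regional alpha–gamma phase–amplitude coupling (PAC) analysis for MEG
studies of antidepressant treatment response.

## The problem

Emotional visual input reaches the amygdala along two routes: a fast
subcortical pathway via the thalamus (~0–50 ms after stimulus onset) and a
slower cortical pathway via the orbitofrontal cortex (~100–200 ms). In MEG
recordings of depressed patients viewing sad faces, the coupling between a
driver region's alpha phase (8–13 Hz) and the amygdala's gamma envelope
(30–100 Hz) along these pathways is attenuated in patients who will not
respond to SSRI treatment, and per-patient coupling strength correlates with
the subsequent symptom improvement — making baseline PAC a candidate
predictor of treatment response.

`megpac` is a tested reimplementation of that analysis chain for
methodologists and electrophysiologists:

- **synthetic cohorts** with injected cross-regional coupling, clinical
  outcomes statistically linked to coupling depth, and a toy forward model
  (`simulationConfig()`, `simulateCohort()`, `projectToSensors()`);
- **preprocessing**: exactly zero-phase notch + 1–100 Hz band-pass and
  robust variance-based trial/channel rejection (`notchBandpass()`,
  `rejectHighVariance()`);
- **source reconstruction**: LCMV beamformer
  `w = (l'C⁻¹l)⁻¹ l'C⁻¹` with unit gain, sign-aligned ROI aggregation, and
  symmetric orthogonalization for leakage control (`lcmvFilters()`,
  `applyFilters()`, `symmetricOrthogonalize()`);
- **spectral analysis**: 4-cycle Hanning and 3-taper Slepian multitaper
  TFRs, spectrum normalization, band-power time courses (`tfrHanning()`,
  `tfrMultitaper()`);
- **coupling**: comodulograms of the phasor–envelope coherence
  `|Σ env·e^(−iφ)| / √(N·Σ env²)` per (phase frequency, amplitude
  frequency) pair and pathway window (`comodulogram()`, `pacCoherence()`);
- **statistics**: pointwise F + Benjamini–Hochberg FDR, post-hoc t, and the
  2-D cluster-based permutation test with max-mass correction
  (`clusterPermutation()`);
- **prediction**: cluster-strength features, Pearson correlation with
  HAM-D-6 reduction ratios, and ROC/AUC with a Youden operating point from
  an OLS feature combination (`correlateFeatures()`, `combineAndRoc()`).

## Worked example

A seeded end-to-end run on a synthetic cohort with the published group
structure (33 non-responders, 32 responders, 29 controls), desk-scale
signal parameters and 200 permutations:

```r
library(megpac)
run <- runPipeline(pipelineConfig(
  seed = 1,
  simulate = list(nTrials = 20, fs = 300, epochLenS = 1.0, preStimS = 0.2),
  cfc = list(ampFreqs = seq(30, 100, 2)),
  stats = list(P = 200)))
print(run)
```

```
PipelineRun: 94 subjects

           HC non_responder     responder 
           29            33            32 

rTHA:rAMG@0-0.05:
ClusterTestResult: 6 x 26 stat map, 200 permutations
  cluster 1: positive, 4 bins, mass 9.01, p = 0.3682
  cluster 2: negative, 1 bins, mass -2.01, p = 0.6219
  cluster 3: negative, 51 bins, mass -133.02, p = 0.01493

rOFC:rAMG@0.1-0.2:
ClusterTestResult: 6 x 26 stat map, 200 permutations
  cluster 1: negative, 51 bins, mass -681.60, p = 0.004975

feature-ratio correlations:
            feature         r            p
1  rTHA:rAMG@0-0.05 0.3969036 1.062518e-03
2 rOFC:rAMG@0.1-0.2 0.8502361 3.246846e-19
RocResult: AUC = 0.996; Youden point sens = 0.939, spec = 1.000 @ 0.5968
```

Reading the output: in both pathway windows the non-responder group shows a
significant *negative* cluster (attenuated coupling relative to
responders); each patient's mean coupling over the cluster bins correlates
positively with their HAM-D-6 reduction ratio; and the OLS combination of
the two cluster-strength features separates non-responders from responders
with an in-sample AUC near 1 at this injected effect size. On real data the
same report is produced from user-supplied epoched recordings and lead
fields.

The methods vignette (`vignettes/megpac-methods.Rmd`) documents the
generative model, every estimator, the numerical choices and the
limitations of synthetic validation.

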