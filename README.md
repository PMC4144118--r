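# rwenet

Wavelet-entropy brain networks from resting-state EEG.

Neurodegenerative disease reorganizes the brain's functional networks before
structural damage is obvious.  `rwenet` quantifies that organization from
multichannel resting-state EEG: every electrode-window is reduced to a
probability distribution over the five classical rhythms (delta, theta,
alpha, beta, gamma) via a periodized discrete wavelet cascade, every ordered
electrode pair is scored with the **Relative Wavelet Entropy**

    RWE(p || q) = sum_j p_j ln(p_j / q_j)        (smaller = more synchronized)

and the resulting 57x57 synchronization matrix is thresholded into binary
directed graphs with a fixed number of edges K in {500, 600, 700, 800}
(densities 15.39-24.62 % by the 100*K/N^2 convention).  Each graph is
summarised by its characteristic path length L, mean clustering coefficient
C, the ratios lambda = L/L_rand and gamma = C/C_rand against the analytic
random references L_rand = ln(N)/ln(k), C_rand = k/N (k = K/N), the
small-world coefficient sigma = gamma/lambda, directed betweenness-centrality
hubs (normalized b_i >= 1.5), and an anterior hub ratio probing left-frontal
recruitment.  A synthetic coupled-oscillator EEG generator with planted
cluster-wise coupling, hub shortcuts and a disease-severity dial makes the
whole pipeline testable without clinical data, and a statistics layer
provides per-density one-way ANOVAs with Tukey HSD plus Pearson correlations
of sigma with MMSE/MoCA-like screening scores.

Intended users: EEG/connectomics researchers who want a reproducible,
tested reference implementation of fixed-density RWE network analysis, or a
synthetic testbed for method development.

## Worked example

```r
library(rwenet)

# a synthetic "healthy" subject: 57 channels, 500 Hz, clustered coupling
# with hub shortcuts at Fz/Cz/Pz
cfg <- generator_config(seed = 11)           # rho = 0.8, severity = 0
rec <- generate_recording(cfg)
rec
#> <eeg_recording> 57 channels x 110000 samples @ 500 Hz (220.0 s)
#>   labels: Fp1 Fpz Fp2 AF3 AFz AF4 F7 F5 ...

fit <- rwe_connectome(rec, n_epochs = 10, seed = 11)
fit
#> RWE connectome fit: 57 electrodes, 1560 windows aggregated
#>    K density_pct     L      C  sigma
#>  500       15.39 1.057 0.8983 10.285
#>  600       18.47 2.058 0.9848  4.450
#>  700       21.55 2.348 0.8901  2.836
#>  800       24.62 2.219 0.8391  2.351
```

Reading the table: at every density the fitted graph is strongly small-world
(`sigma` well above 1) because the generator plants dense within-cluster
synchronization (high `C`) and hub shortcuts (short `L`); `sigma` falls as
the edge budget K grows and weaker, less clustered edges are admitted.
`summary(fit)` additionally lists the identified functional hubs,
`coef(fit)` returns the L/C/lambda/gamma/sigma matrix, and `plot(fit)` draws
the synchronization matrix and the sigma-density profile.

Group-level analysis on a synthetic cohort:

```r
co  <- generate_cohort(10, severities = c(Healthy = 0, aMCI = 1, MD = 2),
                       seed = 8001)
tab <- cohort_metrics(co, n_epochs = 10, seed = 8100)
anova_with_posthoc(tab, "sigma")   # per-density F tests + Tukey HSD
correlate_cognition(tab, "MMSE")   # Pearson r of mean sigma vs score
```

Severity weakens the planted coupling, so the severity-ordered groups come
out ordered in `C` and `sigma`, and `sigma` correlates positively with the
severity-linked scores — the qualitative signature the pipeline is built to
detect.

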