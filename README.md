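# relaygate

Tools for analyzing spike transmission at the retinogeniculate synapse:
which retinal ganglion cell (RGC) spikes does a lateral geniculate nucleus
(LGN) relay neuron forward, and what features of recent spiking history
predict that decision?

The package is aimed at systems neuroscientists working with paired
RGC–LGN (or S-potential–LGN) spike-time recordings, and at anyone who
needs a tested reference implementation of the underlying machinery:
cross-correlogram connectivity detection, spike-transmission efficacy,
Bernoulli-logistic history GLMs with raised-cosine bases, and
cross-validated single-event information.

## The models

Every retinal spike gets a binary *relay status* $y_i$ — whether an LGN
spike followed it inside the detected monosynaptic window (a
cross-correlogram peak exceeding $\mu + 3\sigma$ of a 30–50 ms flanking
baseline, centered 2–6 ms after the retinal spike). Three nested models
predict $y$:

* **ISI-efficacy**: $\lambda = \sigma(\beta P(\mathrm{ISI}) + \alpha)$,
  where $P$ is a smoothed, nonparametric histogram ratio (relayed / total
  per 1-ms ISI bin) and $(\beta, \alpha)$ maximize the Bernoulli
  likelihood.
* **RH** (retinal history): $\lambda = \sigma(X_R \theta)$, a logistic GLM
  on the 1-ms-binned retinal spike pattern preceding each spike, fitted by
  penalized Newton with a first-difference smoothing prior
  $\eta \sum_i (\theta_i - \theta_{i-1})^2$.
* **CH** (combined history): adds the LGN cell's own strictly-causal
  history; both filter components are compressed in a log-warped
  raised-cosine basis $b_k(t) = (\cos q_k(t) + 1)/2$,
  $q_k(t) = (u(t) - u(\phi_k))\,\pi / 2\gamma$, $u(t) = \log(t + \Psi)$,
  with ridge priors on the basis-domain coefficients.

Models are scored by the cross-validated single-event Bernoulli
information, in bits/spike:

$$I_{\mathrm{Bernoulli}} = \frac{1}{n_{\mathrm{test}} \log 2}
  \left( L(\lambda; y_{\mathrm{test}}) - L(\bar\lambda_{\mathrm{test}};
  y_{\mathrm{test}}) \right),$$

the log-likelihood gain over a homogeneous predictor of the test-set mean
efficacy, with balanced stratified folds and nested hyperparameter search.
Burst detection, activity-dependent filter comparisons, BCa bootstrap CIs
and paired permutation tests round out the pipeline, and a synthetic
generator produces paired recordings from a known ground-truth GLM so the
whole chain can be validated end to end.

## Worked example

```r
library(relaygate)

cfg <- generator_config(duration_s = 150, rgc_rate_hz = 40,
                        target_efficacy = 0.2, target_contribution = 0.6,
                        seed = 11L)
gp <- generate_pair(cfg)
conn <- analyze_connectivity(gp$pair)
conn$window
#> <monosyn_window: [2.30, 3.30] ms, peak 2.85 ms, baseline 6.32 +/- 2.51>
conn$labels
#> <relay_labels: efficacy 0.201 (1112/5523), contribution 0.606 (1116/1841),
#>   window [2.30, 3.30] ms>

grid <- list(isi_max = c(0.05, 0.2), isi_sigma = c(0, 0.005),
             rh_span_ms = c(30, 100), rh_eta = c(16, 256))
cv_isi <- cross_validate("isi", gp$pair, conn$labels, grid, seed = 3)
cv_rh  <- cross_validate("rh_time", gp$pair, conn$labels, grid, seed = 3)
round(c(isi = cv_isi$mean_info, rh = cv_rh$mean_info), 4)
#>    isi     rh
#> 0.0091 0.0235
```

The generator injected a 2.8-ms relay delay and an efficacy target of 0.2;
the correlogram recovers the delay window and the labels recover the
efficacy. The retinal-history GLM extracts more information per spike
(0.024 bits) than the ISI-efficacy model (0.009 bits) because the
ground-truth filter integrates history beyond the single preceding
interval — exactly the comparison the pipeline is built to make on real
pairs. For the full model account, parameter tables and numerical
conventions, see `vignettes/relay-modeling.Rmd`.

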