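# causaldecomp

Prediction-free causal inference between two time series, for ecologists,
physiologists and anyone else whose "cause" and "effect" oscillate together
rather than one neatly preceding the other. Classical tools (Granger
causality, convergent cross mapping) infer causality from predictability
and inherit its constraints: a lag structure to choose, sensitivity to
sampling and temporal shifts, and trouble with simultaneous or reciprocal
coupling — the everyday situation in predator–prey systems. This package
instead implements *causal decomposition*: causality is read from
instantaneous phase dependency at a specific time scale, probed by removing
that scale and watching whether the dependency survives.

## The method

Both series are decomposed into intrinsic mode functions (IMFs) by ensemble
empirical mode decomposition (EEMD): each of N trials decomposes the signal
plus Gaussian white noise of amplitude r·sd, and the per-index trial means
are the IMFs. For each paired scale j the instantaneous phase coherence

    Coh_j = | (1/T) Σ_t exp{ i (φ₂ⱼ(t) − φ₁ⱼ(t)) } |   ∈ [0, 1]

is computed from the Hilbert phases φ. The causal probe removes IMF i from
one series, redecomposes the remainder, and measures the variance-weighted
collapse of the coherence profile,

    D(1→2) = { Σⱼ Wⱼ [Coh(S₁ⱼ, S₂ⱼ) − Coh(S₁ⱼ, S′₂ⱼ)]² }^½ ,
    Wⱼ ∝ Var(S₁ⱼ)·Var(S₂ⱼ),  Σ Wⱼ = 1,

and symmetrically for D(2→1). The relative strengths
C(1→2) = D(1→2) / [D(1→2) + D(2→1)] and its complement sum to 1; 0.5 means
no differential causality, and values toward 1 mean series 1 drives
series 2 at that scale (when both D < 0.05, D+1 replaces D so a no-change
outcome reads 0.5). Flags are validated by leave-one-out deletion of single
time points. The only substantive parameter is the EEMD noise level r,
chosen by orthogonality/separability diagnostics (`select_noise_level()`).

## Worked example

The bundled stochastic benchmark couples an AR(2) resonance x (8-sample
period) into a noisy response y = 0.5·x(t−1) + ε:

```r
library(causaldecomp)
m <- ar_stochastic(1000, seed = 1)
params <- eemd_params(noise_level = 0.15, ensemble_size = 200, seed = 11)
causal_profile(m$x, m$y, params)
#> causal decomposition of 'ar_x' vs 'ar_y' (r = 0.15, N = 200)
#>  imf_index  d_ab  d_ba  c_ab  c_ba flagged
#>          1 0.363 0.168 0.684 0.316    TRUE
#>          2 0.125 0.049 0.719 0.281    TRUE
#>          3 0.007 0.004 0.501 0.499   FALSE
#>          4 0.002 0.003 0.500 0.500   FALSE
#>          5 0.004 0.005 0.500 0.500   FALSE
#>          6 0.001 0.001 0.500 0.500   FALSE
#>          7 0.004 0.001 0.501 0.499   FALSE
#>          8 0.003 0.004 0.500 0.500   FALSE
#> flagged causal interaction at IMF 1, 2
```

Reading: at the scales that carry real structure (IMF 2 holds the 8-sample
resonance, IMF 1 the broadband innovations copied into y) removing the mode
from y collapses coherence far more than removing it from x — C(x→y) ≈
0.68–0.72, so x drives y, strongest at IMF 2. All other scales sit at 0.5:
no spurious causality. `leave_one_out()` distributions behind the `flagged`
column are in `as.data.frame(profile)`.

File-based runs (`run_analysis()`) write IMF tables, diagnostics, the
coherence profile, the causal profile (CSV/JSON) and a reproducibility
manifest; `inst/cli/causaldecomp` exposes `generate`, `diagnose`,
`decompose`, `analyze` and `validate` subcommands over the same functions.

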