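# gaitlf

Dynamic stability of human walking from Lyapunov–Floquet theory.

Walking can be treated as a periodic dynamical system: the medio-lateral
(M/L) motion of the centre of mass (CoM) relative to the centre of pressure
(CoP) oscillates about an equilibrium the way an inverted pendulum sways
about upright stance. `gaitlf` quantifies how strongly that system pulls
back toward its limit cycle — and therefore how tolerant a person's gait is
to perturbation — from nothing more than six reflective markers (two heels,
four pelvis landmarks) captured by an optical motion-capture system. It is
aimed at movement-analysis labs studying balance-impaired populations
(e.g. parkinsonian syndromes such as progressive supranuclear palsy, PSP)
where short overground walking trials are all a patient can provide.

## The model and its metrics

From marker trajectories sampled at rate *f* (typically 120 Hz) the
pipeline constructs

- the M/L CoM surrogate (mean of RPSI, LPSI, RASI, LASI) and CoP surrogate
  (mean of RHEE, LHEE), and the relative signal *y(t) = CoM_ML − CoP_ML*;
- per-trial boundary-stride trimming (gait initiation/termination), mean
  normalization, stitching of the ~5 short trials into one record, and a
  zero-phase 4th-order Butterworth low-pass at 10 Hz, giving *Y(t)*;
- the phase state *m(t) = [Y(t), Ẏ(t)]* and its optimized time-delay
  embedding *M(t) = [m(t), m(t+τ), …, m(t+nτ)]* (delay τ from the first
  minimum of average mutual information, dimension from false nearest
  neighbours);
- the **monodromy matrix** Φ(T), the linear map carrying deviations from
  the limit cycle across one stride period *T*, estimated by a pooled
  least-squares fit over stride-separated state pairs on Poincaré sections
  anchored at left heel strikes. Its eigenvalues are the **Floquet
  multipliers** (FM); |FM| ≤ 1 means orbitally stable. The **Floquet
  exponents** log(FM)/T have real parts equal to the long-term Lyapunov
  exponents (**LE_L**, 1/s); LE ≤ 0 means stable.
- the **short-term Lyapunov exponent** (**LE_S**) by Rosenstein's
  nearest-neighbour divergence algorithm, fitted over half a gait cycle.

Cohort-level statistics mirror the clinical study design: Welch t-tests on
demographics, ANCOVA per metric with sex/age/cadence covariates
(Anderson–Darling and Levene assumption checks attached), post-hoc
per-group regressions for significant covariates (slopes reported per
decade of age / per 5 steps·min⁻¹ of cadence), and Spearman correlations
against PSPRS disease-severity scores.

Because clinical recordings cannot be redistributed, the package ships
generators with closed-form ground truth: a pulse-driven damped oscillator
(|FM| = e^(−ζωT), max LE_L = −ζω), a full marker-level gait synthesizer, a
two-group cohort simulator, and a Lorenz benchmark with a Benettin/QR
Lyapunov-spectrum oracle.

## Worked example

```r
library(gaitlf)

# 1) a damped oscillator with known stability: zeta = 0.1, omega = 2*pi,
#    stride period 1 s, so |FM| = exp(-0.2*pi) = 0.53349 and
#    max LE_L = -0.2*pi = -0.62832 in closed form
sim <- simulate_linear_oscillator(zeta = 0.1, omega = 2 * pi, T = 1,
                                  n_strides = 60, rate = 120, seed = 1)
emb <- delay_embed(differentiate(sim), tau = 1, n = 0, stride_time = 1)
glance(estimate_monodromy(emb))
#>   mean_abs_fm max_abs_fm max_le_l ... n_pairs condition_number
#> 1    0.533487   0.533487 -0.62832 ...    1415          6.92223

# 2) a synthetic participant: damping ratio 0.1, cadence 50 steps/min,
#    five 8-stride trials at 120 Hz, noise-free
g <- simulate_marker_gait(zeta = 0.1, cadence = 50, noise_sd = 0,
                          seed = 21, kick_cv = 0)
g$label$max_le_l    # closed-form LE_L: -0.2631183 1/s

row <- run_participant(g$trials, participant_id = "P01")
row[, c("cadence", "stride_time_s", "n_strides", "max_LE_L", "max_LE_S")]
#> # A tibble: 1 x 5
#>   cadence stride_time_s n_strides max_LE_L max_LE_S
#>     <dbl>         <dbl>     <int>    <dbl>    <dbl>
#> 1      50           2.4        20   -0.265    -1.08
```

The oscillator spectrum is recovered to five decimals (0.533487 vs
0.533488; −0.62832 vs −0.62832 s⁻¹). For the marker-level participant the
detected cadence (50 steps/min), stride period (2.400 s) and stride yield
(20 analyzable strides from 5 trials after trimming two per end) match the
generator, the estimated max LE_L (−0.265 vs −0.263 s⁻¹) lands within 1% of
the label, and the negative LE_S says nearby trajectories of this
noise-free limit cycle converge. A cohort-level report with the full
statistical battery:

```r
tb  <- simulate_metrics_cohort(n_per_group = 30, seed = 1)
rep <- run_cohort(tb)
rep$ancova_terms   # Type-II F table per metric
rep$posthoc        # per-group regressions for significant covariates
```

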