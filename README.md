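# enhancerCGI

Transcribed enhancers — the ~63k bidirectionally transcribed elements
defined by CAGE-tag analysis — share promoter-like properties whose
magnitude tracks the presence of a CpG island (CGI). `enhancerCGI`
implements the full analysis pipeline for studying this on data with known
ground truth, for regulatory genomicists who want each stage as a tested,
reusable function:

- **CGI calling**: 100-nt sliding window, GC ≥ 50%, CpG observed/expected
  `(n_CpG · L)/(n_C · n_G)` ≥ 0.6, maximal qualifying runs spanning ≥ 200 bp;
  promoter association ([−200, +200] around the TSS) and enhancer
  association (a call containing one of the two divergent TSSs).
- **Core promoter elements**: twelve PWMs (TATA, Inr, BREu, BREd, DPE, MTE,
  DCE I–III, XCPE1, TCT, Pause Button) with log-odds weights
  `w_bi = log2(((f_bi + c·q_b)/(1+c))/q_b)`, an editable YAML asset, scan over
  [−500, +200], a localized-overrepresentation test (functional window =
  expected position ±2 nt; background from 5-nt windows shifted in 1-bp
  steps; Gaussian `z = (n₊ − μ)/σ` *and* binomial upper tails), and pairwise
  co-occurrence via one-sided hypergeometric tail sums in log space with
  Bonferroni α = 0.05/66.
- **CAGE metrics**: dispersion index
  `s = sqrt((1/c) Σ (j − m)² x_j)` with sharp ⇔ mean ≤ 2.5; tissue
  specificity `τ = Σ(1 − x̂_i)/(n − 1)` over the top-15 groups; enhancer
  directionality `(F − R)/(F + R)` over ±200 nt of the midpoint.
- **Peak overlap**: maximum narrowPeak signal per element and binding-event
  density per 1000 nt (promoter region [−500, +200)), with Mann–Whitney
  group comparisons and a log-space two-sided Fisher test for contingency
  tables.
- **Synthetic data**: generators for genomes with planted CGIs and motifs,
  CAGE tag tables with controlled sharpness/breadth/directionality, and
  narrowPeak files with controlled densities — every stage has a recovery
  test against the planted truth.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(01_simulate → 06_compare), each a thin script over package functions that
writes its tables under `results/`. Running them in order on the default
seed prints, among other things:

```
$ Rscript analysis/02_cgi.R
promoters: 118/200 CGI-associated (planted sensitivity 1.000)
enhancers: 22/300 CGI-associated (planted sensitivity 1.000)

$ Rscript analysis/05_peaks.R
enhancer_cgi       mean density 2.94 /kb (simulated 3.26)
enhancer_noncgi    mean density 1.01 /kb (simulated 1.15)
promoter_cgi       mean density 5.07 /kb (simulated 5.06)
promoter_noncgi    mean density 1.76 /kb (simulated 1.89)

$ Rscript analysis/06_compare.R
                     test n_x n_y     median_x    median_y            p
1  enhancer_length_by_cgi  22 278 4.055000e+02 286.0000000 3.872449e-05
2  enhancer_absdir_by_cgi  22 278 5.913097e-01   0.2407051 3.632318e-05
3     promoter_tau_by_cgi 100  46 7.501552e-03   0.5053042 1.703355e-03
4 promoter_density_by_cgi 118  82 5.714286e+00   1.4285714 1.737456e-20
```

Every planted CGI is recovered; CGI enhancers come out longer (median 406
vs 286 nt) and more directional (median |d| 0.59 vs 0.24); CGI promoters
are less tissue-specific (median τ 0.008 vs 0.51) and carry ~4× the
binding-event density — the direction of every effect in the study system,
here with known ground truth. `run_pipeline(sim_config(seed = 1))` returns
the same report programmatically (`elements`, `overrepresentation`,
`cooccurrence`, `comparisons`, `contingency`, `recovery`).

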