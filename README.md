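# sbsbn

Safety behavior sampling and Bayesian network analysis of high-risk
unsafe work behaviors.

## What it is for

Behavior-based safety programs need to know *which* factors to target.
`sbsbn` implements a complete observational workflow for that question,
aimed at occupational-safety researchers and analysts:

1. **Design** a safety-behavior-sampling (work sampling) campaign.
   From a pilot with `N1` high-risk unsafe behaviors (HRUBs) in `N0`
   instantaneous observations, the behavior rate is `p = N1/N0` and the
   required campaign size at standard-normal multiplier `K` and
   relative accuracy `S` is

   ```
   n = K² (1 − p) / (S² p)
   ```

2. **Model** the joint distribution of nine workplace variables (age,
   experience, marital status, previous accident, education, weekday,
   time of day, safety training, and the binary HRUB outcome) as a
   discrete Bayesian network, `P(X₁,…,Xₙ) = ∏ᵢ P(Xᵢ | Parents(Xᵢ))`,
   on an expert-elicited DAG in which age acts on behavior only through
   experience and marital status.

3. **Estimate** every conditional probability table from observation
   records — with missing cells handled exactly — by
   Expectation-Maximization (`bn_fit()`).

4. **Rank** the drivers of unsafe behavior by belief updating: for each
   state `s` of each variable `X`, the relative percent change

   ```
   V_s = 100 · [P(HRUB=yes | X=s) − P(HRUB=yes)] / P(HRUB=yes)
   ```

   is computed by exact posterior inference (variable elimination);
   variables are ranked by the mean of |V_s|, ties broken by mutual
   information I(X; HRUB).

Because the original field records are not public, the package ships a
calibrated synthetic ground-truth network (`ground_truth_network()`)
whose exact probabilities match the published site figures
(P(HRUB=yes)=0.248, P(married)=0.736, P(major accident)=0.0411,
P(high school)=0.595, P(HRUB=yes | most-trained)=0.123), plus a seeded
ancestral sampler for generating observation campaigns.

## Worked example

```r
library(sbsbn)

# campaign size from the pilot: 90 HRUBs in 200 observations
sbs_design(n1 = 90, n0 = 200)
#> Safety behavior sampling design: pilot 90/200 -> p = 0.45
#> Work-sampling size (relative precision): p = 0.45, K = 2, S = 0.05
#>   raw n = 1955.56;  required n = 1956;  nearest ten = 1960

# simulate a campaign of that size and fit the network by EM
truth <- ground_truth_network()
obs   <- sample_observations(truth, n = 1960, seed = 42)
fit   <- bn_fit(default_study_network(), obs)
fit
#> Bayesian network fitted by EM
#>   records: 1960   iterations: 2   converged: TRUE
#>   log-likelihood: -14750.3286
#>   fitted P(HRUB = yes): 0.2354

# which variables drive unsafe behavior?
sensitivity_report(fit)
#> Sensitivity of HRUB = yes (baseline 0.2354)
#>          variable state1 state2 state3 abs_mean_variation mutual_information rank
#>          Training  36.52 -10.42 -43.72              30.22            0.02320    1
#>        Experience   3.52  25.94 -19.30              16.25            0.00946    2
#>     MaritalStatus  -7.68  23.05      -              15.37            0.00381    3
#>  EducationalLevel  16.43  -7.50   4.96               9.63            0.00221    4
#>               Age  13.48  -3.00 -11.68               9.39            0.00209    5
#>           Weekday  -6.12  -3.28  16.98               8.79            0.00163    6
#>  PreviousAccident  -0.92   0.53  13.84               5.10            0.00021    7
#>           Daytime  -3.13  -0.65   3.83               2.54            0.00019    8
```

The report reads exactly like a site analysis: observing the
most-trained group (`Training = s3`) lowers the posterior HRUB
probability by about half, so training is the first-ranked intervention
target; inexperience, being unmarried, and end-of-week/afternoon
observation windows all raise it.

The numbers above were produced by the code shown (seed 42); rerunning
reproduces them exactly.

An end-to-end run — simulate or ingest a CSV, fit, analyze, and write a
report bundle (fitted network JSON, ranking CSV, per-state conditional
probabilities, markdown report, log) — is one call:

```r
run_pipeline(list(out_dir = "results", seed = 1,
                  simulate = list(n = 1960)))
```

or, from a shell, `Rscript inst/scripts/sbsbn-cli.R run --out-dir results`.

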