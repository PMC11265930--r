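# latchseq

Sequence analysis of multi-solution puzzle-box event logs from
free-ranging animals.

Field studies of innovative problem-solving deploy multi-compartment
puzzle boxes — 24 baited doors, each secured by one of four latch
mechanisms (`H` horizontal side-pull bolt, `R` rod removal, `V` vertical
pull-down bolt, `S` rotating swivel) — and identify visitors passively by
RFID while video supplies per-door work times and exploratory-diversity
scores. `latchseq` is the analysis layer for such experiments, for
behavioural ecologists who need to go from a raw timestamped event log to
statements about innovation, flexibility, individuality and the effect of
competition.

## What it computes

* **Trials and solvers.** Events are segmented into visits ("trials",
  split by ≥ 1 min of absence); an individual that opens ≥ 3 doors of one
  latch type is a solver of it, ≥ 2 types makes it a flexible solver.
  Box state (open doors, re-bait cycles) classifies each trial as
  *unrestricted* (first solver at a fully closed box, never joined by
  another solver) or *competitive*.
* **Complexity.** Each trial's latch sequence `s` of length `n` is scored

  `C(s) = sqrt( (q/(n-1)) * (h/log 4) )`

  with `q` the number of adjacent latch switches and `h` the Shannon
  entropy of latch use: 0 for a one-latch trial, 1 for equal use of all
  four latches with a switch at every door.
* **Dissimilarity.** Pairwise optimal-matching edit distances between
  trial sequences (indel cost 1, substitution costs
  `SC(i,j) = 2 − p(i→j) − p(j→i)` from pooled observed transition
  rates, normalised by the longer length), partitioned into
  intra-individual vs inter-individual comparisons per social condition
  and compared by Mann–Whitney tests.
* **Inference.** χ² goodness-of-fit of first-opened and total latch
  counts against uniform use (over each solver's final five
  first-arrival trials); forward-stepwise binomial GLMs for solving
  success competed by AICc, likelihood-ratio tests and Akaike weights.
* **Synthetic data.** A seeded generator
  (`synthetic_config()`/`generate_dataset()`) produces event logs with
  known individual latch preferences, sticky switching,
  competition-dependent preference sharpening and work-time learning
  curves, so the whole pipeline is testable without field data.

## Worked example

```r
library(latchseq)

cfg <- synthetic_config(seed = 42)         # 30 individuals, 10 nights
d   <- generate_dataset(cfg, "demo")       # events.csv, individuals.csv, truth.json
pc  <- pipeline_config("demo/events.csv", "demo/individuals.csv",
                       "demo_out", seed = 42)
run_pipeline(pc)
```

`demo_out/summary.txt` from this exact run (abridged):

```
individuals tested: 30; solvers: 12 (40%); flexible: 12

latch preference (final 5 first-arrival trials; n = 60):
  first-opened counts  [HRVS order HRVS]: 14 8 13 25
  chi-sq first: 10.267 (df 3, n 60), p = 0.0164
  chi-sq total: 45.189 (df 3, n 349), p = 8.43e-10

dissimilarity (unrestricted): intra median = 0.68 (n = 725), inter median = 0.91 (n = 8455)
  intra vs inter: W = 1639856.0, p = 3.55e-96
dissimilarity (competitive): intra median = 0.60 (n = 391), inter median = 0.95 (n = 4362)
intra-individual, unrestricted (0.68) vs competitive (0.60): W = 164697.5, p = 7.83e-06

solving-success model (forward stepwise binomial GLM):
  best: is_solver ~ exploratory_diversity_first
  vs null: LRT = 19.50 (df 1), p = 1e-05
```

Reading it: latch use departs from uniform (swivel favoured first),
individuals differ from each other far more than from themselves
(inter > intra medians), that self-similarity intensifies under
competition (intra drops 0.68 → 0.60), and first-trial exploratory
diversity predicts who solves — each the signature the generator plants
and the pipeline is built to detect. Single scores are available
directly, e.g.

```r
complexity_index("SVSHRVSH")
#> complexity C = 0.9761 (h = 1.3209 / 1.3863 nats, q = 7 / 7)
```

A command-line front end covering every stage
(`simulate`, `segment`, …, `run-all`) ships in `inst/cli/latchseq.R`:

```sh
Rscript inst/cli/latchseq.R simulate --seed 7 --out data/
Rscript inst/cli/latchseq.R run-all --in data/ --out results/
```

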