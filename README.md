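# panhar

Cooperative human activity recognition (HAR) over a personal area network
(PAN) of body-worn inertial sensor nodes, with energy-aware transmission
suppression.

A main node (a smartphone at the waist, say) and up to three supporting
nodes (chest, leg, arm) each classify their own 6-channel IMU windows —
3-axis accelerometer plus 3-axis gyroscope — into eight activities:
walking, jogging, squats, jump, lying, arms swing, sitting, standing.
Three ideas make the network worth its radios:

* **Local classification.** Node *i* applies a model *M<sub>i</sub>* to its
  window *X<sub>i</sub>(t)* and obtains a class *d<sub>i,t</sub>* with
  weight *w(d<sub>i,t</sub>)*, the softmax probability of the winning
  class. Backends: a recurrent network (LSTM(60) → Dropout(0.5) →
  Dense(60, ReLU) → softmax, Adam, batch 64, ≤ 40 epochs) and a fast
  deterministic feature-based multinomial model.
* **Gated reporting.** A support transmits its result only when the
  recognised class is in its transmit set *D<sub>i</sub><sup>s</sup>*:
  *s<sub>i,t</sub> = 1 ⇔ d<sub>i,t</sub> ∈ D<sub>i</sub><sup>s</sup>*.
  Transmit sets are minimized greedily: starting from the full class set,
  obligations are dropped one at a time while the ensemble's training
  accuracy stays within a tolerance ε (default 0.001) of the running
  baseline.
* **Weighted voting.** The main node sums reported weights per class —
  *d<sub>t</sub> = argmax<sub>j</sub> Σ<sub>i: d<sub>i,t</sub>=j</sub>
  w(d<sub>i,t</sub>)* — and always has its own result, so recognition
  survives support outages.

Expected suppression under balanced activity time and correct local
recognition is *100 (1 − Σ m<sub>i</sub> / 8k)* percent for *k* supports
with *m<sub>i</sub>* flagged classes each, rounded half-up. The packaged
reference table of optimized transmit sets for all 28 multi-node mount
configurations reproduces its suppression column exactly (e.g. 58% for a
waist main with chest, leg and arm supports).

The package also ships a synthetic multi-position IMU generator emulating
the acquisition protocol (2-minute sessions, 10 ms raw sampling, 2%
end-trimming, four mounts recorded simultaneously), a preprocessing
pipeline (trim → decimation → incremental gravity separation → sliding
windows → session-level split), a time-stepped network simulator with
failure injection, and reporting helpers — so the whole method is
trainable, runnable and testable without any external data. See the
methods vignette (`vignettes/panhar-methods.Rmd`) for the model details
and design decisions.

## Worked example

Generate the packaged desk-scale corpus, train a node per mount, minimize
the leg node's transmit set for a chest main, and simulate the two-node
network on held-out sessions:

```r
library(panhar)
library(dplyr)

corpus  <- generate_corpus(seed = 42)                 # 8 activities x 5 sessions x 4 mounts
windows <- prepare_windows(corpus, target_rate = 20, window_size = 64) |>
  split_train_test(seed = 42)

models <- sapply(c("s1", "s2", "s3", "s4"), function(p)
  fit_node_model(filter(windows, position == p), seed = 42), simplify = FALSE)
glance(evaluate_model(models$s2, filter(windows, position == "s2")))
#> # A tibble: 1 × 2
#>   accuracy     n
#>      <dbl> <int>
#> 1    0.981   216

preds_train <- lapply(models, function(m)
  predict(m, filter(windows, position == m$position, split == "train")))
preds_test  <- lapply(models, function(m)
  predict(m, filter(windows, position == m$position, split == "test")))

stream <- align_node_predictions(preds_train[c("s2", "s3")], main = "s2")
opt <- optimize_transmit_sets(stream, epsilon = 0.001)
opt
#> <transmit_opt> main s2 | 6 removal(s) accepted | accuracy 0.9896 -> 0.9942 | expected suppression 75%
format_transmit_vector(opt$final_sets$s3)
#> [1] "[0, 0, 0, 0, 1, 0, 1, 0]"

sim <- simulate_pan(align_node_predictions(preds_test[c("s2", "s3")], "s2"),
                    opt$final_sets, latency = FALSE)
glance(sim)
#> # A tibble: 1 × 7
#>   main  n_supports steps transmissions possible suppression_pct accuracy
#>   <chr>      <int> <int>         <int>    <int>           <dbl>    <dbl>
#> 1 s2             1   216            50      216            76.9    0.991
```

The optimizer keeps exactly the leg reports the chest cannot do without:
the chest's blind spot on this corpus is the lying-vs-sitting pair, so the
leg node ends up reporting only `lying` and `sitting` — suppressing 75% of
its transmissions in expectation (76.9% realised on the test sessions)
while lifting test accuracy from 98.1% to 99.1%. `compare_configurations()`
repeats this for all 28 main/support layouts, and `run_protocol()` wraps
the whole experiment (sweeps, optimization, confusion matrices, report
bundle); a thin CLI lives at `inst/cli/panhar.R`.

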