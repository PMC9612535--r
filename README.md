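# coughclass

Classify pediatric bronchitis vs pneumonia from cough-sound recordings.

Bronchitis and pneumonia are the leading pediatric respiratory
diseases and present nearly identical symptoms; both produce coughs,
and cough sounds carry information about the lungs and airways. This
package implements a complete patient-audio classification pipeline
for the setting where (a) diagnosis labels exist only at the patient
level while a recording contains several cough bursts mixed with
speech and room noise, and (b) the corpus is small (order 10^2
patients). It is aimed at researchers in computational respiratory
diagnostics who want a reproducible, fully testable reference pipeline
that runs without access to private clinical audio.

## Method

A recording is enhanced (log-spectral-amplitude MMSE noise
suppression), peak-normalized to −0.1 dBFS, and segmented into *cough
chunks* by thresholding the frame log energy
`E = 20·log10(sqrt(mean(a_i^2)))` at −36 dBFS. Each chunk yields a
20-dimensional feature — frame log energy plus mel-frequency cepstral
coefficients c1–c19, averaged over frames — and the patient's disease
feature is the componentwise mean over their chunks:

    x_k = (1/n) · Σ_i x_ki ,   x_ki ∈ R^20

which handles chunks that carry no disease information without needing
chunk-level labels. Classification is by a soft-margin SVM,

    min_{w,b,ξ}  ½‖w‖² + C·Σ ξ_i   s.t.  y_i(w·x_i + b) ≥ 1 − ξ_i,  ξ_i ≥ 0

(linear or RBF kernel, `f(x) = sign(w·x + b)`), or by an LSTM sequence
classifier (32 hidden units → fully-connected → softmax, Adam,
cross-entropy) on per-patient frame sequences of length 50. Chunk sets
can be enlarged by time shifting (≤ 0.1 s, tone-filled), upward pitch
shifting (≤ 5 semitones, ratio 2^(s/12)) and white/pink noise mixing,
giving the dataset variants RAW/AR/BR/CR/DR/ER with n/2n/2n/2n/3n/4n
chunks. Evaluation is by repeated random patient-level splits (45
trials, test set 17 bronchitis + 15 pneumonia by default) reporting
accuracy mean ± SD, per-class precision/recall/F1, confusion matrices
and ROC/AUC.

A seeded synthetic corpus generator (`synth_corpus()`) emulates the
structure of a hospital corpus — 173 patients (91/82), mean duration
3.92 s, 1–6 coughs per recording, speech-like distractors, background
noise, and a configurable spectral class effect — so every stage is
testable end to end without clinical data.

## Worked example

```r
library(coughclass)

spec   <- corpus_spec(n_bronchitis = 20, n_pneumonia = 20,
                      class_effect_hz = 60, seed = 42)
corpus <- synth_corpus(spec)
corpus
#> <cough_corpus> 40 patients (20 bronchitis / 20 pneumonia)
#>   mean duration 4.06 s, 99 cough bursts total

report <- run_pipeline(corpus, model = "svm", enhance = FALSE,
                       eval_spec = split_spec(n_trials = 10,
                                              test_bronchitis = 4,
                                              test_pneumonia = 4, seed = 1))
report
#> <eval_report> svm, 10 trials
#>   accuracy: 91.25% +/- 11.86%
#>   pooled AUC: 0.981
#>   bronchitis P=80.00% R=100.00% F1=88.89%
#>   pneumonia  P=100.00% R=75.00% F1=85.71%
#>   confusion (last trial, rows true / cols predicted):
#>     pred
#> true -1 1
#>   -1  4 0
#>   1   1 3
```

The corpus injects a weak 60 Hz spectral separation between the two
classes' cough bursts. Over 10 random splits the SVM recovers it at
91% mean accuracy (the ±11.86% SD reflects the 8-patient test sets);
the pooled AUC of 0.981 is the threshold-free ranking quality of the
SVM margins. Per-class rows read: of patients predicted bronchitis,
80% were bronchitis (precision); all true bronchitis patients were
found (recall). With `class_effect_hz = 0` the same pipeline sits at
chance — the discrimination comes from the injected effect, not the
plumbing.

A command-line front end covering every stage (simulate, preprocess,
segment, augment, features, evaluate, run) is installed at
`system.file("cli/coughclass.R", package = "coughclass")`.

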