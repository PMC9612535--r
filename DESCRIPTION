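Package: coughclass
Title: Cough-Sound Classification of Pediatric Bronchitis and Pneumonia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying pediatric respiratory
    disease (bronchitis versus pneumonia) from patient audio recordings.
    Recordings are enhanced with a log-spectral MMSE noise suppressor,
    peak-normalized, and segmented into cough chunks by frame log-energy
    thresholding. Chunks can be augmented by time shifting, pitch shifting
    and white/pink noise mixing. Each chunk is summarized by a
    20-dimensional feature vector (frame log energy plus 19 mel-frequency
    cepstral coefficients) and chunk features are aggregated per patient by
    their componentwise mean. Classifiers (soft-margin SVM and an LSTM
    sequence model) are evaluated under a repeated random patient-level
    split protocol with accuracy, per-class precision/recall/F1, confusion
    matrices and ROC/AUC. A seeded synthetic corpus generator emulates the
    structure of hospital cough recordings so the whole pipeline can be
    exercised without private clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    withr
Config/testthat/edition: 3
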