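#' Write a corpus to WAV files plus labels and interval CSVs
#'
#' @param corpus A `cough_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes one WAV per patient, `labels.csv`
#'   (`patient_id`, `label`, `file`) and `intervals.csv` with the
#'   ground-truth cough spans.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(corpus$patient_id, ".wav")
  for (i in seq_along(corpus$audios)) {
    write_wav(corpus$audios[[i]], file.path(dir, files[i]))
  }
  utils::write.csv(
    data.frame(patient_id = corpus$patient_id, label = corpus$label,
               file = files),
    file.path(dir, "labels.csv"), row.names = FALSE)
  iv <- do.call(rbind, lapply(seq_along(corpus$audios), function(i) {
    ci <- corpus$audios[[i]]$cough_intervals
    if (is.null(ci) || nrow(ci) == 0) return(NULL)
    cbind(patient_id = corpus$patient_id[i], ci)
  }))
  if (!is.null(iv)) utils::write.csv(iv, file.path(dir, "intervals.csv"),
                                     row.names = FALSE)
  invisible(dir)
}

#' Read a corpus from a directory of WAV files
#'
#' Expects a `labels.csv` with columns `patient_id`, `label`, `file`.
#'
#' @param dir Input directory.
#' @return A `cough_corpus`.
#' @export
read_corpus <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("missing labels file: ", lab_path)
  lab <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  audios <- lapply(seq_len(nrow(lab)), function(i) {
    read_wav(file.path(dir, lab$file[i]),
             patient_id = lab$patient_id[i], label = lab$label[i])
  })
  structure(list(audios = audios, patient_id = lab$patient_id,
                 label = lab$label, spec = NULL),
            class = "cough_corpus")
}

#' Segment every recording of a corpus into cough chunks
#'
#' @param corpus A `cough_corpus` (recordings should be preprocessed /
#'   peak-normalized first so the energy threshold is meaningful).
#' @param cfg A [segmentation_config()].
#' @return A flat list of `cough_chunk` objects.
#' @export
segment_corpus <- function(corpus, cfg = segmentation_config()) {
  unlist(lapply(corpus$audios, segment_audio, cfg = cfg), recursive = FALSE)
}

#' Run the full classification pipeline
#'
#' Stage order: preprocess (resample to `target_rate`, optional
#' log-MMSE enhancement, peak normalization), energy-threshold
#' segmentation into cough chunks, optional augmentation variant,
#' 20-dimensional feature extraction with per-patient mean aggregation,
#' repeated random-split evaluation of the chosen classifier.
#'
#' @param input A `cough_corpus` or a directory readable by
#'   [read_corpus()].
#' @param model `"svm"` or `"lstm"`.
#' @param dataset Augmentation variant (`"RAW"`, `"AR"`, `"BR"`,
#'   `"CR"`, `"DR"`, `"ER"`).
#' @param out_dir Optional output directory for the feature table,
#'   evaluation report (JSON) and pooled ROC points (CSV).
#' @param target_rate Standardized sample rate, Hz.
#' @param target_db Peak normalization level, dBFS.
#' @param enhance Apply log-MMSE enhancement?
#' @param seg_cfg,mfcc_cfg,eval_spec,model_cfg Stage configurations.
#' @param seed Global seed propagated to augmentation and evaluation.
#' @return The `eval_report`.
#' @export
run_pipeline <- function(input, model = c("svm", "lstm"), dataset = "RAW",
                         out_dir = NULL, target_rate = 44100,
                         target_db = -0.1, enhance = TRUE,
                         seg_cfg = segmentation_config(),
                         mfcc_cfg = mfcc_config(),
                         eval_spec = split_spec(),
                         model_cfg = NULL, seed = 1L) {
  model <- match.arg(model)
  corpus <- if (inherits(input, "cough_corpus")) input else read_corpus(input)
  corpus$audios <- lapply(corpus$audios, preprocess_audio,
                          target_rate = target_rate, target_db = target_db,
                          enhance = enhance)
  chunks <- segment_corpus(corpus, seg_cfg)
  if (length(chunks) == 0) stop("segmentation produced no cough chunks")
  chunks <- build_dataset(chunks, augmentation_spec(dataset, seed = seed))
  feats <- patient_features(chunks, mfcc_cfg,
                            sequences = (model == "lstm"),
                            time_step = if (model == "lstm") {
                              if (is.null(model_cfg)) 50 else model_cfg$time_step
                            } else 50)
  eval_spec$seed <- as.integer(seed)
  report <- repeated_eval(feats, model = model, spec = eval_spec,
                          model_cfg = model_cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(report$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(model = model, dataset = dataset, seed = seed,
           n_trials = report$n_trials,
           per_trial_accuracy = report$per_trial_accuracy,
           mean_accuracy = report$mean_accuracy,
           sd_accuracy = report$sd_accuracy,
           auc = report$auc,
           per_class = report$per_class,
           confusion = as.data.frame(as.table(report$confusion))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
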