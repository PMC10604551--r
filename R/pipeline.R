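#' Run the full desk-scale experiment
#'
#' Generates a seeded synthetic dataset, trains the detector on its train
#' split, runs detection on the test split and evaluates it — the complete
#' generate/train/detect/evaluate pipeline in one seeded call. All
#' randomness (scene content, splits, weight init, batch order) derives
#' from `seed`, so repeated single-threaded runs are byte-identical.
#'
#' @param work_dir working directory for the dataset, checkpoints,
#'   predictions and report.
#' @param seed master seed.
#' @param n_pos,n_neg synthetic tile counts (defaults 150/100).
#' @param split_ratio train fraction (default 0.8, i.e. 200 train /
#'   50 held-out at the default counts).
#' @param template a [scene_spec()] describing tile appearance.
#' @param epochs,batch_size,learning_rate training schedule (defaults 20,
#'   8, 0.001).
#' @param backbone a [backbone_config()]; defaults to the `tiny` variant.
#' @param iou_thresh,tau evaluation thresholds (defaults 0.5, 0.5).
#' @param quiet suppress progress messages.
#' @return List with `report` (an `eval_report`), `history` (per-epoch
#'   losses), `predictions`, and file paths.
#' @export
run_experiment <- function(work_dir, seed = 1L, n_pos = 150L, n_neg = 100L,
                           split_ratio = 0.8, template = scene_spec(),
                           epochs = 20L, batch_size = 8L,
                           learning_rate = 0.001,
                           backbone = backbone_config(tiny = TRUE),
                           iou_thresh = 0.5, tau = 0.5, quiet = FALSE) {
  dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(work_dir, "data")
  if (!quiet) message("generating ", n_pos + n_neg, " synthetic tiles ...")
  man <- generate_dataset(data_dir, n_pos, n_neg, template = template,
                          seed = seed, split_ratio = split_ratio,
                          overwrite = TRUE)
  cfg <- train_config(learning_rate = learning_rate, batch_size = batch_size,
                      epochs = epochs, split_ratio = split_ratio, seed = seed,
                      backbone = backbone)
  if (!quiet) message("training (", sum(man$split == "train"), " tiles, ",
                      epochs, " epochs) ...")
  fit <- train_circlenet(data_dir, cfg,
                         log_path = file.path(work_dir, "train_log.jsonl"),
                         quiet = quiet)
  # low confidence floor so the PR curve is swept past the interactive default
  preds <- detect_circles(fit$net, data_dir, score_threshold = 0.05,
                          out_csv = file.path(work_dir, "predictions.csv"))
  gts <- read_annotations_csv(file.path(data_dir, "annotations.csv"))
  test_files <- man$file[man$split == "test"]
  gts <- gts[gts$file %in% test_files, , drop = FALSE]
  report <- evaluate_predictions(preds, gts, images = test_files,
                                 iou_thresh = iou_thresh, tau = tau,
                                 out_json = file.path(work_dir, "report.json"))
  if (!quiet) print(report)
  list(report = report, history = fit$history, predictions = preds,
       data_dir = data_dir, checkpoint_path = fit$checkpoint_path,
       report_path = file.path(work_dir, "report.json"))
}
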