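## Frozen desk-scale study conditions shared by the test suite and the
## acceptance script: compact chart geometry, a scaled-down dense-SK
## network (same code path as the full DenseNet121, smaller config), and
## the published training recipe at smoke length.

#' Desk-scale chart geometry and network configuration
#'
#' `smoke_layout()` is a 48 x 72 px chart holding 480 s of signal with the
#' FHR and UC bands adjacent, so convolutional receptive fields span both
#' channels at low resolution. `smoke_model_config()` is the matching
#' dense-SK network: growth rate 6, two dense blocks of two layers,
#' bottleneck 2, a 3x3 stem with max pooling, single-channel input.
#'
#' @return A `ctg_layout` / `model_config`.
#' @export
smoke_layout <- function() compact_layout(72, 48, duration_s = 480)

#' @rdname smoke_layout
#' @export
smoke_model_config <- function() {
  model_config(growth_rate = 6, block_layout = c(2, 2), num_classes = 2,
               input_size = c(48, 72), in_channels = 1, bn_size = 2,
               stem_channels = 6, stem_kernel = 3, stem_stride = 1,
               stem_pool = TRUE)
}

#' Smoke training run on separable synthetic charts
#'
#' Generates `n_records` charts split evenly between Class I (normal) and
#' Class III (abnormal) recipes — visually separable classes — splits 7:3
#' stratified, and trains the desk-scale dense-SK network with the
#' published recipe (Adam, learning rate 0.001, batch 32, focal loss) for
#' `epochs` epochs.
#'
#' @param n_records Dataset size (default 200).
#' @param seed Controls dataset, split, initialization, and shuffling.
#' @param epochs Training epochs (default 10).
#' @return A list: `report` (test-set `eval_report`), `history`, `fit`.
#' @export
run_smoke_training <- function(n_records = 200, seed = 1, epochs = 10) {
  lay <- smoke_layout()
  ds <- make_dataset(n_records, c(I = 0.5, II = 0, III = 0.5),
                     seed = seed, layout = lay)
  sp <- split_dataset(ds, c(0.7, 0.3), seed = seed)
  xtr <- charts_to_tensor(sp$train$chart)
  xte <- charts_to_tensor(sp$test$chart)
  mod <- build_model(smoke_model_config(), sk_config(), seed = seed)
  fit <- train_model(mod, xtr, dataset_labels(sp$train),
                     train_config(epochs = epochs, seed = seed),
                     xte, dataset_labels(sp$test))
  list(report = evaluate_model(fit$model, sp$test),
       history = fit$history, fit = fit)
}

#' Bimodal versus UC-masked ablation on timing-defined classes
#'
#' For each seed, generates a timing-defined dataset (early versus late
#' decelerations, identical FHR morphology distribution) and trains two
#' identically configured networks: one on the full two-band chart, one
#' with the UC band masked. Only the bimodal model can exploit the
#' FHR--UC lag that defines the abnormal class.
#'
#' @param seeds Integer vector of study seeds.
#' @param n_records Records per seed (default 160).
#' @param epochs Training epochs per run (default 15).
#' @return A tibble: `seed`, `bimodal_auc`, `masked_auc`.
#' @export
run_bimodal_study <- function(seeds = 1:3, n_records = 160, epochs = 15) {
  cfg <- model_config(growth_rate = 8, block_layout = c(2, 2),
                      num_classes = 2, input_size = c(32, 120),
                      in_channels = 1, bn_size = 2, stem_channels = 8,
                      stem_kernel = 3, stem_stride = 1, stem_pool = TRUE)
  rows <- lapply(seeds, function(sd) {
    ds <- make_timing_dataset(n_records, seed = sd)
    sp <- split_dataset(ds, c(0.7, 0.3), seed = sd)
    aucs <- vapply(c(FALSE, TRUE), function(mask) {
      xtr <- charts_to_tensor(sp$train$chart, mask_uc = mask)
      xte <- charts_to_tensor(sp$test$chart, mask_uc = mask)
      mod <- build_model(cfg, sk_config(), seed = sd)
      fit <- train_model(mod, xtr, dataset_labels(sp$train),
                         train_config(epochs = epochs, seed = sd),
                         xte, dataset_labels(sp$test))
      evaluate_model(fit$model, sp$test, mask_uc = mask)$auc
    }, numeric(1))
    tibble::tibble(seed = sd, bimodal_auc = aucs[1], masked_auc = aucs[2])
  })
  dplyr::bind_rows(rows)
}
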