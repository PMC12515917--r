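#' Training configuration
#'
#' The published training recipe: 100 epochs, learning rate 0.001, batch
#' size 32, Adam, focal loss, and a 7:3 train/test split. Desk-scale smoke
#' runs shorten `epochs`.
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param optimizer Only `"adam"` is implemented.
#' @param loss `"focal"` or `"cross_entropy"` (focal with gamma 0,
#'   alpha 1).
#' @param gamma,alpha Focal-loss parameters.
#' @param split Train/test fractions, summing to 1.
#' @param seed Seed for shuffling and any split derived from this config.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 100, learning_rate = 0.001,
                         batch_size = 32, optimizer = "adam",
                         loss = c("focal", "cross_entropy"), gamma = 2,
                         alpha = 0.25, split = c(0.7, 0.3), seed = 1) {
  loss <- match.arg(loss)
  stopifnot(abs(sum(split) - 1) < 1e-8, epochs >= 0, batch_size >= 1)
  if (loss == "cross_entropy") { gamma <- 0; alpha <- 1 }
  structure(as.list(environment()), class = "train_config")
}

#' Stratified train/test split
#'
#' Splits a dataset tibble into disjoint, exhaustive train and test parts,
#' stratified by `binary_label` with largest-remainder rounding of the
#' per-stratum counts (326 records at 7:3 give 228 train / 98 test), and
#' reproducible under `seed`.
#'
#' @param dataset A tibble with a `binary_label` column (e.g. from
#'   [make_dataset()]).
#' @param fractions Length-2 train/test fractions summing to 1.
#' @param seed Integer seed.
#' @param stratify Stratify by label (default `TRUE`).
#' @return A list with `train` and `test` tibbles.
#' @export
split_dataset <- function(dataset, fractions = c(0.7, 0.3), seed = 1,
                          stratify = TRUE) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- nrow(dataset)
  n_train_total <- largest_remainder(n, fractions)[1]
  with_seed(seed, {
    if (stratify) {
      labs <- dataset$binary_label
      strata <- split(seq_len(n), labs)
      per <- largest_remainder(n_train_total,
                               vapply(strata, length, numeric(1)) / n)
      train_idx <- unlist(lapply(seq_along(strata), function(k) {
        idx <- sample(strata[[k]])
        idx[seq_len(per[k])]
      }))
    } else {
      train_idx <- sample(n, n_train_total)
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) > 0 && length(train_idx) > 0 &&
      any(fractions > 0 & fractions < 1)) {
    lt <- unique(dataset$binary_label)
    if (stratify && (!all(lt %in% dataset$binary_label[train_idx]) ||
                     !all(lt %in% dataset$binary_label[test_idx]))) {
      stop("a class is absent from one side of the stratified split",
           call. = FALSE)
    }
  }
  list(train = dataset[train_idx, ], test = dataset[test_idx, ])
}

## ---- batch-norm state bookkeeping --------------------------------------

# collect references to every batch-norm state environment in the model,
# including those inside SK submodule skeletons
collect_bn_states <- function(model) {
  envs <- list()
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$type)) {
        if (x$type %in% c("bn", "bn1d")) {
          envs[[length(envs) + 1]] <<- x$state
        } else if (x$type == "sk") {
          for (sub in x$cfg$sub) walk(sub)
        }
        return(invisible())
      }
      for (el in x) walk(el)
    }
  }
  walk(list(model$net$stem, model$net$blocks, model$net$final_bn))
  envs
}

snapshot_bn <- function(envs) {
  lapply(envs, function(e) list(rm = e$rm, rv = e$rv))
}

restore_bn <- function(envs, snap) {
  for (i in seq_along(envs)) {
    envs[[i]]$rm <- snap[[i]]$rm
    envs[[i]]$rv <- snap[[i]]$rv
  }
}

## ---- Adam -------------------------------------------------------------

adam_new <- function(pflat) {
  list(m = lapply(pflat, function(p) p * 0),
       v = lapply(pflat, function(p) p * 0),
       t = 0, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, pflat, gflat, lr) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(pflat)) {
    g <- gflat[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    pflat[[nm]] <- pflat[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, pflat = pflat)
}

## ---- training loop ----------------------------------------------------

#' Train a model on labeled chart tensors
#'
#' Mini-batch Adam with focal loss. Per-epoch mean training loss (and
#' validation accuracy, when a validation set is given) is recorded; the
#' parameters with the best validation accuracy are restored at the end.
#' Training aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param model A `ctg_model` from [build_model()].
#' @param x Input tensor `(H, W, N, C)` (see [charts_to_tensor()]).
#' @param y Integer labels in `1..num_classes` (1 = normal, 2 = abnormal)
#'   or a factor with those levels.
#' @param cfg A [train_config()].
#' @param x_val,y_val Optional validation set for checkpoint selection.
#' @param verbose Print per-epoch progress.
#' @return A list: `model` (fitted), `history` (tibble of epoch, loss,
#'   val_accuracy), `best_epoch`.
#' @export
train_model <- function(model, x, y, cfg = train_config(), x_val = NULL,
                        y_val = NULL, verbose = FALSE) {
  y <- as_label_int(y)
  n <- dim(x)[3]
  stopifnot(length(y) == n)
  pflat <- flatten_params(model_params(model))
  opt <- adam_new(pflat)
  bn_envs <- collect_bn_states(model)
  history <- list()
  best_acc <- -Inf
  best_pflat <- pflat
  best_bn <- NULL
  best_epoch <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed * 1000 + ep, sample(n))
    losses <- c()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      xb <- x[, , idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- model_forward(model, xb, train = TRUE)
      fg <- focal_loss_grad(fwd$logits, yb, cfg$gamma, cfg$alpha)
      if (!is.finite(fg$loss)) {
        stop("training diverged: loss is not finite at epoch ", ep,
             call. = FALSE)
      }
      losses <- c(losses, fg$loss)
      bwd <- model_backward(model, fwd$caches, fg$dlogits)
      st <- adam_step(opt, pflat, flatten_params(bwd$grads),
                      cfg$learning_rate)
      opt <- st$opt
      pflat <- st$pflat
      model <- model_set_params(model, assign_flat(model_params(model),
                                                   pflat))
    }
    val_acc <- NA_real_
    if (!is.null(x_val)) {
      pv <- predict_model(model, x_val)
      val_acc <- mean(max.col(pv) == as_label_int(y_val))
      if (val_acc > best_acc) {
        best_acc <- val_acc
        best_pflat <- pflat
        best_bn <- snapshot_bn(bn_envs)
        best_epoch <- ep
      }
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                    val_accuracy = val_acc)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f val_acc %.3f", ep,
                      mean(losses), val_acc))
    }
  }
  if (!is.null(x_val) && cfg$epochs > 0) {
    model <- model_set_params(model, assign_flat(model_params(model),
                                                 best_pflat))
    if (!is.null(best_bn)) restore_bn(bn_envs, best_bn)
  }
  list(model = model,
       history = dplyr::bind_rows(history),
       best_epoch = best_epoch)
}

as_label_int <- function(y) {
  if (is.factor(y)) return(as.integer(y))
  if (is.character(y)) {
    return(as.integer(factor(y, levels = c("normal", "abnormal"))))
  }
  as.integer(y)
}

#' Predict class probabilities
#'
#' @param model A `ctg_model`.
#' @param x Input tensor `(H, W, N, C)`.
#' @param batch_size Forward batch size.
#' @return An `N x num_classes` probability matrix (softmax of logits),
#'   computed in evaluation mode (running batch-norm statistics).
#' @export
predict_model <- function(model, x, batch_size = 64) {
  n <- dim(x)[3]
  out <- NULL
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    fwd <- model_forward(model, x[, , idx, , drop = FALSE], train = FALSE)
    out <- rbind(out, softmax(fwd$logits))
  }
  out
}
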