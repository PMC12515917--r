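#' Generate a stratified synthetic chart dataset
#'
#' Builds `n_records` simulated CTG records with ground-truth three-tier
#' classes drawn from `class_mix` (largest-remainder rounding), renders
#' each into a chart image, and labels them normal (Class I) or abnormal
#' (Class II/III). Class recipes: Class I records have a normal baseline,
#' moderate variability and at most benign events (accelerations, early
#' decelerations); Class II records have minimal variability or a
#' tachycardic baseline; Class III records have near-absent variability
#' with recurrent late decelerations, half of them also bradycardic.
#'
#' @param n_records Number of records (> 0).
#' @param class_mix Named or ordered proportions for classes I, II, III;
#'   must sum to 1. The default mirrors a 224:51:51 normal/pathological
#'   cohort split with the abnormal half divided evenly.
#' @param seed Integer seed; the label sequence and every record are
#'   reproducible.
#' @param layout Chart geometry for rendering.
#' @param duration_s Record duration; must fit the layout.
#' @param render Render charts (set `FALSE` for record-only datasets).
#' @return A tibble with `id`, `figo_class`, `binary_label`, `record`
#'   (list of `ctg_record`), and `chart` (list of `ctg_chart` or `NULL`).
#' @export
make_dataset <- function(n_records, class_mix = c(I = 224 / 326,
                                                  II = 51 / 326,
                                                  III = 51 / 326),
                         seed = 1, layout = compact_layout(),
                         duration_s = 480, render = TRUE) {
  if (n_records <= 0) stop("n_records must be positive", call. = FALSE)
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix proportions must sum to 1", call. = FALSE)
  }
  counts <- largest_remainder(n_records, class_mix)
  with_seed(seed, {
    classes <- sample(rep(c("I", "II", "III"), counts))
    seeds <- sample.int(1e8, n_records)
  })
  rows <- purrr::map(seq_len(n_records), function(i) {
    rec <- simulate_class_record(classes[i], seeds[i], duration_s)
    chart <- if (render) render_chart(rec, layout)
    tibble::tibble(
      id = i, figo_class = classes[i],
      binary_label = to_binary(classes[i]),
      record = list(rec), chart = list(chart)
    )
  })
  dplyr::bind_rows(rows)
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  fl <- floor(raw)
  left <- n - sum(fl)
  if (left > 0) {
    add <- order(raw - fl, decreasing = TRUE)[seq_len(left)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

simulate_class_record <- function(figo_class, seed, duration_s) {
  with_seed(seed, {
    sub <- sample.int(1e8, 4)
    base <- min(max(stats::rnorm(1, 142, 8), 125), 155)
    rec <- switch(figo_class,
      I = {
        r <- simulate_record(sim_params(
          baseline_bpm = base, variability_amp = stats::runif(1, 8, 14),
          contraction_rate = 3, duration_s = duration_s, seed = sub[1]))
        ctr <- which(r$events$kind == "contraction")
        if (stats::runif(1) < 0.5) {
          r <- try_inject(r, inject_acceleration,
                          onset_s = stats::runif(1, 0.2, 0.6) * duration_s,
                          height = stats::runif(1, 16, 22), duration_s = 30)
        }
        if (length(ctr) >= 1 && stats::runif(1) < 0.3) {
          r <- try_inject(r, inject_deceleration, "early_decel",
                          sample(length(ctr), 1),
                          depth = stats::runif(1, 20, 30), duration_s = 80)
        }
        r
      },
      II = {
        if (stats::runif(1) < 0.5) {
          simulate_record(sim_params(
            baseline_bpm = base,
            variability_amp = stats::runif(1, 2.5, 5),
            contraction_rate = 3, duration_s = duration_s, seed = sub[1]))
        } else {
          simulate_record(sim_params(
            baseline_bpm = stats::runif(1, 163, 175),
            variability_amp = stats::runif(1, 8, 14),
            contraction_rate = 3, duration_s = duration_s, seed = sub[1]))
        }
      },
      III = {
        b3 <- if (stats::runif(1) < 0.5) stats::runif(1, 95, 105) else base
        r <- simulate_record(sim_params(
          baseline_bpm = b3, variability_amp = stats::runif(1, 0.5, 1.5),
          contraction_rate = 4, duration_s = duration_s, seed = sub[1]))
        ctr <- which(r$events$kind == "contraction")
        for (ci in ctr) {
          r <- try_inject(r, inject_deceleration, "late_decel", ci,
                          depth = stats::runif(1, 25, 45), duration_s = 80,
                          lag_s = stats::runif(1, 25, 40))
        }
        r
      },
      stop("unknown class ", figo_class)
    )
    rec$figo_class <- figo_class
    rec$binary_label <- to_binary(figo_class)
    rec
  })
}

try_inject <- function(rec, fn, ...) {
  tryCatch(fn(rec, ...), error = function(e) rec)
}

#' Generate a timing-defined bimodal test dataset
#'
#' Normal and abnormal classes differ only in FHR--UC timing. Deceleration
#' nadir times, depths, and lags are drawn by an identical procedure for
#' both classes, so the FHR channel is class-independent by construction;
#' the contraction bumps are then placed either at the nadirs (normal:
#' early decelerations) or a 35--60 s lag ahead of them (abnormal: late
#' decelerations, whose nadir lags the contraction peak). With the UC
#' channel masked the classes are therefore indistinguishable — the
#' construction isolates the value of the second modality.
#'
#' @param n_records,seed,layout,duration_s As in [make_dataset()].
#' @param n_decels Decelerations (and contractions) per record.
#' @return A tibble like [make_dataset()].
#' @export
make_timing_dataset <- function(n_records, seed = 1,
                                layout = compact_layout(120, 32, 600),
                                duration_s = 600, n_decels = 3) {
  with_seed(seed, {
    labels <- sample(rep(c("normal", "abnormal"),
                         largest_remainder(n_records, c(0.5, 0.5))))
    seeds <- sample.int(1e8, n_records)
  })
  rows <- purrr::map(seq_len(n_records), function(i) {
    rec <- with_seed(seeds[i], {
      r <- simulate_record(sim_params(
        baseline_bpm = stats::runif(1, 130, 150),
        variability_amp = stats::runif(1, 6, 9),
        contraction_rate = 0, duration_s = duration_s,
        seed = sample.int(1e8, 1)))
      # jittered grid of nadir times, identical law for both classes
      spacing <- (duration_s - 240) / max(n_decels - 1, 1)
      nadirs <- 120 + (seq_len(n_decels) - 1) * spacing +
        stats::runif(n_decels, -20, 20)
      lags <- stats::runif(n_decels, 35, 60)
      depths <- stats::runif(n_decels, 30, 45)
      amps <- stats::runif(n_decels, 45, 65)
      for (k in seq_len(n_decels)) {
        peak <- if (labels[i] == "normal") nadirs[k] else nadirs[k] - lags[k]
        r <- inject_contraction(r, peak, amps[k],
                                stats::runif(1, 60, 80))
      }
      for (k in seq_len(n_decels)) {
        r <- if (labels[i] == "normal") {
          try_inject(r, inject_deceleration, "early_decel", k,
                     depth = depths[k], duration_s = 80)
        } else {
          try_inject(r, inject_deceleration, "late_decel", k,
                     depth = depths[k], duration_s = 80, lag_s = lags[k])
        }
      }
      r$binary_label <- labels[i]
      r
    })
    tibble::tibble(
      id = i, figo_class = NA_character_, binary_label = labels[i],
      record = list(rec), chart = list(render_chart(rec, layout))
    )
  })
  dplyr::bind_rows(rows)
}

#' Convert charts to a network input tensor
#'
#' Inverts intensity (trace becomes 1, paper 0), optionally blanks the UC
#' band (the unimodal "FHR only" ablation), and bilinearly resizes to the
#' network input size.
#'
#' @param charts List of `ctg_chart` matrices.
#' @param input_hw Target `(height, width)` in pixels; `NULL` keeps the
#'   chart resolution.
#' @param mask_uc Blank the UC band before resizing.
#' @return An `(H, W, N, 1)` array in \[0, 1\].
#' @export
charts_to_tensor <- function(charts, input_hw = NULL, mask_uc = FALSE) {
  mats <- lapply(charts, function(ch) {
    lay <- attr(ch, "layout")
    g <- unclass(ch)
    if (mask_uc && !is.null(lay)) {
      g[(lay$uc_band[1] + 1L):(lay$uc_band[2] + 1L), ] <- 255
    }
    g <- 1 - g / 255
    if (!is.null(input_hw)) g <- resize_bilinear(g, input_hw[1], input_hw[2])
    g
  })
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  x <- array(0, c(H, W, length(mats), 1))
  for (i in seq_along(mats)) x[, , i, 1] <- mats[[i]]
  x
}

resize_bilinear <- function(img, h2, w2) {
  h1 <- nrow(img); w1 <- ncol(img)
  ry <- (seq_len(h2) - 0.5) * h1 / h2 + 0.5
  rx <- (seq_len(w2) - 0.5) * w1 / w2 + 0.5
  y0 <- pmin(pmax(floor(ry), 1), h1); y1 <- pmin(y0 + 1, h1)
  x0 <- pmin(pmax(floor(rx), 1), w1); x1 <- pmin(x0 + 1, w1)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * (1 - fy) + img[y1, x0, drop = FALSE] * fy
  a * rep(1 - fx, each = h2) +
    (img[y0, x1, drop = FALSE] * (1 - fy) +
       img[y1, x1, drop = FALSE] * fy) * rep(fx, each = h2)
}

dataset_labels <- function(dataset) {
  factor(dataset$binary_label, levels = c("normal", "abnormal"))
}
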