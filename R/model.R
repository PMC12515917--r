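#' Dense network configuration
#'
#' Architecture hyperparameters for the densely connected backbone. The
#' defaults are the DenseNet121 reference: growth rate K = 32, block layout
#' (6, 12, 24, 16) with bottleneck factor 4, transition compression 0.5, a
#' 7x7/2 stem with 3x3/2 max pooling, and 224 x 224 RGB input. Smaller
#' configurations (fewer blocks, smaller K, gentler stem) use the same code
#' path for desk-scale training.
#'
#' @param growth_rate Channels added by each dense layer (K).
#' @param block_layout Integer vector: dense layers per block.
#' @param num_classes Output classes (task default 2; reference 1000).
#' @param input_size Square input side in pixels.
#' @param in_channels Input channels (3 for RGB charts, 1 for grayscale).
#' @param bn_size Bottleneck width multiplier (1x1 conv outputs
#'   `bn_size * growth_rate` channels).
#' @param compression Transition channel compression factor.
#' @param stem_channels,stem_kernel,stem_stride,stem_pool Stem convolution
#'   width/kernel/stride and whether a 3x3/2 max pool follows.
#' @return A `model_config` list.
#' @export
model_config <- function(growth_rate = 32, block_layout = c(6, 12, 24, 16),
                         num_classes = 2, input_size = 224, in_channels = 3,
                         bn_size = 4, compression = 0.5,
                         stem_channels = 2 * growth_rate, stem_kernel = 7,
                         stem_stride = 2, stem_pool = TRUE) {
  stopifnot(growth_rate > 0, length(block_layout) >= 1, num_classes >= 2)
  structure(as.list(environment()), class = "model_config")
}

#' Selective-kernel attention configuration
#'
#' The SK module runs two 3x3 branch convolutions — dilation 1 and
#' dilation 2, the latter covering a 5x5 receptive field — fuses them by
#' summation, pools to a channel descriptor, compresses it to dimension
#' `d = max(C / reduction_ratio, dim_floor)`, and gates the two branches
#' per channel with a softmax that always sums to one. Branch convolutions
#' are grouped; with `conv_groups = 8` on the 32-channel dense-layer
#' operand the module budget matches the published 0.32M SK parameter
#' count.
#'
#' @param reduction_ratio Descriptor compression ratio r (default 16).
#' @param dim_floor Lower bound L on the descriptor dimension (default 32).
#' @param conv_groups Groups for the branch convolutions (clipped to the
#'   channel count).
#' @param insertion `"per_dense_layer"` (applied to each dense layer's
#'   K-channel output before concatenation, the default) or `"per_block"`
#'   (one SK on each block's concatenated output).
#' @return An `sk_config` list.
#' @export
sk_config <- function(reduction_ratio = 16, dim_floor = 32, conv_groups = 8,
                      insertion = c("per_dense_layer", "per_block")) {
  insertion <- match.arg(insertion)
  stopifnot(reduction_ratio >= 1, dim_floor >= 1, conv_groups >= 1)
  structure(list(reduction_ratio = reduction_ratio, dim_floor = dim_floor,
                 conv_groups = conv_groups, insertion = insertion),
            class = "sk_config")
}

#' Descriptor dimension of the SK fuse stage
#'
#' @param C Channel count of the SK operand.
#' @param cfg An [sk_config()].
#' @return `max(C / r, dim_floor)` as an integer.
#' @export
sk_fuse_dim <- function(C, cfg = sk_config()) {
  as.integer(max(C %/% cfg$reduction_ratio, cfg$dim_floor))
}

## ---- SK module --------------------------------------------------------

nn_sk <- function(C, cfg = sk_config()) {
  g <- min(cfg$conv_groups, C)
  while (C %% g != 0) g <- g - 1
  d <- sk_fuse_dim(C, cfg)
  sub <- list(
    conv1 = nn_conv(C, C, k = 3, pad = 1, dilation = 1, groups = g),
    bn1 = nn_bn(C),
    conv2 = nn_conv(C, C, k = 3, pad = 2, dilation = 2, groups = g),
    bn2 = nn_bn(C),
    bnz = nn_bn1d(d)
  )
  params <- lapply(sub, `[[`, "params")
  params$Wfuse <- he_init(c(C, d), C)
  params$A <- he_init(c(d, C), d)
  params$B <- he_init(c(d, C), d)
  list(type = "sk", params = params,
       cfg = list(C = C, d = d, groups = g,
                  sub = lapply(sub, function(m) { m$params <- NULL; m })))
}

with_params <- function(skel, p) { skel$params <- p; skel }

sum_hw <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colSums(x), d[3], d[4])
}

broadcast_nc <- function(m, H, W) {
  array(rep(as.vector(m), each = H * W), c(H, W, nrow(m), ncol(m)))
}

sk_forward <- function(mod, x, train = TRUE) {
  p <- mod$params
  cf <- mod$cfg
  d <- dim(x)
  H <- d[1]; W <- d[2]
  c1 <- conv_forward(with_params(cf$sub$conv1, p$conv1), x)
  b1 <- bn_forward(with_params(cf$sub$bn1, p$bn1), c1$y, train)
  r1 <- relu_forward(b1$y)
  c2 <- conv_forward(with_params(cf$sub$conv2, p$conv2), x)
  b2 <- bn_forward(with_params(cf$sub$bn2, p$bn2), c2$y, train)
  r2 <- relu_forward(b2$y)
  Y1 <- r1$y; Y2 <- r2$y
  gp <- gap_forward(Y1 + Y2)
  s <- gp$y                                   # (N, C)
  zlin <- s %*% p$Wfuse                       # (N, d)
  bz <- bn_forward(with_params(cf$sub$bnz, p$bnz), zlin, train)
  rz <- relu_forward(bz$y)
  z <- rz$y
  l1 <- z %*% p$A                             # (N, C)
  l2 <- z %*% p$B
  a <- 1 / (1 + exp(l2 - l1))                 # softmax over two branches
  ab <- broadcast_nc(a, H, W)
  V <- ab * Y1 + (1 - ab) * Y2
  list(y = V,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    gp = gp$cache, bz = bz$cache, rz = rz$cache,
                    Y1 = Y1, Y2 = Y2, s = s, z = z, a = a, ab = ab,
                    H = H, W = W))
}

sk_backward <- function(mod, cache, dy) {
  p <- mod$params
  cf <- mod$cfg
  H <- cache$H; W <- cache$W
  a <- cache$a
  da <- sum_hw(dy * cache$Y1)
  db <- sum_hw(dy * cache$Y2)
  dl1 <- (da - db) * a * (1 - a)
  dz <- dl1 %*% t(p$A) - dl1 %*% t(p$B)
  dA <- crossprod(cache$z, dl1)
  dB <- -dA
  drz <- dz * cache$rz
  bzb <- bn_backward(with_params(cf$sub$bnz, p$bnz), cache$bz, drz)
  dzlin <- bzb$dx
  dWfuse <- crossprod(cache$s, dzlin)
  ds <- tcrossprod(dzlin, p$Wfuse)
  dY <- gap_backward(cache$gp, ds)
  dY1 <- dy * cache$ab + dY
  dY2 <- dy * (1 - cache$ab) + dY
  d1 <- dY1 * cache$r1
  b1b <- bn_backward(with_params(cf$sub$bn1, p$bn1), cache$b1, d1)
  c1b <- conv_backward(with_params(cf$sub$conv1, p$conv1), cache$c1, b1b$dx)
  d2 <- dY2 * cache$r2
  b2b <- bn_backward(with_params(cf$sub$bn2, p$bn2), cache$b2, d2)
  c2b <- conv_backward(with_params(cf$sub$conv2, p$conv2), cache$c2, b2b$dx)
  list(dx = c1b$dx + c2b$dx,
       grads = list(conv1 = c1b$grads, bn1 = b1b$grads,
                    conv2 = c2b$grads, bn2 = b2b$grads,
                    bnz = bzb$grads, Wfuse = dWfuse, A = dA, B = dB))
}

## ---- dense layers / blocks --------------------------------------------

dense_layer_new <- function(cin, K, bn_size, skc = NULL) {
  lay <- list(
    bn1 = nn_bn(cin),
    conv1 = nn_conv(cin, bn_size * K, k = 1, pad = 0),
    bn2 = nn_bn(bn_size * K),
    conv2 = nn_conv(bn_size * K, K, k = 3, pad = 1)
  )
  if (!is.null(skc) && skc$insertion == "per_dense_layer") {
    lay$sk <- nn_sk(K, skc)
  }
  lay
}

dense_layer_forward <- function(lay, x, train) {
  b1 <- nn_forward(lay$bn1, x, train)
  r1 <- relu_forward(b1$y)
  c1 <- nn_forward(lay$conv1, r1$y, train)
  b2 <- nn_forward(lay$bn2, c1$y, train)
  r2 <- relu_forward(b2$y)
  c2 <- nn_forward(lay$conv2, r2$y, train)
  out <- c2$y
  skc <- NULL
  if (!is.null(lay$sk)) {
    sk <- nn_forward(lay$sk, out, train)
    out <- sk$y
    skc <- sk$cache
  }
  list(y = out, cache = list(b1 = b1$cache, r1 = r1$cache, c1 = c1$cache,
                             b2 = b2$cache, r2 = r2$cache, c2 = c2$cache,
                             sk = skc))
}

dense_layer_backward <- function(lay, cache, dnew) {
  grads <- list()
  d <- dnew
  if (!is.null(lay$sk)) {
    skb <- nn_backward(lay$sk, cache$sk, d)
    grads$sk <- skb$grads
    d <- skb$dx
  }
  c2b <- nn_backward(lay$conv2, cache$c2, d)
  r2b <- c2b$dx * cache$r2
  b2b <- nn_backward(lay$bn2, cache$b2, r2b)
  c1b <- nn_backward(lay$conv1, cache$c1, b2b$dx)
  r1b <- c1b$dx * cache$r1
  b1b <- nn_backward(lay$bn1, cache$b1, r1b)
  grads$bn1 <- b1b$grads
  grads$conv1 <- c1b$grads
  grads$bn2 <- b2b$grads
  grads$conv2 <- c2b$grads
  list(dx = b1b$dx, grads = grads)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3], da[4] + db[4]))
}

transition_new <- function(cin, compression) {
  cout <- floor(cin * compression)
  list(bn = nn_bn(cin), conv = nn_conv(cin, cout, k = 1, pad = 0),
       pool = nn_avgpool(), cout = cout)
}

#' Build the dense network with optional SK attention
#'
#' Constructs the densely connected classifier described by `model_cfg`,
#' inserting a selective-kernel module per dense layer (or per block) when
#' `sk_cfg` is given, and reports trainable parameter counts: the base
#' network, the SK modules alone, and the total. With the DenseNet121
#' reference configuration and a 1000-class head the base counts 7,978,856
#' parameters; the default SK insertion adds 322,944.
#'
#' @param model_cfg A [model_config()].
#' @param sk_cfg An [sk_config()] or `NULL` for the plain backbone.
#' @param seed Seed for weight initialization.
#' @return A `ctg_model`: list with `net`, `model_cfg`, `sk_cfg`, and
#'   `param_report` (`base`, `sk`, `total`).
#' @examples
#' m <- build_model(model_config(num_classes = 1000), sk_cfg = NULL)
#' m$param_report$total  # 7978856
#' @export
build_model <- function(model_cfg = model_config(), sk_cfg = NULL,
                        seed = 1) {
  stopifnot(inherits(model_cfg, "model_config"))
  if (!is.null(sk_cfg)) stopifnot(inherits(sk_cfg, "sk_config"))
  with_seed(seed, {
    cfgm <- model_cfg
    net <- list()
    net$stem <- list(
      conv = nn_conv(cfgm$in_channels, cfgm$stem_channels,
                     k = cfgm$stem_kernel, stride = cfgm$stem_stride,
                     pad = (cfgm$stem_kernel - 1) %/% 2),
      bn = nn_bn(cfgm$stem_channels),
      pool = if (cfgm$stem_pool) nn_maxpool()
    )
    C <- cfgm$stem_channels
    blocks <- list()
    for (bi in seq_along(cfgm$block_layout)) {
      layers <- list()
      for (li in seq_len(cfgm$block_layout[bi])) {
        layers[[li]] <- dense_layer_new(C, cfgm$growth_rate, cfgm$bn_size,
                                        sk_cfg)
        C <- C + cfgm$growth_rate
      }
      blk <- list(layers = layers)
      if (!is.null(sk_cfg) && sk_cfg$insertion == "per_block") {
        blk$sk <- nn_sk(C, sk_cfg)
      }
      if (bi < length(cfgm$block_layout)) {
        blk$transition <- transition_new(C, cfgm$compression)
        C <- blk$transition$cout
      }
      blocks[[bi]] <- blk
    }
    net$blocks <- blocks
    net$final_bn <- nn_bn(C)
    net$head <- nn_linear(C, cfgm$num_classes)
    net$final_channels <- C

    model <- structure(
      list(net = net, model_cfg = model_cfg, sk_cfg = sk_cfg),
      class = "ctg_model"
    )
    model$param_report <- count_params(model)
    model
  })
}

# collect the nested parameter tree of a model
model_params <- function(model) {
  net <- model$net
  walk <- function(x) {
    if (is.list(x) && !is.null(x$type)) return(x$params)
    if (is.list(x)) {
      out <- lapply(x, walk)
      out[!vapply(out, is.null, logical(1))]
    } else NULL
  }
  walk(list(stem = net$stem, blocks = net$blocks,
            final_bn = net$final_bn, head = net$head))
}

model_set_params <- function(model, ptree) {
  set_walk <- function(x, p) {
    if (is.list(x) && !is.null(x$type)) { x$params <- p; return(x) }
    if (is.list(x)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        x[[key]] <- set_walk(x[[key]], p[[i]])
      }
      return(x)
    }
    x
  }
  top <- list(stem = model$net$stem, blocks = model$net$blocks,
              final_bn = model$net$final_bn, head = model$net$head)
  top <- set_walk(top, ptree)
  model$net$stem <- top$stem
  model$net$blocks <- top$blocks
  model$net$final_bn <- top$final_bn
  model$net$head <- top$head
  model
}

#' Parameter counts of a built model
#'
#' @param model A `ctg_model`.
#' @return List with `base`, `sk`, and `total` trainable parameter counts.
#' @export
count_params <- function(model) {
  flat <- flatten_params(model_params(model))
  n_all <- sum(vapply(flat, length, numeric(1)))
  is_sk <- grepl("(^|\\.)sk\\.", names(flat))
  n_sk <- sum(vapply(flat[is_sk], length, numeric(1)))
  list(base = n_all - n_sk, sk = n_sk, total = n_all)
}

#' @export
print.ctg_model <- function(x, ...) {
  pr <- x$param_report
  cat(sprintf(
    "<ctg_model> %s blocks, K=%d, %d classes | params: base %s, SK %s, total %s\n",
    paste(x$model_cfg$block_layout, collapse = "-"),
    x$model_cfg$growth_rate, x$model_cfg$num_classes,
    format(pr$base, big.mark = ","), format(pr$sk, big.mark = ","),
    format(pr$total, big.mark = ",")
  ))
  invisible(x)
}

## ---- full-network forward / backward ----------------------------------

model_forward <- function(model, x, train = TRUE) {
  net <- model$net
  caches <- list()
  st <- net$stem
  cv <- nn_forward(st$conv, x, train)
  bn <- nn_forward(st$bn, cv$y, train)
  rl <- relu_forward(bn$y)
  h <- rl$y
  caches$stem <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  if (!is.null(st$pool)) {
    pl <- nn_forward(st$pool, h, train)
    h <- pl$y
    caches$stem$pool <- pl$cache
  }
  caches$blocks <- vector("list", length(net$blocks))
  for (bi in seq_along(net$blocks)) {
    blk <- net$blocks[[bi]]
    bl_cache <- list(layers = vector("list", length(blk$layers)))
    for (li in seq_along(blk$layers)) {
      lf <- dense_layer_forward(blk$layers[[li]], h, train)
      bl_cache$layers[[li]] <- lf$cache
      h <- concat_c(h, lf$y)
    }
    if (!is.null(blk$sk)) {
      skf <- nn_forward(blk$sk, h, train)
      bl_cache$sk <- skf$cache
      h <- skf$y
    }
    if (!is.null(blk$transition)) {
      tr <- blk$transition
      tb <- nn_forward(tr$bn, h, train)
      trl <- relu_forward(tb$y)
      tc <- nn_forward(tr$conv, trl$y, train)
      tp <- nn_forward(tr$pool, tc$y, train)
      bl_cache$transition <- list(bn = tb$cache, relu = trl$cache,
                                  conv = tc$cache, pool = tp$cache)
      h <- tp$y
    }
    caches$blocks[[bi]] <- bl_cache
  }
  fb <- nn_forward(net$final_bn, h, train)
  fr <- relu_forward(fb$y)
  gp <- gap_forward(fr$y)
  hd <- nn_forward(net$head, gp$y, train)
  caches$final <- list(bn = fb$cache, relu = fr$cache, gap = gp$cache,
                       head = hd$cache)
  list(logits = hd$y, caches = caches)
}

model_backward <- function(model, caches, dlogits) {
  net <- model$net
  grads <- list()
  hb <- nn_backward(net$head, caches$final$head, dlogits)
  grads$head <- hb$grads
  dg <- gap_backward(caches$final$gap, hb$dx)
  dr <- dg * caches$final$relu
  fbb <- nn_backward(net$final_bn, caches$final$bn, dr)
  grads$final_bn <- fbb$grads
  d <- fbb$dx
  grads$blocks <- vector("list", length(net$blocks))
  for (bi in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[bi]]
    bc <- caches$blocks[[bi]]
    bg <- list()
    if (!is.null(blk$transition)) {
      tr <- blk$transition
      tcb <- nn_backward(tr$conv, bc$transition$conv,
                         avgpool_backward(bc$transition$pool, d))
      trb <- tcb$dx * bc$transition$relu
      tbb <- nn_backward(tr$bn, bc$transition$bn, trb)
      bg$transition <- list(bn = tbb$grads, conv = tcb$grads)
      d <- tbb$dx
    }
    if (!is.null(blk$sk)) {
      skb <- nn_backward(blk$sk, bc$sk, d)
      bg$sk <- skb$grads
      d <- skb$dx
    }
    K <- model$model_cfg$growth_rate
    bg$layers <- vector("list", length(blk$layers))
    for (li in rev(seq_along(blk$layers))) {
      dd <- dim(d)
      Cin <- dd[4] - K
      dnew <- d[, , , Cin + seq_len(K), drop = FALSE]
      dprev <- d[, , , seq_len(Cin), drop = FALSE]
      lb <- dense_layer_backward(blk$layers[[li]], bc$layers[[li]], dnew)
      bg$layers[[li]] <- lb$grads
      d <- dprev + lb$dx
    }
    grads$blocks[[bi]] <- bg
  }
  if (!is.null(net$stem$pool)) {
    d <- nn_backward(net$stem$pool, caches$stem$pool, d)$dx
  }
  dsr <- d * caches$stem$relu
  sbb <- nn_backward(net$stem$bn, caches$stem$bn, dsr)
  scb <- nn_backward(net$stem$conv, caches$stem$conv, sbb$dx)
  grads$stem <- list(conv = scb$grads, bn = sbb$grads)
  list(dx = scb$dx, grads = grads)
}

## ---- losses ------------------------------------------------------------

#' Focal loss
#'
#' Mean of `-alpha * (1 - p_t)^gamma * log(p_t)` over the batch, where
#' `p_t` is the probability assigned to the true class. With `gamma = 0`
#' and `alpha = 1` this is the ordinary cross-entropy.
#'
#' @param probabilities Either an `N x K` matrix of class probabilities or
#'   a length-N vector of true-class probabilities `p_t`.
#' @param labels Integer class labels in `1..K` (ignored when
#'   `probabilities` is already `p_t`).
#' @param gamma Focusing exponent (default 2).
#' @param alpha Class-balance weight (default 0.25).
#' @return A single scalar loss.
#' @export
focal_loss <- function(probabilities, labels = NULL, gamma = 2,
                       alpha = 0.25) {
  pt <- if (is.matrix(probabilities)) {
    stopifnot(!is.null(labels), length(labels) == nrow(probabilities))
    probabilities[cbind(seq_len(nrow(probabilities)), labels)]
  } else probabilities
  if (any(pt <= 0)) {
    warning("true-class probability of 0 clamped to 1e-12", call. = FALSE)
    pt <- pmax(pt, 1e-12)
  }
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# focal loss and its gradient with respect to the logits
focal_loss_grad <- function(logits, labels, gamma = 2, alpha = 0.25) {
  N <- nrow(logits)
  p <- softmax(logits)
  idx <- cbind(seq_len(N), labels)
  pt <- pmax(p[idx], 1e-12)
  loss <- mean(-alpha * (1 - pt)^gamma * log(pt))
  # dL/dpt, then chain through softmax: dpt/dlogit_j = pt (delta_tj - p_j)
  dldpt <- alpha * (gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
                      (1 - pt)^gamma / pt) / N
  onehot <- matrix(0, N, ncol(logits))
  onehot[idx] <- 1
  dlogits <- dldpt * pt * (onehot - p)
  list(loss = loss, dlogits = dlogits, probs = p)
}
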