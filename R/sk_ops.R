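## Standalone selective-kernel operations (split / fuse / select) exposing
## the attention stages individually, plus a dense-block forward
## convenience. These wrap the same modules the full network uses.

#' Create a standalone SK attention module
#'
#' @param C Channel count of the operand.
#' @param cfg An [sk_config()].
#' @param seed Seed for weight initialization.
#' @return An SK module usable with [sk_split()], [sk_fuse()],
#'   [sk_select()], and [sk_apply()].
#' @export
sk_module <- function(C, cfg = sk_config(), seed = 1) {
  with_seed(seed, nn_sk(C, cfg))
}

#' SK split: two-branch multi-scale convolution
#'
#' Runs the two branch convolutions (3x3 dilation 1 and 3x3 dilation 2 —
#' a 5x5 receptive field), each followed by batch norm and ReLU. The two
#' outputs have identical shape, equal to the input shape.
#'
#' @param mod An [sk_module()].
#' @param x Input tensor `(H, W, N, C)`.
#' @param train Batch-norm mode.
#' @return List with `Y1` and `Y2`.
#' @export
sk_split <- function(mod, x, train = TRUE) {
  p <- mod$params
  cf <- mod$cfg
  y1 <- relu_forward(bn_forward(with_params(cf$sub$bn1, p$bn1),
                                conv_forward(with_params(cf$sub$conv1,
                                                         p$conv1), x)$y,
                                train)$y)$y
  y2 <- relu_forward(bn_forward(with_params(cf$sub$bn2, p$bn2),
                                conv_forward(with_params(cf$sub$conv2,
                                                         p$conv2), x)$y,
                                train)$y)$y
  list(Y1 = y1, Y2 = y2)
}

#' SK fuse: sum, pool, compress
#'
#' Fuses the branches by elementwise summation, global-average-pools to
#' the channel statistic `s` (one value per channel per image), and
#' compresses to the descriptor `z = ReLU(BN(W s))` of dimension
#' `d = max(C / r, dim_floor)`.
#'
#' @param mod An [sk_module()].
#' @param Y1,Y2 Branch outputs from [sk_split()].
#' @param train Batch-norm mode.
#' @return List with `s` (`N x C`), `z` (`N x d`), and `d`.
#' @export
sk_fuse <- function(mod, Y1, Y2, train = TRUE) {
  p <- mod$params
  cf <- mod$cfg
  s <- gap_forward(Y1 + Y2)$y
  z <- relu_forward(bn_forward(with_params(cf$sub$bnz, p$bnz),
                               s %*% p$Wfuse, train)$y)$y
  list(s = s, z = z, d = cf$d)
}

#' SK select: soft branch gating
#'
#' Maps the descriptor through the learnable matrices A and B and a
#' per-channel two-way softmax into gates `a_c + b_c = 1`, then mixes the
#' branches: `V_c = a_c Y1_c + b_c Y2_c`.
#'
#' @param mod An [sk_module()].
#' @param z Descriptor from [sk_fuse()].
#' @param Y1,Y2 Branch outputs.
#' @return List with `a`, `b` (`N x C` gates) and `V` (same shape as the
#'   input).
#' @export
sk_select <- function(mod, z, Y1, Y2) {
  p <- mod$params
  l1 <- z %*% p$A
  l2 <- z %*% p$B
  a <- 1 / (1 + exp(l2 - l1))
  d <- dim(Y1)
  ab <- broadcast_nc(a, d[1], d[2])
  list(a = a, b = 1 - a, V = ab * Y1 + (1 - ab) * Y2)
}

#' Full SK attention pass
#'
#' @param mod An [sk_module()].
#' @param x Input tensor.
#' @param train Batch-norm mode.
#' @return The gated output `V`, same shape as `x`.
#' @export
sk_apply <- function(mod, x, train = TRUE) {
  br <- sk_split(mod, x, train)
  fu <- sk_fuse(mod, br$Y1, br$Y2, train)
  sk_select(mod, fu$z, br$Y1, br$Y2)$V
}

#' Forward a standalone dense block
#'
#' Builds a dense block (each layer: BN, ReLU, 1x1 bottleneck conv, BN,
#' ReLU, 3x3 conv producing K channels, concatenated onto its input) with
#' fresh weights and forwards `x` through it. Output channels equal input
#' channels plus `n_layers * K`; zero layers is the identity.
#'
#' @param x Input tensor `(H, W, N, C)`.
#' @param n_layers Dense layers in the block.
#' @param K Growth rate.
#' @param bn_size Bottleneck multiplier.
#' @param sk_cfg Optional [sk_config()] for per-layer attention.
#' @param seed Weight seed.
#' @return The block output tensor.
#' @export
dense_block_forward <- function(x, n_layers, K, bn_size = 4, sk_cfg = NULL,
                                seed = 1) {
  if (n_layers == 0) return(x)
  with_seed(seed, {
    C <- dim(x)[4]
    h <- x
    for (li in seq_len(n_layers)) {
      lay <- dense_layer_new(C, K, bn_size, sk_cfg)
      h <- concat_c(h, dense_layer_forward(lay, h, TRUE)$y)
      C <- C + K
    }
    h
  })
}
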