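# Convolutional blocks used on the encoder/decoder paths.
#
# Three types, each in an encoder and a decoder variant:
#  - plain:            conv-BN-ReLU, conv-BN-ReLU (classic U-Net double conv)
#  - residual:         y = ReLU(BN(conv(ReLU(BN(conv(x))))) + proj(x))
#                      (one additive skip around the whole unit)
#  - sparse_residual:  encoder: y1 = BN(conv(x)) + proj(x);
#                               y2 = BN(conv(y1)) + y1; out = ReLU(y2)
#                      decoder: out = ReLU(BN(conv(x)) + proj(x))
#                      (a skip after every single conv+BN stage; the decoder
#                      uses the single-stage form)
# The skip path uses a 1x1 convolution when input/output channels differ.

unet_block <- function(cin, cout, k = 3L,
                       type = c("sparse_residual", "plain", "residual"),
                       variant = c("encoder", "decoder")) {
  type <- match.arg(type)
  variant <- match.arg(variant)
  b <- new.env(parent = emptyenv())
  b$type <- type; b$variant <- variant
  need_proj <- cin != cout
  proj <- if (need_proj) nn_conv1d(cin, cout, 1L) else nn_identity()

  if (type == "plain") {
    conv1 <- nn_conv1d(cin, cout, k); bn1 <- nn_batchnorm(cout); r1 <- nn_relu()
    conv2 <- nn_conv1d(cout, cout, k); bn2 <- nn_batchnorm(cout); r2 <- nn_relu()
    b$leaves <- list(conv1, bn1, conv2, bn2)
    b$forward <- function(x, train = TRUE) {
      a <- r1$forward(bn1$forward(conv1$forward(x, train), train))
      r2$forward(bn2$forward(conv2$forward(a, train), train))
    }
    b$backward <- function(dy) {
      da <- conv2$backward(bn2$backward(r2$backward(dy)))
      conv1$backward(bn1$backward(r1$backward(da)))
    }
  } else if (type == "residual") {
    conv1 <- nn_conv1d(cin, cout, k); bn1 <- nn_batchnorm(cout); rmid <- nn_relu()
    conv2 <- nn_conv1d(cout, cout, k); bn2 <- nn_batchnorm(cout); rout <- nn_relu()
    b$leaves <- c(list(conv1, bn1, conv2, bn2), if (need_proj) list(proj))
    b$forward <- function(x, train = TRUE) {
      a <- rmid$forward(bn1$forward(conv1$forward(x, train), train))
      f <- bn2$forward(conv2$forward(a, train), train)
      rout$forward(f + proj$forward(x, train))
    }
    b$backward <- function(dy) {
      dsum <- rout$backward(dy)
      da <- conv2$backward(bn2$backward(dsum))
      conv1$backward(bn1$backward(rmid$backward(da))) + proj$backward(dsum)
    }
  } else if (variant == "encoder") {      # sparse_residual, two skips
    conv1 <- nn_conv1d(cin, cout, k); bn1 <- nn_batchnorm(cout)
    conv2 <- nn_conv1d(cout, cout, k); bn2 <- nn_batchnorm(cout)
    rout <- nn_relu()
    b$leaves <- c(list(conv1, bn1, conv2, bn2), if (need_proj) list(proj))
    b$forward <- function(x, train = TRUE) {
      y1 <- bn1$forward(conv1$forward(x, train), train) + proj$forward(x, train)
      y2 <- bn2$forward(conv2$forward(y1, train), train) + y1
      rout$forward(y2)
    }
    b$backward <- function(dy) {
      dy2 <- rout$backward(dy)
      dy1 <- conv2$backward(bn2$backward(dy2)) + dy2
      conv1$backward(bn1$backward(dy1)) + proj$backward(dy1)
    }
  } else {                                # sparse_residual decoder, one skip
    conv1 <- nn_conv1d(cin, cout, k); bn1 <- nn_batchnorm(cout)
    rout <- nn_relu()
    b$leaves <- c(list(conv1, bn1), if (need_proj) list(proj))
    b$forward <- function(x, train = TRUE) {
      rout$forward(bn1$forward(conv1$forward(x, train), train) +
                   proj$forward(x, train))
    }
    b$backward <- function(dy) {
      dsum <- rout$backward(dy)
      conv1$backward(bn1$backward(dsum)) + proj$backward(dsum)
    }
  }
  b
}

#' Model architecture configuration
#'
#' Describes the 1-D encoder-decoder network: four (by default) downsampling
#' levels whose channel count doubles per level, a bottleneck, four
#' upsampling levels with attention-weighted skip concatenation, and five
#' prediction heads (the full-resolution `out` head plus one auxiliary head
#' per decoder level, each upsampled to the input length for deep
#' supervision).
#'
#' The three `block_type`s and three `skip_type`s span the seven ablation
#' variants of the architecture (see [ablation_grid()]); the full model is
#' `block_type = "sparse_residual"` with `skip_type = "se_gru"`.
#'
#' @param depth Number of down/upsampling levels (default 4).
#' @param base_channels Channels at the first level; doubled per level
#'   (default 32; 8 is a practical CPU "desk" setting).
#' @param kernel_size Convolution kernel size (default 3).
#' @param input_len Input window length in samples (default 1024); must be
#'   divisible by `2^depth`.
#' @param block_type `"sparse_residual"`, `"residual"` or `"plain"`.
#' @param skip_type `"se_gru"`, `"se"` or `"plain"` (pass-through skip).
#' @param se_reduction Squeeze-and-excitation reduction factor `r`; must
#'   divide the channel count at every skip level (default 8).
#' @param supervision_weights Deep-supervision loss weights, `depth + 1`
#'   values ordered `[out, level1, ..., level4]`
#'   (default `c(1, 0.9, 0.8, 0.7, 0.6)`).
#' @param aux_weight_order `"shallow_first"` (default) attaches `level1` to
#'   the shallowest (full-resolution) decoder output; `"deep_first"`
#'   reverses the attachment.
#' @return A list of class `ppgbp_unet_config`.
#' @export
unet_config <- function(depth = 4L, base_channels = 32L, kernel_size = 3L,
                        input_len = 1024L,
                        block_type = c("sparse_residual", "plain", "residual"),
                        skip_type = c("se_gru", "plain", "se"),
                        se_reduction = 8L,
                        supervision_weights = c(1, 0.9, 0.8, 0.7, 0.6),
                        aux_weight_order = c("shallow_first", "deep_first")) {
  block_type <- match.arg(block_type)
  skip_type <- match.arg(skip_type)
  aux_weight_order <- match.arg(aux_weight_order)
  depth <- as.integer(depth)
  if (input_len %% 2L^depth != 0L) {
    stop("input_len (", input_len, ") must be divisible by 2^depth (",
         2L^depth, ")", call. = FALSE)
  }
  if (length(supervision_weights) != depth + 1L) {
    stop("supervision_weights must have depth + 1 = ", depth + 1L, " entries",
         call. = FALSE)
  }
  channels <- base_channels * 2L^(0:(depth - 1L))
  if (skip_type %in% c("se", "se_gru") && any(channels %% se_reduction != 0L)) {
    stop("se_reduction r = ", se_reduction,
         " must divide the channel count at every level (",
         paste(channels, collapse = ", "), ")", call. = FALSE)
  }
  structure(list(
    depth = depth, base_channels = as.integer(base_channels),
    kernel_size = as.integer(kernel_size), input_len = as.integer(input_len),
    block_type = block_type, skip_type = skip_type,
    se_reduction = as.integer(se_reduction),
    supervision_weights = supervision_weights,
    aux_weight_order = aux_weight_order
  ), class = "ppgbp_unet_config")
}

#' The seven architecture ablation variants
#'
#' Enumerates the block/skip combinations used to isolate the contribution of
#' each module: the plain U-Net, SE or SE-GRU skip attention on plain blocks,
#' and ordinary or sparse residual blocks under each attention type, up to
#' the full model (sparse residual + SE-GRU). All variants use deep
#' supervision.
#'
#' @return A tibble with columns `variant`, `block_type`, `skip_type`.
#' @export
ablation_grid <- function() {
  tibble::tibble(
    variant = c("plain", "plain+se", "plain+se_gru", "residual+se",
                "sparse+se", "residual+se_gru", "sparse+se_gru"),
    block_type = c("plain", "plain", "plain", "residual",
                   "sparse_residual", "residual", "sparse_residual"),
    skip_type = c("plain", "se", "se_gru", "se", "se", "se_gru", "se_gru")
  )
}

#' Build the 1-D attention U-Net
#'
#' Constructs the network described by a [unet_config()]: encoder levels of
#' block + x2 max-pool with channels doubling, a bottleneck block, decoder
#' levels of x2 transposed-convolution upsampling + attention-weighted skip
#' concatenation + block, and `depth + 1` prediction heads (1x1
#' convolutions; auxiliary heads are linearly upsampled to the input length).
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `ppgbp_unet` with `$forward(X, train)`,
#'   `$backward(...)` and `$leaves` (parameterized modules).
#' @export
build_unet1d <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ppgbp_unet_config"))
  withr::with_seed(as.integer(seed), {
    depth <- cfg$depth
    ch <- cfg$base_channels * 2L^(0:depth)    # ch[i] = channels at level i
    net <- new.env(parent = emptyenv())
    net$cfg <- cfg
    net$enc <- lapply(seq_len(depth), function(i)
      unet_block(if (i == 1L) 1L else ch[i - 1L], ch[i], cfg$kernel_size,
                 cfg$block_type, "encoder"))
    net$pool <- lapply(seq_len(depth), function(i) nn_maxpool2())
    net$bottleneck <- unet_block(ch[depth], ch[depth + 1L], cfg$kernel_size,
                                 cfg$block_type, "encoder")
    net$upconv <- lapply(seq_len(depth), function(i)
      nn_upconv2(ch[i + 1L], ch[i]))
    net$attn <- lapply(seq_len(depth), function(i)
      switch(cfg$skip_type,
             plain = nn_identity(),
             se = nn_se_fc(ch[i], cfg$se_reduction),
             se_gru = nn_se_gru(ch[i], cfg$se_reduction)))
    net$dec <- lapply(seq_len(depth), function(i)
      unet_block(2L * ch[i], ch[i], cfg$kernel_size, cfg$block_type, "decoder"))
    net$out_head <- nn_conv1d(ch[1L], 1L, 1L)
    net$aux_head <- lapply(seq_len(depth), function(i) nn_conv1d(ch[i], 1L, 1L))

    net$leaves <- c(
      unlist(lapply(net$enc, `[[`, "leaves"), recursive = FALSE),
      net$bottleneck$leaves,
      net$upconv,
      Filter(function(a) length(a$params) > 0, net$attn),
      unlist(lapply(net$dec, `[[`, "leaves"), recursive = FALSE),
      list(net$out_head),
      net$aux_head
    )

    net$forward <- function(X, train = TRUE) {
      stopifnot(is.matrix(X), ncol(X) == cfg$input_len)
      B <- nrow(X)
      x <- array(t(X), c(1L, cfg$input_len, B))
      skips <- vector("list", depth)
      for (i in seq_len(depth)) {
        skips[[i]] <- net$enc[[i]]$forward(x, train)
        x <- net$pool[[i]]$forward(skips[[i]], train)
      }
      x <- net$bottleneck$forward(x, train)
      dec_out <- vector("list", depth)
      for (i in rev(seq_len(depth))) {
        up <- net$upconv[[i]]$forward(x, train)
        sk <- net$attn[[i]]$forward(skips[[i]], train)
        Cc <- dim(sk)[1L]
        cat_x <- array(0, c(2L * Cc, dim(sk)[2L], B))
        cat_x[seq_len(Cc), , ] <- sk
        cat_x[Cc + seq_len(Cc), , ] <- up
        x <- net$dec[[i]]$forward(cat_x, train)
        dec_out[[i]] <- x
      }
      main <- net$out_head$forward(dec_out[[1L]], train)
      aux <- vector("list", depth)
      for (i in seq_len(depth)) {
        a <- net$aux_head[[i]]$forward(dec_out[[i]], train)
        while (dim(a)[2L] < cfg$input_len) a <- upsample2_linear(a)
        aux[[i]] <- a
      }
      net$.B <- B
      list(main = t(matrix(main, cfg$input_len, B)),
           aux = lapply(aux, function(a) t(matrix(a, cfg$input_len, B))))
    }

    # d_main, d_aux: gradients of the loss wrt the head outputs (B x L each)
    net$backward <- function(d_main, d_aux) {
      B <- net$.B
      to_arr <- function(M) array(t(M), c(1L, cfg$input_len, B))
      g_aux <- vector("list", depth)
      for (i in seq_len(depth)) {
        a <- to_arr(d_aux[[i]])
        lvl_len <- cfg$input_len %/% 2L^(i - 1L)
        while (dim(a)[2L] > lvl_len) a <- upsample2_linear_bw(a)
        g_aux[[i]] <- net$aux_head[[i]]$backward(a)
      }
      g <- net$out_head$backward(to_arr(d_main)) + g_aux[[1L]]
      g_skip <- vector("list", depth)
      for (i in seq_len(depth)) {
        g_cat <- net$dec[[i]]$backward(g)
        Cc <- dim(g_cat)[1L] %/% 2L
        g_skip[[i]] <- net$attn[[i]]$backward(g_cat[seq_len(Cc), , , drop = FALSE])
        g_up <- net$upconv[[i]]$backward(g_cat[Cc + seq_len(Cc), , , drop = FALSE])
        g <- if (i < depth) g_up + g_aux[[i + 1L]] else g_up
      }
      g <- net$bottleneck$backward(g)
      for (i in rev(seq_len(depth))) {
        g <- net$pool[[i]]$backward(g) + g_skip[[i]]
        g <- net$enc[[i]]$backward(g)
      }
      invisible(NULL)
    }
    class(net) <- "ppgbp_unet"
    net
  })
}

#' @export
print.ppgbp_unet <- function(x, ...) {
  cfg <- x$cfg
  ch <- cfg$base_channels * 2L^(0:cfg$depth)
  n_par <- sum(vapply(x$leaves, function(l) sum(lengths(l$params)), numeric(1)))
  cat("1-D attention U-Net\n")
  cat("  blocks:      ", cfg$block_type, "\n")
  cat("  skips:       ", cfg$skip_type, "\n")
  cat("  depth:       ", cfg$depth, " (channels ",
      paste(ch[seq_len(cfg$depth)], collapse = "-"), ", bottleneck ",
      ch[cfg$depth + 1L], ")\n", sep = "")
  cat("  input length:", cfg$input_len, "\n")
  cat("  heads:        out + ", cfg$depth, " auxiliary (weights ",
      paste(cfg$supervision_weights, collapse = ", "), ")\n", sep = "")
  cat("  parameters:  ", format(n_par, big.mark = ","), "\n")
  invisible(x)
}
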