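#' Specify a U-Net encoder-decoder
#'
#' A compact U-Net: a contracting path of stacked 3x3 convolution + ReLU
#' pairs with 2x2 max pooling, a symmetric expanding path of convolutional
#' layers only (no dense layers) with skip connections, and a final 1x1
#' convolution to per-class scores. Input spatial dimensions must be
#' divisible by `2^depth`; training and prediction enforce this by
#' reflection padding.
#'
#' @param in_channels Number of input bands (the selected band subset size).
#' @param n_classes Number of output classes including background (K + 1).
#' @param depth Number of pooling stages (default 3).
#' @param base_channels Channels of the first encoder block (default 16),
#'   doubled at each depth.
#' @param upsampling `"bilinear_plus_conv"` (default; the expanding path
#'   contains only convolutional layers) or `"transposed_conv"`.
#' @return Object of class `unet_spec`.
#' @export
unet_spec <- function(in_channels, n_classes, depth = 3, base_channels = 16,
                      upsampling = c("bilinear_plus_conv", "transposed_conv")) {
  upsampling <- match.arg(upsampling)
  stopifnot(in_channels >= 1, n_classes >= 2, depth >= 1, base_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 upsampling = upsampling),
            class = "unet_spec")
}

#' Training configuration
#'
#' @param epochs Number of passes over the training scenes (default 80).
#' @param learning_rate Adam step size.
#' @param seed Seed fixing all stochastic components (weight initialization
#'   and scene shuffling).
#' @param loss `"combined"` (cross-entropy + soft Jaccard, default),
#'   `"cross_entropy"`, or `"jaccard"`.
#' @param jaccard_weight Weight of the Jaccard term in the combined loss.
#' @return Object of class `training_config`.
#' @export
training_config <- function(epochs = 80, learning_rate = 1e-3, seed = 1L,
                            loss = c("combined", "cross_entropy", "jaccard"),
                            jaccard_weight = 1) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), loss = loss,
                 jaccard_weight = jaccard_weight),
            class = "training_config")
}

unet_channels <- function(spec) {
  c(spec$base_channels * 2^(seq_len(spec$depth) - 1),
    spec$base_channels * 2^spec$depth)
}

new_conv <- function(cin, cout, k = 9) {
  list(W = matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                  k * cin, cout),
       b = numeric(cout))
}

#' Build a U-Net model with seeded weight initialization
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for He-style weight initialization.
#' @return Object of class `unet_model`.
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ch <- unet_channels(spec)
  d <- spec$depth
  params <- list()
  cin <- spec$in_channels
  for (i in seq_len(d)) {
    params[[paste0("enc", i, "_c1")]] <- new_conv(cin, ch[i])
    params[[paste0("enc", i, "_c2")]] <- new_conv(ch[i], ch[i])
    cin <- ch[i]
  }
  params[["bott_c1"]] <- new_conv(ch[d], ch[d + 1])
  params[["bott_c2"]] <- new_conv(ch[d + 1], ch[d + 1])
  for (i in rev(seq_len(d))) {
    cup <- if (i == d) ch[d + 1] else ch[i + 1]
    if (spec$upsampling == "bilinear_plus_conv") {
      params[[paste0("dec", i, "_up")]] <- new_conv(cup, ch[i])
    } else {
      # transposed 2x2 conv: Cin x (4*Cout), one tap per input channel
      params[[paste0("dec", i, "_up")]] <- list(
        W = matrix(stats::rnorm(cup * 4 * ch[i], 0, sqrt(2 / cup)),
                   cup, 4 * ch[i]),
        b = numeric(ch[i]))
    }
    params[[paste0("dec", i, "_c1")]] <- new_conv(2 * ch[i], ch[i])
    params[[paste0("dec", i, "_c2")]] <- new_conv(ch[i], ch[i])
  }
  params[["final"]] <- new_conv(ch[1], spec$n_classes, k = 1)
  structure(list(spec = spec, params = params, band_wavelengths = NULL),
            class = "unet_model")
}

conv_block_fwd <- function(x, p1, p2) {
  c1 <- conv3_fwd(x, p1$W, p1$b)
  a1 <- relu(c1$out)
  c2 <- conv3_fwd(a1, p2$W, p2$b)
  a2 <- relu(c2$out)
  list(out = a2, P1 = c1$P, a1 = a1, P2 = c2$P, in_dim = dim(x),
       mid_dim = dim(a1))
}

unet_forward <- function(model, x) {
  spec <- model$spec
  d <- spec$depth
  p <- model$params
  cache <- list(enc = vector("list", d), pool = vector("list", d),
                dec = vector("list", d), up = vector("list", d))
  h <- x
  for (i in seq_len(d)) {
    blk <- conv_block_fwd(h, p[[paste0("enc", i, "_c1")]],
                          p[[paste0("enc", i, "_c2")]])
    cache$enc[[i]] <- blk
    pool <- maxpool_fwd(blk$out)
    cache$pool[[i]] <- list(arg = pool$arg, in_dim = dim(blk$out))
    h <- pool$out
  }
  blk <- conv_block_fwd(h, p$bott_c1, p$bott_c2)
  cache$bott <- blk
  h <- blk$out
  for (i in rev(seq_len(d))) {
    nm <- paste0("dec", i, "_up")
    if (spec$upsampling == "bilinear_plus_conv") {
      hd <- dim(h)
      Ur <- bilinear_matrix(2 * hd[1], hd[1])
      Uc <- bilinear_matrix(2 * hd[2], hd[2])
      u <- upsample_fwd(h, Ur, Uc)
      cu <- conv3_fwd(u, p[[nm]]$W, p[[nm]]$b)
      au <- relu(cu$out)
      cache$up[[i]] <- list(kind = "bilinear", Ur = Ur, Uc = Uc, P = cu$P,
                            pre = cu$out, u_dim = dim(u), in_dim = hd)
    } else {
      tc <- tconv_fwd(h, p[[nm]]$W, p[[nm]]$b)
      au <- relu(tc$out)
      cache$up[[i]] <- list(kind = "tconv", x_mat = tc$x_mat,
                            pre = tc$out, in_dim = dim(h))
    }
    skip <- cache$enc[[i]]$out
    cat_in <- array(c(au, skip), c(dim(au)[1], dim(au)[2],
                                   dim(au)[3] + dim(skip)[3]))
    blk <- conv_block_fwd(cat_in, p[[paste0("dec", i, "_c1")]],
                          p[[paste0("dec", i, "_c2")]])
    cache$dec[[i]] <- c(blk, list(n_up = dim(au)[3]))
    h <- blk$out
  }
  hd <- dim(h)
  h_mat <- matrix(h, hd[1] * hd[2], hd[3])
  logits_mat <- sweep(h_mat %*% p$final$W, 2, p$final$b, "+")
  cache$final_in <- h_mat
  cache$final_dim <- hd
  list(logits = array(logits_mat, c(hd[1], hd[2], spec$n_classes)),
       cache = cache)
}

block_bwd <- function(d_out, blk, p1, p2) {
  # through relu2
  d2 <- d_out
  d2[blk$out <= 0] <- 0
  g2 <- conv3_bwd(d2, blk$P2, p2$W, blk$mid_dim)
  d1 <- g2$dx
  d1[blk$a1 <= 0] <- 0
  g1 <- conv3_bwd(d1, blk$P1, p1$W, blk$in_dim)
  list(dx = g1$dx, g1 = list(dW = g1$dW, db = g1$db),
       g2 = list(dW = g2$dW, db = g2$db))
}

unet_backward <- function(model, cache, d_logits) {
  spec <- model$spec
  d <- spec$depth
  p <- model$params
  grads <- list()
  hd <- cache$final_dim
  dl_mat <- matrix(d_logits, hd[1] * hd[2], spec$n_classes)
  grads$final <- list(dW = crossprod(cache$final_in, dl_mat),
                      db = colSums(dl_mat))
  dh <- array(tcrossprod(dl_mat, p$final$W), hd)
  d_enc_extra <- vector("list", d)
  for (i in seq_len(d)) {
    blk <- cache$dec[[i]]
    g <- block_bwd(dh, blk, p[[paste0("dec", i, "_c1")]],
                   p[[paste0("dec", i, "_c2")]])
    grads[[paste0("dec", i, "_c1")]] <- g$g1
    grads[[paste0("dec", i, "_c2")]] <- g$g2
    dcat <- g$dx
    n_up <- blk$n_up
    dau <- dcat[, , seq_len(n_up), drop = FALSE]
    d_enc_extra[[i]] <- dcat[, , (n_up + 1):dim(dcat)[3], drop = FALSE]
    up <- cache$up[[i]]
    dpre <- dau
    dpre[up$pre <= 0] <- 0
    nm <- paste0("dec", i, "_up")
    if (up$kind == "bilinear") {
      gu <- conv3_bwd(dpre, up$P, p[[nm]]$W, up$u_dim)
      grads[[nm]] <- list(dW = gu$dW, db = gu$db)
      dh <- upsample_bwd(gu$dx, up$Ur, up$Uc)
    } else {
      gu <- tconv_bwd(dpre, up$x_mat, p[[nm]]$W, up$in_dim)
      grads[[nm]] <- list(dW = gu$dW, db = gu$db)
      dh <- gu$dx
    }
    # dh now flows into the next (deeper) decoder stage input, i.e. the
    # output of stage i+1 (or the bottleneck when i == d)
  }
  g <- block_bwd(dh, cache$bott, p$bott_c1, p$bott_c2)
  grads$bott_c1 <- g$g1
  grads$bott_c2 <- g$g2
  dpool_out <- g$dx
  for (i in rev(seq_len(d))) {
    pool <- cache$pool[[i]]
    d_enc_out <- maxpool_bwd(dpool_out, pool$arg, pool$in_dim) +
      d_enc_extra[[i]]
    g <- block_bwd(d_enc_out, cache$enc[[i]],
                   p[[paste0("enc", i, "_c1")]], p[[paste0("enc", i, "_c2")]])
    grads[[paste0("enc", i, "_c1")]] <- g$g1
    grads[[paste0("enc", i, "_c2")]] <- g$g2
    dpool_out <- g$dx
  }
  grads
}
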