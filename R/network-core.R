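# Runtime of the scalable classification network: parameter
# initialization, forward pass, and hand-derived backward pass. Tensors
# are H x W x C x N arrays; convolutions run through the compiled
# im2col/GEMM kernels.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# ---- elementwise layers (compiled kernels in src/layer_ops.cpp) ----------

sigmoid_ <- function(x) 1 / (1 + exp(-x))

swish_fw <- function(x) swish_fw_cpp(x)

swish_bw <- function(x, dy) swish_bw_cpp(x, dy)

# ---- batch normalization -------------------------------------------------

bn_fw <- function(x, g, b, mean_run, var_run, training) {
  if (training) {
    out <- bn_train_fw(x, g, b, BN_EPS)
    list(y = out$y,
         cache = list(xhat = out$xhat, istd = out$istd, g = g),
         mean = BN_MOMENTUM * mean_run + (1 - BN_MOMENTUM) * out$mean,
         var = BN_MOMENTUM * var_run + (1 - BN_MOMENTUM) * out$var)
  } else {
    list(y = bn_infer_fw(x, g, b, mean_run, var_run, BN_EPS),
         cache = NULL, mean = mean_run, var = var_run)
  }
}

bn_bw <- function(cache, dy) {
  bn_train_bw(cache$xhat, cache$istd, cache$g, dy)
}

# ---- global average pooling ---------------------------------------------

gap_fw <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  out <- colMeans(x)                       # C x N (or length C when N = 1)
  if (is.null(dim(out))) out <- matrix(out, ncol = 1L)
  out
}

gap_bw <- function(ds, h, w) {
  # ds: C x N -> (h, w, C, N)
  array(rep(c(ds) / (h * w), each = h * w),
        dim = c(h, w, nrow(ds), ncol(ds)))
}

# ---- network construction ------------------------------------------------

# Flatten a network_spec into an ordered block plan with explicit channel
# counts; the parameter list is derived from this plan.
network_plan <- function(spec) {
  stages <- spec$stages
  plan <- list()
  stem <- stages[[1L]]
  plan[[1L]] <- list(type = "stem", name = "stem", kernel = stem$kernel,
                     stride = stem$stride_first, cin = 3L,
                     cout = stem$out_channels)
  cin <- stem$out_channels
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (st$operator != "mbconv") next
    for (l in seq_len(st$layers)) {
      stride <- if (l == 1L) st$stride_first else 1L
      plan[[length(plan) + 1L]] <- list(
        type = "mbconv", name = sprintf("s%d_b%d", i, l),
        kernel = st$kernel, stride = stride, cin = cin,
        cout = st$out_channels, expansion = st$expansion,
        se_dim = max(1L, as.integer(round(cin * 0.25))))
      cin <- st$out_channels
    }
  }
  plan[[length(plan) + 1L]] <- list(type = "head", name = "head", kernel = 1L,
                                    stride = 1L, cin = cin,
                                    cout = spec$feature_dim)
  plan
}

# Named list of parameter array dimensions implied by a network_spec.
param_shapes <- function(spec) {
  shapes <- list()
  add_bn <- function(prefix, c) {
    shapes[[paste0(prefix, "_bn_g")]] <<- c
    shapes[[paste0(prefix, "_bn_b")]] <<- c
  }
  for (blk in network_plan(spec)) {
    nm <- blk$name
    if (blk$type %in% c("stem", "head")) {
      shapes[[paste0(nm, "_w")]] <- c(blk$kernel, blk$kernel, blk$cin, blk$cout)
      add_bn(nm, blk$cout)
    } else {
      cexp <- blk$cin * blk$expansion
      if (blk$expansion > 1L) {
        shapes[[paste0(nm, "_exp_w")]] <- c(1L, 1L, blk$cin, cexp)
        add_bn(paste0(nm, "_exp"), cexp)
      }
      shapes[[paste0(nm, "_dw_w")]] <- c(blk$kernel, blk$kernel, cexp)
      add_bn(paste0(nm, "_dw"), cexp)
      shapes[[paste0(nm, "_se_r_w")]] <- c(cexp, blk$se_dim)
      shapes[[paste0(nm, "_se_r_b")]] <- blk$se_dim
      shapes[[paste0(nm, "_se_e_w")]] <- c(blk$se_dim, cexp)
      shapes[[paste0(nm, "_se_e_b")]] <- cexp
      shapes[[paste0(nm, "_proj_w")]] <- c(1L, 1L, cexp, blk$cout)
      add_bn(paste0(nm, "_proj"), blk$cout)
    }
  }
  shapes[["fc_w"]] <- c(spec$feature_dim, spec$num_classes)
  shapes[["fc_b"]] <- spec$num_classes
  shapes
}

#' Total trainable parameter count of a network specification
#' @param spec a `network_spec`.
#' @return integer number of trainable parameters (batch-normalization
#'   running statistics excluded).
#' @export
count_parameters <- function(spec) {
  sum(vapply(param_shapes(spec), prod, 0))
}

init_param <- function(name, shape) {
  if (grepl("_bn_g$", name)) return(rep(1, shape))
  if (grepl("_bn_b$", name) || grepl("_b$", name)) return(rep(0, shape))
  if (length(shape) == 4L) {
    if (grepl("_dw_w$", name)) {
      fan_out <- shape[1] * shape[2]
    } else {
      fan_out <- shape[1] * shape[2] * shape[4]
    }
    return(array(stats::rnorm(prod(shape), sd = sqrt(2 / fan_out)),
                 dim = shape))
  }
  if (length(shape) == 3L) {                      # depthwise kernel
    return(array(stats::rnorm(prod(shape), sd = sqrt(2 / (shape[1] * shape[2]))),
                 dim = shape))
  }
  if (length(shape) == 2L) {                      # dense
    return(matrix(stats::rnorm(prod(shape), sd = sqrt(1 / shape[1])),
                  nrow = shape[1]))
  }
  rep(0, shape)
}

#' Build a network from a specification
#'
#' Constructs the full network: stem convolution, MBConv stages (1x1
#' expansion, depthwise convolution, squeeze-excitation with reduction
#' ratio 0.25, 1x1 projection, residual connection when stride is 1 and
#' channel counts match), 1x1 head convolution to the depth-feature
#' dimension, global average pooling, and a fully-connected classifier.
#' Batch normalization and swish activations throughout. Weight
#' initialization is deterministic given `seed`.
#'
#' @param spec a `network_spec` from [scale_spec()] or
#'   [tiny_network_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `seiznet_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  shapes <- param_shapes(spec)
  params <- with_seed(mix_seed(seed, 7L), {
    out <- vector("list", length(shapes))
    names(out) <- names(shapes)
    for (nm in names(shapes)) out[[nm]] <- init_param(nm, shapes[[nm]])
    out
  })
  stats <- list()
  for (nm in names(shapes)) {
    if (grepl("_bn_g$", nm)) {
      base <- sub("_bn_g$", "", nm)
      stats[[paste0(base, "_bn_mean")]] <- rep(0, shapes[[nm]])
      stats[[paste0(base, "_bn_var")]] <- rep(1, shapes[[nm]])
    }
  }
  structure(list(spec = spec, plan = network_plan(spec), params = params,
                 bn_stats = stats, seed = as.integer(seed), history = NULL),
            class = "seiznet_network")
}

#' @export
print.seiznet_network <- function(x, ...) {
  lvl <- if (is.na(x$spec$level)) "tiny preset" else paste0("level ", x$spec$level)
  trained <- if (is.null(x$history)) "untrained" else
    sprintf("trained, best val acc %.2f%%", 100 * max(x$history$val_acc))
  cat(sprintf("<seiznet_network> %s: input %d, %d blocks, %s params, %s\n",
              lvl, x$spec$input_resolution, length(x$plan),
              format(count_parameters(x$spec), big.mark = ","), trained))
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

conv_block_fw <- function(x, params, stats, nm, stride, pad, training,
                          cache_on) {
  w <- params[[paste0(nm, "_w")]]
  z <- conv2d_fw(x, w, stride, pad)
  bn <- bn_fw(z, params[[paste0(nm, "_bn_g")]], params[[paste0(nm, "_bn_b")]],
              stats[[paste0(nm, "_bn_mean")]], stats[[paste0(nm, "_bn_var")]],
              training)
  y <- swish_fw(bn$y)
  cache <- if (cache_on) list(x = x, bn = bn$cache, pre_act = bn$y) else NULL
  list(y = y, cache = cache, bn_mean = bn$mean, bn_var = bn$var)
}

mbconv_fw <- function(x, params, stats, blk, training, cache_on) {
  nm <- blk$name
  pad <- (blk$kernel - 1L) %/% 2L
  new_stats <- list()
  cache <- if (cache_on) list(x0 = x) else NULL

  u <- x
  if (blk$expansion > 1L) {
    pe <- paste0(nm, "_exp")
    z <- conv2d_fw(u, params[[paste0(pe, "_w")]], 1L, 0L)
    bn <- bn_fw(z, params[[paste0(pe, "_bn_g")]], params[[paste0(pe, "_bn_b")]],
                stats[[paste0(pe, "_bn_mean")]], stats[[paste0(pe, "_bn_var")]],
                training)
    new_stats[[paste0(pe, "_bn_mean")]] <- bn$mean
    new_stats[[paste0(pe, "_bn_var")]] <- bn$var
    u2 <- swish_fw(bn$y)
    if (cache_on) {
      cache$exp_bn <- bn$cache; cache$exp_pre <- bn$y
    }
    u <- u2
  }
  pd <- paste0(nm, "_dw")
  if (cache_on) cache$dw_in <- u
  z <- dwconv2d_fw(u, params[[paste0(pd, "_w")]], blk$stride, pad)
  bn <- bn_fw(z, params[[paste0(pd, "_bn_g")]], params[[paste0(pd, "_bn_b")]],
              stats[[paste0(pd, "_bn_mean")]], stats[[paste0(pd, "_bn_var")]],
              training)
  new_stats[[paste0(pd, "_bn_mean")]] <- bn$mean
  new_stats[[paste0(pd, "_bn_var")]] <- bn$var
  v <- swish_fw(bn$y)
  if (cache_on) { cache$dw_bn <- bn$cache; cache$dw_pre <- bn$y }

  # squeeze-excitation on the expanded tensor
  s <- gap_fw(v)                                        # Cexp x N
  z1 <- crossprod(params[[paste0(nm, "_se_r_w")]], s) +
    params[[paste0(nm, "_se_r_b")]]
  a1 <- swish_fw(z1)
  z2 <- crossprod(params[[paste0(nm, "_se_e_w")]], a1) +
    params[[paste0(nm, "_se_e_b")]]
  gate <- sigmoid_(z2)                                  # Cexp x N
  w_ <- channel_gate_fw(v, gate)
  if (cache_on) {
    cache$se <- list(v = v, s = s, z1 = z1, a1 = a1, gate = gate)
  }

  pp <- paste0(nm, "_proj")
  if (cache_on) cache$proj_in <- w_
  z <- conv2d_fw(w_, params[[paste0(pp, "_w")]], 1L, 0L)
  bn <- bn_fw(z, params[[paste0(pp, "_bn_g")]], params[[paste0(pp, "_bn_b")]],
              stats[[paste0(pp, "_bn_mean")]], stats[[paste0(pp, "_bn_var")]],
              training)
  new_stats[[paste0(pp, "_bn_mean")]] <- bn$mean
  new_stats[[paste0(pp, "_bn_var")]] <- bn$var
  y <- bn$y
  if (cache_on) cache$proj_bn <- bn$cache
  residual <- blk$stride == 1L && blk$cin == blk$cout
  if (residual) y <- y + x
  list(y = y, cache = cache, new_stats = new_stats, residual = residual)
}

mbconv_bw <- function(params, blk, cache, dy) {
  nm <- blk$name
  pad <- (blk$kernel - 1L) %/% 2L
  grads <- list()
  dx0_res <- if (blk$stride == 1L && blk$cin == blk$cout) dy else 0

  pp <- paste0(nm, "_proj")
  b <- bn_bw(cache$proj_bn, dy)
  grads[[paste0(pp, "_bn_g")]] <- b$dg
  grads[[paste0(pp, "_bn_b")]] <- b$db
  cv <- conv2d_bw(cache$proj_in, params[[paste0(pp, "_w")]], b$dx, 1L, 0L)
  grads[[paste0(pp, "_w")]] <- cv$dw
  dw_ <- cv$dx                                          # grad wrt gated tensor

  se <- cache$se
  dv_direct <- channel_gate_fw(dw_, se$gate)
  dgate <- channel_dot(dw_, se$v)                       # sum over H,W
  dz2 <- dgate * se$gate * (1 - se$gate)
  grads[[paste0(nm, "_se_e_w")]] <- se$a1 %*% t(dz2)
  grads[[paste0(nm, "_se_e_b")]] <- rowSums(dz2)
  da1 <- params[[paste0(nm, "_se_e_w")]] %*% dz2
  dz1 <- swish_bw(se$z1, da1)
  grads[[paste0(nm, "_se_r_w")]] <- se$s %*% t(dz1)
  grads[[paste0(nm, "_se_r_b")]] <- rowSums(dz1)
  ds <- params[[paste0(nm, "_se_r_w")]] %*% dz1
  dv <- dv_direct + gap_bw(ds, dim(se$v)[1], dim(se$v)[2])

  pd <- paste0(nm, "_dw")
  dpre <- swish_bw(cache$dw_pre, dv)
  b <- bn_bw(cache$dw_bn, dpre)
  grads[[paste0(pd, "_bn_g")]] <- b$dg
  grads[[paste0(pd, "_bn_b")]] <- b$db
  cv <- dwconv2d_bw(cache$dw_in, params[[paste0(pd, "_w")]], b$dx,
                    blk$stride, pad)
  grads[[paste0(pd, "_w")]] <- cv$dw
  du <- cv$dx

  if (blk$expansion > 1L) {
    pe <- paste0(nm, "_exp")
    dpre <- swish_bw(cache$exp_pre, du)
    b <- bn_bw(cache$exp_bn, dpre)
    grads[[paste0(pe, "_bn_g")]] <- b$dg
    grads[[paste0(pe, "_bn_b")]] <- b$db
    cv <- conv2d_bw(cache$x0, params[[paste0(pe, "_w")]], b$dx, 1L, 0L)
    grads[[paste0(pe, "_w")]] <- cv$dw
    dx <- cv$dx
  } else {
    dx <- du
  }
  list(dx = dx + dx0_res, grads = grads)
}

# Full forward pass. x: (H, W, 3, N) array at the spec's input
# resolution. Returns logits (N x K), depth features (N x feature_dim),
# updated BN stats, and (optionally) the cache for backward.
net_forward <- function(net, x, training = FALSE, cache_on = FALSE) {
  params <- net$params
  stats <- net$bn_stats
  caches <- vector("list", length(net$plan))
  for (i in seq_along(net$plan)) {
    blk <- net$plan[[i]]
    if (blk$type %in% c("stem", "head")) {
      pad <- (blk$kernel - 1L) %/% 2L
      out <- conv_block_fw(x, params, stats, blk$name, blk$stride, pad,
                           training, cache_on)
      stats[[paste0(blk$name, "_bn_mean")]] <- out$bn_mean
      stats[[paste0(blk$name, "_bn_var")]] <- out$bn_var
      caches[[i]] <- out$cache
      x <- out$y
    } else {
      out <- mbconv_fw(x, params, stats, blk, training, cache_on)
      for (nm in names(out$new_stats)) stats[[nm]] <- out$new_stats[[nm]]
      caches[[i]] <- out$cache
      x <- out$y
    }
  }
  feat <- t(gap_fw(x))                                  # N x feature_dim
  logits <- feat %*% params$fc_w +
    matrix(params$fc_b, nrow(feat), length(params$fc_b), byrow = TRUE)
  list(logits = logits, features = feat, bn_stats = stats,
       caches = if (cache_on) caches else NULL,
       final_map_dim = dim(x))
}

# Backward pass from the logit gradient; returns named gradient list.
net_backward <- function(net, fwd, dlogits) {
  params <- net$params
  grads <- list(
    fc_w = t(fwd$features) %*% dlogits,
    fc_b = colSums(dlogits)
  )
  dfeat <- dlogits %*% t(params$fc_w)                   # N x fd
  d <- fwd$final_map_dim
  dx <- gap_bw(t(dfeat), d[1], d[2])
  for (i in rev(seq_along(net$plan))) {
    blk <- net$plan[[i]]
    cache <- fwd$caches[[i]]
    if (blk$type %in% c("stem", "head")) {
      nm <- blk$name
      pad <- (blk$kernel - 1L) %/% 2L
      dpre <- swish_bw(cache$pre_act, dx)
      b <- bn_bw(cache$bn, dpre)
      grads[[paste0(nm, "_bn_g")]] <- b$dg
      grads[[paste0(nm, "_bn_b")]] <- b$db
      cv <- conv2d_bw(cache$x, params[[paste0(nm, "_w")]], b$dx, blk$stride,
                      pad)
      grads[[paste0(nm, "_w")]] <- cv$dw
      dx <- cv$dx
    } else {
      out <- mbconv_bw(params, blk, cache, dx)
      grads <- c(grads, out$grads)
      dx <- out$dx
    }
  }
  grads
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

cross_entropy <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  onehot <- matrix(0, n, ncol(p))
  onehot[cbind(seq_len(n), y)] <- 1
  list(loss = loss, dlogits = (p - onehot) / n)
}
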