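#' Desk-scale volumetric map-completion model
#'
#' A hybrid of a 3D vision transformer and CNN: the Patterson map and one
#' partial-structure template map are stacked as two channels, passed
#' through a 3D convolutional stem, patchified into tokens, processed by a
#' stack of pre-norm transformer blocks with Nystrom approximate
#' attention (token grids are downsampled by strided convolution after
#' selected blocks and upsampled by transposed convolution after later
#' ones), and de-patchified into a single-channel density prediction of
#' the input shape. Trained with a composite loss: mean-squared error plus
#' a weighted negative Pearson correlation.
#'
#' Because crystallographic maps are periodic in the unit cell, all
#' padding (stem convolution and divisibility padding) is circular.
#'
#' @name model
NULL

#' Model architecture configuration
#'
#' Defaults follow the full-scale training configuration (patch 4, embed
#' 512, 12 heads of dimension 64, MLP 2048, 12 layers, downsampling after
#' blocks 2 and 4, upsampling after blocks 8 and 10). The attention inner
#' dimension is `n_heads * head_dim` with a linear projection back to
#' `embed_dim`.
#'
#' @param conv_channels stem convolution output channels.
#' @param patch patch edge length (voxels).
#' @param embed_dim token embedding dimension.
#' @param head_dim,n_heads attention geometry.
#' @param mlp_dim hidden width of the per-token MLP.
#' @param n_layers number of transformer blocks.
#' @param landmarks Nystrom landmark count (exact attention is used when
#'   tokens <= landmarks).
#' @param pinv_iter iterations of the Moore-Penrose pseudo-inverse scheme.
#' @param downsample_after,upsample_after block indices after which the
#'   token grid is downsampled / upsampled by a factor 2 per axis (paired
#'   LIFO).
#' @param scale_equivariant use the multi-scale shared-weight stem with
#'   max-over-scale pooling instead of a plain convolution.
#' @param pc_loss_weight weight of the negative-Pearson loss term.
#' @return list of class `model_config`.
#' @export
model_config <- function(conv_channels = 10, patch = 4, embed_dim = 512,
                         head_dim = 64, n_heads = 12, mlp_dim = 2048,
                         n_layers = 12, landmarks = 64, pinv_iter = 6,
                         downsample_after = c(2, 4),
                         upsample_after = c(8, 10),
                         scale_equivariant = FALSE, pc_loss_weight = 1.0) {
  stopifnot(patch >= 1, n_layers >= max(c(upsample_after, 0)),
            length(downsample_after) == length(upsample_after))
  structure(list(conv_channels = conv_channels, patch = patch,
                 embed_dim = embed_dim, head_dim = head_dim,
                 n_heads = n_heads, mlp_dim = mlp_dim, n_layers = n_layers,
                 landmarks = landmarks, pinv_iter = pinv_iter,
                 downsample_after = downsample_after,
                 upsample_after = upsample_after,
                 scale_equivariant = scale_equivariant,
                 pc_loss_weight = pc_loss_weight),
            class = "model_config")
}

#' Toy preset that fits a CPU desk run
#' @param ... overrides passed to [model_config()].
#' @export
toy_model_config <- function(...) {
  args <- list(conv_channels = 6, patch = 2, embed_dim = 64, head_dim = 16,
               n_heads = 4, mlp_dim = 128, n_layers = 4, landmarks = 16,
               downsample_after = 2, upsample_after = 3)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

#' Training configuration
#'
#' One-cycle learning-rate schedule between the configured endpoints,
#' decoupled (AdamW-style) weight decay 3e-2, gradient accumulation every
#' two batches.
#'
#' @param steps optimizer steps to run.
#' @param lr_initial,lr_max,lr_final one-cycle endpoints.
#' @param weight_decay decoupled weight decay.
#' @param betas Adam moment coefficients.
#' @param accumulate optimizer updates are applied every `accumulate`
#'   batches with averaged gradients.
#' @param warmup_frac fraction of steps spent ramping from `lr_initial` to
#'   `lr_max`.
#' @param seed parameter-initialisation / shuffling seed.
#' @export
train_config <- function(steps = 500, lr_initial = 4.5e-4, lr_max = 2.85e-3,
                         lr_final = 8.57e-4, weight_decay = 3e-2,
                         betas = c(0.9, 0.999), accumulate = 2,
                         warmup_frac = 0.3, seed = 1) {
  stopifnot(lr_initial > 0, lr_max > 0, lr_final > 0, steps >= 1)
  structure(list(steps = steps, lr_initial = lr_initial, lr_max = lr_max,
                 lr_final = lr_final, weight_decay = weight_decay,
                 betas = betas, accumulate = accumulate,
                 warmup_frac = warmup_frac, seed = seed),
            class = "train_config")
}

#' One-cycle learning rate at a given step
#'
#' Cosine ramp from `lr_initial` to `lr_max` over the warmup fraction,
#' cosine anneal from `lr_max` to `lr_final` afterwards; the endpoints are
#' hit exactly at steps 1, peak and `steps`.
#'
#' @param step step number in `1..cfg$steps`.
#' @param cfg a [train_config()].
#' @export
one_cycle_lr <- function(step, cfg) {
  s_peak <- max(2, ceiling(cfg$warmup_frac * cfg$steps))
  if (cfg$steps == 1) return(cfg$lr_max)
  if (step <= s_peak) {
    t <- (step - 1) / (s_peak - 1)
    cfg$lr_initial + (cfg$lr_max - cfg$lr_initial) * (1 - cos(pi * t)) / 2
  } else {
    t <- (step - s_peak) / (cfg$steps - s_peak)
    cfg$lr_final + (cfg$lr_max - cfg$lr_final) * (1 + cos(pi * t)) / 2
  }
}

# ---- index helpers ---------------------------------------------------------

# flat (column-major) positions for a 4D (n1,n2,n3,C) layout stored as an
# (n1*n2*n3) x C matrix in voxel-major order
flat_vox <- function(dims, i1, i2, i3) {
  i1 + dims[1] * ((i2 - 1) + dims[2] * (i3 - 1))
}

circ <- function(i, n) ((i - 1) %% n) + 1

# gather-index cache: the same index matrices (and their scatter plans)
# recur on every forward pass, so build each once per geometry
.idx_cache <- new.env(parent = emptyenv())

cached_idx <- function(key, maker) {
  hit <- .idx_cache[[key]]
  if (is.null(hit)) {
    idx <- maker()
    hit <- list(idx = idx, plan = gather_plan(idx))
    .idx_cache[[key]] <- hit
  }
  hit
}

key3 <- function(tag, ...) paste(tag, paste(unlist(list(...)), collapse = "-"),
                                 sep = ":")

gather_cached <- function(x, key, maker) {
  hit <- cached_idx(key, maker)
  ad_gather(x, hit$idx, plan = hit$plan)
}

cached_val <- function(key, maker) {
  hit <- .idx_cache[[key]]
  if (is.null(hit)) {
    hit <- maker()
    .idx_cache[[key]] <- hit
  }
  hit
}

# im2col indices for a circular 3^3 convolution at dilation `dil` over a
# volume matrix (Nvox x C): result (Nvox x 27*C)
make_im2col_idx <- function(dims, n_channels, dil = 1L) {
  nvox <- prod(dims)
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  cols <- matrix(0L, nrow = nvox, ncol = 27L * n_channels)
  col <- 0L
  for (o in seq_len(27)) {
    vox <- flat_vox(dims,
                    circ(g$i + offs$di[o] * dil, dims[1]),
                    circ(g$j + offs$dj[o] * dil, dims[2]),
                    circ(g$k + offs$dk[o] * dil, dims[3]))
    for (ch in seq_len(n_channels)) {
      col <- col + 1L
      cols[, col] <- vox + nvox * (ch - 1L)
    }
  }
  cols
}

# patchify indices: volume matrix (Nvox x C) -> (Ntok x p^3*C)
make_patchify_idx <- function(dims, n_channels, p) {
  gd <- dims %/% p
  tok <- expand.grid(ti = seq_len(gd[1]), tj = seq_len(gd[2]),
                     tk = seq_len(gd[3]))
  offs <- expand.grid(di = seq_len(p), dj = seq_len(p), dk = seq_len(p))
  nvox <- prod(dims)
  idx <- matrix(0L, nrow = nrow(tok), ncol = p^3 * n_channels)
  col <- 0L
  for (o in seq_len(nrow(offs))) {
    vox <- flat_vox(dims,
                    (tok$ti - 1L) * p + offs$di[o],
                    (tok$tj - 1L) * p + offs$dj[o],
                    (tok$tk - 1L) * p + offs$dk[o])
    for (ch in seq_len(n_channels)) {
      col <- col + 1L
      idx[, col] <- vox + nvox * (ch - 1L)
    }
  }
  idx
}

# inverse of patchify: (Ntok x p^3*C) -> volume matrix (Nvox x C)
make_depatchify_idx <- function(dims, n_channels, p) {
  gd <- dims %/% p
  ntok <- prod(gd)
  g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                   k = seq_len(dims[3]))
  ti <- (g$i - 1L) %/% p + 1L; di <- (g$i - 1L) %% p + 1L
  tj <- (g$j - 1L) %/% p + 1L; dj <- (g$j - 1L) %% p + 1L
  tk <- (g$k - 1L) %/% p + 1L; dk <- (g$k - 1L) %% p + 1L
  tok <- flat_vox(gd, ti, tj, tk)
  slot <- di + p * ((dj - 1L) + p * (dk - 1L))
  idx <- matrix(0L, nrow = prod(dims), ncol = n_channels)
  for (ch in seq_len(n_channels)) {
    idx[, ch] <- tok + ntok * ((slot - 1L) + p^3 * (ch - 1L))
  }
  idx
}

# circular padding of a volume matrix (Nvox x C) to target dims
make_pad_idx <- function(dims, target, n_channels) {
  nvox <- prod(dims)
  g <- expand.grid(i = circ(seq_len(target[1]), dims[1]),
                   j = circ(seq_len(target[2]), dims[2]),
                   k = circ(seq_len(target[3]), dims[3]))
  vox <- flat_vox(dims, g$i, g$j, g$k)
  idx <- matrix(0L, nrow = prod(target), ncol = n_channels)
  for (ch in seq_len(n_channels)) idx[, ch] <- vox + nvox * (ch - 1L)
  idx
}

# centred crop of a volume matrix (Nvox x C) back to target dims
make_crop_idx <- function(dims, target, n_channels) {
  start <- (dims - target) %/% 2L
  nvox <- prod(dims)
  g <- expand.grid(i = start[1] + seq_len(target[1]),
                   j = start[2] + seq_len(target[2]),
                   k = start[3] + seq_len(target[3]))
  vox <- flat_vox(dims, g$i, g$j, g$k)
  idx <- matrix(0L, nrow = prod(target), ncol = n_channels)
  for (ch in seq_len(n_channels)) idx[, ch] <- vox + nvox * (ch - 1L)
  idx
}

# 3D sinusoidal positional encoding for a token grid, parameter-free and
# therefore usable across heterogeneous grid shapes
positional_encoding <- function(gd, d) {
  per_axis <- d %/% 3
  enc <- matrix(0, nrow = prod(gd), ncol = d)
  g <- expand.grid(i = seq_len(gd[1]), j = seq_len(gd[2]), k = seq_len(gd[3]))
  for (ax in 1:3) {
    pos <- (g[[ax]] - 1) / max(gd[ax] - 1, 1)
    nfreq <- per_axis %/% 2
    for (f in seq_len(nfreq)) {
      w <- pi * 2^(f - 1)
      enc[, (ax - 1) * per_axis + 2 * f - 1] <- sin(w * pos)
      enc[, (ax - 1) * per_axis + 2 * f] <- cos(w * pos)
    }
  }
  enc
}

# ---- parameters ------------------------------------------------------------

xavier <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
         nrow = n_in, ncol = n_out)
}

#' Initialise model parameters
#'
#' @param config a [model_config()].
#' @param n_in input channels (2: Patterson + template).
#' @param seed integer seed for reproducible initialisation.
#' @return named list of `ad_node` leaves (class `model_params`).
#' @export
init_params <- function(config, n_in = 2, seed = 1) {
  set.seed(seed)
  d <- config$embed_dim
  inner <- config$n_heads * config$head_dim
  p <- list()
  p$conv_w <- xavier(27 * n_in, config$conv_channels)
  p$conv_b <- numeric(config$conv_channels)
  p$embed_w <- xavier(config$patch^3 * config$conv_channels, d)
  p$embed_b <- numeric(d)
  for (l in seq_len(config$n_layers)) {
    p[[paste0("ln1_g_", l)]] <- rep(1, d)
    p[[paste0("ln1_b_", l)]] <- numeric(d)
    p[[paste0("qkv_w_", l)]] <- xavier(d, 3 * inner)
    p[[paste0("qkv_b_", l)]] <- numeric(3 * inner)
    p[[paste0("proj_w_", l)]] <- xavier(inner, d)
    p[[paste0("proj_b_", l)]] <- numeric(d)
    p[[paste0("ln2_g_", l)]] <- rep(1, d)
    p[[paste0("ln2_b_", l)]] <- numeric(d)
    p[[paste0("mlp1_w_", l)]] <- xavier(d, config$mlp_dim)
    p[[paste0("mlp1_b_", l)]] <- numeric(config$mlp_dim)
    p[[paste0("mlp2_w_", l)]] <- xavier(config$mlp_dim, d)
    p[[paste0("mlp2_b_", l)]] <- numeric(d)
  }
  for (i in seq_along(config$downsample_after)) {
    p[[paste0("down_w_", i)]] <- xavier(8 * d, d)
    p[[paste0("down_b_", i)]] <- numeric(d)
    p[[paste0("up_w_", i)]] <- xavier(d, 8 * d)
    p[[paste0("up_b_", i)]] <- numeric(8 * d)
  }
  p$ln_f_g <- rep(1, d)
  p$ln_f_b <- numeric(d)
  p$head_w <- xavier(d, config$patch^3) * 0.1   # small init for the head
  p$head_b <- numeric(config$patch^3)
  out <- lapply(p, ad_leaf)
  class(out) <- "model_params"
  out
}

# ---- attention -------------------------------------------------------------

# exact softmax attention on ad nodes; q,k,v are (N x dh), pre-scaled
ad_exact_attention <- function(q, k, v) {
  ad_matmul(ad_softmax_rows(ad_matmul(q, ad_transpose(k))), v)
}

# Nystrom approximation: m landmark rows by contiguous segment means,
# iterative Moore-Penrose pseudo-inverse of the landmark kernel
ad_nystrom_attention <- function(q, k, v, m, iters) {
  n <- nrow(q$val)
  if (n <= m) return(ad_exact_attention(q, k, v))
  seg <- cached_val(key3("seg", n, m), function() {
    sm <- matrix(0, nrow = m, ncol = n)
    bounds <- floor(seq(0, n, length.out = m + 1))
    for (i in seq_len(m)) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      sm[i, idx] <- 1 / length(idx)
    }
    sm
  })
  ql <- ad_matmul(ad_leaf(seg), q)
  kl <- ad_matmul(ad_leaf(seg), k)
  f1 <- ad_softmax_rows(ad_matmul(q, ad_transpose(kl)))       # N x m
  a <- ad_softmax_rows(ad_matmul(ql, ad_transpose(kl)))       # m x m
  b1 <- ad_softmax_rows(ad_matmul(ql, ad_transpose(k)))       # m x N
  # iterative cubic Moore-Penrose pseudo-inverse of the landmark kernel
  av <- a$val
  z <- ad_scale(ad_transpose(a), 1 / (max(rowSums(abs(av))) *
                                        max(colSums(abs(av)))))
  eye <- ad_leaf(cached_val(key3("eye", m), function() diag(m)))
  for (it in seq_len(iters)) {
    az <- ad_matmul(a, z)
    inner1 <- ad_sub(ad_scale(eye, 7), az)
    inner2 <- ad_sub(ad_scale(eye, 15), ad_matmul(az, inner1))
    inner3 <- ad_sub(ad_scale(eye, 13), ad_matmul(az, inner2))
    z <- ad_scale(ad_matmul(z, inner3), 0.25)
  }
  ad_matmul(f1, ad_matmul(z, ad_matmul(b1, v)))
}

#' Nystrom approximate attention on plain matrices
#'
#' Softmax attention `softmax(Q K' / sqrt(d)) V` approximated with
#' `landmarks` contiguous-segment landmark means and an iterative
#' pseudo-inverse; falls back to exact attention when the token count does
#' not exceed the landmark count.
#'
#' @param q,k,v numeric matrices (tokens x head dimension).
#' @param landmarks number of landmarks.
#' @param iters pseudo-inverse iterations.
#' @return numeric matrix, same shape as `v`.
#' @export
nystrom_attention <- function(q, k, v, landmarks = 16, iters = 6) {
  s <- ncol(q)^(-0.25)
  ad_value(ad_nystrom_attention(ad_leaf(q * s), ad_leaf(k * s), ad_leaf(v),
                                landmarks, iters))
}

# ---- forward ---------------------------------------------------------------

#' Model forward pass
#'
#' @param patterson,partial `map_grid`s (or arrays) of identical shape,
#'   normalised to `[-1, 1]`.
#' @param params a `model_params` list from [init_params()].
#' @param config the matching [model_config()].
#' @param tape return the output `ad_node` (for training) instead of a
#'   `map_grid`.
#' @return predicted density `map_grid` of the input shape (or the output
#'   node when `tape = TRUE`).
#' @export
model_forward <- function(patterson, partial, params, config, tape = FALSE) {
  pv <- if (inherits(patterson, "map_grid")) patterson$values else patterson
  tv <- if (inherits(partial, "map_grid")) partial$values else partial
  if (!identical(dim(pv), dim(tv))) rlang::abort("input shapes differ")
  in_dims <- dim(pv)
  p <- config$patch
  n_down <- length(config$downsample_after)
  mult <- p * 2^n_down
  target <- as.integer(ceiling(in_dims / mult) * mult)

  x <- ad_leaf(cbind(as.vector(pv), as.vector(tv)))   # Nvox x 2
  if (!identical(target, in_dims)) {
    x <- gather_cached(x, key3("pad", in_dims, target, 2L),
                       function() make_pad_idx(in_dims, target, 2L))
  }
  dims <- target

  # convolutional stem (circular); optional multi-scale shared-weight
  # variant with max-over-scale pooling
  conv_out <- ad_add_bias(
    ad_matmul(gather_cached(x, key3("im2col", dims, 1L, 2L),
                            function() make_im2col_idx(dims, 2L, 1L)),
              params$conv_w),
    params$conv_b)
  if (isTRUE(config$scale_equivariant)) {
    conv_out2 <- ad_add_bias(
      ad_matmul(gather_cached(x, key3("im2col", dims, 2L, 2L),
                              function() make_im2col_idx(dims, 2L, 2L)),
                params$conv_w),
      params$conv_b)
    conv_out <- ad_pmax(conv_out, conv_out2)
  }
  x <- ad_gelu(conv_out)                               # Nvox x C

  gd <- dims %/% p
  tok <- ad_add_bias(
    ad_matmul(gather_cached(x, key3("patch", dims, p, config$conv_channels),
                            function() make_patchify_idx(dims,
                                                         config$conv_channels,
                                                         p)),
              params$embed_w),
    params$embed_b)
  pe <- cached_val(key3("posenc", gd, config$embed_dim),
                   function() positional_encoding(gd, config$embed_dim))
  tok <- ad_add(tok, ad_leaf(pe))

  dim_stack <- list()
  down_i <- 0L; up_i <- 0L
  for (l in seq_len(config$n_layers)) {
    tok <- transformer_block(tok, params, config, l)
    if (l %in% config$downsample_after) {
      down_i <- down_i + 1L
      dim_stack[[length(dim_stack) + 1]] <- gd
      even <- as.integer(ceiling(gd / 2) * 2)
      if (!identical(even, gd)) {
        gd_old <- gd
        tok <- gather_cached(tok, key3("pad", gd_old, even, config$embed_dim),
                             function() make_pad_idx(gd_old, even,
                                                     config$embed_dim))
        gd <- even
      }
      gd_now <- gd
      tok <- ad_add_bias(
        ad_matmul(gather_cached(tok, key3("patch", gd_now, 2L,
                                          config$embed_dim),
                                function() make_patchify_idx(gd_now,
                                                             config$embed_dim,
                                                             2L)),
                  params[[paste0("down_w_", down_i)]]),
        params[[paste0("down_b_", down_i)]])
      gd <- gd %/% 2L
    }
    if (l %in% config$upsample_after) {
      up_i <- up_i + 1L
      expanded <- ad_add_bias(
        ad_matmul(tok, params[[paste0("up_w_", n_down - up_i + 1L)]]),
        params[[paste0("up_b_", n_down - up_i + 1L)]])
      big <- gd * 2L
      tok <- gather_cached(expanded, key3("depatch", big, 2L,
                                          config$embed_dim),
                           function() make_depatchify_idx(big,
                                                          config$embed_dim,
                                                          2L))
      prev <- dim_stack[[length(dim_stack)]]
      dim_stack[[length(dim_stack)]] <- NULL
      if (!identical(big, prev)) {
        tok <- gather_cached(tok, key3("crop", big, prev, config$embed_dim),
                             function() make_crop_idx(big, prev,
                                                      config$embed_dim))
      }
      gd <- prev
    }
  }

  tok <- ad_layernorm_rows(tok, params$ln_f_g, params$ln_f_b)
  out_tok <- ad_add_bias(ad_matmul(tok, params$head_w), params$head_b)
  vol <- gather_cached(out_tok, key3("depatch", dims, p, 1L),
                       function() make_depatchify_idx(dims, 1L, p))
  if (!identical(target, in_dims)) {
    vol <- gather_cached(vol, key3("crop", dims, in_dims, 1L),
                         function() make_crop_idx(dims, in_dims, 1L))
  }
  if (tape) {
    attr(vol, "in_dims") <- in_dims
    return(vol)
  }
  out <- array(ad_value(vol), dim = in_dims)
  cellv <- if (inherits(patterson, "map_grid")) patterson$cell else rep(NA_real_, 3)
  map_grid(out, cellv, "density",
           d_min = if (inherits(patterson, "map_grid")) patterson$d_min
           else NA_real_)
}

transformer_block <- function(tok, params, config, l) {
  d <- config$embed_dim
  inner <- config$n_heads * config$head_dim
  n <- nrow(tok$val)
  h <- ad_layernorm_rows(tok, params[[paste0("ln1_g_", l)]],
                         params[[paste0("ln1_b_", l)]])
  qkv <- ad_add_bias(ad_matmul(h, params[[paste0("qkv_w_", l)]]),
                     params[[paste0("qkv_b_", l)]])
  s <- config$head_dim^(-0.25)
  heads <- vector("list", config$n_heads)
  for (hd in seq_len(config$n_heads)) {
    off <- (hd - 1) * config$head_dim
    qc <- off + seq_len(config$head_dim)
    q <- ad_scale(ad_cols(qkv, qc), s)
    k <- ad_scale(ad_cols(qkv, inner + qc), s)
    v <- ad_cols(qkv, 2 * inner + qc)
    heads[[hd]] <- ad_nystrom_attention(q, k, v, config$landmarks,
                                        config$pinv_iter)
  }
  att <- ad_add_bias(ad_matmul(ad_cbind(heads),
                               params[[paste0("proj_w_", l)]]),
                     params[[paste0("proj_b_", l)]])
  tok <- ad_add(tok, att)
  h2 <- ad_layernorm_rows(tok, params[[paste0("ln2_g_", l)]],
                          params[[paste0("ln2_b_", l)]])
  mlp <- ad_add_bias(
    ad_matmul(ad_gelu(ad_add_bias(ad_matmul(h2, params[[paste0("mlp1_w_", l)]]),
                                  params[[paste0("mlp1_b_", l)]])),
              params[[paste0("mlp2_w_", l)]]),
    params[[paste0("mlp2_b_", l)]])
  ad_add(tok, mlp)
}

# column subset of a matrix node (contiguous column ranges)
ad_cols <- function(x, cols) {
  n <- nrow(x$val)
  nc <- ncol(x$val)
  hit <- cached_idx(paste("cols", n, nc, cols[1], length(cols), sep = ":"),
                    function() outer(seq_len(n), (cols - 1L) * n, "+"))
  ad_gather(x, hit$idx, c(n, length(cols)), plan = hit$plan)
}

# ---- loss ------------------------------------------------------------------

# Pearson correlation between two nodes (flattened), on the tape
ad_pearson <- function(a, b) {
  ac <- ad_sub_scalar(a, ad_mean(a))
  bc <- ad_sub_scalar(b, ad_mean(b))
  num <- ad_mean(ad_mul(ac, bc))
  den <- ad_sqrt(ad_mul(ad_mean(ad_mul(ac, ac)), ad_mean(ad_mul(bc, bc))))
  ad_div(num, den)
}

#' Composite training loss
#'
#' `L = MSE(pred, truth) + pc_weight * (-r(pred, truth))` with `r` the
#' Pearson correlation over all voxels. With `pc_weight = 0` the loss is
#' plain MSE. A zero-variance truth map drops the Pearson term with a
#' warning.
#'
#' @param pred,truth `map_grid`s or arrays of identical shape (or an
#'   `ad_node` for `pred` during training).
#' @param pc_weight weight of the negative-correlation term.
#' @return scalar loss (an `ad_node` when `pred` is one, else numeric).
#' @export
model_loss <- function(pred, truth, pc_weight = 1.0) {
  tv <- if (inherits(truth, "map_grid")) truth$values else truth
  on_tape <- inherits(pred, "ad_node")
  pn <- if (on_tape) pred
  else ad_leaf(if (inherits(pred, "map_grid")) pred$values else pred)
  if (length(pn$val) != length(tv)) rlang::abort("shape mismatch")
  tn <- ad_leaf(as.vector(tv))
  pn_flat <- if (is.null(dim(pn$val)) || length(dim(pn$val)) == 1) pn
  else ad_gather(pn, seq_along(pn$val), length(pn$val))
  diff <- ad_sub(pn_flat, tn)
  loss <- ad_mean(ad_mul(diff, diff))
  if (pc_weight != 0) {
    if (stats::sd(as.vector(tv)) == 0) {
      rlang::warn("zero-variance truth: Pearson loss term skipped")
    } else {
      loss <- ad_add(loss, ad_scale(ad_pearson(pn_flat, tn), -pc_weight))
    }
  }
  if (on_tape) loss else ad_value(loss)
}

# ---- training --------------------------------------------------------------

#' Train the toy model on a small dataset
#'
#' Full-batch records are cycled in batches; an AdamW-style optimizer with
#' decoupled weight decay applies an update every `accumulate` batches
#' under the one-cycle schedule. Deterministic under `train_cfg$seed`.
#'
#' @param records list of training records, each
#'   `list(patterson =, partial =, truth =)` of `map_grid`s/arrays of one
#'   common shape (use [training_records()] to flatten dataset examples).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param batch_size records per batch.
#' @param verbose print progress every 50 steps.
#' @return object of class `xtal_model`: list with `params`, `config`,
#'   `train_config` and `history` (tibble: step, lr, loss).
#' @export
train_toy <- function(records, model_cfg = toy_model_config(),
                      train_cfg = train_config(), batch_size = 8,
                      verbose = FALSE) {
  if (length(records) == 0) rlang::abort("empty dataset")
  params <- init_params(model_cfg, seed = train_cfg$seed)
  state <- lapply(params, function(p) list(m = p$val * 0, v = p$val * 0))
  history <- vector("list", train_cfg$steps)
  set.seed(train_cfg$seed + 1)
  n <- length(records)
  batch_of <- function(i) {
    idx <- (((i - 1) * batch_size):((i) * batch_size - 1)) %% n + 1
    records[idx]
  }
  t_adam <- 0
  for (step in seq_len(train_cfg$steps)) {
    lr <- one_cycle_lr(step, train_cfg)
    losses <- numeric(train_cfg$accumulate)
    for (acc in seq_len(train_cfg$accumulate)) {
      batch <- batch_of((step - 1) * train_cfg$accumulate + acc)
      for (rec in batch) {
        ad_tape_start()
        out <- model_forward(rec$patterson, rec$partial, params, model_cfg,
                             tape = TRUE)
        loss <- model_loss(out, rec$truth, model_cfg$pc_loss_weight)
        ad_backward(loss)
        losses[acc] <- losses[acc] + ad_value(loss) / length(batch)
        ad_tape_stop()
      }
    }
    n_grads <- train_cfg$accumulate * batch_size
    t_adam <- t_adam + 1
    b1 <- train_cfg$betas[1]; b2 <- train_cfg$betas[2]
    for (nm in names(params)) {
      p <- params[[nm]]
      g <- (p$grad %||% (p$val * 0)) / n_grads
      st <- state[[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      state[[nm]] <- st
      mhat <- st$m / (1 - b1^t_adam)
      vhat <- st$v / (1 - b2^t_adam)
      p$val <- p$val - lr * (mhat / (sqrt(vhat) + 1e-8) +
                               train_cfg$weight_decay * p$val)
      p$grad <- NULL
    }
    history[[step]] <- tibble::tibble(step = step, lr = lr,
                                      loss = mean(losses))
    if (verbose && step %% 50 == 0) {
      message(sprintf("step %d  lr %.2e  loss %.4f", step, lr, mean(losses)))
    }
  }
  structure(list(params = params, config = model_cfg,
                 train_config = train_cfg,
                 history = dplyr::bind_rows(history)),
            class = "xtal_model")
}

#' Flatten dataset examples into training records
#'
#' One record per (example, partial) pair: the example's Patterson map,
#' one partial template and the ground-truth density.
#'
#' @param examples list of `dataset_example`s (normalised).
#' @return list of `list(patterson =, partial =, truth =)`.
#' @export
training_records <- function(examples) {
  out <- list()
  for (ex in examples) {
    for (p in ex$partials) {
      out[[length(out) + 1]] <- list(patterson = ex$patterson,
                                     partial = p$map,
                                     truth = ex$ground_truth)
    }
  }
  out
}

#' @export
print.xtal_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$val), numeric(1)))
  cat(sprintf("<xtal_model: %d parameters, %d layers, trained %d steps, final loss %.4f>\n",
              np, x$config$n_layers, nrow(x$history),
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' Training history of a fitted model
#' @param x an `xtal_model`.
#' @param ... unused.
#' @return tibble: `step`, `lr`, `loss`.
#' @export
#' @exportS3Method generics::tidy
tidy.xtal_model <- function(x, ...) x$history

#' One-row fit summary of a trained model
#' @param x an `xtal_model`.
#' @param ... unused.
#' @export
#' @exportS3Method generics::glance
glance.xtal_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, function(p) length(p$val), numeric(1))),
    n_layers = x$config$n_layers,
    steps = nrow(x$history),
    final_loss = utils::tail(x$history$loss, 1),
    final_lr = utils::tail(x$history$lr, 1))
}

#' Predict a density map from a Patterson/template pair
#'
#' @param object an `xtal_model`.
#' @param patterson,partial input `map_grid`s (normalised scale).
#' @param ... unused.
#' @export
predict.xtal_model <- function(object, patterson, partial, ...) {
  model_forward(patterson, partial, object$params, object$config)
}
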