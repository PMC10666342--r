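#' 3D U-Net configuration
#'
#' Both sub-networks share this backbone: an encoder-decoder with skip
#' connections, 3x3x3 convolutions spanning (phase, row, col) with circular
#' padding along the cardiac-phase axis (cine loops are periodic) and zero
#' padding in-plane, leaky-ReLU activations, 2x2 in-plane average pooling
#' between levels and nearest-neighbour upsampling. The two heads differ
#' only in their input/output layers: the VI head takes 1 channel and ends
#' in a sigmoid (map in (0,1)); the AS head takes 2 channels (movie + VI
#' map) and ends non-negative linear (ReLU-clamped magnitude image).
#'
#' @param depth number of resolution levels (>= 2).
#' @param base_channels channels at the top level (>= 4); doubled per level.
#' @param in_channels,out_channels head input/output channels.
#' @param final_activation `"sigmoid"`, `"linear"` or `"softplus"`. The AS
#'   head uses `"linear"` with an output clamp at 0 applied in
#'   [as_forward()] (non-negative linear), so training gradients never
#'   vanish on dark voxels.
#' @return list of class `net_config`.
#' @export
net_config <- function(depth = 3, base_channels = 16, in_channels = 1,
                       out_channels = 1,
                       final_activation = c("sigmoid", "linear", "softplus")) {
  final_activation <- match.arg(final_activation)
  if (depth < 2) stop("depth must be >= 2")
  if (base_channels < 4) stop("base_channels must be >= 4")
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = in_channels, out_channels = out_channels,
                 final_activation = final_activation, kernel = 3L),
            class = "net_config")
}

# Table of conv layers implied by a config.
unet_layers <- function(config) {
  d <- config$depth
  ch <- config$base_channels * 2^(seq_len(d) - 1)
  rows <- list()
  for (l in seq_len(d)) {
    cin <- if (l == 1) config$in_channels else ch[l - 1]
    rows[[length(rows) + 1]] <- list(name = paste0("enc", l, "a"), cin = cin, cout = ch[l], ks = 3L)
    rows[[length(rows) + 1]] <- list(name = paste0("enc", l, "b"), cin = ch[l], cout = ch[l], ks = 3L)
  }
  for (l in rev(seq_len(d - 1))) {
    rows[[length(rows) + 1]] <- list(name = paste0("dec", l, "a"),
                                     cin = ch[l] + ch[l + 1], cout = ch[l], ks = 3L)
    rows[[length(rows) + 1]] <- list(name = paste0("dec", l, "b"), cin = ch[l], cout = ch[l], ks = 3L)
  }
  rows[[length(rows) + 1]] <- list(name = "final", cin = ch[1],
                                   cout = config$out_channels, ks = 1L)
  rows
}

#' Build a 3D U-Net with deterministic initialization
#'
#' He-normal weight initialization driven by `seed`; two builds with the
#' same `(config, seed)` have identical parameters.
#'
#' @param config a [net_config()].
#' @param seed integer seed.
#' @return list of class `unet` with `config`, `params`, `seed`.
#' @export
build_unet <- function(config, seed = 0L) {
  stopifnot(inherits(config, "net_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  params <- list()
  for (ly in unet_layers(config)) {
    fan_in <- ly$cin * ly$ks^3
    sdv <- if (ly$name == "final") sqrt(1 / fan_in) else sqrt(2 / fan_in)
    W <- matrix(stats::rnorm(ly$cout * fan_in, 0, sdv), ly$cout, fan_in)
    params[[ly$name]] <- list(W = W, b = numeric(ly$cout), ks = ly$ks)
  }
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "unet")
}

lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_grad <- function(pre) ifelse(pre > 0, 1, 0.1)
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

avgpool2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[3], 2); i2 <- i1 + 1
  j1 <- seq(1, d[4], 2); j2 <- j1 + 1
  (x[, , i1, j1, drop = FALSE] + x[, , i2, j1, drop = FALSE] +
     x[, , i1, j2, drop = FALSE] + x[, , i2, j2, drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, in_dim) {
  dx <- array(0, dim = in_dim)
  d <- dim(dy)
  i1 <- seq(1, in_dim[3], 2); i2 <- i1 + 1
  j1 <- seq(1, in_dim[4], 2); j2 <- j1 + 1
  q <- dy / 4
  dx[, , i1, j1] <- q; dx[, , i2, j1] <- q
  dx[, , i1, j2] <- q; dx[, , i2, j2] <- q
  dx
}

upsample2 <- function(x) {
  d <- dim(x)
  x[, , rep(seq_len(d[3]), each = 2), rep(seq_len(d[4]), each = 2), drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1, d[3], 2); i2 <- i1 + 1
  j1 <- seq(1, d[4], 2); j2 <- j1 + 1
  dy[, , i1, j1, drop = FALSE] + dy[, , i2, j1, drop = FALSE] +
    dy[, , i1, j2, drop = FALSE] + dy[, , i2, j2, drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

check_input_dims <- function(config, d) {
  div <- 2^(config$depth - 1)
  if (d[3] %% div != 0 || d[4] %% div != 0) {
    stop("in-plane size (", d[3], " x ", d[4], ") is not divisible by 2^(depth-1) = ",
         div, "; pad or crop the movie before the forward pass")
  }
  if (d[3] < 2 * div || d[4] < 2 * div) {
    stop("input smaller than the network's receptive grid; reduce depth")
  }
}

# Forward pass. x: array (C, P, H, W). Returns list(out, cache) when
# cache = TRUE, else just the output array (Cout, P, H, W).
unet_forward <- function(net, x, cache = FALSE) {
  config <- net$config; params <- net$params
  d <- dim(x)
  if (d[1] != config$in_channels) {
    stop("expected ", config$in_channels, " input channel(s), got ", d[1])
  }
  check_input_dims(config, d)
  cc <- if (cache) new.env(parent = emptyenv()) else NULL
  conv_act <- function(name, h, act = TRUE) {
    p <- params[[name]]
    xd <- as.double(h)
    y <- cb_conv3d_fwd(xd, dim(h), p$W, p$b, p$ks)
    if (cache) assign(name, list(x = xd, pre = y, in_dim = dim(h)), envir = cc)
    if (act) lrelu(y) else y
  }
  depth <- config$depth
  skips <- vector("list", depth - 1)
  pool_dims <- vector("list", depth - 1)
  h <- x
  for (l in seq_len(depth)) {
    h <- conv_act(paste0("enc", l, "a"), h)
    h <- conv_act(paste0("enc", l, "b"), h)
    if (l < depth) {
      skips[[l]] <- h
      pool_dims[[l]] <- dim(h)
      h <- avgpool2(h)
    }
  }
  for (l in rev(seq_len(depth - 1))) {
    h <- concat_ch(skips[[l]], upsample2(h))
    h <- conv_act(paste0("dec", l, "a"), h)
    h <- conv_act(paste0("dec", l, "b"), h)
  }
  pre <- conv_act("final", h, act = FALSE)
  out <- switch(config$final_activation,
                sigmoid = sigmoid(pre),
                linear = pre,
                softplus = softplus(pre))
  if (cache) {
    assign(".pre_final", pre, envir = cc)
    assign(".pool_dims", pool_dims, envir = cc)
    list(out = out, cache = cc)
  } else out
}

# Backward pass. dout: gradient of the loss w.r.t. the head output.
# Returns list(grads) with the same structure as net$params.
unet_backward <- function(net, cache, out, dout) {
  config <- net$config; params <- net$params
  grads <- list()
  conv_bwd <- function(name, dy, act = TRUE) {
    st <- get(name, envir = cache)
    if (act) dy <- dy * lrelu_grad(st$pre)
    p <- params[[name]]
    r <- cb_conv3d_bwd(st$x, st$in_dim, p$W, as.double(dy), p$ks)
    grads[[name]] <<- list(W = r$dW, b = as.numeric(r$db))
    r$dx
  }
  pre <- get(".pre_final", envir = cache)
  dpre <- switch(config$final_activation,
                 sigmoid = dout * out * (1 - out),
                 linear = dout,
                 softplus = dout * sigmoid(pre))
  dh <- conv_bwd("final", dpre, act = FALSE)
  depth <- config$depth
  ch <- config$base_channels * 2^(seq_len(depth) - 1)
  pool_dims <- get(".pool_dims", envir = cache)
  dskips <- vector("list", depth - 1)
  for (l in seq_len(depth - 1)) {
    dh <- conv_bwd(paste0("dec", l, "b"), dh)
    dh <- conv_bwd(paste0("dec", l, "a"), dh)
    dskips[[l]] <- dh[seq_len(ch[l]), , , , drop = FALSE]
    dh <- upsample2_bwd(dh[ch[l] + seq_len(ch[l + 1]), , , , drop = FALSE])
  }
  for (l in rev(seq_len(depth))) {
    if (l < depth) dh <- avgpool2_bwd(dh, pool_dims[[l]]) + dskips[[l]]
    dh <- conv_bwd(paste0("enc", l, "b"), dh)
    dh <- conv_bwd(paste0("enc", l, "a"), dh)
  }
  grads
}

#' Build the voxel-identification (VI) sub-network
#'
#' One input channel (the cine movie), sigmoid head: the output VI map is
#' architecturally confined to (0, 1).
#' @param depth,base_channels backbone size.
#' @param seed integer seed.
#' @return a `unet`.
#' @export
build_vi_net <- function(depth = 3, base_channels = 16, seed = 0L) {
  build_unet(net_config(depth, base_channels, in_channels = 1,
                        out_channels = 1, final_activation = "sigmoid"), seed)
}

#' Build the artifact-suppression (AS) sub-network
#'
#' Two input channels -- the cine movie concatenated with its VI map -- and
#' a non-negative linear (ReLU-clamped) head so the restored movie is a
#' magnitude image.
#' @inheritParams build_vi_net
#' @return a `unet`.
#' @export
build_as_net <- function(depth = 3, base_channels = 16, seed = 1L) {
  build_unet(net_config(depth, base_channels, in_channels = 2,
                        out_channels = 1, final_activation = "linear"), seed)
}

as_movie_array <- function(movie) {
  if (inherits(movie, "cine_movie")) movie$data
  else if (is.array(movie) && length(dim(movie)) == 3) movie
  else stop("expected a cine_movie or a (phases x H x W) array")
}

#' VI sub-network forward pass
#'
#' @param net a VI `unet` (1 input channel, sigmoid head).
#' @param movie a preprocessed `cine_movie` or movie-shaped array.
#' @return list of class `vi_map` with `data` (phases x H x W, values in
#'   (0,1)).
#' @export
vi_forward <- function(net, movie) {
  stopifnot(inherits(net, "unet"))
  if (net$config$in_channels != 1) stop("not a VI network (expects 1 input channel)")
  m <- as_movie_array(movie)
  x <- array(m, dim = c(1, dim(m)))
  out <- unet_forward(net, x)
  structure(list(data = array(out, dim = dim(m))), class = "vi_map")
}

#' AS sub-network forward pass
#'
#' Consumes exactly the concatenation (movie, VI map); the VI channel is
#' mandatory. Sequence metadata is carried through unchanged.
#'
#' @param net an AS `unet` (2 input channels, softplus head).
#' @param movie a preprocessed `cine_movie`.
#' @param vimap the corresponding `vi_map` (same geometry).
#' @return a non-negative `cine_movie` of identical geometry.
#' @export
as_forward <- function(net, movie, vimap) {
  stopifnot(inherits(net, "unet"))
  if (net$config$in_channels != 2) {
    stop("not an AS network (expects 2 input channels: movie + VI map)")
  }
  if (missing(vimap) || is.null(vimap)) {
    stop("the AS sub-network requires the VI map channel; none was supplied")
  }
  m <- as_movie_array(movie)
  v <- if (inherits(vimap, "vi_map")) vimap$data else vimap
  if (!identical(dim(m), dim(v))) stop("movie and VI map geometry mismatch")
  x <- array(0, dim = c(2, dim(m)))
  x[1, , , ] <- m; x[2, , , ] <- v
  out <- unet_forward(net, x)
  # non-negative linear head: clamp the linear output at the module
  # boundary so the restored movie is a valid magnitude image
  data <- array(pmax(out, 0), dim = dim(m))
  if (inherits(movie, "cine_movie")) {
    res <- new_cine_movie(data, movie$offset_hz, movie$tr_ms, movie$te_ms,
                          movie$flip_deg, movie$pe_axis)
    attr(res, "norm_factor") <- attr(movie, "norm_factor")
    res
  } else data
}

# Flatten / unflatten parameter lists for the optimizer.
params_flatten <- function(params) {
  unlist(lapply(params, function(p) c(as.numeric(p$W), p$b)), use.names = FALSE)
}
params_checksum <- function(params) {
  v <- params_flatten(params)
  c(n = length(v), sum = sum(v), sumsq = sum(v^2))
}
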