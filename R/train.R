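#' Training configuration
#'
#' @param epochs epochs per stage (>= 1).
#' @param batch_size movies per optimizer step.
#' @param lr Adam learning rate (cosine-decayed over the stage).
#' @param vi_loss,as_loss losses: MSE against the soft VI labels, L1
#'   against the SPC labels.
#' @param val_fraction fraction of subjects held out for validation,
#'   in (0, 1). Splitting is always by subject, never by movie, so offsets
#'   of the same anatomy cannot leak across the split.
#' @param seed integer seed controlling initialization and batching.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 4, lr = 1e-3,
                         vi_loss = "mse", as_loss = "l1",
                         val_fraction = 0.25, seed = 0L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1) stop("val_fraction must be in (0,1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, optimizer = "adam", vi_loss = vi_loss,
                 as_loss = as_loss, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a paired training set from a synthetic sweep collection
#'
#' For every movie of every sweep: the normalized input, the SPC label on
#' the same intensity scale (AS target) and the sigmoid VI label computed
#' from the raw intensities (VI target).
#'
#' @param collection a `sweep_collection` from [generate_dataset()].
#' @param central_band_hz SPC central band (default 55 Hz).
#' @return list of class `training_set`: `samples` (each with `x`, `vi`,
#'   `as`, `subject`, `sweep_index`, `movie_index`, `norm_factor`),
#'   `spc_source_offsets_hz`, `central_band_hz`.
#' @export
build_training_set <- function(collection, central_band_hz = 55) {
  stopifnot(inherits(collection, "sweep_collection"))
  samples <- list()
  src_offsets <- NULL
  for (k in seq_along(collection$sweeps)) {
    sw <- collection$sweeps[[k]]
    spc <- spc_combine(sw, central_band_hz)
    src_offsets <- spc$source_offsets_hz
    man_k <- collection$manifest[collection$manifest$sweep_index == k, ]
    subject <- man_k$subject[1]
    for (i in seq_along(sw$movies)) {
      mv <- sw$movies[[i]]
      pm <- preprocess(mv)
      f <- attr(pm, "norm_factor")
      vi <- vi_label(spc, mv)
      samples[[length(samples) + 1]] <- list(
        x = pm$data, vi = vi$data, as = spc$data / f,
        subject = subject, sweep_index = k, movie_index = i,
        norm_factor = f)
    }
  }
  structure(list(samples = samples, spc_source_offsets_hz = src_offsets,
                 central_band_hz = central_band_hz),
            class = "training_set")
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Split sample indices by subject, deterministically under the config seed.
split_by_subject <- function(samples, val_fraction, seed) {
  subj <- vapply(samples, function(s) s$subject, numeric(1))
  subjects <- sort(unique(subj))
  n_val <- max(1L, floor(val_fraction * length(subjects)))
  if (n_val >= length(subjects)) stop("val_fraction leaves no training subjects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  val_subjects <- sample(subjects, n_val)
  list(train = which(!subj %in% val_subjects),
       val = which(subj %in% val_subjects),
       val_subjects = val_subjects)
}

loss_and_grad <- function(kind, pred, target) {
  n <- length(pred)
  if (kind == "mse") {
    list(loss = mean((pred - target)^2), grad = 2 * (pred - target) / n)
  } else if (kind == "l1") {
    list(loss = mean(abs(pred - target)), grad = sign(pred - target) / n)
  } else stop("unknown loss: ", kind)
}

# Shared SGD loop for both stages. make_input maps a sample to the network
# input array (C,P,H,W); target_field picks the label.
run_training <- function(net, tset, config, make_input, target_field, loss_kind) {
  split <- split_by_subject(tset$samples, config$val_fraction, config$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  state <- adam_init(net$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  step <- 0L
  eval_loss <- function(idx) {
    ls <- vapply(idx, function(i) {
      s <- tset$samples[[i]]
      out <- unet_forward(net, make_input(s))
      loss_and_grad(loss_kind, out, array(s[[target_field]], dim = dim(out)))$loss
    }, numeric(1))
    mean(ls)
  }
  for (epoch in seq_len(config$epochs)) {
    lr_e <- config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    ord <- sample(split$train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_losses <- numeric(0)
    for (bi in batches) {
      acc <- NULL
      bl <- 0
      for (i in bi) {
        s <- tset$samples[[i]]
        fw <- unet_forward(net, make_input(s), cache = TRUE)
        lg <- loss_and_grad(loss_kind, fw$out,
                            array(s[[target_field]], dim = dim(fw$out)))
        bl <- bl + lg$loss
        g <- unet_backward(net, fw$cache, fw$out, lg$grad)
        if (is.null(acc)) acc <- g
        else for (nm in names(acc)) {
          acc[[nm]]$W <- acc[[nm]]$W + g[[nm]]$W
          acc[[nm]]$b <- acc[[nm]]$b + g[[nm]]$b
        }
      }
      for (nm in names(acc)) {
        acc[[nm]]$W <- acc[[nm]]$W / length(bi)
        acc[[nm]]$b <- acc[[nm]]$b / length(bi)
      }
      step <- step + 1L
      upd <- adam_step(net$params, acc, state, lr_e, step)
      net$params <- upd$params; state <- upd$state
      tr_losses <- c(tr_losses, bl / length(bi))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(tr_losses),
      val_loss = eval_loss(split$val), lr = lr_e))
  }
  list(net = net, history = history, val_subjects = split$val_subjects)
}

#' Stage 1: train the VI sub-network
#'
#' Fits the VI network to the sigmoid voxel-identity labels with MSE loss.
#' Deterministic given `(training set, config)`.
#'
#' @param tset a [build_training_set()] result; every sample must carry a
#'   `vi` label.
#' @param config a [train_config()].
#' @param net optional pre-built VI `unet`
#'   (default `build_vi_net(seed = config$seed)`).
#' @return list of class `checkpoint`: `net`, `history` (per-epoch
#'   train/val loss), `stage = "vi"`, `config`, `val_subjects`.
#' @export
train_vi <- function(tset, config = train_config(), net = NULL) {
  stopifnot(inherits(tset, "training_set"))
  missing_vi <- which(vapply(tset$samples, function(s) is.null(s$vi), logical(1)))
  if (length(missing_vi) > 0) {
    stop("samples missing VI labels: ", paste(missing_vi, collapse = ", "))
  }
  if (is.null(net)) net <- build_vi_net(seed = config$seed)
  res <- run_training(net, tset, config,
                      make_input = function(s) array(s$x, dim = c(1, dim(s$x))),
                      target_field = "vi", loss_kind = config$vi_loss)
  structure(list(net = res$net, history = res$history, stage = "vi",
                 config = config, val_subjects = res$val_subjects,
                 seed = config$seed),
            class = "checkpoint")
}

#' Stage 2: train the AS sub-network with a frozen VI network
#'
#' The VI checkpoint is used only to compute the conditioning VI-map
#' channel; its parameters receive no gradient and are asserted bit-
#' identical before and after the stage. AS is fit to the SPC labels with
#' L1 loss.
#'
#' @param tset a [build_training_set()] result (samples must carry `as`
#'   labels).
#' @param vi_checkpoint the stage-1 `checkpoint`.
#' @param config a [train_config()].
#' @param net optional pre-built AS `unet`.
#' @return a `checkpoint` (stage `"as"`) carrying `vi_frozen_checksum`.
#' @export
train_as <- function(tset, vi_checkpoint, config = train_config(), net = NULL) {
  stopifnot(inherits(tset, "training_set"))
  if (!inherits(vi_checkpoint, "checkpoint") || vi_checkpoint$stage != "vi") {
    stop("vi_checkpoint must be a stage-1 ('vi') checkpoint")
  }
  missing_as <- which(vapply(tset$samples, function(s) is.null(s$as), logical(1)))
  if (length(missing_as) > 0) {
    stop("samples missing SPC labels: ", paste(missing_as, collapse = ", "))
  }
  vi_params_before <- vi_checkpoint$net$params
  # precompute the frozen VI maps once per sample
  tset$samples <- lapply(tset$samples, function(s) {
    s$vi_map <- vi_forward(vi_checkpoint$net, s$x)$data
    s
  })
  if (is.null(net)) net <- build_as_net(seed = config$seed + 1L)
  make_input <- function(s) {
    x <- array(0, dim = c(2, dim(s$x)))
    x[1, , , ] <- s$x; x[2, , , ] <- s$vi_map
    x
  }
  res <- run_training(net, tset, config, make_input,
                      target_field = "as", loss_kind = config$as_loss)
  if (!identical(vi_checkpoint$net$params, vi_params_before)) {
    stop("freeze contract violated: VI parameters changed during AS training")
  }
  structure(list(net = res$net, history = res$history, stage = "as",
                 config = config, val_subjects = res$val_subjects,
                 seed = config$seed,
                 vi_frozen_checksum = params_checksum(vi_params_before)),
            class = "checkpoint")
}

#' Two-stage training of the dual-stage network
#'
#' Trains the VI sub-network first, freezes it, then trains the AS
#' sub-network conditioned on the frozen VI map.
#'
#' @param tset a [build_training_set()] result.
#' @param config a [train_config()] shared by both stages.
#' @return list of class `dualstage_fit`: `vi` and `as` checkpoints plus a
#'   `report` (configs, seeds, SPC source offsets, final losses, freeze
#'   check).
#' @export
two_stage_train <- function(tset, config = train_config()) {
  vi_ck <- train_vi(tset, config)
  as_ck <- train_as(tset, vi_ck, config)
  frozen_ok <- identical(params_checksum(vi_ck$net$params),
                         as_ck$vi_frozen_checksum)
  report <- list(
    seed = config$seed,
    spc_source_offsets_hz = tset$spc_source_offsets_hz,
    central_band_hz = tset$central_band_hz,
    epochs_per_stage = config$epochs,
    vi_final_val_loss = utils::tail(vi_ck$history$val_loss, 1),
    as_final_val_loss = utils::tail(as_ck$history$val_loss, 1),
    vi_frozen = frozen_ok)
  structure(list(vi = vi_ck, as = as_ck, report = report),
            class = "dualstage_fit")
}

#' Apply a trained dual-stage network to a cine movie
#'
#' Normalizes the movie, runs the VI sub-network, conditions the AS
#' sub-network on the VI map, and maps the suppressed movie back to the
#' original intensity scale.
#'
#' @param movie a raw `cine_movie`.
#' @param vi_checkpoint,as_checkpoint trained checkpoints (or a
#'   `dualstage_fit` passed as `vi_checkpoint`).
#' @return list with `vi_map` (a `vi_map`) and `suppressed`
#'   (a `cine_movie` on the input scale).
#' @export
suppress_artifacts <- function(movie, vi_checkpoint, as_checkpoint = NULL) {
  if (inherits(vi_checkpoint, "dualstage_fit")) {
    as_checkpoint <- vi_checkpoint$as
    vi_checkpoint <- vi_checkpoint$vi
  }
  pm <- preprocess(movie)
  vmap <- vi_forward(vi_checkpoint$net, pm)
  out <- as_forward(as_checkpoint$net, pm, vmap)
  list(vi_map = vmap, suppressed = unpreprocess(out))
}
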