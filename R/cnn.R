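# Multi-path residual CNN for spectrogram-based quality classification.
# One convolutional path per ECG channel: three residual blocks (a pair of
# 3x3 convolutions with batch norm and ReLU, plus a 1x1-convolution bypass
# summed into the block output before the final ReLU), a 24-unit fully
# connected layer per path, concatenation across paths and a single sigmoid
# output neuron. Trained with Adam on binary cross-entropy; the epoch with
# the highest validation AUC supplies the returned weights.
#
# Activations are (H, W, C*B) arrays, image-major (channel c of image b in
# slice (b-1)*C + c). The convolution/pooling kernels live in compiled code.

#' CNN architecture configuration
#'
#' @param n_paths number of convolutional paths: 4 (M, A1--A3) or 3 when
#'   the maternal channel is excluded.
#' @param filters three filter counts, one per residual block.
#' @param kernel square kernel size of the paired convolutions (stride is
#'   always 1x1).
#' @param fc_units width of the per-path fully connected layer.
#' @param input_shape spectrogram image shape (rows, cols).
#' @param pool if `TRUE`, a 2x2 max-pooling follows each residual block
#'   (an option for memory/time-constrained runs; off by default).
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(n_paths = 4, filters = c(16, 32, 64), kernel = 3,
                        fc_units = 24, input_shape = c(40, 126),
                        pool = FALSE) {
  if (!n_paths %in% c(3, 4)) stop("n_paths must be 3 or 4")
  if (length(filters) != 3L) stop("exactly 3 residual blocks: give 3 filter counts")
  if (kernel %% 2 != 1) stop("kernel must be odd (same padding)")
  structure(list(n_paths = as.integer(n_paths), filters = as.integer(filters),
                 kernel = as.integer(kernel), fc_units = as.integer(fc_units),
                 input_shape = as.integer(input_shape), pool = isTRUE(pool)),
            class = "arch_config")
}

#' CNN training configuration
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 28,
                         learning_rate = 5e-4, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

.bn_new <- function(f) list(run_mean = numeric(f), run_var = rep(1, f))

#' Build a multi-path residual CNN
#'
#' Weights use fan-in-scaled Gaussian initialisation, seeded for
#' reproducibility. Convolutions carry no bias (batch-norm shift plays that
#' role); the fully connected and output layers have biases.
#'
#' @param arch an `arch_config`.
#' @param seed integer seed for the initialisation.
#' @return An object of class `cnn_model` with elements `arch`, `params`
#'   (trainable tensors), `stats` (batch-norm running statistics) and
#'   `concat_width` (`n_paths * fc_units`).
#' @export
build_model <- function(arch = arch_config(), seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  set.seed(as.integer(seed))
  k <- arch$kernel
  params <- list(); stats <- list()
  hw <- arch$input_shape
  for (p in seq_len(arch$n_paths)) {
    c_in <- 1L
    for (b in 1:3) {
      f <- arch$filters[b]
      key <- sprintf("p%d_b%d", p, b)
      params[[paste0(key, "_Wa")]] <- .he_init(c_in * k * k, f, c_in * k * k)
      params[[paste0(key, "_Wb")]] <- .he_init(f * k * k, f, f * k * k)
      params[[paste0(key, "_Ws")]] <- .he_init(c_in, f, c_in)
      for (tag in c("g1", "g2", "gs")) {
        params[[paste0(key, "_", tag)]] <- rep(1, f)
      }
      for (tag in c("e1", "e2", "es")) {
        params[[paste0(key, "_", tag)]] <- numeric(f)
      }
      for (tag in c("bn1", "bn2", "bns")) {
        stats[[paste0(key, "_", tag)]] <- .bn_new(f)
      }
      c_in <- f
      if (arch$pool) hw <- hw %/% 2L
    }
    d <- prod(hw) * c_in
    params[[sprintf("p%d_fcW", p)]] <- .he_init(d, arch$fc_units, d)
    params[[sprintf("p%d_fcb", p)]] <- numeric(arch$fc_units)
    hw <- arch$input_shape
  }
  cw <- arch$n_paths * arch$fc_units
  params[["out_w"]] <- .he_init(cw, 1L, cw)
  params[["out_b"]] <- 0
  structure(list(arch = arch, params = params, stats = stats,
                 concat_width = cw), class = "cnn_model")
}

# ---- path forward/backward (heavy lifting in compiled code) ---------------

# assemble the per-block parameter+statistics lists the compiled path
# kernels expect
.blocks_for_cpp <- function(model, p) {
  lapply(1:3, function(b) {
    key <- sprintf("p%d_b%d", p, b)
    pr <- model$params; st <- model$stats
    list(Wa = pr[[paste0(key, "_Wa")]], Wb = pr[[paste0(key, "_Wb")]],
         Ws = pr[[paste0(key, "_Ws")]],
         g1 = pr[[paste0(key, "_g1")]], e1 = pr[[paste0(key, "_e1")]],
         g2 = pr[[paste0(key, "_g2")]], e2 = pr[[paste0(key, "_e2")]],
         gs = pr[[paste0(key, "_gs")]], es = pr[[paste0(key, "_es")]],
         m1 = st[[paste0(key, "_bn1")]]$run_mean,
         v1 = st[[paste0(key, "_bn1")]]$run_var,
         m2 = st[[paste0(key, "_bn2")]]$run_mean,
         v2 = st[[paste0(key, "_bn2")]]$run_var,
         ms = st[[paste0(key, "_bns")]]$run_mean,
         vs = st[[paste0(key, "_bns")]]$run_var)
  })
}

.path_fwd <- function(model, p, X, B, train) {
  arch <- model$arch
  res <- cpp_path_fwd(X, .blocks_for_cpp(model, p),
                      model$params[[sprintf("p%d_fcW", p)]],
                      model$params[[sprintf("p%d_fcb", p)]],
                      B, arch$kernel, arch$pool, train, 0.1, 1e-5, p)
  st <- model$stats
  if (train) {
    for (b in 1:3) {
      key <- sprintf("p%d_b%d", p, b)
      ns <- res$stats[[b]]
      st[[paste0(key, "_bn1")]] <- list(run_mean = as.numeric(ns$m1),
                                        run_var = as.numeric(ns$v1))
      st[[paste0(key, "_bn2")]] <- list(run_mean = as.numeric(ns$m2),
                                        run_var = as.numeric(ns$v2))
      st[[paste0(key, "_bns")]] <- list(run_mean = as.numeric(ns$ms),
                                        run_var = as.numeric(ns$vs))
    }
  }
  list(h = res$h, stats = st)
}

.path_bwd <- function(model, p, dh, B) {
  arch <- model$arch
  g <- cpp_path_bwd(dh, .blocks_for_cpp(model, p),
                    model$params[[sprintf("p%d_fcW", p)]],
                    B, arch$kernel, arch$pool, p)
  grads <- list()
  for (b in 1:3) {
    key <- sprintf("p%d_b%d", p, b)
    gb <- g$blocks[[b]]
    for (nm in c("Wa", "Wb", "Ws")) {
      grads[[paste0(key, "_", nm)]] <- gb[[nm]]
    }
    for (nm in c("g1", "e1", "g2", "e2", "gs", "es")) {
      grads[[paste0(key, "_", nm)]] <- as.numeric(gb[[nm]])
    }
  }
  grads[[sprintf("p%d_fcW", p)]] <- g$fcW
  grads[[sprintf("p%d_fcb", p)]] <- as.numeric(g$fcb)
  grads
}

.model_fwd <- function(model, x, train) {
  # x: array (H, W, C, B)
  d <- dim(x)
  B <- d[4]
  H <- matrix(0, B, model$concat_width)
  fc <- model$arch$fc_units
  for (p in seq_len(model$arch$n_paths)) {
    Xp <- array(x[, , p, ], c(d[1], d[2], B))   # C = 1 per path
    fw <- .path_fwd(model, p, Xp, B, train)
    model$stats <- fw$stats
    H[, ((p - 1) * fc + 1):(p * fc)] <- fw$h
  }
  logits <- as.numeric(H %*% model$params$out_w) + model$params$out_b
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, H = H, model = model)
}

# ---- Adam ------------------------------------------------------------------

.adam_step <- function(opt, params, grads, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) { opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0 }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + eps)
  }
  list(opt = opt, params = params)
}

.as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == "good")
  else as.integer(y)
}

#' Train the CNN
#'
#' Minimises binary cross-entropy with Adam. After every epoch the model is
#' evaluated on the validation set (using batch-norm running statistics)
#' and the weights of the epoch with the highest validation AUC — earliest
#' epoch on ties — are returned.
#'
#' @param model a `cnn_model` from [build_model()].
#' @param train_x,val_x arrays of shape (H, W, n_paths, N) of spectrogram
#'   images.
#' @param train_y,val_y labels: `"good"`/`"bad"` or 1/0 (good = positive).
#' @param config a `train_config`.
#' @return List with `model` (best weights), `history` (per-epoch
#'   data.frame: epoch, train_loss, train_acc, val_auc) and `best_epoch`.
#' @export
train_cnn <- function(model, train_x, train_y, val_x, val_y,
                      config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  ytr <- .as_binary_labels(train_y)
  yva <- .as_binary_labels(val_y)
  if (length(ytr) == 0L || length(yva) == 0L) stop("empty training or validation set")
  if (length(unique(yva)) < 2L) {
    stop("validation set must contain both classes (AUC undefined)")
  }
  set.seed(config$seed)
  n <- length(ytr)
  opt <- list(t = 0L, m = list(), v = list())
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_auc = numeric())
  best <- list(auc = -Inf, params = model$params, stats = model$stats,
               epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c(); accs <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next   # batch norm needs > 1 sample
      xb <- train_x[, , , idx, drop = FALSE]
      yb <- ytr[idx]
      fw <- .model_fwd(model, xb, train = TRUE)
      model <- fw$model
      p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      losses <- c(losses, -mean(yb * log(p) + (1 - yb) * log(1 - p)))
      accs <- c(accs, mean((p > 0.5) == (yb == 1)))
      dlogit <- (p - yb) / length(yb)
      grads <- list(out_w = t(fw$H) %*% dlogit, out_b = sum(dlogit))
      dH <- dlogit %*% t(model$params$out_w)
      fc <- model$arch$fc_units
      for (pp in seq_len(model$arch$n_paths)) {
        dh <- dH[, ((pp - 1) * fc + 1):(pp * fc), drop = FALSE]
        grads <- c(grads, .path_bwd(model, pp, dh, length(idx)))
      }
      up <- .adam_step(opt, model$params, grads, config$learning_rate)
      opt <- up$opt
      model$params <- up$params
    }
    val_p <- predict_cnn(model, val_x)
    vauc <- .rank_auc(val_p, yva)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         train_acc = mean(accs),
                                         val_auc = vauc))
    if (vauc > best$auc) {
      best <- list(auc = vauc, params = model$params, stats = model$stats,
                   epoch = ep)
    }
  }
  model$params <- best$params
  model$stats <- best$stats
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Predict good-quality probabilities
#'
#' Forward pass in inference mode (batch-norm running statistics), so
#' scores are independent of batch composition.
#'
#' @param model a `cnn_model`.
#' @param x array (H, W, n_paths, N); an empty fourth dimension yields an
#'   empty result.
#' @param batch_size evaluation batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_cnn <- function(model, x, batch_size = 64L) {
  stopifnot(inherits(model, "cnn_model"))
  d <- dim(x)
  if (length(d) != 4L || d[1] != model$arch$input_shape[1] ||
      d[2] != model$arch$input_shape[2] || d[3] != model$arch$n_paths) {
    stop("input shape does not match the model architecture")
  }
  n <- d[4]
  if (n == 0L) return(numeric())
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx] <- .model_fwd(model, x[, , , idx, drop = FALSE], train = FALSE)$prob
  }
  out
}

#' Stack per-segment spectrogram images into a CNN input array
#'
#' Greyscale pixel values in \\[0, 128\\] are rescaled to \\[0, 1\\] for
#' network conditioning (a fixed linear map, inverted nowhere).
#'
#' @param images list (one element per segment) of lists of `stft_image`
#'   objects as produced by [preprocess_recording()].
#' @param channels channel names to include, in path order.
#' @return Array of shape (H, W, length(channels), n_segments).
#' @export
stack_images <- function(images, channels = c("M", "A1", "A2", "A3")) {
  if (!length(images)) stop("no images to stack")
  d <- dim(images[[1]][[1]]$pixels)
  out <- array(0, c(d[1], d[2], length(channels), length(images)))
  for (i in seq_along(images)) {
    for (j in seq_along(channels)) {
      out[, , j, i] <- images[[i]][[channels[j]]]$pixels / 128
    }
  }
  out
}

#' Save / load a CNN model
#'
#' The model (weights, batch-norm statistics, architecture) is written in
#' R's native serialized form, alongside a human-readable JSON sidecar
#' describing the architecture.
#'
#' @param model a `cnn_model`.
#' @param path file path for the serialized model; the architecture JSON
#'   is written next to it as `<path>.arch.json`.
#' @return `save_cnn` returns `path` invisibly; `load_cnn` returns the
#'   restored `cnn_model`.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$arch), paste0(path, ".arch.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cnn_model")) stop("not a serialized cnn_model")
  model
}
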