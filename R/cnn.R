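#' Architecture of the three-layer strided CNN classifier
#'
#' Each convolution layer uses square kernels with stride equal to the
#' kernel size and no padding, so a layer with kernel `k` maps an `n x n`
#' input to `floor((n - k)/k) + 1` per side — a non-overlapping patch
#' decomposition that learns grey-matter features at progressively coarser
#' scales.  A single fully connected layer maps the third-layer features to
#' the two class scores.  Defaults are the optimum reported for the
#' full-scale study (40 filters 20x20; 10 filters 10x10; 15 filters 20x20);
#' note that under the stride-equals-kernel rule this chain only fits very
#' large inputs, so reduced-scale analyses pass smaller kernels.
#'
#' @param conv list of three `c(n_filters, kernel)` pairs.
#' @return An object of class `cnn_spec`.
#' @examples
#' cnn_spec(conv = list(c(8, 16), c(8, 2), c(8, 2)))  # for 64 x 64 inputs
#' @export
cnn_spec <- function(conv = list(c(40, 20), c(10, 10), c(15, 20))) {
  stopifnot(length(conv) == 3L)
  for (l in conv) {
    stopifnot(length(l) == 2L, l[1] >= 1, l[2] >= 2)
  }
  structure(list(conv = lapply(conv, as.integer), type = "cnn"),
            class = "cnn_spec")
}

#' Architecture of the DAG-CNN classifier
#'
#' Same three strided convolution layers as [cnn_spec()], plus an addition
#' layer with two inputs: the first convolution layer's feature maps
#' (subtle, fine-scale patterns) and the third layer's (coarse patterns).
#' Before addition the first-layer maps are shape-equalized to the third
#' layer's: deterministic nearest-neighbour spatial resampling plus a
#' learnable 1x1 channel projection.  Defaults are the reported DAG optimum
#' (10 filters 30x30; 40 filters 15x15; 20 filters 15x15).
#'
#' @param conv list of three `c(n_filters, kernel)` pairs.
#' @return An object of class `dag_spec` (also a `cnn_spec`).
#' @export
dag_spec <- function(conv = list(c(10, 30), c(40, 15), c(20, 15))) {
  sp <- cnn_spec(conv)
  sp$type <- "dag"
  class(sp) <- c("dag_spec", class(sp))
  sp
}

#' Training hyperparameters
#'
#' @param learning_rate SGD learning rate (the full-scale study optima are
#'   6e-4 for the CNN and 4e-4 for the DAG-CNN).
#' @param epochs number of passes over the training data.
#' @param validation_frequency validate once every this many epochs.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum coefficient.
#' @param seed integer seed fixing initialization and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 6e-4, epochs = 160L,
                         validation_frequency = 80L, batch_size = 16L,
                         momentum = 0.9, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, validation_frequency >= 1,
            batch_size >= 1, momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 validation_frequency = as.integer(validation_frequency),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Spatial output size of a strided valid convolution
#'
#' `floor((n - kernel) / kernel) + 1`; errors if the kernel does not fit.
#'
#' @param n input side length.
#' @param kernel kernel (= stride) size.
#' @return Output side length (>= 1).
#' @export
conv_out_dim <- function(n, kernel) {
  out <- (n - kernel) %/% kernel + 1L
  if (out < 1L) {
    stop(sprintf("kernel %d does not fit input of size %d", kernel, n),
         call. = FALSE)
  }
  out
}

# per-layer spatial sizes for a spec on an h x w input; errors if any
# stage collapses below 1
layer_dims <- function(spec, input_dim) {
  h <- input_dim[1]; w <- input_dim[2]
  dims <- vector("list", 3L)
  for (l in 1:3) {
    k <- spec$conv[[l]][2]
    h <- conv_out_dim(h, k)
    w <- conv_out_dim(w, k)
    dims[[l]] <- c(h, w)
  }
  dims
}

#' Build an untrained CNN model
#'
#' Validates that the kernel chain fits the input size, then allocates
#' He-initialized convolution weights and a Glorot-scale classifier.
#'
#' @param spec a [cnn_spec()].
#' @param input_dim `c(height, width)` of the input images.
#' @param seed integer seed for weight initialization.
#' @return An object of class `cnn_model` with elements `spec`,
#'   `input_dim`, `dims` (per-layer spatial sizes) and `params`.
#' @export
build_cnn <- function(spec, input_dim, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  dims <- layer_dims(spec, input_dim)
  with_seed(seed, {
    params <- list(conv = vector("list", 3L))
    c_in <- 1L
    for (l in 1:3) {
      nf <- spec$conv[[l]][1]; k <- spec$conv[[l]][2]
      fan_in <- k * k * c_in
      params$conv[[l]] <- list(
        W = array(stats::rnorm(fan_in * nf, sd = sqrt(2 / fan_in)),
                  dim = c(k, k, c_in, nf)),
        b = rep(0.05, nf))
      c_in <- nf
    }
    c3 <- spec$conv[[3]][1]
    if (spec$type == "dag") {
      c1 <- spec$conv[[1]][1]
      params$proj <- list(
        W = matrix(stats::rnorm(c1 * c3, sd = sqrt(1 / c1)), c1, c3),
        b = numeric(c3))
    }
    d_fc <- prod(dims[[3]]) * c3
    params$fc <- list(
      W = matrix(stats::rnorm(2L * d_fc, sd = sqrt(1 / d_fc)), 2L, d_fc),
      b = numeric(2L))
    structure(list(spec = spec, input_dim = as.integer(input_dim),
                   dims = dims, params = params, trained = FALSE,
                   history = NULL),
              class = "cnn_model")
  })
}

#' Build an untrained DAG-CNN model
#'
#' @param spec a [dag_spec()].
#' @inheritParams build_cnn
#' @return A `cnn_model` whose forward pass includes the addition layer.
#' @export
build_dag_cnn <- function(spec, input_dim, seed = 1L) {
  stopifnot(inherits(spec, "dag_spec"))
  build_cnn(spec, input_dim, seed = seed)
}

#' Total number of learnable parameters
#' @param model a [build_cnn()] model.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(rapply(model$params, length, how = "unlist"), identity, numeric(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<%s model: input %dx%d, conv %s, %d parameters, %s>\n",
              toupper(x$spec$type), x$input_dim[1], x$input_dim[2],
              paste(vapply(x$spec$conv, function(l)
                sprintf("%dx(%dx%d)", l[1], l[2], l[2]), ""), collapse = " -> "),
              n_parameters(x), if (x$trained) "trained" else "untrained"),
      ...)
  invisible(x)
}

## --- low-level layers -----------------------------------------------------
## Tensors are [height, width, channels, batch].  With stride = kernel and
## no padding, convolution is a non-overlapping patch decomposition and
## reduces to one dense matrix product per layer.

conv_forward <- function(x, W, b) {
  d <- dim(x); k <- dim(W)[1]; c_out <- dim(W)[4]
  oh <- (d[1] - k) %/% k + 1L; ow <- (d[2] - k) %/% k + 1L
  xc <- x[seq_len(oh * k), seq_len(ow * k), , , drop = FALSE]
  dim(xc) <- c(k, oh, k, ow, d[3], d[4])
  xp <- aperm(xc, c(1, 3, 5, 2, 4, 6))
  dim(xp) <- c(k * k * d[3], oh * ow * d[4])
  y <- crossprod(matrix(W, nrow = k * k * d[3]), xp) + b
  dim(y) <- c(c_out, oh, ow, d[4])
  list(out = aperm(y, c(2, 3, 1, 4)),
       cache = list(xp = xp, in_dim = d, k = k, oh = oh, ow = ow))
}

conv_backward <- function(dy, W, cache) {
  k <- cache$k; d <- cache$in_dim; oh <- cache$oh; ow <- cache$ow
  c_out <- dim(W)[4]
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(c_out, oh * ow * d[4])
  wm <- matrix(W, nrow = k * k * d[3])
  dW <- cache$xp %*% t(dym)
  dim(dW) <- dim(W)
  db <- rowSums(dym)
  dxp <- wm %*% dym
  dim(dxp) <- c(k, k, d[3], oh, ow, d[4])
  dxc <- aperm(dxp, c(1, 4, 2, 5, 3, 6))
  dim(dxc) <- c(oh * k, ow * k, d[3], d[4])
  dx <- array(0, dim = d)
  dx[seq_len(oh * k), seq_len(ow * k), , ] <- dxc
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }

# deterministic nearest-neighbour source rows/cols for resampling n_src
# positions onto n_dst, aligned to the stride grid
nn_index <- function(n_src, n_dst) {
  pmin(floor((seq_len(n_dst) - 1) * n_src / n_dst) + 1L, n_src)
}

resample_nn <- function(x, oh, ow) {
  d <- dim(x)
  x[nn_index(d[1], oh), nn_index(d[2], ow), , , drop = FALSE]
}

# scatter-add adjoint of resample_nn
resample_nn_backward <- function(dy, src_dim) {
  d <- dim(dy)
  ri <- nn_index(src_dim[1], d[1]); ci <- nn_index(src_dim[2], d[2])
  cell <- as.integer(outer(ri, (ci - 1L) * src_dim[1], "+"))  # src cell per target
  dym <- dy
  dim(dym) <- c(d[1] * d[2], d[3] * d[4])
  acc <- rowsum(dym, group = cell)
  dx <- matrix(0, src_dim[1] * src_dim[2], d[3] * d[4])
  dx[as.integer(rownames(acc)), ] <- acc
  dim(dx) <- c(src_dim[1], src_dim[2], d[3], d[4])
  dx
}

# channel mixing with a [c_in, c_out] matrix applied pixelwise
proj_forward <- function(x, W, b) {
  d <- dim(x)
  xm <- aperm(x, c(3, 1, 2, 4))
  dim(xm) <- c(d[3], d[1] * d[2] * d[4])
  y <- crossprod(W, xm) + b
  dim(y) <- c(ncol(W), d[1], d[2], d[4])
  list(out = aperm(y, c(2, 3, 1, 4)), cache = list(xm = xm, d = d))
}

proj_backward <- function(dy, W, cache) {
  d <- cache$d
  dym <- aperm(dy, c(3, 1, 2, 4))
  dim(dym) <- c(ncol(W), d[1] * d[2] * d[4])
  dW <- cache$xm %*% t(dym)
  db <- rowSums(dym)
  dxm <- W %*% dym
  dim(dxm) <- c(d[3], d[1], d[2], d[4])
  list(dx = aperm(dxm, c(2, 3, 1, 4)), dW = dW, db = db)
}

# full forward pass; keep_caches enables backprop, keep_acts stores each
# layer's pre-activation output (the activation maps used for
# visualization)
forward_pass <- function(model, x, keep_caches = FALSE, keep_acts = FALSE) {
  p <- model$params
  caches <- list(); acts <- list()
  z <- vector("list", 3L); a <- vector("list", 3L)
  inp <- x
  for (l in 1:3) {
    cf <- conv_forward(inp, p$conv[[l]]$W, p$conv[[l]]$b)
    z[[l]] <- cf$out
    if (keep_caches) caches[[l]] <- cf$cache
    if (keep_acts) acts[[l]] <- cf$out
    a[[l]] <- relu(cf$out)
    inp <- a[[l]]
  }
  feat <- a[[3]]
  dagc <- NULL
  if (model$spec$type == "dag") {
    d3 <- dim(a[[3]])
    r <- resample_nn(a[[1]], d3[1], d3[2])
    pf <- proj_forward(r, p$proj$W, p$proj$b)
    feat <- a[[3]] + pf$out
    if (keep_acts) acts$addition <- feat
    dagc <- list(r = r, proj_cache = pf$cache, a1_dim = dim(a[[1]]))
  }
  dfe <- dim(feat)
  fm <- feat
  dim(fm) <- c(prod(dfe[1:3]), dfe[4])
  scores <- p$fc$W %*% fm + p$fc$b
  list(scores = scores, z = if (keep_caches) z else NULL,
       caches = caches, fm = fm, feat_dim = dfe, dag = dagc, acts = acts)
}

softmax_cols <- function(s) {
  s <- sweep(s, 2, apply(s, 2, max))
  e <- exp(s)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy loss and full gradient for a batch
loss_and_grads <- function(model, x, y01) {
  fw <- forward_pass(model, x, keep_caches = TRUE)
  p <- model$params
  b <- ncol(fw$scores)
  prob <- softmax_cols(fw$scores)
  eps <- 1e-12
  loss <- -mean(log(prob[cbind(y01 + 1L, seq_len(b))] + eps))
  dsc <- prob
  dsc[cbind(y01 + 1L, seq_len(b))] <- dsc[cbind(y01 + 1L, seq_len(b))] - 1
  dsc <- dsc / b

  g <- list(conv = vector("list", 3L))
  g$fc <- list(W = dsc %*% t(fw$fm), b = rowSums(dsc))
  dfm <- t(p$fc$W) %*% dsc
  dim(dfm) <- fw$feat_dim
  dfeat <- dfm

  da <- vector("list", 3L)
  da[[3]] <- dfeat
  if (model$spec$type == "dag") {
    pb <- proj_backward(dfeat, p$proj$W, fw$dag$proj_cache)
    g$proj <- list(W = pb$dW, b = pb$db)
    da1_branch <- resample_nn_backward(pb$dx, fw$dag$a1_dim)
  }
  for (l in 3:1) {
    dz <- da[[l]] * (fw$z[[l]] > 0)
    cb <- conv_backward(dz, p$conv[[l]]$W, fw$caches[[l]])
    g$conv[[l]] <- list(W = cb$dW, b = cb$db)
    if (l > 1L) {
      da[[l - 1L]] <- cb$dx
      if (l == 2L && model$spec$type == "dag") {
        da[[1L]] <- da[[1L]] + da1_branch
      }
    }
  }
  list(loss = loss, grads = g)
}

dataset_tensor <- function(ds) {
  d <- dim(ds$images)
  x <- ds$images
  dim(x) <- c(d[1], d[2], 1L, d[3])
  x
}

#' Train a CNN or DAG-CNN classifier
#'
#' Minibatch stochastic gradient descent with momentum on the softmax
#' cross-entropy loss.  Initialization and shuffling draw from a single
#' stream fixed by `cfg$seed`, so training is reproducible.  Validation
#' accuracy is recorded once every `validation_frequency` epochs (and at
#' the final epoch).
#'
#' @param spec a [cnn_spec()] or [dag_spec()].
#' @param train_set a [gm_dataset()] with both classes present.
#' @param val_set optional [gm_dataset()], disjoint from `train_set`.
#' @param cfg a [train_config()].
#' @return A trained `cnn_model`; `$history` holds per-epoch loss and the
#'   validation-accuracy checkpoints.
#' @export
train_model <- function(spec, train_set, val_set = NULL, cfg = train_config()) {
  stopifnot(inherits(train_set, "gm_dataset"))
  if (!dataset_trainable(train_set)) {
    stop("training set must contain both classes", call. = FALSE)
  }
  d <- dim(train_set$images)
  model <- if (spec$type == "dag") {
    build_dag_cnn(spec, d[1:2], seed = cfg$seed)
  } else {
    build_cnn(spec, d[1:2], seed = cfg$seed)
  }
  x <- dataset_tensor(train_set)
  y <- as.integer(train_set$records$label)
  n <- d[3]
  vel <- rapply(model$params, function(w) w * 0, how = "replace")
  hist_loss <- numeric(cfg$epochs)
  val_rows <- list()

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        lg <- loss_and_grads(model, x[, , , idx, drop = FALSE], y[idx])
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
        # momentum update, applied leaf-by-leaf
        for (l in 1:3) {
          for (nm in c("W", "b")) {
            vel$conv[[l]][[nm]] <- cfg$momentum * vel$conv[[l]][[nm]] -
              cfg$learning_rate * lg$grads$conv[[l]][[nm]]
            model$params$conv[[l]][[nm]] <- model$params$conv[[l]][[nm]] +
              vel$conv[[l]][[nm]]
          }
        }
        extra <- intersect(c("proj", "fc"), names(lg$grads))
        for (part in extra) {
          for (nm in c("W", "b")) {
            vel[[part]][[nm]] <- cfg$momentum * vel[[part]][[nm]] -
              cfg$learning_rate * lg$grads[[part]][[nm]]
            model$params[[part]][[nm]] <- model$params[[part]][[nm]] +
              vel[[part]][[nm]]
          }
        }
      }
      hist_loss[ep] <- ep_loss / nb
      if (!is.null(val_set) &&
          (ep %% cfg$validation_frequency == 0L || ep == cfg$epochs)) {
        acc <- mean((predict_scores(model, val_set) >= 0.5) ==
                      (val_set$records$label == 1L))
        val_rows[[length(val_rows) + 1L]] <- data.frame(epoch = ep,
                                                        val_accuracy = acc)
      }
    }
  })
  model$trained <- TRUE
  model$cfg <- cfg
  model$history <- list(
    loss = data.frame(epoch = seq_len(cfg$epochs), loss = hist_loss),
    validation = if (length(val_rows)) do.call(rbind, val_rows) else
      data.frame(epoch = integer(0), val_accuracy = numeric(0)))
  model
}

#' Predicted TLE probability for each image
#'
#' Softmax probability of the positive (TLE) class; the predicted label is
#' `score >= 0.5`.
#'
#' @param model a trained `cnn_model`.
#' @param data a [gm_dataset()], a `[h, w, n]` array, or a single matrix.
#' @return Numeric vector of probabilities in \[0,1\].
#' @export
predict_scores <- function(model, data) {
  x <- if (inherits(data, "gm_dataset")) dataset_tensor(data)
       else if (is.matrix(data)) array(data, dim = c(dim(data), 1L, 1L))
       else { d <- dim(data); array(data, dim = c(d[1], d[2], 1L, d[3])) }
  if (!identical(as.integer(dim(x)[1:2]), model$input_dim)) {
    stop(sprintf("image size %dx%d does not match the model's %dx%d input",
                 dim(x)[1], dim(x)[2], model$input_dim[1], model$input_dim[2]),
         call. = FALSE)
  }
  fw <- forward_pass(model, x)
  as.numeric(softmax_cols(fw$scores)[2L, ])
}

#' Per-filter activation maps of one convolution layer
#'
#' Returns the layer's pre-nonlinearity convolution outputs for a single
#' image: one 2D map per filter, the raw (possibly negative) responses the
#' visualization procedure takes absolute values of.
#'
#' @param model a trained `cnn_model`.
#' @param image a matrix or [gm_slice()] matching the model input size.
#' @param layer convolution layer index, 1 to 3.
#' @return Array `[h_l, w_l, n_filters]`.
#' @export
layer_activations <- function(model, image, layer) {
  if (!(layer %in% 1:3)) stop("layer must be 1, 2 or 3", call. = FALSE)
  x <- array(as.numeric(image), dim = c(dim(image), 1L, 1L))
  fw <- forward_pass(model, x, keep_acts = TRUE)
  m <- fw$acts[[layer]]
  array(m, dim = dim(m)[1:3])
}

#' Save / load a trained model
#'
#' The checkpoint stores the spec, fitted parameters, training
#' configuration and history.
#' @param model a `cnn_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
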