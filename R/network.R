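# the dual-pathway patch CNN: architecture definition, shape tracing, the
# softmax-with-loss classifier, seeded SGD training, and batched inference
#
# Both pathways are structurally identical: two hidden layers of
# [5x5 conv (stride 1) -> ReLU -> LRN -> 3x3 max-pool (stride 2)] followed
# by a third of [5x5 conv -> ReLU]. All convolutions are valid (unpadded)
# and pooling is floor-mode, which realises the 51 -> 47 -> 23 -> 19 -> 9
# -> 5 spatial trace; each pathway ends in 64 maps of 5x5 so the
# concatenation carries 128. A cascade 5x5 conv turns those into 512 maps
# of 1x1. The 77x77 patch is bilinearly resampled to 51x51 before entering
# its pathway so both emit the same spatial extent. Both the concatenated
# maps and the cascade output are tapped by fully connected layers, joined,
# passed through a further fully connected layer with ReLU and dropout, and
# classified by softmax-with-loss.

#' Dual-pathway network architecture
#'
#' @param input_size small-patch edge fed to each pathway (the large patch
#'   is resampled to this size), px, odd
#' @param large_size capture size of the contextual patch, px, odd
#' @param channels per-pathway channel progression over the three conv
#'   layers; the last entry doubles across the two pathways at the concat
#' @param cascade channel count of the cascade conv output
#' @param fc_tap width of the fully connected tap on each feature source
#' @param fc_join width of the joint fully connected layer
#' @param classes number of classes (2: background / region)
#' @param kernel conv kernel edge
#' @param pool_size,pool_stride max-pooling window and stride
#' @param lrn local response normalization constants (across channels)
#' @param dropout dropout probability on the joint layer (training only)
#' @return a `network_spec` object
#' @export
network_spec <- function(input_size = 51L, large_size = 77L,
                         channels = c(32L, 48L, 64L), cascade = 512L,
                         fc_tap = 256L, fc_join = 256L, classes = 2L,
                         kernel = 5L, pool_size = 3L, pool_stride = 2L,
                         lrn = list(size = 5L, alpha = 1e-4, beta = 0.75, k = 1),
                         dropout = 0.5) {
  stopifnot(input_size %% 2 == 1, large_size > input_size,
            length(channels) == 3L, dropout >= 0, dropout < 1)
  spec <- structure(list(input_size = as.integer(input_size),
                         large_size = as.integer(large_size),
                         channels = as.integer(channels),
                         cascade = as.integer(cascade),
                         fc_tap = as.integer(fc_tap),
                         fc_join = as.integer(fc_join),
                         classes = as.integer(classes),
                         kernel = as.integer(kernel),
                         pool_size = as.integer(pool_size),
                         pool_stride = as.integer(pool_stride),
                         lrn = lrn, dropout = dropout),
                    class = "network_spec")
  trace_shapes(spec)  # errors if the input cannot traverse the stack
  spec
}

#' Trace the spatial shapes through the network
#'
#' Applies the valid-convolution / floor-mode pooling arithmetic
#' `out = floor((in - k) / s) + 1` layer by layer for one pathway, the
#' pathway concatenation, and the cascade convolution.
#'
#' @param spec a [network_spec()]
#' @param input_size input edge to trace (defaults to the spec's)
#' @return data frame with one row per stage: layer name, spatial size and
#'   channel count
#' @export
trace_shapes <- function(spec, input_size = spec$input_size) {
  k <- spec$kernel; pk <- spec$pool_size; ps <- spec$pool_stride
  ch <- spec$channels
  rows <- list(list(layer = "input", size = input_size, channels = 1L))
  sz <- input_size
  step <- function(layer, new_sz, channels) {
    if (new_sz < 1)
      stop(sprintf("input size %d too small: %s would output %d px",
                   input_size, layer, new_sz))
    rows[[length(rows) + 1L]] <<- list(layer = layer, size = new_sz,
                                       channels = channels)
    sz <<- new_sz
  }
  for (l in 1:2) {
    step(sprintf("conv%d", l), sz - k + 1L, ch[l])
    step(sprintf("pool%d", l), (sz - pk) %/% ps + 1L, ch[l])
  }
  step("conv3", sz - k + 1L, ch[3])
  step("concat", sz, 2L * ch[3])
  step("cascade", sz - k + 1L, spec$cascade)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Numerically stable softmax with multinomial logistic loss
#'
#' Computes the class probabilities `sigma(z)` and the combined loss
#' `log(sum_j exp(z_j)) - z_y`, evaluated with a max-shift so large scores
#' do not overflow. The loss equals `-log(sigma_y(z))` exactly.
#'
#' @param z pre-softmax score vector
#' @param y true class index in `1..length(z)`
#' @return list with `sigma` (probabilities) and `loss`
#' @export
softmax_loss <- function(z, y) {
  stopifnot(all(is.finite(z)), y >= 1, y <= length(z))
  m <- max(z)
  e <- exp(z - m)
  sigma <- e / sum(e)
  loss <- (log(sum(e)) + m) - z[y]
  list(sigma = sigma, loss = loss)
}

#' Training configuration
#'
#' Defaults follow the reference schedule: mini-batches of 200, learning
#' rate 0.01 with a step decay every 10,000 iterations, momentum 0.9 and
#' weight decay 5e-4, capped at 100 epochs or 50,000 iterations, whichever
#' comes first. Desk-scale runs lower `epochs` and feed fewer samples; the
#' schedule itself is unchanged.
#'
#' @param batch_size samples per SGD step
#' @param epochs maximum passes over the training set
#' @param max_iter maximum SGD iterations
#' @param lr initial learning rate
#' @param lr_step iterations between learning-rate decays
#' @param lr_gamma multiplicative decay factor
#' @param momentum SGD momentum
#' @param weight_decay L2 penalty coefficient
#' @param seed seed for initialization, shuffling and dropout
#' @return a `train_config` object
#' @export
train_config <- function(batch_size = 200L, epochs = 100L, max_iter = 50000L,
                         lr = 0.01, lr_step = 10000L, lr_gamma = 0.1,
                         momentum = 0.9, weight_decay = 5e-4, seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, max_iter >= 1, lr > 0,
            lr_gamma > 0, lr_gamma < 1, momentum >= 0, weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_iter = as.integer(max_iter),
                 lr = lr, lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

# He-normal initialization of all weight matrices, seeded
init_weights <- function(spec, seed = 1L) {
  k2 <- spec$kernel^2
  ch <- spec$channels
  tr <- trace_shapes(spec)
  sz_casc <- tr$size[tr$layer == "cascade"]
  dims <- list(
    c(ch[1], k2), c(ch[2], ch[1] * k2), c(ch[3], ch[2] * k2),   # small path
    c(ch[1], k2), c(ch[2], ch[1] * k2), c(ch[3], ch[2] * k2),   # large path
    c(spec$cascade, 2L * ch[3] * k2),                           # cascade conv
    c(spec$fc_tap, tap_dim(spec)),                              # tap on concat
    c(spec$fc_tap, spec$cascade * sz_casc^2),                   # tap on cascade
    c(spec$fc_join, 2L * spec$fc_tap),                          # joint fc
    c(spec$classes, spec$fc_join))                              # classifier
  with_seed(seed, {
    weights <- lapply(dims, function(d)
      matrix(stats::rnorm(prod(d), sd = sqrt(2 / d[2])), d[1], d[2]))
    biases <- lapply(dims, function(d) numeric(d[1]))
    list(weights = weights, biases = biases)
  })
}

# the concat tap dimension assumes 5x5 pathway output; recompute from trace
tap_dim <- function(spec) {
  tr <- trace_shapes(spec)
  sz <- tr$size[tr$layer == "concat"]
  2L * spec$channels[3] * sz^2
}

# live C++ handle for a model (cached per session; rebuilt after reload)
model_ptr <- function(model) {
  env <- model$ptr_env
  if (is.null(env$ptr)) {
    env$ptr <- cpp_net_create(model$weights, model$biases,
                              c(model$spec, list()))
  }
  env$ptr
}

new_model <- function(spec, weights, biases, config = NULL,
                      input_scale = 255) {
  structure(list(spec = spec, weights = weights, biases = biases,
                 config = config, input_scale = input_scale,
                 history = NULL, ptr_env = new.env(parent = emptyenv())),
            class = "dualpath_model")
}

#' @export
print.dualpath_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, 1)) + sum(vapply(x$biases, length, 1))
  cat(sprintf("<dualpath_model> patches %d/%d px, %s parameters%s\n",
              x$spec$input_size, x$spec$large_size, format(np, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d iterations", max(x$history$iter))))
  invisible(x)
}

# assemble scaled input arrays for the C++ net
net_inputs <- function(model, small, large) {
  list(xs = small / model$input_scale, xl = large / model$input_scale)
}

#' Train the dual-pathway network
#'
#' Mini-batch SGD with momentum and weight decay on the softmax loss;
#' dropout is active during training only. Weights, shuffling and dropout
#' are all seeded from the configuration, so identical inputs give
#' identical models. Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param train,val [screen_and_augment()]-style sample sets (patch pixel
#'   intensities on the storage scale); `val` may be `NULL`
#' @param spec a [network_spec()]
#' @param config a [train_config()]
#' @param verbose print per-epoch progress?
#' @return a trained `dualpath_model` with a loss/accuracy history
#' @export
train_network <- function(train, val = NULL, spec = network_spec(),
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(train, "sample_set"), length(train$label) > 0)
  init <- init_weights(spec, seed = config$seed)
  model <- new_model(spec, init$weights, init$biases, config,
                     input_scale = max(train$intensity_range))
  ptr <- model_ptr(model)
  n <- length(train$label)
  xs_all <- train$small / model$input_scale
  xl_all <- train$large / model$input_scale
  iter <- 0L
  history <- list()
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / config$batch_size)
      epoch_loss <- 0
      for (b in seq_len(nb)) {
        if (iter >= config$max_iter) break
        idx <- ord[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, n)]
        lr <- config$lr * config$lr_gamma^(iter %/% config$lr_step)
        drop <- matrix(stats::rbinom(length(idx) * spec$fc_join, 1L,
                                     1 - spec$dropout),
                       length(idx), spec$fc_join)
        loss <- cpp_net_train_batch(ptr, xs_all[, , idx, drop = FALSE],
                                    xl_all[, , idx, drop = FALSE],
                                    train$label[idx], drop, lr,
                                    config$momentum, config$weight_decay,
                                    update = TRUE)
        iter <- iter + 1L
        epoch_loss <- epoch_loss + loss
        history[[length(history) + 1L]] <-
          data.frame(iter = iter, epoch = epoch, loss = loss, lr = lr)
      }
      if (verbose) {
        vacc <- NA_real_
        if (!is.null(val) && length(val$label)) {
          p <- predict_on_arrays(ptr, model, val$small, val$large)
          vacc <- mean((p > 0.5) == (val$label == 1))
        }
        message(sprintf("epoch %d: mean loss %.4f%s", epoch,
                        epoch_loss / max(1, nb),
                        if (is.na(vacc)) "" else sprintf(", val acc %.3f", vacc)))
      }
      if (iter >= config$max_iter) break
    }
  })
  model$weights <- cpp_net_weights(ptr)$weights
  model$biases <- cpp_net_weights(ptr)$biases
  model$history <- do.call(rbind, history)
  if (!is.null(val) && length(val$label)) {
    p <- predict_on_arrays(ptr, model, val$small, val$large)
    model$val_accuracy <- mean((p > 0.5) == (val$label == 1))
  }
  model
}

predict_on_arrays <- function(ptr, model, small, large, chunk = 1000L) {
  n <- dim(small)[3]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs <- cpp_net_predict(ptr, small[, , idx, drop = FALSE] / model$input_scale,
                             large[, , idx, drop = FALSE] / model$input_scale)
    out[idx] <- probs[, 2]
  }
  out
}

#' Predict region probabilities for a batch of patch pairs
#'
#' Runs the trained network (dropout disabled) on co-centred patch arrays
#' and returns the probability of the "region" class per centre.
#'
#' @param model a trained `dualpath_model`
#' @param small,large patch arrays (edge x edge x n, the large patch
#'   already resampled to the small edge), or a `sample_set` as `small`
#' @return numeric vector of probabilities in `[0, 1]`
#' @export
predict_batch <- function(model, small, large = NULL) {
  stopifnot(inherits(model, "dualpath_model"))
  if (inherits(small, "sample_set")) {
    large <- small$large
    small <- small$small
  }
  p <- model$spec$input_size
  if (!all(dim(small)[1:2] == p) || !all(dim(large)[1:2] == p))
    stop(sprintf("patches must be %d x %d (large patches resampled)", p, p))
  if (!identical(dim(small), dim(large)))
    stop("small and large patch arrays must align")
  predict_on_arrays(model_ptr(model), model, small, large)
}
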