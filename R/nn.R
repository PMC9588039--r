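# ---------------------------------------------------------------------------
# Residual gCNN internals: parameter containers, forward and backward passes.
#
# Activations are stored channels-first: a batch of B subjects with n padded
# vertices and C channels is a C x (B*n) column-major matrix whose column
# (j-1)*B + b is subject b's channel vector at vertex j. Each vertex then
# owns one contiguous C*B block, so the compiled Chebyshev recurrence makes
# a single pass over the shared sparse Laplacian per product; batch-norm and
# bias arithmetic reduce to R vector recycling over rows; and because
# sibling vertices are adjacent after hierarchy reordering, stride-2 max
# pooling is a reduction over adjacent column blocks.
# ---------------------------------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Model configuration
#'
#' @param input_features number of per-node input features: 3 (subcortical
#'   only), 6 (cortical only) or 9 (combined, zero-padded layout).
#' @param channels integer vector of channel widths per stage:
#'   pre-convolution, one entry per residual block, and the post residual
#'   block. `length(channels) - 2` residual blocks are built, each followed
#'   by stride-2 max pooling, so the hierarchy must have at least that many
#'   levels. The default 32-32-64-64-128-128 (four residual blocks) is this
#'   package's configuration choice.
#' @param K Chebyshev polynomial order (default 3).
#' @param dropout_rate dropout probability for the fully connected head
#'   (default 0.5).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `gcnn_model_config`.
#' @export
gcnn_model_config <- function(input_features = 9L,
                              channels = c(32L, 32L, 64L, 64L, 128L, 128L),
                              K = 3L, dropout_rate = 0.5, seed = 1L) {
  stopifnot(input_features %in% c(3L, 6L, 9L), length(channels) >= 3L,
            all(channels >= 1L), K >= 1L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_features = as.integer(input_features),
                 channels = as.integer(channels),
                 n_blocks = length(channels) - 2L,
                 K = as.integer(K),
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "gcnn_model_config")
}

init_conv <- function(f_in, f_out, k) {
  list(theta = matrix(rnorm(k * f_in * f_out, sd = sqrt(2 / (f_in * k))),
                      k * f_in, f_out),
       bias = numeric(f_out))
}

init_bn <- function(f) list(gamma = rep(1, f), beta = numeric(f))

init_block <- function(c_in, c_out, k) {
  list(bn1 = init_bn(c_in), conv1 = init_conv(c_in, c_out, k),
       bn2 = init_bn(c_out), conv2 = init_conv(c_out, c_out, k),
       proj = if (c_in != c_out) init_conv(c_in, c_out, 1L) else NULL)
}

init_bn_state <- function(f) list(mean = numeric(f), var = rep(1, f))

#' Build a residual graph convolutional network
#'
#' Architecture: a pre-convolutional Chebyshev layer at full mesh
#' resolution; `n_blocks` residual blocks, each two
#' BN -> ReLU -> Chebyshev-convolution subblocks with an identity shortcut
#' (an order-1 Chebyshev projection when channel counts differ), each
#' followed by stride-2 max pooling one hierarchy level down; a post
#' residual block at the coarsest level; then flatten, dropout, and a single
#' fully connected output producing one scalar per subject.
#'
#' @param config a [gcnn_model_config()].
#' @param hierarchy a `graph_hierarchy` with at least `n_blocks` levels.
#' @return an object of class `gcnn_model_state`.
#' @export
build_model <- function(config, hierarchy) {
  stopifnot(inherits(config, "gcnn_model_config"),
            inherits(hierarchy, "graph_hierarchy"))
  nb <- config$n_blocks
  if (hierarchy$num_levels < nb)
    stop(sprintf("hierarchy has %d levels but the model needs %d",
                 hierarchy$num_levels, nb))
  ch <- config$channels
  k <- config$K
  set.seed(config$seed)
  params <- list(pre = init_conv(config$input_features, ch[1L], k))
  bn_state <- list(res = vector("list", nb + 1L))
  params$res <- vector("list", nb + 1L)     # blocks 1..nb + post block
  c_in <- ch[1L]
  for (i in seq_len(nb + 1L)) {
    c_out <- ch[i + 1L]
    params$res[[i]] <- init_block(c_in, c_out, k)
    bn_state$res[[i]] <- list(bn1 = init_bn_state(c_in),
                              bn2 = init_bn_state(c_out))
    c_in <- c_out
  }
  d <- hierarchy$levels[[nb + 1L]]$n_padded * ch[length(ch)]
  params$fc <- list(w = matrix(rnorm(d, sd = sqrt(2 / (d + 1))), d, 1L),
                    b = 0)
  structure(list(params = params, bn_state = bn_state, config = config,
                 hierarchy = hierarchy, checksum = hierarchy$checksum,
                 training = FALSE),
            class = "gcnn_model_state")
}

#' @export
print.gcnn_model_state <- function(x, ...) {
  cat(sprintf(
    "gcnn_model_state: f=%d, channels=%s, K=%d, %d residual blocks + post, %d parameters\n",
    x$config$input_features, paste(x$config$channels, collapse = "-"),
    x$config$K, x$config$n_blocks, count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Each Chebyshev convolution contributes `F_in * F_out * K` filter
#' coefficients (biases and batch-norm parameters counted separately via
#' `include_aux`).
#'
#' @param model a `gcnn_model_state`.
#' @param include_aux include biases and batch-norm gamma/beta.
#' @return integer parameter count.
#' @export
count_parameters <- function(model, include_aux = TRUE) {
  leaves <- tree_leaves(model$params)
  tot <- 0L
  for (nm in names(leaves)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    leaf <- path[length(path)]
    if (include_aux || leaf == "theta" || (leaf == "w" && path[1L] == "fc"))
      tot <- tot + length(leaves[[nm]])
  }
  tot
}

## batched Chebyshev convolution on one hierarchy level; the recurrence and
## the BLAS contractions run in compiled code against the level's shared
## scaled Laplacian (CSC slots). theta is stacked (K*C_in) x F_out with row
## block k holding theta_k.
conv_fwd <- function(lev, x, conv, k, b) {
  lt <- lev$scaled
  conv_fwd_cpp(lt@p, lt@i, lt@x, lev$n_padded, b, x, conv$theta, conv$bias, k)
}

## filter/bias gradients and (optionally) the input gradient
## dX = sum_k T_k(Lt) (theta_k dY) via one fused Clenshaw pass
conv_bwd <- function(lev, dy, conv, basis, k, b, want_dx = TRUE) {
  lt <- lev$scaled
  conv_bwd_cpp(lt@p, lt@i, lt@x, lev$n_padded, b, dy, conv$theta, basis, k,
               want_dx)
}

## fused batch norm (over batch and vertices, per channel) + ReLU
bnrelu_fwd <- function(x, bn, state, training) {
  out <- bnrelu_fwd_cpp(x, bn$gamma, bn$beta, state$mean, state$var,
                        training, BN_EPS)
  out$state <- if (training) {
    list(mean = BN_MOMENTUM * state$mean + (1 - BN_MOMENTUM) * out$mu,
         var = BN_MOMENTUM * state$var + (1 - BN_MOMENTUM) * out$var)
  } else state
  out
}

bnrelu_bwd <- function(dy, cache, bn, training) {
  bnrelu_bwd_cpp(dy, cache$mask, cache$xhat, cache$invstd, bn$gamma, training)
}

pool_fwd <- function(x, lev, b) {
  out <- pool_fwd_cpp(x, b, lev$fake_mask)
  list(y = out$y, win = out$win)
}

pool_bwd <- function(dy, cache, lev, b) {
  pool_bwd_cpp(dy, cache$win, b, lev$fake_mask)
}

block_fwd <- function(model, x, i, level, b, training) {
  p <- model$params$res[[i]]
  st <- model$bn_state$res[[i]]
  lev <- model$hierarchy$levels[[level + 1L]]
  k <- model$config$K
  bn1 <- bnrelu_fwd(x, p$bn1, st$bn1, training)
  cv1 <- conv_fwd(lev, bn1$y, p$conv1, k, b)
  bn2 <- bnrelu_fwd(cv1$y, p$bn2, st$bn2, training)
  cv2 <- conv_fwd(lev, bn2$y, p$conv2, k, b)
  s <- if (is.null(p$proj)) x else {
    crossprod(p$proj$theta, x) + p$proj$bias
  }
  y <- cv2$y + s
  ## a_last follows the residual-network convention: the activations of the
  ## last convolutional stage are the block output (after the shortcut add),
  ## which is exactly the representation the head reads
  list(y = y, a_last = y,
       cache = list(x = x, bn1 = bn1, cv1 = cv1, bn2 = bn2, cv2 = cv2,
                    cin1 = nrow(x), cin2 = nrow(cv1$y),
                    level = level, b = b),
       state = list(bn1 = bn1$state, bn2 = bn2$state))
}

block_bwd <- function(model, dy, i, cache, training) {
  p <- model$params$res[[i]]
  lev <- model$hierarchy$levels[[cache$level + 1L]]
  k <- model$config$K
  b <- cache$b
  ## conv2 branch
  g2 <- conv_bwd(lev, dy, p$conv2, cache$cv2$basis, k, b)
  b2 <- bnrelu_bwd(g2$dx, cache$bn2, p$bn2, training)
  dcv1 <- b2$dx
  g1 <- conv_bwd(lev, dcv1, p$conv1, cache$cv1$basis, k, b)
  b1 <- bnrelu_bwd(g1$dx, cache$bn1, p$bn1, training)
  dx <- b1$dx
  ## shortcut
  if (is.null(p$proj)) {
    dx <- dx + dy
    dproj <- NULL
  } else {
    dproj <- list(theta = cache$x %*% t(dy), bias = rowSums(dy))
    dx <- dx + p$proj$theta %*% dy
  }
  list(dx = dx,
       grads = list(bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    conv1 = list(theta = g1$theta, bias = g1$bias),
                    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                    conv2 = list(theta = g2$theta, bias = g2$bias),
                    proj = dproj))
}

#' Forward pass of the residual gCNN
#'
#' @param model a `gcnn_model_state`.
#' @param x_batch numeric array `n_padded x f x B` (or a matrix for a single
#'   subject) of padded, permuted node features (see [pad_features()]).
#' @param training run in training mode (batch statistics, dropout). In
#'   evaluation mode (default) the pass is deterministic.
#' @param keep_cache retain intermediate tensors for a backward pass.
#' @return list with `pred` (B finite scalars), and when requested `cache`
#'   and updated `bn_state`.
#' @export
forward <- function(model, x_batch, training = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(model, "gcnn_model_state"))
  if (is.matrix(x_batch)) x_batch <- array(x_batch, dim = c(dim(x_batch), 1L))
  n0 <- model$hierarchy$levels[[1L]]$n_padded
  f <- model$config$input_features
  if (dim(x_batch)[1L] != n0 || dim(x_batch)[2L] != f)
    stop(sprintf("feature batch is %d x %d; model expects %d x %d",
                 dim(x_batch)[1L], dim(x_batch)[2L], n0, f))
  b <- dim(x_batch)[3L]
  nb <- model$config$n_blocks
  ## channels-first stack: column (j-1)*b + s holds subject s at vertex j
  xs <- matrix(aperm(x_batch, c(2L, 3L, 1L)), f, b * n0)
  caches <- list()
  new_state <- model$bn_state
  pre <- conv_fwd(model$hierarchy$levels[[1L]], xs, model$params$pre,
                  model$config$K, b)
  caches$pre <- if (keep_cache) pre["basis"] else NULL
  h <- pre$y
  for (i in seq_len(nb)) {
    blk <- block_fwd(model, h, i, level = i - 1L, b = b, training = training)
    new_state$res[[i]] <- blk$state
    lev <- model$hierarchy$levels[[i]]
    pl <- pool_fwd(blk$y, lev, b)
    caches$res[[i]] <- if (keep_cache) list(block = blk$cache, pool = pl) else NULL
    h <- pl$y
  }
  blk <- block_fwd(model, h, nb + 1L, level = nb, b = b, training = training)
  new_state$res[[nb + 1L]] <- blk$state
  caches$post <- if (keep_cache) blk$cache else NULL
  a_last <- blk$a_last
  h <- blk$y
  ## flatten per subject
  n_l <- model$hierarchy$levels[[nb + 1L]]$n_padded
  c_l <- nrow(h)
  flat <- matrix(aperm(array(h, dim = c(c_l, b, n_l)), c(2L, 1L, 3L)),
                 b, c_l * n_l)
  drop_mask <- NULL
  p <- model$config$dropout_rate
  if (training && p > 0) {
    drop_mask <- matrix(runif(length(flat)) >= p, b, ncol(flat)) / (1 - p)
    flat_d <- flat * drop_mask
  } else flat_d <- flat
  pred <- as.numeric(flat_d %*% model$params$fc$w) + model$params$fc$b
  out <- list(pred = pred)
  if (keep_cache) {
    caches$flat <- flat
    caches$drop_mask <- drop_mask
    caches$dims <- c(n_l = n_l, b = b, c_l = c_l)
    caches$a_last <- a_last
    caches$training <- training
    out$cache <- caches
    out$bn_state <- new_state
  } else if (training) {
    out$bn_state <- new_state
  }
  out
}

## Backward pass: dpred is the loss gradient w.r.t. the B predictions.
## Returns gradients in the same shape as model$params, plus (optionally)
## the gradient at the post block's final conv activations (for Grad-CAM).
backward <- function(model, cache, dpred, want_alast_grad = FALSE) {
  nb <- model$config$n_blocks
  training <- cache$training
  grads <- list()
  dims <- cache$dims
  b <- dims[["b"]]; n_l <- dims[["n_l"]]; c_l <- dims[["c_l"]]
  flat_d <- if (is.null(cache$drop_mask)) cache$flat
            else cache$flat * cache$drop_mask
  dpred <- matrix(dpred, ncol = 1L)
  grads$fc <- list(w = crossprod(flat_d, dpred), b = sum(dpred))
  dflat <- dpred %*% t(model$params$fc$w)
  if (!is.null(cache$drop_mask)) dflat <- dflat * cache$drop_mask
  ## unflatten to channels-first stack
  dh <- matrix(aperm(array(dflat, dim = c(b, c_l, n_l)), c(2L, 1L, 3L)),
               c_l, b * n_l)
  post <- block_bwd(model, dh, nb + 1L, cache$post, training)
  grads$res <- vector("list", nb + 1L)
  grads$res[[nb + 1L]] <- post$grads
  da_last <- if (want_alast_grad) dh else NULL   # y depends on A only via +s
  dh <- post$dx
  for (i in rev(seq_len(nb))) {
    dh <- pool_bwd(dh, cache$res[[i]]$pool,
                   model$hierarchy$levels[[i]], b)
    blk <- block_bwd(model, dh, i, cache$res[[i]]$block, training)
    grads$res[[i]] <- blk$grads
    dh <- blk$dx
  }
  g0 <- conv_bwd(model$hierarchy$levels[[1L]], dh, model$params$pre,
                 cache$pre$basis, model$config$K, b, want_dx = FALSE)
  grads$pre <- list(theta = g0$theta, bias = g0$bias)
  list(grads = grads, da_last = da_last)
}

# ---------------------------------------------------------------------------
# Parameter-tree utilities and Adam
# ---------------------------------------------------------------------------

## apply f(leaf_a, leaf_b, path) over two parallel parameter trees;
## unnamed list nodes (e.g. the residual-block list) use positional labels
tree_map2 <- function(a, b, f, path = character()) {
  if (is.list(a)) {
    nms <- names(a)
    named <- !is.null(nms)
    if (!named) nms <- as.character(seq_along(a))
    out <- a
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      bi <- if (named) b[[nms[i]]] else b[[i]]
      out[[i]] <- tree_map2(a[[i]], bi, f, c(path, nms[i]))
    }
    out
  } else f(a, b, path)
}

tree_leaves <- function(a, path = character()) {
  if (is.list(a)) {
    nms <- names(a)
    if (is.null(nms)) nms <- as.character(seq_along(a))
    out <- list()
    for (i in seq_along(a)) {
      if (is.null(a[[i]])) next
      out <- c(out, tree_leaves(a[[i]], c(path, nms[i])))
    }
    out
  } else {
    stats::setNames(list(a), paste(path, collapse = "."))
  }
}

tree_zero <- function(a) tree_map2(a, a, function(x, y, p) x * 0)

## leaves subject to l2 regularization: filter coefficients and FC weights
is_reg_leaf <- function(path) {
  nm <- path[length(path)]
  nm == "theta" || (nm == "w" && path[length(path) - 1L] == "fc")
}

adam_init <- function(params) list(m = tree_zero(params), v = tree_zero(params),
                                   t = 0L)

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map2(opt$m, grads, function(m, g, p) beta1 * m + (1 - beta1) * g)
  opt$v <- tree_map2(opt$v, grads, function(v, g, p) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  mh <- tree_map2(opt$m, opt$m, function(m, ., p) m / bc1)
  vh <- tree_map2(opt$v, opt$v, function(v, ., p) v / bc2)
  upd <- tree_map2(mh, vh, function(m, v, p) lr * m / (sqrt(v) + eps))
  params <- tree_map2(params, upd, function(w, u, p) w - u)
  list(params = params, opt = opt)
}

## sum of squared regularized weights (filter coefficients + FC weights,
## excluding biases and batch-norm parameters)
reg_norm <- function(params) {
  leaves <- tree_leaves(params)
  tot <- 0
  for (nm in names(leaves)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (is_reg_leaf(path)) tot <- tot + sum(leaves[[nm]]^2)
  }
  tot
}

add_reg_grad <- function(grads, params, lambda1) {
  if (lambda1 == 0) return(grads)
  tree_map2(grads, params, function(g, w, p)
    if (is_reg_leaf(p)) g + 2 * lambda1 * w else g)
}

#' Pad and reorder subject features for the model
#'
#' Maps an `n x f` template-ordered feature matrix onto the hierarchy's
#' padded, sibling-contiguous vertex ordering; padding vertices get zero
#' features.
#'
#' @param x `n x f` matrix (template order) or `n x f x B` array.
#' @param hierarchy a `graph_hierarchy`.
#' @return padded matrix/array with `n_padded` rows.
#' @export
pad_features <- function(x, hierarchy) {
  lev0 <- hierarchy$levels[[1L]]
  perm <- lev0$perm
  if (is.matrix(x)) {
    out <- matrix(0, lev0$n_padded, ncol(x))
    out[!lev0$fake_mask, ] <- x[perm[!lev0$fake_mask], , drop = FALSE]
  } else {
    out <- array(0, dim = c(lev0$n_padded, dim(x)[2L], dim(x)[3L]))
    out[!lev0$fake_mask, , ] <- x[perm[!lev0$fake_mask], , , drop = FALSE]
  }
  out
}

#' Save / load a fitted model
#'
#' Serializes parameters, batch-norm state, configuration and the template
#' checksum; the round trip reproduces all parameters bit-exactly. The
#' hierarchy itself is not embedded and is re-attached on load.
#'
#' @param model a `gcnn_model_state` (or `gcnn` fit).
#' @param path file path.
#' @param hierarchy hierarchy to re-attach on load (checksum-verified).
#' @return `save_gcnn`: `path` invisibly; `load_gcnn`: the restored model.
#' @export
save_gcnn <- function(model, path) {
  if (inherits(model, "gcnn")) model <- model$model
  stopifnot(inherits(model, "gcnn_model_state"))
  saveRDS(list(params = model$params, bn_state = model$bn_state,
               config = model$config, checksum = model$checksum), path)
  invisible(path)
}

#' @rdname save_gcnn
#' @export
load_gcnn <- function(path, hierarchy) {
  obj <- readRDS(path)
  if (!identical(obj$checksum, hierarchy$checksum))
    stop("template/hierarchy checksum mismatch: model was trained on a different template")
  m <- build_model(obj$config, hierarchy)
  m$params <- obj$params
  m$bn_state <- obj$bn_state
  m
}
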