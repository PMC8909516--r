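#' Training configuration for the GRU stress classifier
#'
#' Defaults follow the model settings used for the rice-stress task:
#' `input_size = 8` (one channel per spectral index), `hidden_size = 256`,
#' `batch_size = 8`, `learning_rate = 1e-4`. The dense head width defaults to
#' `hidden_size / 2`. Optimization is mini-batch Adam on multiclass
#' cross-entropy with patience-based early stopping on test loss.
#'
#' @param input_size Number of feature channels per time step.
#' @param hidden_size Number of GRU hidden units.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without test-loss improvement before stopping.
#' @param n_classes Number of output classes.
#' @param head_size Width of the first dense layer (default `hidden_size/2`).
#' @param seed Integer seed controlling initialization and batch order.
#' @return An object of class `gru_config`.
#' @export
gru_config <- function(input_size = 8L, hidden_size = 256L, batch_size = 8L,
                       learning_rate = 1e-4, max_epochs = 50L, patience = 5L,
                       n_classes = 3L, head_size = NULL, seed = 1L) {
  if (input_size < 1 || hidden_size < 1 || batch_size < 1 || n_classes < 2)
    stopf("gru_config: sizes must be positive (and n_classes >= 2)")
  if (learning_rate < 0)
    stopf("gru_config: learning_rate must be nonnegative")
  head_size <- as.integer(head_size %||% max(hidden_size %/% 2L, 1L))
  structure(list(input_size = as.integer(input_size),
                 hidden_size = as.integer(hidden_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_classes = as.integer(n_classes),
                 head_size = head_size,
                 seed = as.integer(seed)),
            class = "gru_config")
}

# row-broadcast a bias vector over a batch
add_bias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

#' Initialize GRU weights
#'
#' Nine gate/candidate parameter blocks (`Wxr, Wxz, Wxh` of shape `d x h`;
#' `Whr, Whz, Whh` of shape `h x h`; biases `br, bz, bh` of length `h`) plus a
#' two-layer dense head (`W1: h x head`, `W2: head x n_classes`). Weights are
#' drawn uniformly on `(-1/sqrt(h), 1/sqrt(h))`; biases start at zero.
#'
#' @param config A [gru_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Named list of weight matrices and bias vectors.
#' @export
gru_init <- function(config, seed = config$seed) {
  d <- config$input_size; h <- config$hidden_size
  hd <- config$head_size; k <- config$n_classes
  s <- 1 / sqrt(h)
  local_seed(seed, {
    rmat <- function(a, b) matrix(stats::runif(a * b, -s, s), a, b)
    list(Wxr = rmat(d, h), Wxz = rmat(d, h), Wxh = rmat(d, h),
         Whr = rmat(h, h), Whz = rmat(h, h), Whh = rmat(h, h),
         br = numeric(h), bz = numeric(h), bh = numeric(h),
         W1 = rmat(h, hd), b1 = numeric(hd),
         W2 = rmat(hd, k), b2 = numeric(k))
  })
}

#' Number of trainable parameters of the model
#'
#' Closed form: `3 (d h + h^2 + h)` for the three gate/candidate blocks plus
#' `(h head + head) + (head k + k)` for the dense head.
#' @param input_size,hidden_size,head_size,n_classes Layer sizes.
#' @export
gru_param_count <- function(input_size, hidden_size,
                            head_size = max(hidden_size %/% 2, 1),
                            n_classes = 3) {
  3 * (input_size * hidden_size + hidden_size^2 + hidden_size) +
    (hidden_size * head_size + head_size) +
    (head_size * n_classes + n_classes)
}

# One GRU step returning the full cache needed for backpropagation.
gru_cell_full <- function(x_t, h_prev, w) {
  r <- sigmoid(add_bias(x_t %*% w$Wxr + h_prev %*% w$Whr, w$br))
  z <- sigmoid(add_bias(x_t %*% w$Wxz + h_prev %*% w$Whz, w$bz))
  h_tilde <- tanh(add_bias(x_t %*% w$Wxh + (r * h_prev) %*% w$Whh, w$bh))
  h <- z * h_prev + (1 - z) * h_tilde
  list(h = h, r = r, z = z, h_tilde = h_tilde)
}

#' One GRU cell step
#'
#' Computes the reset gate `R_t = sigmoid(X_t Wxr + H_{t-1} Whr + br)`, update
#' gate `Z_t = sigmoid(X_t Wxz + H_{t-1} Whz + bz)`, candidate state
#' `H~_t = tanh(X_t Wxh + (R_t * H_{t-1}) Whh + bh)` and the new hidden state
#' `H_t = Z_t * H_{t-1} + (1 - Z_t) * H~_t` (elementwise products). The reset
#' gate controls how much past state enters the candidate (0 = discard
#' history); the update gate controls how much past state is carried forward.
#'
#' @param x_t Input rows, `n x d` matrix (a vector is treated as one row).
#' @param h_prev Previous hidden state, `n x h` matrix.
#' @param w Weights from [gru_init()].
#' @return New hidden state `h_t`, `n x h`.
#' @export
gru_cell_step <- function(x_t, h_prev, w) {
  if (is.vector(x_t)) x_t <- matrix(x_t, nrow = 1)
  if (is.vector(h_prev)) h_prev <- matrix(h_prev, nrow = 1)
  if (ncol(x_t) != nrow(w$Wxr))
    stopf("gru_cell_step: x_t has %d columns but Wxr expects %d",
          ncol(x_t), nrow(w$Wxr))
  if (ncol(h_prev) != ncol(w$Wxr))
    stopf("gru_cell_step: h_prev has %d columns but hidden size is %d",
          ncol(h_prev), ncol(w$Wxr))
  gru_cell_full(x_t, h_prev, w)$h
}

# Forward pass over a batch. x: (n, T, d) array. Returns final hidden state,
# head activations, probabilities and (optionally) the per-step cache.
gru_forward_batch <- function(w, x, keep_cache = FALSE) {
  n <- dim(x)[1]; nt <- dim(x)[2]
  h <- matrix(0, n, ncol(w$Wxr))
  cache <- if (keep_cache) vector("list", nt) else NULL
  for (t in seq_len(nt)) {
    x_t <- matrix(x[, t, ], nrow = n)
    st <- gru_cell_full(x_t, h, w)
    if (keep_cache) {
      st$h_prev <- h
      st$x_t <- x_t
      cache[[t]] <- st
    }
    h <- st$h
  }
  u <- tanh(add_bias(h %*% w$W1, w$b1))
  scores <- add_bias(u %*% w$W2, w$b2)
  smax <- apply(scores, 1, max)
  es <- exp(scores - smax)
  probs <- es / rowSums(es)
  list(h_final = h, u = u, scores = scores, probs = probs, cache = cache)
}

#' Forward pass: class probabilities for one sequence or a batch
#'
#' Runs the GRU cell over all dates from a zero initial state, passes the
#' final hidden state through the tanh dense layer and the linear output
#' layer, and applies softmax. Output rows are nonnegative and sum to 1.
#'
#' @param model A trained or initialized `gru_model` (or a bare weight list
#'   with a matching `config` attribute).
#' @param x Either a single `T x d` sequence matrix or an `(n, T, d)` array.
#' @return Matrix of class probabilities, one row per sample; columns named by
#'   `model$classes` when available.
#' @export
gru_forward <- function(model, x) {
  w <- model$weights %||% model
  if (is.matrix(x)) x <- array(x, dim = c(1, nrow(x), ncol(x)))
  if (length(dim(x)) != 3L || dim(x)[2] < 1L)
    stopf("gru_forward: x must be a T x d matrix or (n, T, d) array with T >= 1")
  if (dim(x)[3] != nrow(w$Wxr))
    stopf("gru_forward: %d feature channels supplied but model expects %d",
          dim(x)[3], nrow(w$Wxr))
  p <- gru_forward_batch(w, x)$probs
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}

# Cross-entropy loss and analytic gradients via backpropagation through time.
# x: (n, T, d); y: integer class indices in 1..k. Returns mean loss and a
# gradient list matching the weight list's structure.
gru_loss_grad <- function(w, x, y) {
  n <- dim(x)[1]; nt <- dim(x)[2]
  fwd <- gru_forward_batch(w, x, keep_cache = TRUE)
  probs <- fwd$probs
  eps_ix <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(probs[eps_ix], .Machine$double.xmin)))

  g <- lapply(w, function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m))
              else numeric(length(m)))

  ds <- probs
  ds[eps_ix] <- ds[eps_ix] - 1
  ds <- ds / n
  g$W2 <- crossprod(fwd$u, ds)
  g$b2 <- colSums(ds)
  du <- ds %*% t(w$W2)
  da1 <- du * (1 - fwd$u^2)
  g$W1 <- crossprod(fwd$cache[[nt]]$h, da1)   # final hidden state
  g$b1 <- colSums(da1)
  dh <- da1 %*% t(w$W1)

  for (t in rev(seq_len(nt))) {
    st <- fwd$cache[[t]]
    dz <- dh * (st$h_prev - st$h_tilde)
    dht <- dh * (1 - st$z)
    dh_prev <- dh * st$z

    dah <- dht * (1 - st$h_tilde^2)
    g$Wxh <- g$Wxh + crossprod(st$x_t, dah)
    g$Whh <- g$Whh + crossprod(st$r * st$h_prev, dah)
    g$bh <- g$bh + colSums(dah)
    drh <- dah %*% t(w$Whh)                   # gradient wrt (r * h_prev)
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r

    dar <- dr * st$r * (1 - st$r)
    daz <- dz * st$z * (1 - st$z)
    g$Wxr <- g$Wxr + crossprod(st$x_t, dar)
    g$Whr <- g$Whr + crossprod(st$h_prev, dar)
    g$br <- g$br + colSums(dar)
    g$Wxz <- g$Wxz + crossprod(st$x_t, daz)
    g$Whz <- g$Whz + crossprod(st$h_prev, daz)
    g$bz <- g$bz + colSums(daz)

    dh_prev <- dh_prev + dar %*% t(w$Whr) + daz %*% t(w$Whz)
    dh <- dh_prev
  }
  list(loss = loss, grad = g)
}

# Loss only (used by the finite-difference gradient check).
gru_loss <- function(w, x, y) {
  n <- dim(x)[1]
  probs <- gru_forward_batch(w, x)$probs
  -mean(log(pmax(probs[cbind(seq_len(n), y)], .Machine$double.xmin)))
}
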