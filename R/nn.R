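# Recurrent network core: stacked LSTM cells with an optional time-aware
# memory decomposition, plus hand-derived reverse-mode gradients. Gate
# columns in the fused weight matrices are ordered [input, forget, output,
# candidate]. All per-sample computations use plain numeric vectors; no
# external autodiff is involved, which keeps eval-mode forward passes
# bit-reproducible.

#' Model configuration for sequence classifiers
#'
#' @param embed_dim embedding dimension (default 128).
#' @param hidden_size neurons per recurrent layer (default 128).
#' @param dropout dropout rate in [0, 1), applied between recurrent layers
#'   and before the output head during training (default 0.2).
#' @param n_layers total recurrent depth (default 8). For RETAIN the layers
#'   are split evenly between the two reverse-time attention encoders.
#' @param max_vocab input vocabulary capacity (default 30000).
#' @param time_decay elapsed-time discount applied to the short-term memory
#'   component of the TLSTM cell; default \code{g(dt) = 1/log(e + dt)} with
#'   \code{dt} in days. \code{dt <= 0} means no discount.
#' @param seed integer seed controlling weight initialization and training
#'   randomness.
#' @return object of class \code{model_config}.
#' @export
model_config <- function(embed_dim = 128, hidden_size = 128, dropout = 0.2,
                         n_layers = 8, max_vocab = 30000,
                         time_decay = function(dt) 1 / log(exp(1) + dt),
                         seed = 1L) {
  if (dropout < 0 || dropout >= 1)
    stop_config("dropout", "must lie in [0, 1)")
  if (embed_dim < 1 || hidden_size < 1 || n_layers < 1)
    stop_config("dims", "embed_dim, hidden_size and n_layers must be positive")
  structure(list(embed_dim = as.integer(embed_dim),
                 hidden_size = as.integer(hidden_size),
                 dropout = dropout, n_layers = as.integer(n_layers),
                 max_vocab = as.integer(max_vocab), time_decay = time_decay,
                 seed = as.integer(seed)),
            class = "model_config")
}

init_mat <- function(nr, nc, scale) {
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

init_cell <- function(in_dim, h, time_aware) {
  s <- 1 / sqrt(h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias
  cell <- list(W = init_mat(in_dim, 4 * h, s), U = init_mat(h, 4 * h, s), b = b)
  if (time_aware) {
    cell$Wd <- init_mat(h, h, s)
    cell$bd <- numeric(h)
  }
  cell
}

#' Initialize parameters for a sequence classifier
#'
#' @param model \code{"tlstm"} or \code{"retain"}.
#' @param vocab_size number of assigned token indices (excluding padding).
#' @param config a [model_config()].
#' @return nested list of parameter arrays.
#' @export
nn_init <- function(model = c("tlstm", "retain"), vocab_size, config) {
  model <- match.arg(model)
  set.seed(config$seed)
  m <- config$embed_dim; h <- config$hidden_size
  E <- matrix(rnorm(vocab_size * m, sd = 0.1), vocab_size, m)
  if (model == "tlstm") {
    cells <- lapply(seq_len(config$n_layers), function(l)
      init_cell(if (l == 1) m else h, h, time_aware = TRUE))
    list(E = E, cells = cells,
         w_out = runif(h, -1 / sqrt(h), 1 / sqrt(h)), b_out = 0)
  } else {
    la <- max(1L, config$n_layers %/% 2L)
    lb <- max(1L, config$n_layers - la)
    ac <- lapply(seq_len(la), function(l)
      init_cell(if (l == 1) m else h, h, time_aware = FALSE))
    bc <- lapply(seq_len(lb), function(l)
      init_cell(if (l == 1) m else h, h, time_aware = FALSE))
    list(E = E, alpha_cells = ac, beta_cells = bc,
         w_alpha = runif(h, -1 / sqrt(h), 1 / sqrt(h)), b_alpha = 0,
         W_beta = init_mat(h, m, 1 / sqrt(h)), b_beta = numeric(m),
         w_out = runif(m, -1 / sqrt(m), 1 / sqrt(m)), b_out = 0)
  }
}

# ---- stacked LSTM scan -----------------------------------------------------

# X: T x in_dim matrix (already in scan order). elapsed: per-step day gaps
# (NULL for plain LSTM). masks: list of T x h dropout masks per layer (or
# NULL). Returns top-layer hidden states and caches for backprop.
lstm_stack_forward <- function(cells, X, elapsed = NULL, time_decay = NULL,
                               masks = NULL, cache = FALSE) {
  L <- length(cells); Tn <- nrow(X)
  h <- length(cells[[1]]$b) / 4
  caches <- if (cache) vector("list", L) else NULL
  inp <- X
  for (l in seq_len(L)) {
    cl <- cells[[l]]
    hs <- matrix(0, Tn, h)
    h_prev <- numeric(h); c_prev <- numeric(h)
    lc <- if (cache) vector("list", Tn) else NULL
    for (t in seq_len(Tn)) {
      x <- inp[t, ]
      dt <- if (is.null(elapsed)) 0 else elapsed[t]
      if (!is.null(elapsed) && dt > 0) {
        gval <- time_decay(dt)
        pre_d <- as.vector(c_prev %*% cl$Wd) + cl$bd
        CS <- tanh(pre_d)
        c_adj <- c_prev - CS + CS * gval
      } else {
        gval <- 1; CS <- NULL; c_adj <- c_prev
      }
      z <- as.vector(x %*% cl$W) + as.vector(h_prev %*% cl$U) + cl$b
      i1 <- 1:h; i2 <- (h + 1):(2 * h); i3 <- (2 * h + 1):(3 * h)
      i4 <- (3 * h + 1):(4 * h)
      ig <- sigmoid(z[i1]); fg <- sigmoid(z[i2]); og <- sigmoid(z[i3])
      gg <- tanh(z[i4])
      c_new <- fg * c_adj + ig * gg
      tc <- tanh(c_new)
      h_new <- og * tc
      if (cache)
        lc[[t]] <- list(x = x, h_prev = h_prev, c_prev = c_prev, dt = dt,
                        gval = gval, CS = CS, c_adj = c_adj, i = ig, f = fg,
                        o = og, g = gg, c_new = c_new, tc = tc)
      hs[t, ] <- h_new
      h_prev <- h_new; c_prev <- c_new
    }
    if (!is.null(masks)) hs <- hs * masks[[l]]
    if (cache) caches[[l]] <- list(steps = lc, out = hs, inp = inp)
    inp <- hs
  }
  list(H = inp, caches = caches)
}

zero_like_cell <- function(cl) {
  g <- list(W = cl$W * 0, U = cl$U * 0, b = cl$b * 0)
  if (!is.null(cl$Wd)) { g$Wd <- cl$Wd * 0; g$bd <- cl$bd * 0 }
  g
}

# dH: T x h gradient w.r.t. the (post-mask) top-layer outputs.
# Returns per-cell gradients and dX (gradient w.r.t. the stack input).
lstm_stack_backward <- function(cells, caches, dH, masks = NULL) {
  L <- length(cells)
  grads <- lapply(cells, zero_like_cell)
  dout <- dH
  for (l in rev(seq_len(L))) {
    cl <- cells[[l]]; ca <- caches[[l]]
    Tn <- length(ca$steps)
    h <- length(cl$b) / 4
    if (!is.null(masks)) dout <- dout * masks[[l]]
    i1 <- 1:h; i2 <- (h + 1):(2 * h); i3 <- (2 * h + 1):(3 * h)
    i4 <- (3 * h + 1):(4 * h)
    dX <- matrix(0, Tn, nrow(cl$W))
    dh_next <- numeric(h); dc_next <- numeric(h)
    g <- grads[[l]]
    for (t in rev(seq_len(Tn))) {
      st <- ca$steps[[t]]
      dh <- dout[t, ] + dh_next
      dc <- dc_next + dh * st$o * (1 - st$tc^2)
      do_ <- dh * st$tc
      di <- dc * st$g
      dg <- dc * st$i
      df <- dc * st$c_adj
      dc_adj <- dc * st$f
      dz <- c(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
              do_ * st$o * (1 - st$o), dg * (1 - st$g^2))
      g$W <- g$W + outer(st$x, dz)
      g$U <- g$U + outer(st$h_prev, dz)
      g$b <- g$b + dz
      dX[t, ] <- as.vector(cl$W %*% dz)
      dh_next <- as.vector(cl$U %*% dz)
      if (!is.null(st$CS)) {
        dCS <- dc_adj * (st$gval - 1)
        dpre <- dCS * (1 - st$CS^2)
        g$Wd <- g$Wd + outer(st$c_prev, dpre)
        g$bd <- g$bd + dpre
        dc_next <- dc_adj + as.vector(cl$Wd %*% dpre)
      } else {
        dc_next <- dc_adj
      }
    }
    grads[[l]] <- g
    dout <- dX
  }
  list(grads = grads, dX = dout)
}

embed_visits <- function(E, visits) {
  m <- ncol(E)
  vals <- vapply(visits, function(ix)
    if (length(ix) == 1) E[ix, ] else colSums(E[ix, , drop = FALSE]),
    numeric(m))
  # vapply returns a vector when m == 1; always produce a T x m matrix
  if (m == 1) matrix(vals, ncol = 1) else t(vals)
}

check_sequence <- function(visits, elapsed) {
  if (!length(visits)) stop("empty visit sequence", call. = FALSE)
  if (length(elapsed) != length(visits))
    stop("elapsed must have one entry per visit", call. = FALSE)
  if (any(elapsed < 0)) stop("negative elapsed time", call. = FALSE)
  if (elapsed[1] != 0) stop("elapsed time of the first visit must be 0",
                            call. = FALSE)
}

# ---- TLSTM -----------------------------------------------------------------

#' TLSTM forward pass
#'
#' Embeds each visit as the sum of its token embeddings and runs a stacked
#' time-aware LSTM: before each step the previous cell memory is decomposed
#' into a learned short-term component (discounted by
#' \code{config$time_decay} of the elapsed days since the previous visit)
#' and a long-term remainder. A sigmoid head on the last hidden state gives
#' the risk probability. With all elapsed gaps zero the discount is skipped
#' entirely and the network is exactly a standard stacked LSTM.
#'
#' @param visits list of integer vectors (vocabulary indices per visit).
#' @param elapsed numeric vector of day gaps between consecutive visits
#'   (first entry 0).
#' @param params parameter list from [nn_init()] (model \code{"tlstm"}).
#' @param config a [model_config()].
#' @param time_aware set \code{FALSE} to disable the memory decomposition
#'   (plain stacked LSTM with the same weights).
#' @return list with \code{probability} and \code{hidden} (last top-layer
#'   hidden state).
#' @export
tlstm_forward <- function(visits, elapsed, params, config,
                          time_aware = TRUE) {
  check_sequence(visits, elapsed)
  X <- embed_visits(params$E, visits)
  out <- lstm_stack_forward(params$cells, X,
                            elapsed = if (time_aware) elapsed else NULL,
                            time_decay = config$time_decay)
  hT <- out$H[nrow(out$H), ]
  list(probability = sigmoid(sum(params$w_out * hT) + params$b_out),
       hidden = hT)
}

# loss + gradients for one sample (BCE); masks: dropout masks or NULL
tlstm_grad <- function(visits, elapsed, y, params, config, masks = NULL) {
  X <- embed_visits(params$E, visits)
  out <- lstm_stack_forward(params$cells, X, elapsed = elapsed,
                            time_decay = config$time_decay, masks = masks,
                            cache = TRUE)
  Tn <- nrow(X)
  hd <- out$H[Tn, ]  # top-layer mask (if any) acts as pre-head dropout
  p <- sigmoid(sum(params$w_out * hd) + params$b_out)
  eps <- 1e-12
  loss <- -(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dlogit <- p - y
  dh <- dlogit * params$w_out
  dH <- matrix(0, Tn, config$hidden_size)
  dH[Tn, ] <- dh
  bk <- lstm_stack_backward(params$cells, out$caches, dH, masks = masks)
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  for (t in seq_len(Tn)) {
    ix <- visits[[t]]
    dE[ix, ] <- dE[ix, , drop = FALSE] +
      matrix(bk$dX[t, ], length(ix), ncol(params$E), byrow = TRUE)
  }
  grads <- list(E = dE, cells = bk$grads,
                w_out = dlogit * hd, b_out = dlogit)
  list(loss = loss, p = p, grads = grads)
}

# ---- RETAIN ----------------------------------------------------------------

#' RETAIN forward pass
#'
#' Two-level neural attention over visit embeddings, scanned in reverse
#' time order so that recent visits dominate: one stacked LSTM encoder
#' yields scalar visit-attention logits (softmax-normalized to
#' \code{alpha}), a second yields coordinate-level attention vectors
#' \code{beta = tanh(...)}. The context vector is
#' \code{sum_i alpha_i * (beta_i * v_i)} and a sigmoid head gives the risk
#' probability. The returned \code{alpha} (non-negative, summing to 1) and
#' \code{beta} expose which visits and coordinates drive the prediction.
#'
#' @param visits list of integer vectors (vocabulary indices per visit).
#' @param params parameter list from [nn_init()] (model \code{"retain"}).
#' @param config a [model_config()].
#' @return list with \code{probability}, \code{alpha} (per-visit weights in
#'   original time order) and \code{beta} (T x embed_dim matrix).
#' @export
retain_forward <- function(visits, params, config) {
  if (!length(visits)) stop("empty visit sequence", call. = FALSE)
  V <- embed_visits(params$E, visits)
  Tn <- nrow(V)
  rev_ix <- Tn:1
  Xr <- V[rev_ix, , drop = FALSE]
  Ga <- lstm_stack_forward(params$alpha_cells, Xr)$H[rev_ix, , drop = FALSE]
  Hb <- lstm_stack_forward(params$beta_cells, Xr)$H[rev_ix, , drop = FALSE]
  e <- as.vector(Ga %*% params$w_alpha) + params$b_alpha
  alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
  B <- tanh(Hb %*% params$W_beta +
              matrix(params$b_beta, Tn, length(params$b_beta), byrow = TRUE))
  ctx <- colSums(alpha * (B * V))
  list(probability = sigmoid(sum(params$w_out * ctx) + params$b_out),
       alpha = alpha, beta = B)
}

retain_grad <- function(visits, y, params, config, masks_a = NULL,
                        masks_b = NULL) {
  V <- embed_visits(params$E, visits)
  Tn <- nrow(V); m <- ncol(V)
  rev_ix <- Tn:1
  Xr <- V[rev_ix, , drop = FALSE]
  fa <- lstm_stack_forward(params$alpha_cells, Xr, masks = masks_a, cache = TRUE)
  fb <- lstm_stack_forward(params$beta_cells, Xr, masks = masks_b, cache = TRUE)
  Ga <- fa$H[rev_ix, , drop = FALSE]
  Hb <- fb$H[rev_ix, , drop = FALSE]
  e <- as.vector(Ga %*% params$w_alpha) + params$b_alpha
  alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
  B <- tanh(Hb %*% params$W_beta + matrix(params$b_beta, Tn, m, byrow = TRUE))
  BV <- B * V
  ctx <- colSums(alpha * BV)
  p <- sigmoid(sum(params$w_out * ctx) + params$b_out)
  eps <- 1e-12
  loss <- -(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dlogit <- p - y
  dctx <- dlogit * params$w_out
  dalpha <- as.vector(BV %*% dctx)
  dBV <- alpha %o% dctx
  dB <- dBV * V
  dV_direct <- dBV * B
  de <- alpha * (dalpha - sum(alpha * dalpha))
  dGa <- de %o% params$w_alpha
  dpreB <- dB * (1 - B^2)
  dHb <- dpreB %*% t(params$W_beta)
  bka <- lstm_stack_backward(params$alpha_cells, fa$caches,
                             dGa[rev_ix, , drop = FALSE], masks = masks_a)
  bkb <- lstm_stack_backward(params$beta_cells, fb$caches,
                             dHb[rev_ix, , drop = FALSE], masks = masks_b)
  dV <- dV_direct + bka$dX[rev_ix, , drop = FALSE] + bkb$dX[rev_ix, , drop = FALSE]
  dE <- matrix(0, nrow(params$E), m)
  for (t in seq_len(Tn)) {
    ix <- visits[[t]]
    dE[ix, ] <- dE[ix, , drop = FALSE] +
      matrix(dV[t, ], length(ix), m, byrow = TRUE)
  }
  grads <- list(E = dE, alpha_cells = bka$grads, beta_cells = bkb$grads,
                w_alpha = as.vector(t(Ga) %*% de), b_alpha = sum(de),
                W_beta = t(Hb) %*% dpreB, b_beta = colSums(dpreB),
                w_out = dlogit * ctx, b_out = dlogit)
  list(loss = loss, p = p, grads = grads)
}

# ---- optimizer -------------------------------------------------------------

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(el) tree_map(f, el)) else f(x)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0)
}

adam_step <- function(params, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
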