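test_that("model configuration validates its fields", {
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(hidden_size = 0), "positive")
  cfg <- model_config()
  expect_equal(cfg$embed_dim, 128L)
  expect_equal(cfg$hidden_size, 128L)
  expect_equal(cfg$n_layers, 8L)
  expect_equal(cfg$max_vocab, 30000L)
  expect_equal(cfg$time_decay(0), 1)
})

test_that("TLSTM with zero gaps is bit-identical to a plain LSTM", {
  cfg <- model_config(embed_dim = 5, hidden_size = 6, dropout = 0,
                      n_layers = 3, seed = 2)
  params <- nn_init("tlstm", 12, cfg)
  visits <- list(c(1L, 3L), 5L, c(2L, 9L, 12L), 7L)
  zero <- rep(0, 4)
  p_t <- tlstm_forward(visits, zero, params, cfg, time_aware = TRUE)
  p_l <- tlstm_forward(visits, zero, params, cfg, time_aware = FALSE)
  expect_identical(p_t$probability, p_l$probability)
  expect_identical(p_t$hidden, p_l$hidden)
  # with a positive gap the outputs genuinely differ
  p_gap <- tlstm_forward(visits, c(0, 30, 0, 0), params, cfg)
  expect_false(identical(p_gap$probability, p_l$probability))
})

test_that("1-unit TLSTM forward pass matches hand-computed arithmetic", {
  params <- toy_tlstm_params()
  cfg <- toy_config()
  sg <- function(x) 1 / (1 + exp(-x))
  # step 1: token 1 (x = 0.5), no previous state, dt = 0
  x1 <- 0.5
  i1 <- sg(0.1 * x1); f1 <- sg(0.2 * x1 + 1); o1 <- sg(0.3 * x1)
  g1 <- tanh(0.4 * x1)
  c1 <- i1 * g1            # c_prev = 0
  h1 <- o1 * tanh(c1)
  one <- tlstm_forward(list(1L), 0, params, cfg)
  expect_equal(one$probability, sg(1.5 * h1 - 0.2), tolerance = 1e-12)
  # step 2: token 2 (x = -0.3), dt = 10 engages the memory decomposition
  dt <- 10; gd <- 1 / log(exp(1) + dt)
  cs <- tanh(0.7 * c1 + 0.2)
  c_adj <- c1 - cs + cs * gd
  x2 <- -0.3
  i2 <- sg(0.1 * x2 + 0.05 * h1); f2 <- sg(0.2 * x2 - 0.05 * h1 + 1)
  o2 <- sg(0.3 * x2 + 0.1 * h1); g2 <- tanh(0.4 * x2 - 0.1 * h1)
  c2 <- f2 * c_adj + i2 * g2
  h2 <- o2 * tanh(c2)
  two <- tlstm_forward(list(1L, 2L), c(0, dt), params, cfg)
  expect_equal(two$probability, sg(1.5 * h2 - 0.2), tolerance = 1e-12)
  expect_gt(two$probability, 0); expect_lt(two$probability, 1)
})

test_that("time discount shrinks the short-term memory monotonically", {
  params <- toy_tlstm_params()
  cfg <- toy_config()
  gaps <- c(1, 5, 30, 180, 365)
  probs <- vapply(gaps, function(d)
    tlstm_forward(list(1L, 2L), c(0, d), params, cfg)$probability, numeric(1))
  # discounted short-term norm is non-increasing in the gap
  g <- vapply(gaps, cfg$time_decay, numeric(1))
  expect_true(all(diff(g) < 0))
  cs <- 0.4  # any fixed short-term memory value
  expect_true(all(diff(abs(cs * g)) < 0))
  # and the hand net's output varies smoothly with the gap
  expect_equal(length(unique(probs)), length(gaps))
})

test_that("sequence validation rejects degenerate inputs", {
  cfg <- model_config(embed_dim = 4, hidden_size = 4, n_layers = 1, seed = 1)
  params <- nn_init("tlstm", 6, cfg)
  expect_error(tlstm_forward(list(), numeric(0), params, cfg), "empty")
  expect_error(tlstm_forward(list(1L), -1, params, cfg), "negative|first visit")
  expect_error(tlstm_forward(list(1L, 2L), c(0, -3), params, cfg), "negative")
  expect_error(tlstm_forward(list(1L, 2L), c(5, 0), params, cfg), "first visit")
  expect_error(retain_forward(list(), nn_init("retain", 6, cfg), cfg), "empty")
})

test_that("RETAIN attention weights are a distribution; single visit gets 1", {
  cfg <- model_config(embed_dim = 5, hidden_size = 4, dropout = 0,
                      n_layers = 2, seed = 4)
  params <- nn_init("retain", 10, cfg)
  out <- retain_forward(list(c(1L, 2L), 4L, c(3L, 7L)), params, cfg)
  expect_true(all(out$alpha >= 0))
  expect_equal(sum(out$alpha), 1, tolerance = 1e-12)
  expect_equal(dim(out$beta), c(3, 5))
  single <- retain_forward(list(5L), params, cfg)
  expect_equal(single$alpha, 1)
  expect_gt(single$probability, 0); expect_lt(single$probability, 1)
})

test_that("toy 2-visit RETAIN matches a hand-computed attention combination", {
  # 1-dim embeddings and hidden units, single-layer encoders
  sg <- function(x) 1 / (1 + exp(-x))
  cell <- list(W = matrix(c(0.2, 0.1, 0.3, 0.5), 1, 4),
               U = matrix(0, 1, 4), b = c(0, 0, 0, 0))
  params <- list(E = matrix(c(0.8, -0.6), 2, 1),
                 alpha_cells = list(cell), beta_cells = list(cell),
                 w_alpha = 2, b_alpha = 0.1,
                 W_beta = matrix(1.2, 1, 1), b_beta = 0.3,
                 w_out = 1.1, b_out = -0.4)
  cfg <- model_config(embed_dim = 1, hidden_size = 1, dropout = 0,
                      n_layers = 2, seed = 1)
  lstm_step <- function(x, h, c) {
    i <- sg(0.2 * x); f <- sg(0.1 * x); o <- sg(0.3 * x); g <- tanh(0.5 * x)
    c2 <- f * c + i * g
    list(h = sg(0.3 * x) * tanh(c2), c = c2)
  }
  v <- c(0.8, -0.6)
  # reverse scan: visit 2 first, then visit 1
  s2 <- lstm_step(v[2], 0, 0)
  # U = 0 so each step depends on x only through the cell memory chain
  i1 <- sg(0.2 * v[1]); f1 <- sg(0.1 * v[1]); o1 <- sg(0.3 * v[1])
  g1 <- tanh(0.5 * v[1])
  c1 <- f1 * s2$c + i1 * g1
  h1 <- o1 * tanh(c1)
  g_rev <- c(h1, s2$h)  # back in original order: position 1 saw both visits
  e <- 2 * g_rev + 0.1
  alpha <- exp(e - max(e)); alpha <- alpha / sum(alpha)
  beta <- tanh(1.2 * g_rev + 0.3)
  ctx <- sum(alpha * beta * v)
  expected <- sg(1.1 * ctx - 0.4)
  out <- retain_forward(list(1L, 2L), params, cfg)
  expect_equal(out$probability, expected, tolerance = 1e-12)
  expect_equal(out$alpha, alpha, tolerance = 1e-12)
})

test_that("visit embeddings are order-free within a visit", {
  cfg <- model_config(embed_dim = 6, hidden_size = 5, dropout = 0,
                      n_layers = 2, seed = 6)
  pt <- nn_init("tlstm", 9, cfg)
  pr <- nn_init("retain", 9, cfg)
  a <- list(c(1L, 4L, 7L), c(2L, 3L))
  b <- list(c(7L, 1L, 4L), c(3L, 2L))
  expect_equal(tlstm_forward(a, c(0, 5), pt, cfg)$probability,
               tlstm_forward(b, c(0, 5), pt, cfg)$probability,
               tolerance = 1e-12)
  expect_equal(retain_forward(a, pr, cfg)$probability,
               retain_forward(b, pr, cfg)$probability, tolerance = 1e-12)
})

test_that("eval-mode forward passes are deterministic under fixed weights", {
  cfg <- model_config(embed_dim = 8, hidden_size = 8, dropout = 0.2,
                      n_layers = 2, seed = 8)
  params <- nn_init("retain", 15, cfg)
  visits <- list(c(1L, 2L), c(5L, 9L), 14L)
  expect_identical(retain_forward(visits, params, cfg)$probability,
                   retain_forward(visits, params, cfg)$probability)
  pt <- nn_init("tlstm", 15, cfg)
  expect_identical(tlstm_forward(visits, c(0, 3, 40), pt, cfg)$probability,
                   tlstm_forward(visits, c(0, 3, 40), pt, cfg)$probability)
})

test_that("analytic gradients match finite differences on a tiny network", {
  flatten <- function(x) {
    if (is.list(x)) unlist(lapply(x, flatten), use.names = FALSE)
    else as.vector(x)
  }
  assign_flat <- function(x, vals) {
    k <- 0
    rec <- function(x) {
      if (is.list(x)) { for (i in seq_along(x)) x[[i]] <- rec(x[[i]]); x }
      else { n <- length(x); x[] <- vals[k + seq_len(n)]; k <<- k + n; x }
    }
    rec(x)
  }
  cfg <- model_config(embed_dim = 3, hidden_size = 3, dropout = 0,
                      n_layers = 2, seed = 3)
  visits <- list(c(1L, 2L), 3L, c(2L, 4L))
  elapsed <- c(0, 7, 30)
  for (model in c("tlstm", "retain")) {
    params <- nn_init(model, 5, cfg)
    loss_of <- function(vals) {
      p <- assign_flat(params, vals)
      if (model == "tlstm")
        seqrisk:::tlstm_grad(visits, elapsed, 1, p, cfg)$loss
      else seqrisk:::retain_grad(visits, 1, p, cfg)$loss
    }
    gr <- if (model == "tlstm")
      seqrisk:::tlstm_grad(visits, elapsed, 1, params, cfg)$grads
    else seqrisk:::retain_grad(visits, 1, params, cfg)$grads
    fv <- flatten(params)
    ga <- flatten(gr)
    eps <- 1e-6
    idx <- seq(1, length(fv), by = 7)  # spot-check a spread of parameters
    for (j in idx) {
      up <- fv; up[j] <- up[j] + eps
      dn <- fv; dn[j] <- dn[j] - eps
      gn <- (loss_of(up) - loss_of(dn)) / (2 * eps)
      expect_equal(ga[j], gn, tolerance = 1e-5)
    }
  }
})

test_that("logistic forward scores match plogis arithmetic", {
  expect_equal(lr_forward(numeric(3), c(1, 2, 3), intercept = 0.7), plogis(0.7))
  expect_equal(lr_forward(c(1, 0, 2), c(0.5, -1, 0.25), intercept = -0.2),
               plogis(-0.2 + 0.5 + 0.5))
  expect_error(lr_forward(c(1, Inf), c(1, 1)), "finite")
})
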