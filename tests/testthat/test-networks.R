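test_that("lstm_step reproduces hand-derived gate values", {
  # all parameters zero: every sigmoid gate is 0.5, candidate is 0, so
  # the new cell and hidden states are 0
  p0 <- list(W = matrix(0, 8, 3), b = numeric(8))
  st <- lstm_step(1.5, h_prev = c(0.3, -0.2), c_prev = c(1, -1), p = p0)
  expect_equal(st$c, 0.5 * c(1, -1) + 0.5 * 0)
  expect_equal(st$h, 0.5 * tanh(st$c))

  # saturated forget bias keeps the cell state
  p_keep <- list(W = matrix(0, 8, 3), b = c(100, 100, 0, 0, 0, 0, 0, 0))
  st2 <- lstm_step(0, h_prev = c(0, 0), c_prev = c(2, -3), p = p_keep)
  expect_equal(st2$c, c(2, -3), tolerance = 1e-12)

  # hidden state is always inside (-1, 1)
  set.seed(8)
  for (k in 1:20) {
    lp <- rand_lstm(3, 4, sd = 2)
    st3 <- lstm_step(rnorm(3), rnorm(4), rnorm(4), lp$fused)
    expect_true(all(abs(st3$h) < 1))
  }
})

test_that("lstm_step matches the per-gate oracle on 100 random draws", {
  set.seed(101)
  worst <- 0
  for (k in 1:100) {
    input <- sample(1:6, 1)
    hidden <- sample(1:8, 1)
    lp <- rand_lstm(input, hidden)
    x <- rnorm(input); h <- rnorm(hidden); cc <- rnorm(hidden)
    got <- lstm_step(x, h, cc, lp$fused)
    want <- oracle_lstm_step(x, h, cc, lp$Wf, lp$Wi, lp$Wc, lp$Wo,
                             lp$bf, lp$bi, lp$bc, lp$bo)
    worst <- max(worst,
                 max(abs(got$h - want$h) / pmax(abs(want$h), 1e-12)),
                 max(abs(got$c - want$c) / pmax(abs(want$c), 1e-12)))
  }
  expect_lt(worst, 1e-10)
})

test_that("attention_pool follows the scaled-dot-product definition", {
  set.seed(9)
  p <- list(Wq = matrix(rnorm(5 * 64), 5, 64),
            Wk = matrix(rnorm(5 * 64), 5, 64),
            Wv = matrix(rnorm(5), 5, 1))
  # singleton sequence: weight exactly 1
  one <- matrix(rnorm(5), 1, 5)
  a1 <- attention_pool(one, p)
  expect_equal(a1$weights, 1)
  expect_equal(a1$context, drop(one %*% p$Wv))
  # two identical positions: symmetric weights
  two <- rbind(one, one)
  a2 <- attention_pool(two, p)
  expect_equal(a2$weights, c(0.5, 0.5))
  expect_equal(a2$context, drop(one %*% p$Wv))
  expect_error(attention_pool(matrix(numeric(0), 0, 5), p), "non-empty")
})

test_that("attention_pool matches the oracle on 100 random draws and is
           shift invariant", {
  set.seed(33)
  worst <- 0
  for (k in 1:100) {
    width <- sample(2:6, 1)
    len <- sample(1:7, 1)
    p <- list(Wq = matrix(rnorm(width * 64, sd = 0.3), width, 64),
              Wk = matrix(rnorm(width * 64, sd = 0.3), width, 64),
              Wv = matrix(rnorm(width, sd = 0.3), width, 1))
    s <- matrix(rnorm(len * width), len, width)
    got <- attention_pool(s, p)
    want <- oracle_attention(s, p$Wq, p$Wk, p$Wv)
    expect_equal(sum(got$weights), 1, tolerance = 1e-12)
    worst <- max(worst,
                 abs(got$context - want$context) /
                   max(abs(want$context), 1e-12),
                 max(abs(got$weights - want$weights)))
  }
  expect_lt(worst, 1e-10)

  # engineered projections give pre-scaling scores (1, 0), so the
  # weights are softmax(1/8, 0) under the d = 64 scaling
  Wq <- cbind(c(0, 1), matrix(0, 2, 63))   # query (from final row) = e1
  Wk <- cbind(c(1, 0), matrix(0, 2, 63))   # key_1 = e1, key_2 = 0
  Wv <- matrix(0, 2, 1)
  s <- rbind(c(1, 0), c(0, 1))
  a <- attention_pool(s, list(Wq = Wq, Wk = Wk, Wv = Wv))
  expect_equal(a$weights, c(exp(1 / 8), 1) / (exp(1 / 8) + 1),
               tolerance = 1e-12)
  expect_equal(round(a$weights, 4), c(0.5312, 0.4688))

  # adding a constant to every score leaves the weights unchanged
  shift <- rbind(c(25, rep(0, 63)), c(25, rep(0, 63)))
  a_sh <- attention_pool(s, list(Wq = Wq, Wk = Wk + shift, Wv = Wv))
  expect_equal(a_sh$weights, a$weights, tolerance = 1e-12)
})

test_that("generator forward meets the reference width contracts", {
  p <- init_generator_params(seed = 5)
  expect_equal(dim(p$fusion$W), c(56L, 57L))   # head-to-tail fusion width
  expect_equal(dim(p$head$W), c(56L, 56L))
  expect_equal(nrow(p$lstm2$W) / 4, 28)
  z <- rnorm(56)
  out <- generator_forward(z, p)
  expect_length(out, 56)
  expect_true(all(is.finite(out)))
  # deterministic in inference mode
  expect_identical(out, generator_forward(z, p))
  # batched input: one row per vector
  zb <- matrix(rnorm(3 * 56), 3, 56)
  expect_equal(dim(generator_forward(zb, p)), c(3L, 56L))
  expect_error(generator_forward(rnorm(55), p), "56")
})

test_that("zero-parameter generator outputs its fusion bias", {
  bias <- seq_len(56) / 100
  p <- zero_generator(bias)
  expect_equal(generator_forward(rnorm(56), p), bias, tolerance = 1e-12)
})

test_that("compiled generator matches the lstm_step/attention_pool
           composition", {
  set.seed(14)
  for (seed in c(2, 71)) {
    p <- init_generator_params(seed, sd = 0.3)
    z <- rnorm(56)
    expect_equal(generator_forward(z, p),
                 cyclemol:::generator_forward_ref(z, p),
                 tolerance = 1e-9)
  }
})

test_that("discriminator produces one bounded-then-affine real score", {
  set.seed(15)
  d <- init_discriminator_params(seed = 6, sd = 0.3)
  z <- rnorm(56)
  s <- discriminator_forward(z, d)
  expect_length(s, 1)
  expect_true(is.finite(s))
  expect_equal(s, cyclemol:::discriminator_forward_ref(z, d),
               tolerance = 1e-9)
  # with out_dense fixed to identity the score is the squashed context,
  # hence inside (0, 1) for any input
  d_id <- d
  d_id$out$W <- matrix(1)
  d_id$out$b <- 0
  for (k in 1:20) {
    sk <- discriminator_forward(rnorm(56, sd = 3), d_id)
    expect_true(sk > 0 && sk < 1)
  }
  # reference-form switch: disabling the sigmoid changes the score path
  d_lin <- d_id
  d_lin$use_sigmoid <- FALSE
  expect_false(isTRUE(all.equal(discriminator_forward(z, d_id),
                                discriminator_forward(z, d_lin))))
})

test_that("model archive round-trips bitwise and rejects corrupt shapes", {
  bundle <- init_model_bundle(77)
  dir <- tempfile("model")
  save_model(bundle, dir)
  back <- load_model(dir)
  z <- matrix(rnorm(4 * 56), 4, 56)
  expect_identical(generator_forward(z, bundle$G),
                   generator_forward(z, back$G))
  expect_identical(discriminator_forward(z, bundle$D_X),
                   discriminator_forward(z, back$D_X))
  expect_equal(back$weights$lambda1, 0.4)
  expect_equal(back$weights$lambda2, 0.15)

  # corrupt the manifest shape -> loud failure
  man_path <- file.path(dir, "manifest.json")
  man <- jsonlite::read_json(man_path)
  man$layers[[1]]$shape <- c(55L, 56L)
  jsonlite::write_json(man, man_path, auto_unbox = TRUE)
  expect_error(load_model(dir), "mismatch")
})

test_that("numerical input gradients of the generator are finite", {
  p <- init_generator_params(seed = 31)
  z <- rnorm(56)
  base <- generator_forward(z, p)
  h <- 1e-6
  for (j in c(1, 29, 56)) {
    zp <- z; zp[j] <- zp[j] + h
    g <- (generator_forward(zp, p) - base) / h
    expect_true(all(is.finite(g)))
  }
})
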