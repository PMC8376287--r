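# Constructed generators/discriminators (plain functions on n x 56
# matrices) exercise the loss closed forms without any network.
gen_identity <- function(z) z
gen_shift <- function(a) function(z) z + a
disc_const <- function(v) function(z) rep(v, nrow(z))

test_that("cycle loss matches its closed forms", {
  set.seed(1)
  x <- matrix(rnorm(56), 1, 56)
  y <- matrix(rnorm(56), 1, 56)
  expect_equal(cycle_loss(gen_identity, gen_identity, x, y), 0)
  # G adds 1 everywhere, F identity: each round trip misses by 1 per
  # coordinate, 56 + 56 = 112
  expect_equal(cycle_loss(gen_shift(1), gen_identity, x, y), 112,
               tolerance = 1e-10)
  # non-negativity on arbitrary maps
  set.seed(2)
  for (k in 1:5) {
    a <- rnorm(1); b <- rnorm(1)
    expect_gte(cycle_loss(gen_shift(a), gen_shift(b),
                          matrix(rnorm(3 * 56), 3, 56),
                          matrix(rnorm(2 * 56), 2, 56)), 0)
  }
  expect_error(cycle_loss(gen_identity, gen_identity,
                          matrix(numeric(0), 0, 56), y), "non-empty")
})

test_that("identity loss matches its closed forms and symmetry", {
  x <- matrix(rnorm(56), 1, 56)
  y <- matrix(rnorm(56), 1, 56)
  expect_equal(identity_loss(gen_identity, gen_identity, x, y), 0)
  # F moves y by 0.5 per coordinate: 56 * 0.5 = 28 from the first term
  expect_equal(identity_loss(gen_identity, gen_shift(0.5), x, y), 28,
               tolerance = 1e-10)
  # symmetric under swapping (G, batch_x) with (F, batch_y)
  g <- gen_shift(0.3); f <- gen_shift(-0.7)
  expect_equal(identity_loss(g, f, x, y), identity_loss(f, g, y, x),
               tolerance = 1e-12)
})

test_that("least-squares adversarial losses match arithmetic", {
  x <- matrix(rnorm(2 * 56), 2, 56)
  y <- matrix(rnorm(2 * 56), 2, 56)
  perfect <- function(z) rep(1, nrow(z))
  expect_equal(lsgan_discriminator_loss(
    function(z) if (identical(z, x)) rep(1, nrow(z)) else rep(0, nrow(z)),
    real_batch = x, fake_batch = y), 0)
  expect_equal(lsgan_discriminator_loss(disc_const(0.5), x, y), 0.25)
  # worst case: 0 on real, 1 on fake
  expect_equal(lsgan_discriminator_loss(
    function(z) if (identical(z, x)) rep(0, nrow(z)) else rep(1, nrow(z)),
    x, y), 1.0)
  expect_equal(lsgan_generator_loss(perfect, y), 0)
  expect_equal(lsgan_generator_loss(disc_const(0), y), 0.5)
  # monotone improvement as D(fake) moves toward 1
  vals <- vapply(seq(0, 1, 0.25),
                 function(v) lsgan_generator_loss(disc_const(v), y),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("total generator objective weights its components as stated", {
  x <- matrix(rnorm(56), 1, 56)
  y <- matrix(rnorm(56), 1, 56)
  # all components zero
  b0 <- structure(list(G = gen_identity, F = gen_identity,
                       D_X = disc_const(1), D_Y = disc_const(1),
                       weights = list(lambda1 = 0.4, lambda2 = 0.15)),
                  class = "model_bundle")
  expect_equal(total_generator_loss(b0, x, y)$total, 0)
  # adv terms 0, cycle = 1, identity = 1 -> 0.4 + 0.15
  b1 <- b0
  b1$G <- gen_shift(1.5 / 112)
  b1$F <- gen_shift(-0.5 / 112)
  r <- total_generator_loss(b1, x, y)
  expect_equal(r$cycle, 1, tolerance = 1e-10)
  expect_equal(r$identity, 1, tolerance = 1e-10)
  expect_equal(r$total, 0.55, tolerance = 1e-10)
  # bookkeeping identity on real networks
  bundle <- init_model_bundle(55)
  xb <- matrix(rnorm(3 * 56), 3, 56)
  yb <- matrix(rnorm(3 * 56), 3, 56)
  rr <- total_generator_loss(bundle, xb, yb)
  expect_equal(rr$total,
               rr$adv_G + rr$adv_F + 0.4 * rr$cycle + 0.15 * rr$identity,
               tolerance = 1e-12)
})

test_that("compiled joint gradients agree with finite differences", {
  set.seed(3)
  bundle <- init_model_bundle(11)
  # larger-than-default weights so every path carries measurable signal
  bundle$G <- init_generator_params(21, sd = 0.4)
  bundle$F <- init_generator_params(22, sd = 0.4)
  bundle$D_X <- init_discriminator_params(23, sd = 0.4)
  bundle$D_Y <- init_discriminator_params(24, sd = 0.4)
  xb <- matrix(rnorm(4 * 56), 4, 56)
  yb <- matrix(rnorm(4 * 56), 4, 56) + 1
  res <- cyclemol:::cpp_generator_update_grads(bundle, xb, yb)
  expect_equal(res$loss,
               total_generator_loss(bundle, xb, yb, training = TRUE)$total,
               tolerance = 1e-10)
  loss_fn <- function(b)
    total_generator_loss(b, xb, yb, training = TRUE)$total
  set.seed(5)
  for (layer in list(c("G", "head", "W"), c("G", "fusion", "W"),
                     c("G", "bn", "gamma"), c("F", "attn", "Wv"),
                     c("F", "lstm2", "W"))) {
    arr <- bundle[[layer[1]]][[layer[2]]][[layer[3]]]
    v <- rnorm(length(arr)); v <- v / sqrt(sum(v^2))
    h <- 1e-5
    bp <- bundle; bm <- bundle
    bp[[layer[1]]][[layer[2]]][[layer[3]]] <- arr + h * v
    bm[[layer[1]]][[layer[2]]][[layer[3]]] <- arr - h * v
    num <- (loss_fn(bp) - loss_fn(bm)) / (2 * h)
    ana <- sum(as.numeric(
      res[[paste0("grad_", layer[1])]][[layer[2]]][[layer[3]]]) * v)
    expect_equal(ana, num, tolerance = 5e-4,
                 label = paste(layer, collapse = "."))
  }
  # discriminator side
  dres <- cyclemol:::cpp_disc_update_grads(bundle$D_X, xb, yb)
  expect_equal(dres$loss, lsgan_discriminator_loss(bundle$D_X, xb, yb),
               tolerance = 1e-10)
  arr <- bundle$D_X$d2$W
  v <- rnorm(length(arr)); v <- v / sqrt(sum(v^2))
  h <- 1e-5
  Dp <- bundle$D_X; Dm <- bundle$D_X
  Dp$d2$W <- arr + h * v
  Dm$d2$W <- arr - h * v
  num <- (lsgan_discriminator_loss(Dp, xb, yb) -
            lsgan_discriminator_loss(Dm, xb, yb)) / (2 * h)
  expect_equal(sum(as.numeric(dres$grads$d2$W) * v), num,
               tolerance = 5e-4)
})

test_that("training is seed-deterministic, resumable and bounded", {
  dom <- sample_synthetic_domains(64, 2.0, 1.0, 17)
  bundle <- init_model_bundle(17)
  cfg <- train_config(epochs = 3, batch_size = 16, seed = 17)
  r1 <- train(bundle, dom$x, dom$y, cfg)
  r2 <- train(bundle, dom$x, dom$y, cfg)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$history), 3)
  expect_true(all(is.finite(as.matrix(r1$history))))
  expect_true(all(r1$history$cycle >= 0))
  expect_true(all(r1$history$identity >= 0))

  # zero epochs: untouched bundle, empty history
  r0 <- train(bundle, dom$x, dom$y,
              train_config(epochs = 0, seed = 17))
  expect_identical(r0$bundle, bundle)
  expect_equal(nrow(r0$history), 0)

  # checkpoint segmentation reproduces the single-run history exactly
  ckdir <- tempfile("ck")
  cfg_seg <- train_config(epochs = 3, batch_size = 16, seed = 17,
                          checkpoint_interval = 1, checkpoint_dir = ckdir)
  rs <- train(bundle, dom$x, dom$y, cfg_seg)
  expect_equal(rs$history, r1$history, tolerance = 1e-14)
  expect_true(dir.exists(file.path(ckdir, "epoch_0002")))
  # checkpoint round trip: stored model reproduces forward outputs
  ck <- load_model(file.path(ckdir, "epoch_0003"))
  probe <- matrix(rnorm(5 * 56), 5, 56)
  expect_identical(generator_forward(probe, ck$G),
                   generator_forward(probe, rs$bundle$G))
  expect_error(train(bundle, matrix(numeric(0), 0, 56), dom$y, cfg),
               "non-empty")
})
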