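#' Losses and the alternating adversarial training loop
#'
#' The translator is trained with four loss ingredients: least-squares
#' adversarial losses for both directions, an L1 cycle-consistency loss
#' (translating X to Y and back must recover the input), and an L1
#' identity-mapping loss keeping each generator's output close to its own
#' input. The generator objective is
#' `adv_G + adv_F + lambda1 * cycle + lambda2 * identity` with default
#' weights `lambda1 = 0.4`, `lambda2 = 0.15`; the discriminators minimise
#' `0.5 E[D(fake)^2] + 0.5 E[(D(real) - 1)^2]`.
#'
#' @name training
NULL

# Apply a generator: either generator parameters or a plain R function on
# n x 56 matrices (used for constructed test cases).
apply_generator <- function(G, z, training = FALSE) {
  if (is.function(G)) G(z) else generator_forward(z, G, training)
}

apply_discriminator <- function(D, z) {
  if (is.function(D)) D(z) else discriminator_forward(z, D)
}

check_batch <- function(z, name) {
  z <- as_latent_matrix(z)
  if (nrow(z) == 0) stop(name, " must be non-empty.", call. = FALSE)
  z
}

#' Cycle-consistency loss
#'
#' Mean L1 reconstruction error of the round trips:
#' `E_x ||F(G(x)) - x||_1 + E_y ||G(F(y)) - y||_1` (the norm sums over the
#' 56 coordinates; the expectation averages over the batch).
#'
#' @param G,F Generator parameter lists, or functions mapping an `n x 56`
#'   matrix to an `n x 56` matrix.
#' @param batch_x,batch_y Non-empty `n x 56` latent batches.
#' @param training Batch-norm mode forwarded to parametric generators.
#' @return Non-negative scalar.
#' @export
cycle_loss <- function(G, F, batch_x, batch_y, training = FALSE) {
  batch_x <- check_batch(batch_x, "batch_x")
  batch_y <- check_batch(batch_y, "batch_y")
  fgx <- apply_generator(F, apply_generator(G, batch_x, training), training)
  gfy <- apply_generator(G, apply_generator(F, batch_y, training), training)
  mean(rowSums(abs(fgx - batch_x))) + mean(rowSums(abs(gfy - batch_y)))
}

#' Identity-mapping loss
#'
#' `E_y ||F(y) - y||_1 + E_x ||G(x) - x||_1`, in exactly this
#' orientation: each
#' generator is penalised for moving its *own-domain source* input (this
#' keeps generated molecules close to the starting molecules; it differs
#' from the classic image-translation identity loss, which feeds each
#' generator the opposite domain).
#'
#' @inheritParams cycle_loss
#' @return Non-negative scalar.
#' @export
identity_loss <- function(G, F, batch_x, batch_y, training = FALSE) {
  batch_x <- check_batch(batch_x, "batch_x")
  batch_y <- check_batch(batch_y, "batch_y")
  fy <- apply_generator(F, batch_y, training)
  gx <- apply_generator(G, batch_x, training)
  mean(rowSums(abs(fy - batch_y))) + mean(rowSums(abs(gx - batch_x)))
}

#' Least-squares discriminator loss
#'
#' `0.5 E[D(fake)^2] + 0.5 E[(D(real) - 1)^2]`: real samples are pushed
#' toward score 1, fakes toward 0.
#'
#' @param D Discriminator parameters, or a function mapping an `n x 56`
#'   matrix to a score vector.
#' @param real_batch,fake_batch Non-empty `n x 56` latent batches.
#' @return Non-negative scalar.
#' @export
lsgan_discriminator_loss <- function(D, real_batch, fake_batch) {
  real_batch <- check_batch(real_batch, "real_batch")
  fake_batch <- check_batch(fake_batch, "fake_batch")
  s_real <- apply_discriminator(D, real_batch)
  s_fake <- apply_discriminator(D, fake_batch)
  0.5 * mean(s_fake^2) + 0.5 * mean((s_real - 1)^2)
}

#' Least-squares generator-side adversarial loss
#'
#' `0.5 E[(D(fake) - 1)^2]`: the generator is rewarded for fakes the
#' discriminator scores as real.
#'
#' @inheritParams lsgan_discriminator_loss
#' @return Non-negative scalar.
#' @export
lsgan_generator_loss <- function(D, fake_batch) {
  fake_batch <- check_batch(fake_batch, "fake_batch")
  0.5 * mean((apply_discriminator(D, fake_batch) - 1)^2)
}

#' Total generator objective and its components
#'
#' `adv_G + adv_F + lambda1 * cycle + lambda2 * identity`, where `adv_G`
#' scores `G(x)` with `D_Y` and `adv_F` scores `F(y)` with `D_X`.
#'
#' @param bundle A `model_bundle`.
#' @inheritParams cycle_loss
#' @return List with `total` and components `adv_G`, `adv_F`, `cycle`,
#'   `identity`; the weighted component sum equals `total`.
#' @export
total_generator_loss <- function(bundle, batch_x, batch_y,
                                 training = FALSE) {
  stopifnot(inherits(bundle, "model_bundle"))
  batch_x <- check_batch(batch_x, "batch_x")
  batch_y <- check_batch(batch_y, "batch_y")
  gx <- apply_generator(bundle$G, batch_x, training)
  fy <- apply_generator(bundle$F, batch_y, training)
  adv_G <- lsgan_generator_loss(bundle$D_Y, gx)
  adv_F <- lsgan_generator_loss(bundle$D_X, fy)
  cyc <- cycle_loss(bundle$G, bundle$F, batch_x, batch_y, training)
  idt <- identity_loss(bundle$G, bundle$F, batch_x, batch_y, training)
  w <- bundle$weights
  list(total = adv_G + adv_F + w$lambda1 * cyc + w$lambda2 * idt,
       adv_G = adv_G, adv_F = adv_F, cycle = cyc, identity = idt)
}

#' Training configuration
#'
#' @param epochs Number of passes over the data (>= 0).
#' @param batch_size Mini-batch size (clamped to the smaller domain).
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param seed Integer seed driving initial shuffling order (one derived
#'   stream per epoch, so segmented runs reproduce a single run).
#' @param bn_momentum Running-statistics update rate of the generator
#'   batch-norm layer.
#' @param checkpoint_interval Optional epochs between checkpoints.
#' @param checkpoint_dir Directory for checkpoints (required when
#'   `checkpoint_interval` is set).
#' @return A validated `train_config` list.
#' @export
train_config <- function(epochs, batch_size = 64, learning_rate = 2e-4,
                         beta1 = 0.5, beta2 = 0.999, seed = 1L,
                         bn_momentum = 0.1, checkpoint_interval = NULL,
                         checkpoint_dir = NULL) {
  epochs <- as.integer(epochs)
  stopifnot(!is.na(epochs), epochs >= 0,
            batch_size >= 1, learning_rate > 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            bn_momentum > 0, bn_momentum <= 1)
  if (!is.null(checkpoint_interval)) {
    stopifnot(checkpoint_interval >= 1, !is.null(checkpoint_dir))
  }
  structure(list(epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, seed = as.integer(seed),
                 bn_momentum = bn_momentum,
                 checkpoint_interval = checkpoint_interval,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Train the translator
#'
#' Alternates, per mini-batch, one least-squares update of each
#' discriminator with one joint Adam update of both generators (1:1
#' ratio). Shuffling, initialisation and batch order all derive from
#' `cfg$seed`, so identical inputs and seed give bitwise-identical loss
#' histories. A non-finite loss aborts with the epoch/batch index.
#'
#' @param bundle A `model_bundle` (see [init_model_bundle()]).
#' @param x_train,y_train Latent matrices (`n x 56`), one row per
#'   molecule.
#' @param cfg A [train_config()].
#' @param state Optional optimizer state from a previous [train()] call
#'   (enables exact resumption).
#' @return List with the trained `bundle`, a `history` data frame (one row
#'   per epoch: discriminator, adversarial, cycle, identity and total
#'   generator losses), and the optimizer `state`.
#' @export
train <- function(bundle, x_train, y_train, cfg, state = NULL) {
  stopifnot(inherits(bundle, "model_bundle"), inherits(cfg, "train_config"))
  x_train <- check_batch(x_train, "x_train")
  y_train <- check_batch(y_train, "y_train")

  empty_history <- data.frame(
    epoch = numeric(0), loss_d_x = numeric(0), loss_d_y = numeric(0),
    adv_g = numeric(0), adv_f = numeric(0), cycle = numeric(0),
    identity = numeric(0), total_g = numeric(0))
  if (cfg$epochs == 0) {
    return(list(bundle = bundle, history = empty_history, state = state))
  }

  seg <- if (is.null(cfg$checkpoint_interval)) cfg$epochs
         else cfg$checkpoint_interval
  done <- 0L
  history <- empty_history
  while (done < cfg$epochs) {
    n_now <- min(seg, cfg$epochs - done)
    res <- cpp_train(bundle, x_train, y_train, list(
      epochs = as.integer(n_now), batch_size = cfg$batch_size,
      learning_rate = cfg$learning_rate, beta1 = cfg$beta1,
      beta2 = cfg$beta2, seed = cfg$seed, start_epoch = done,
      bn_momentum = cfg$bn_momentum, state = state))
    bundle <- res$bundle
    state <- res$state
    history <- rbind(history, res$history)
    done <- done + n_now
    if (!is.null(cfg$checkpoint_interval)) {
      ckpt <- file.path(cfg$checkpoint_dir, sprintf("epoch_%04d", done))
      save_model(bundle, ckpt)
    }
  }
  list(bundle = bundle, history = history, state = state)
}
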