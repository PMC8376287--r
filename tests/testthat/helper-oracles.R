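# Independent straight-from-the-equation oracles.  These deliberately do
# not share code with the package: gates use one weight matrix per gate,
# similarity metrics are brute-force loops, and the Frechet distance has
# a 1-D closed form.

oracle_lstm_step <- function(x_t, h_prev, c_prev, Wf, Wi, Wc, Wo,
                             bf, bi, bc, bo) {
  cat_v <- c(h_prev, x_t)
  sig <- function(u) 1 / (1 + exp(-u))
  f <- sig(drop(Wf %*% cat_v) + bf)
  i <- sig(drop(Wi %*% cat_v) + bi)
  cp <- tanh(drop(Wc %*% cat_v) + bc)
  o <- sig(drop(Wo %*% cat_v) + bo)
  c_t <- f * c_prev + i * cp
  list(h = o * tanh(c_t), c = c_t)
}

# random fused parameters plus their per-gate decomposition
rand_lstm <- function(input, hidden, sd = 0.5) {
  W <- matrix(rnorm(4 * hidden * (hidden + input), sd = sd),
              4 * hidden, hidden + input)
  b <- rnorm(4 * hidden, sd = sd)
  blocks <- function(k) ((k - 1) * hidden + 1):(k * hidden)
  list(fused = list(W = W, b = b),
       Wf = W[blocks(1), , drop = FALSE], bf = b[blocks(1)],
       Wi = W[blocks(2), , drop = FALSE], bi = b[blocks(2)],
       Wc = W[blocks(3), , drop = FALSE], bc = b[blocks(3)],
       Wo = W[blocks(4), , drop = FALSE], bo = b[blocks(4)])
}

oracle_attention <- function(seq_mat, Wq, Wk, Wv, d = 64) {
  n <- nrow(seq_mat)
  query <- drop(seq_mat[n, ] %*% Wq)
  scores <- numeric(n)
  values <- numeric(n)
  for (t in 1:n) {
    key <- drop(seq_mat[t, ] %*% Wk)
    scores[t] <- sum(query * key) / sqrt(d)
    values[t] <- drop(seq_mat[t, ] %*% Wv)
  }
  w <- exp(scores) / sum(exp(scores))
  list(context = sum(w * values), weights = w)
}

oracle_tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(1)
  inter <- sum(a %in% b)
  inter / (length(a) + length(b) - inter)
}

oracle_snn <- function(G, R) {
  acc <- 0
  for (g in G) {
    best <- 0
    for (r in R) best <- max(best, oracle_tanimoto(g, r))
    acc <- acc + best
  }
  acc / length(G)
}

oracle_intdiv <- function(G, p) {
  n <- length(G)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + oracle_tanimoto(G[[i]], G[[j]])^p
  1 - (s / n^2)^(1 / p)
}

oracle_cosine <- function(fg, fr) {
  vocab <- union(names(fg), names(fr))
  g <- r <- setNames(numeric(length(vocab)), vocab)
  g[names(fg)] <- fg
  r[names(fr)] <- fr
  sum(g * r) / sqrt(sum(g^2) * sum(r^2))
}

# 1-D Frechet closed form: (mu1-mu2)^2 + (sd1-sd2)^2
oracle_fcd_1d <- function(mu1, var1, mu2, var2) {
  (mu1 - mu2)^2 + (sqrt(var1) - sqrt(var2))^2
}

oracle_mean_cov <- function(m) {
  n <- nrow(m)
  mu <- colSums(m) / n
  centered <- sweep(m, 2, mu)
  list(mu = mu, sigma = t(centered) %*% centered / (n - 1))
}

make_stats <- function(mu, sigma) {
  structure(list(mu = mu, sigma = as.matrix(sigma), n = NA,
                 provider = "manual"),
            class = "activation_stats")
}

random_fp <- function(n_bits = 30) sort(sample(0:2047, n_bits))

# session-cached toy molecule set (one bridge call for the whole suite)
toy_cache <- new.env()
toy_mols <- function() {
  if (is.null(toy_cache$mols)) toy_cache$mols <- make_toy_molecules()
  toy_cache$mols
}

# generator parameters with every weight zero (bias-only network)
zero_generator <- function(bias = numeric(56)) {
  p <- init_generator_params(seed = 1)
  zero <- function(x) {
    x[] <- 0
    x
  }
  for (nm in c("head", "fusion")) p[[nm]] <- lapply(p[[nm]], zero)
  for (nm in c("lstm1", "lstm2", "lstm3")) {
    p[[nm]]$W <- zero(p[[nm]]$W)
    p[[nm]]$b <- zero(p[[nm]]$b)
  }
  p$attn <- lapply(p$attn, zero)
  p$bn$gamma <- rep(1, 56)
  p$bn$beta <- numeric(56)
  p$bn$running_mean <- numeric(56)
  p$bn$running_var <- rep(1, 56)
  p$fusion$b <- bias
  p
}
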