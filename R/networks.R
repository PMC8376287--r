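#' Network architecture
#'
#' The translator is a pair of generators (G: X to Y, F: Y to X) and a pair
#' of discriminators operating on 56-dimensional latent vectors. A
#' generator is: Dense 56 (with batch normalisation and a rectifier), the
#' 56 resulting features unrolled as a 56-step scalar sequence through an
#' LSTM stack of hidden widths 56 / 28 / 56, a scaled-dot-product attention
#' pool (key width 64, value width 1) over the last LSTM's per-step
#' outputs, head-to-tail fusion (the width-56 head concatenated with the
#' width-1 attention tail into a width-57 vector), and a final Dense 56.
#' A discriminator is Dense 56/28/56 with rectifiers, the width-56 result
#' treated as a 56-step scalar sequence into the same attention pool, a
#' sigmoid squashing, and a final Dense 1 producing the real score used by
#' the least-squares adversarial losses.
#'
#' @name networks
NULL

BN_EPS <- 1e-5
ATTN_KEY_WIDTH <- 64L

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step
#'
#' Computes the standard gated recurrence: with `cat = c(h_prev, x_t)`,
#' \deqn{f = \sigma(W_f cat + b_f),\; i = \sigma(W_i cat + b_i),\;
#'       C' = \tanh(W_C cat + b_C),\; o = \sigma(W_o cat + b_o)}
#' \deqn{c_t = f \odot c_{prev} + i \odot C', \qquad
#'       h_t = o \odot \tanh(c_t).}
#' Gate activations are strictly in (0,1) and every entry of `h_t` lies in
#' (-1,1).
#'
#' @param x_t Input vector for this step.
#' @param h_prev,c_prev Previous hidden and cell states (length = hidden
#'   width).
#' @param p LSTM parameters: `W` is the fused `(4*hidden) x (hidden +
#'   input)` weight matrix with row blocks in gate order f, i, C', o and
#'   column order `c(h_prev, x_t)`; `b` is the fused length `4*hidden`
#'   bias.
#' @return List with elements `h` and `c`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, p) {
  hid <- length(h_prev)
  stopifnot(length(c_prev) == hid,
            nrow(p$W) == 4 * hid,
            ncol(p$W) == hid + length(x_t),
            length(p$b) == 4 * hid)
  pre <- drop(p$W %*% c(h_prev, x_t)) + p$b
  f <- sigmoid(pre[seq_len(hid)])
  i <- sigmoid(pre[hid + seq_len(hid)])
  g <- tanh(pre[2 * hid + seq_len(hid)])
  o <- sigmoid(pre[3 * hid + seq_len(hid)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

#' Scaled-dot-product attention pooling over a sequence
#'
#' The query is the projection of the final sequence element; per-position
#' scores are `query . key_t / sqrt(d)` with `d = 64`; the softmax of the
#' scores gives the position weights, and the context is the
#' weight-averaged width-1 value projection.
#'
#' @param sequence Numeric matrix, one row per position (equal-width
#'   elements); a vector is treated as a one-row sequence of that width.
#' @param p Attention parameters: `Wq`, `Wk` (`width x 64`) and `Wv`
#'   (`width x 1`).
#' @return List with `context` (scalar) and `weights` (probability vector
#'   over positions, summing to 1).
#' @export
attention_pool <- function(sequence, p) {
  if (is.list(sequence)) sequence <- do.call(rbind, sequence)
  if (is.null(dim(sequence))) sequence <- matrix(sequence, nrow = 1)
  n <- nrow(sequence)
  if (n == 0) stop("attention_pool() needs a non-empty sequence.",
                   call. = FALSE)
  stopifnot(nrow(p$Wq) == ncol(sequence), ncol(p$Wq) == ATTN_KEY_WIDTH,
            identical(dim(p$Wq), dim(p$Wk)), ncol(p$Wv) == 1)
  query <- drop(sequence[n, , drop = FALSE] %*% p$Wq)      # length 64
  keys <- sequence %*% p$Wk                                # n x 64
  scores <- drop(keys %*% query) / sqrt(ATTN_KEY_WIDTH)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  values <- drop(sequence %*% p$Wv)                        # length n
  list(context = sum(w * values), weights = w)
}

## ---- parameter construction -------------------------------------------

rand_mat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

init_lstm_params <- function(input, hidden, sd = 0.02) {
  list(W = rand_mat(4 * hidden, hidden + input, sd),
       b = numeric(4 * hidden), input = as.integer(input),
       hidden = as.integer(hidden))
}

init_attention_params <- function(input, sd = 0.02) {
  list(Wq = rand_mat(input, ATTN_KEY_WIDTH, sd),
       Wk = rand_mat(input, ATTN_KEY_WIDTH, sd),
       Wv = rand_mat(input, 1, sd))
}

#' Initialise generator parameters
#'
#' Weights are seeded Gaussian draws (sd 0.02), biases zero, batch-norm
#' scale/shift at 1/0 with running statistics at 0/1.
#'
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @param sd Weight initialisation standard deviation.
#' @return A `generator_params` list (see source for layout).
#' @export
init_generator_params <- function(seed = NULL, sd = 0.02) {
  build <- function() {
    structure(list(
      head = list(W = rand_mat(56, 56, sd), b = numeric(56)),
      bn = list(gamma = rep(1, 56), beta = numeric(56),
                running_mean = numeric(56), running_var = rep(1, 56)),
      lstm1 = init_lstm_params(1, 56, sd),
      lstm2 = init_lstm_params(56, 28, sd),
      lstm3 = init_lstm_params(28, 56, sd),
      attn = init_attention_params(56, sd),
      fusion = list(W = rand_mat(56, 57, sd), b = numeric(56))
    ), class = "generator_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Initialise discriminator parameters
#'
#' @inheritParams init_generator_params
#' @param use_sigmoid Apply the reference design's sigmoid squashing before
#'   the final width-1 dense layer (default `TRUE`; set `FALSE` for the
#'   conventional least-squares discriminator head).
#' @return A `discriminator_params` list.
#' @export
init_discriminator_params <- function(seed = NULL, sd = 0.02,
                                      use_sigmoid = TRUE) {
  build <- function() {
    structure(list(
      d1 = list(W = rand_mat(56, 56, sd), b = numeric(56)),
      d2 = list(W = rand_mat(28, 56, sd), b = numeric(28)),
      d3 = list(W = rand_mat(56, 28, sd), b = numeric(56)),
      attn = init_attention_params(1, sd),
      out = list(W = rand_mat(1, 1, sd), b = numeric(1)),
      use_sigmoid = isTRUE(use_sigmoid)
    ), class = "discriminator_params")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Bundle the two generators, two discriminators and loss weights
#'
#' @param seed Integer seed; the four networks draw from derived
#'   sub-seeds so the bundle is reproducible.
#' @param lambda1 Cycle-consistency weight (default 0.4).
#' @param lambda2 Identity-mapping weight (default 0.15).
#' @param use_sigmoid Discriminator sigmoid switch (see
#'   [init_discriminator_params()]).
#' @return A `model_bundle` with elements `G`, `F`, `D_X`, `D_Y`,
#'   `weights`.
#' @export
init_model_bundle <- function(seed, lambda1 = 0.4, lambda2 = 0.15,
                              use_sigmoid = TRUE) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  seed <- as.integer(seed)
  structure(list(
    G = init_generator_params(seed),
    F = init_generator_params(seed + 1L),
    D_X = init_discriminator_params(seed + 2L, use_sigmoid = use_sigmoid),
    D_Y = init_discriminator_params(seed + 3L, use_sigmoid = use_sigmoid),
    weights = list(lambda1 = lambda1, lambda2 = lambda2)
  ), class = "model_bundle")
}

## ---- forward wrappers ---------------------------------------------------

as_latent_matrix <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  assert_latent(as.matrix(z))
}

#' Generator forward pass
#'
#' @param z Latent input: a length-56 vector or an `n x 56` matrix.
#' @param p `generator_params`.
#' @param training Use batch statistics in the batch-norm layer (`TRUE`) or
#'   the stored running averages (`FALSE`, deterministic per row).
#' @return Latent output with the same shape convention as `z`.
#' @export
generator_forward <- function(z, p, training = FALSE) {
  vec <- is.null(dim(z))
  out <- cpp_generator_forward(p, as_latent_matrix(z), isTRUE(training))
  if (vec) drop(out) else out
}

#' Discriminator forward pass
#'
#' @param z Latent input: a length-56 vector or an `n x 56` matrix.
#' @param p `discriminator_params`.
#' @return Numeric vector of unbounded real scores, one per row.
#' @export
discriminator_forward <- function(z, p) {
  drop(cpp_discriminator_forward(p, as_latent_matrix(z)))
}

## ---- reference forward (used for cross-checking the compiled path) -----

#' Pure-R reference generator forward for a single vector
#'
#' Composes [lstm_step()] and [attention_pool()] exactly as the compiled
#' forward does; used in the test-suite as the second route of the
#' dual-route architecture check. Inference-mode batch norm only.
#'
#' @keywords internal
generator_forward_ref <- function(z, p) {
  stopifnot(length(z) == 56)
  a <- drop(p$head$W %*% z) + p$head$b
  ahat <- (a - p$bn$running_mean) / sqrt(p$bn$running_var + BN_EPS)
  h0 <- pmax(p$bn$gamma * ahat + p$bn$beta, 0)
  st <- list(l1 = list(h = numeric(56), c = numeric(56)),
             l2 = list(h = numeric(28), c = numeric(28)),
             l3 = list(h = numeric(56), c = numeric(56)))
  seq3 <- matrix(0, 56, 56)
  for (t in 1:56) {
    st$l1 <- lstm_step(h0[t], st$l1$h, st$l1$c, p$lstm1)
    st$l2 <- lstm_step(st$l1$h, st$l2$h, st$l2$c, p$lstm2)
    st$l3 <- lstm_step(st$l2$h, st$l3$h, st$l3$c, p$lstm3)
    seq3[t, ] <- st$l3$h
  }
  att <- attention_pool(seq3, p$attn)
  fused <- c(h0, att$context)                 # width 57
  drop(p$fusion$W %*% fused) + p$fusion$b
}

#' Pure-R reference discriminator forward for a single vector
#' @keywords internal
discriminator_forward_ref <- function(z, p) {
  stopifnot(length(z) == 56)
  a1 <- pmax(drop(p$d1$W %*% z) + p$d1$b, 0)
  a2 <- pmax(drop(p$d2$W %*% a1) + p$d2$b, 0)
  a3 <- pmax(drop(p$d3$W %*% a2) + p$d3$b, 0)
  att <- attention_pool(matrix(a3, ncol = 1), p$attn)
  s <- if (isTRUE(p$use_sigmoid)) sigmoid(att$context) else att$context
  drop(p$out$W %*% s) + p$out$b
}

## ---- model archive ------------------------------------------------------

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    path <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    if (is.list(v)) {
      out <- c(out, flatten_params(v, path))
    } else if (is.numeric(v)) {
      out[[path]] <- v
    } else if (is.logical(v)) {
      out[[path]] <- as.numeric(v)
    }
  }
  out
}

#' Save a model bundle as a text parameter archive
#'
#' Writes `manifest.json` (layer names, shapes, flag fields and a content
#' hash) plus `params.txt` (all values flattened in manifest order, full
#' double precision) into `dir`. Optimizer / batch-norm state travels with
#' the bundle.
#'
#' @param bundle A `model_bundle`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- flatten_params(unclass(bundle))
  shapes <- lapply(flat, function(v) {
    if (is.matrix(v)) dim(v) else length(v)
  })
  vals <- unlist(lapply(flat, as.numeric), use.names = FALSE)
  txt <- sprintf("%.17g", vals)
  writeLines(txt, file.path(dir, "params.txt"))
  manifest <- list(
    format = "cyclemol-model/1",
    layers = lapply(names(flat), function(nm)
      list(name = nm, shape = as.integer(shapes[[nm]]))),
    n_values = length(vals),
    hash = content_hash(txt)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a model bundle saved by [save_model()]
#'
#' Fails loudly on any shape mismatch between the manifest and the
#' parameter file.
#'
#' @param dir Archive directory.
#' @return A `model_bundle`.
#' @export
load_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  if (!identical(man$format, "cyclemol-model/1")) {
    stop("Unrecognised model archive format.", call. = FALSE)
  }
  vals <- as.numeric(readLines(file.path(dir, "params.txt")))
  if (length(vals) != man$n_values) {
    stop("Parameter archive corrupt: expected ", man$n_values,
         " values, found ", length(vals), ".", call. = FALSE)
  }
  template <- init_model_bundle(1L)
  flat <- flatten_params(unclass(template))
  pos <- 1L
  for (layer in man$layers) {
    nm <- layer$name
    shape <- as.integer(unlist(layer$shape))
    if (!nm %in% names(flat)) {
      stop("Unknown layer '", nm, "' in manifest.", call. = FALSE)
    }
    expect <- if (is.matrix(flat[[nm]])) dim(flat[[nm]])
              else length(flat[[nm]])
    if (!identical(as.integer(expect), shape)) {
      stop("Shape mismatch for layer '", nm, "': archive ",
           paste(shape, collapse = "x"), ", expected ",
           paste(expect, collapse = "x"), ".", call. = FALSE)
    }
    n <- prod(shape)
    chunk <- vals[pos:(pos + n - 1L)]
    pos <- pos + n
    flat[[nm]] <- if (length(shape) == 2) matrix(chunk, shape[1], shape[2])
                  else chunk
  }
  if (pos - 1L != length(vals)) {
    stop("Parameter archive has trailing values.", call. = FALSE)
  }
  bundle <- template
  assign_path <- function(x, parts, value) {
    if (length(parts) == 1) {
      if (is.logical(x[[parts]])) value <- as.logical(value)
      if (!is.null(attr(x[[parts]], "names"))) names(value) <- NULL
      x[[parts]] <- value
    } else {
      x[[parts[1]]] <- assign_path(x[[parts[1]]], parts[-1], value)
    }
    x
  }
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    bundle <- assign_path(bundle, parts, flat[[nm]])
  }
  # integer fields of the lstm param lists are structural, not stored
  for (g in c("G", "F")) {
    for (l in c("lstm1", "lstm2", "lstm3")) {
      bundle[[g]][[l]]$input <- ncol(bundle[[g]][[l]]$W) -
        nrow(bundle[[g]][[l]]$W) / 4L
      bundle[[g]][[l]]$hidden <- nrow(bundle[[g]][[l]]$W) / 4L
    }
  }
  bundle
}
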