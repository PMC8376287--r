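#' Embedders: the 56-dimensional latent representation
#'
#' All networks in this package operate on length-56 real vectors. Full-scale
#' pipelines in this model family obtain them from a pretrained
#' junction-tree variational autoencoder, which this package deliberately
#' does not re-implement; instead an embedder is a pluggable contract — any object
#' with [encode()] and [decode()] methods and `dimension == 56` — and a
#' self-contained surrogate ([fit_surrogate()]) is bundled for desk-scale
#' work. The surrogate guarantees an exact encode/decode round trip on its
#' own library; no claim is made that its latent geometry matches a
#' neural autoencoder's.
#'
#' @name embedders
NULL

LATENT_DIM <- 56L

assert_latent <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != LATENT_DIM) {
    stop("Latent vectors must have exactly ", LATENT_DIM, " columns, got ",
         ncol(z), ".", call. = FALSE)
  }
  if (!all(is.finite(z))) {
    stop("Latent vectors must be finite.", call. = FALSE)
  }
  z
}

#' Fit the surrogate embedder on a molecule library
#'
#' Builds count-valued circular substructure fingerprints (radius 2,
#' folded to 2048 indices) for every library molecule, projects them to
#' 56 dimensions through a seeded Gaussian random linear map, and
#' standardises each latent coordinate to zero mean / unit variance over
#' the library. Counts (rather than binary presence bits) are projected
#' because highly symmetric molecules — unbranched rings of different
#' sizes, for instance — set identical bit sets and would collapse to one
#' latent point; the multiplicities keep the map injective in practice.
#' Decoding is nearest-neighbour lookup into the stored library, so every
#' library molecule round-trips exactly.
#'
#' @param mols A `molecule_set` with at least 2 distinct valid molecules.
#' @param seed Integer seed for the random projection.
#' @return A `surrogate_embedder` with fields `name`, `dimension`,
#'   `library` (canonical SMILES), `latents` (library latent matrix),
#'   `projection`, `center`, `scale`, `seed`.
#' @export
fit_surrogate <- function(mols, seed) {
  stopifnot(inherits(mols, "molecule_set"))
  mols <- mols[mols$valid, , drop = FALSE]
  mols <- mols[!duplicated(mols$canonical), , drop = FALSE]
  if (nrow(mols) < 2) {
    stop("fit_surrogate() needs at least 2 distinct valid molecules.",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  fp <- fingerprint_counts(mols)
  nbits <- 2048L
  proj <- with_seed(seed,
                    matrix(stats::rnorm(nbits * LATENT_DIM), nbits,
                           LATENT_DIM))
  raw <- t(vapply(fp, project_counts, numeric(LATENT_DIM), proj = proj))
  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  lat <- sweep(sweep(raw, 2, center), 2, scale, "/")
  structure(list(
    name = "surrogate-fingerprint-projection",
    dimension = LATENT_DIM,
    library = mols$canonical,
    latents = lat,
    projection = proj,
    center = center,
    scale = scale,
    seed = seed
  ), class = c("surrogate_embedder", "embedder"))
}

#' Encode molecules as latent vectors
#'
#' @param embedder An embedder object.
#' @param rec A `molecule_set` of valid molecules (or a character vector of
#'   SMILES, which is parsed first).
#' @param ... Method-specific arguments.
#' @return Numeric matrix, one row per molecule, 56 columns.
#' @export
encode <- function(embedder, rec, ...) UseMethod("encode")

#' @export
encode.surrogate_embedder <- function(embedder, rec, ...) {
  if (is.character(rec)) rec <- parse_molecules(rec)
  stopifnot(inherits(rec, "molecule_set"))
  if (any(!rec$valid)) {
    stop("encode() requires valid molecules.", call. = FALSE)
  }
  if (nrow(rec) == 0) {
    return(matrix(numeric(0), 0, LATENT_DIM))
  }
  fp <- fingerprint_counts(rec)
  raw <- t(vapply(fp, project_counts, numeric(LATENT_DIM),
                  proj = embedder$projection))
  sweep(sweep(raw, 2, embedder$center), 2, embedder$scale, "/")
}

# counts: two-column matrix (index, count); proj: 2048 x 56
project_counts <- function(counts, proj) {
  if (nrow(counts) == 0) return(numeric(LATENT_DIM))
  drop(crossprod(proj[counts[, 1] + 1L, , drop = FALSE], counts[, 2]))
}

#' Decode latent vectors back to molecules
#'
#' The surrogate returns, for each row of `z`, the library molecule whose
#' latent vector is nearest in Euclidean distance, ties broken by library
#' order. Decode failure is a value, not an exception: adapters for
#' external autoencoders may return `NA` for undecodable vectors.
#'
#' @param embedder An embedder object.
#' @param z Numeric matrix (rows are latent vectors) or a single length-56
#'   vector.
#' @param ... Method-specific arguments.
#' @return Character vector of canonical SMILES (`NA` = decode failure).
#' @export
decode <- function(embedder, z, ...) UseMethod("decode")

#' @export
decode.surrogate_embedder <- function(embedder, z, ...) {
  z <- assert_latent(z)
  lib <- embedder$latents
  vapply(seq_len(nrow(z)), function(i) {
    d2 <- rowSums(sweep(lib, 2, z[i, ])^2)
    embedder$library[[which.min(d2)]]  # which.min takes the first tie
  }, character(1))
}

#' Morgan fingerprints as 0-based bit-index sets
#'
#' @param mols A `molecule_set` of valid molecules (or character SMILES).
#' @param radius Circular fingerprint radius (default 2).
#' @param nbits Bit-space size (default 2048).
#' @return List of integer vectors (sorted 0-based on-bit indices).
#' @export
molecule_fingerprints <- function(mols, radius = 2, nbits = 2048) {
  smi <- if (inherits(mols, "molecule_set")) {
    stopifnot(all(mols$valid))
    mols$canonical
  } else as.character(mols)
  if (length(smi) == 0) return(list())
  res <- chem_call("fingerprints", smi, radius = radius, nbits = nbits)
  lapply(res, function(bits) {
    if (is.null(bits)) stop("Fingerprint requested for unparsable SMILES.",
                            call. = FALSE)
    sort(as.integer(unlist(bits)))
  })
}

#' Count-valued circular fingerprints (surrogate input)
#'
#' @param mols A `molecule_set` of valid molecules (or character SMILES).
#' @param radius Circular fingerprint radius (default 2).
#' @param nbits Folded index space (default 2048).
#' @return List of two-column integer matrices `(index, count)`, indices
#'   0-based.
#' @keywords internal
fingerprint_counts <- function(mols, radius = 2, nbits = 2048) {
  smi <- if (inherits(mols, "molecule_set")) {
    stopifnot(all(mols$valid))
    mols$canonical
  } else as.character(mols)
  if (length(smi) == 0) return(list())
  res <- chem_call("fingerprints", smi, radius = radius, nbits = nbits,
                   counts = TRUE)
  lapply(res, function(pairs) {
    if (is.null(pairs)) stop("Fingerprint requested for unparsable SMILES.",
                             call. = FALSE)
    if (length(pairs) == 0) {
      return(matrix(integer(0), 0, 2))
    }
    do.call(rbind, lapply(pairs, function(p) as.integer(unlist(p))))
  })
}

#' Sample a pair of synthetic Gaussian latent domains
#'
#' Generates the stated test world for the translation networks: domain X
#' is N(0, noise_sd^2 I) in 56 dimensions and domain Y is the same
#' Gaussian translated by `true_shift`, a vector of magnitude
#' `shift_magnitude` along a seeded random unit direction.
#'
#' @param n_per_domain Number of vectors per domain (>= 1).
#' @param shift_magnitude Euclidean length of the true translation.
#' @param noise_sd Isotropic standard deviation (> 0).
#' @param seed Integer seed.
#' @return A `synthetic_domains` list: `x`, `y` (n x 56 matrices),
#'   `true_shift`, `seed`, `noise_sd`, `shift_magnitude`.
#' @export
sample_synthetic_domains <- function(n_per_domain, shift_magnitude,
                                     noise_sd, seed) {
  n <- as.integer(n_per_domain)
  if (is.na(n) || n < 1) stop("n_per_domain must be >= 1.", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive.", call. = FALSE)
  }
  seed <- as.integer(seed)
  with_seed(seed, {
    u <- stats::rnorm(LATENT_DIM)
    u <- u / sqrt(sum(u^2))
    true_shift <- shift_magnitude * u
    x <- matrix(stats::rnorm(n * LATENT_DIM, sd = noise_sd), n, LATENT_DIM)
    y <- matrix(stats::rnorm(n * LATENT_DIM, sd = noise_sd), n, LATENT_DIM)
    y <- sweep(y, 2, true_shift, "+")
    structure(list(x = x, y = y, true_shift = true_shift, seed = seed,
                   noise_sd = noise_sd, shift_magnitude = shift_magnitude),
              class = "synthetic_domains")
  })
}

#' Write a latent matrix as delimited text with a JSON sidecar
#'
#' One row per molecule, 56 tab-separated numeric columns, optional
#' leading ID column. The sidecar `<path>.json` records the embedder name,
#' seed and a hash of the library.
#'
#' @param z Numeric matrix with 56 columns.
#' @param path Output path.
#' @param ids Optional character IDs (leading column).
#' @param embedder Optional embedder whose provenance is recorded.
#' @return `path`, invisibly.
#' @export
write_latents <- function(z, path, ids = NULL, embedder = NULL) {
  z <- assert_latent(z)
  df <- as.data.frame(z)
  if (!is.null(ids)) df <- cbind(data.frame(id = as.character(ids)), df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  meta <- list(dimension = LATENT_DIM, n = nrow(z),
               has_ids = !is.null(ids))
  if (!is.null(embedder)) {
    meta$embedder <- embedder$name
    meta$seed <- embedder$seed
    meta$library_hash <- content_hash(embedder$library)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a latent matrix written by [write_latents()]
#'
#' @param path Input path.
#' @return Numeric matrix with 56 columns; row IDs (when present) are kept
#'   in the `"ids"` attribute.
#' @export
read_latents <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  ids <- NULL
  if (ncol(df) == LATENT_DIM + 1 && !is.numeric(df[[1]])) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  z <- assert_latent(as.matrix(df))
  dimnames(z) <- NULL
  if (!is.null(ids)) attr(z, "ids") <- ids
  z
}

#' MD5 content hash of a character vector
#' @keywords internal
content_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(x), tmp)
  unname(tools::md5sum(tmp))
}
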