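#' Generative-model evaluation metrics
#'
#' The evaluation suite compares a generated molecule set G against a
#' reference set R with the benchmark-standard battery: set ratios (Valid,
#' Filters, Novelty, Uniqueness, Success rate, Non-identity), similarity
#' statistics over circular fingerprints (Tanimoto, nearest-neighbour
#' similarity SNN, internal diversity IntDiv_p), frequency-vector cosine
#' similarities over retrosynthetic fragments (Frag) and Bemis-Murcko
#' scaffolds (Scaff), a Frechet distance between Gaussian summaries of
#' per-molecule activation vectors (FCD form), and physicochemical
#' property profiles (MW, logP, SA).
#'
#' The bundled activation provider is a standardised physicochemical
#' descriptor panel, not the pretrained neural activations behind
#' ChemNet-based FCD values in the benchmarking literature; reports label it accordingly and values are not
#' comparable across providers.
#'
#' @name metrics
NULL

#' Tanimoto similarity of two fingerprint bit sets
#'
#' `|A intersect B| / |A union B|`; two empty sets denote identical
#' (feature-free) objects and score 1.
#'
#' @param a,b Integer vectors of on-bit indices.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Nearest-neighbour similarity (SNN)
#'
#' Mean, over generated fingerprints, of the maximum Tanimoto similarity
#' to any reference fingerprint.
#'
#' @param G_fps,R_fps Non-empty lists of fingerprint bit-index vectors
#'   (see [molecule_fingerprints()]).
#' @return Value in `[0, 1]`.
#' @export
snn <- function(G_fps, R_fps) {
  if (length(G_fps) == 0 || length(R_fps) == 0) {
    stop("snn() requires non-empty fingerprint sets.", call. = FALSE)
  }
  mean(vapply(G_fps, function(g) {
    max(vapply(R_fps, function(r) tanimoto(g, r), numeric(1)))
  }, numeric(1)))
}

#' Internal diversity of a molecule set
#'
#' `1 - ( mean over all ordered pairs (including self-pairs) of T^p )^(1/p)`;
#' detects mode collapse (identical molecules give 0).
#'
#' @param G_fps Non-empty list of fingerprint bit-index vectors.
#' @param p Power, 1 or 2.
#' @return Value in `[0, 1]`.
#' @export
intdiv <- function(G_fps, p = 1) {
  if (length(G_fps) == 0) {
    stop("intdiv() requires a non-empty fingerprint set.", call. = FALSE)
  }
  stopifnot(p %in% c(1, 2))
  n <- length(G_fps)
  tmat <- matrix(1, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        tmat[i, j] <- tmat[j, i] <- tanimoto(G_fps[[i]], G_fps[[j]])
      }
    }
  }
  1 - mean(tmat^p)^(1 / p)
}

#' Fragment frequency vector of a molecule set
#'
#' Fragments come from retrosynthetic (BRICS-style) bond cleavage; each
#' molecule contributes each of its distinct fragments once, so a
#' duplicated set doubles every frequency.
#'
#' @param mols A `molecule_set` of valid molecules.
#' @return Named numeric vector: fragment key (canonical fragment SMILES)
#'   to frequency.
#' @export
fragment_vector <- function(mols) {
  stopifnot(inherits(mols, "molecule_set"), all(mols$valid))
  if (nrow(mols) == 0) return(stats::setNames(numeric(0), character(0)))
  frags <- chem_call("fragments", mols$canonical)
  keys <- unlist(lapply(frags, function(f) as.character(unlist(f))))
  if (length(keys) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(keys)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Scaffold frequency vector of a molecule set
#'
#' Bemis-Murcko frameworks (ring systems plus linkers); acyclic molecules
#' have an empty framework and contribute nothing.
#'
#' @inheritParams fragment_vector
#' @return Named numeric vector: scaffold SMILES to frequency.
#' @export
scaffold_vector <- function(mols) {
  stopifnot(inherits(mols, "molecule_set"), all(mols$valid))
  if (nrow(mols) == 0) return(stats::setNames(numeric(0), character(0)))
  scafs <- unlist(chem_call("scaffolds", mols$canonical))
  scafs <- scafs[nzchar(scafs)]
  if (length(scafs) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(scafs)
  stats::setNames(as.numeric(tab), names(tab))
}

cosine_counts <- function(fg, fr, as_distance = FALSE) {
  if (sum(fg) == 0 || sum(fr) == 0) {
    warning("All-zero frequency vector; similarity undefined (NA).",
            call. = FALSE)
    return(NA_real_)
  }
  vocab <- union(names(fg), names(fr))
  g <- stats::setNames(numeric(length(vocab)), vocab)
  r <- g
  g[names(fg)] <- fg
  r[names(fr)] <- fr
  cs <- sum(g * r) / sqrt(sum(g^2) * sum(r^2))
  if (as_distance) 1 - cs else cs
}

#' Fragment similarity between two molecule sets
#'
#' Cosine similarity of the fragment frequency vectors over the union
#' vocabulary. The distance form `1 - cos` is available via
#' `as_distance = TRUE`.
#'
#' @param G,R `molecule_set`s of valid molecules, or precomputed
#'   frequency vectors from [fragment_vector()].
#' @param as_distance Emit `1 - cos` instead of the similarity.
#' @return Value in `[0, 1]` (`NA` if either vector is all-zero).
#' @export
frag_similarity <- function(G, R, as_distance = FALSE) {
  fg <- if (inherits(G, "molecule_set")) fragment_vector(G) else G
  fr <- if (inherits(R, "molecule_set")) fragment_vector(R) else R
  cosine_counts(fg, fr, as_distance)
}

#' Scaffold similarity between two molecule sets
#'
#' @inheritParams frag_similarity
#' @param G,R `molecule_set`s of valid molecules, or precomputed
#'   frequency vectors from [scaffold_vector()].
#' @return Value in `[0, 1]` (`NA` if either vector is all-zero).
#' @export
scaff_similarity <- function(G, R, as_distance = FALSE) {
  fg <- if (inherits(G, "molecule_set")) scaffold_vector(G) else G
  fr <- if (inherits(R, "molecule_set")) scaffold_vector(R) else R
  cosine_counts(fg, fr, as_distance)
}

#' Standardised-descriptor activation surrogate
#'
#' Maps each molecule to a 10-dimensional physicochemical descriptor
#' vector (MW, logP, TPSA, HBA, HBD, rotatable bonds, ring count,
#' aromatic rings, Fsp3, heavy atoms), affinely standardised with fixed
#' drug-like location/scale constants so that values are comparable
#' across calls. This is the default activation provider for the Frechet
#' distance and is *not* the neural-network activation space behind
#' literature FCD values.
#'
#' @param mols A `molecule_set` of valid molecules.
#' @return Numeric matrix, one row per molecule.
#' @export
descriptor_activations <- function(mols) {
  stopifnot(inherits(mols, "molecule_set"), all(mols$valid))
  res <- chem_call("descriptors", mols$canonical)
  m <- do.call(rbind, lapply(res, function(r) as.numeric(unlist(r))))
  colnames(m) <- chem_descriptor_names()
  center <- c(mw = 350, logp = 2.5, tpsa = 70, hba = 4, hbd = 1.5,
              rot = 5, rings = 3, arom_rings = 2, fcsp3 = 0.4, heavy = 25)
  scale <- c(mw = 100, logp = 1.5, tpsa = 35, hba = 2, hbd = 1.2,
             rot = 3, rings = 1.5, arom_rings = 1.2, fcsp3 = 0.2,
             heavy = 8)
  sweep(sweep(m, 2, center), 2, scale, "/")
}

#' Gaussian activation summary of a molecule set
#'
#' Column means and sample covariance of the provider's per-molecule
#' activation vectors.
#'
#' @param mols A `molecule_set` with at least 2 molecules.
#' @param provider Function mapping a `molecule_set` to an activation
#'   matrix (default [descriptor_activations()]).
#' @return An `activation_stats` list: `mu`, `sigma`, `n`, `provider`.
#' @export
activation_stats <- function(mols, provider = descriptor_activations) {
  stopifnot(inherits(mols, "molecule_set"))
  if (nrow(mols) < 2) {
    stop("activation_stats() needs at least 2 molecules.", call. = FALSE)
  }
  act <- provider(mols)
  structure(list(mu = colMeans(act), sigma = stats::cov(act),
                 n = nrow(act),
                 provider = attr(provider, "label") %||%
                   "descriptor-surrogate"),
            class = "activation_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frechet distance between two Gaussian activation summaries
#'
#' `||mu_G - mu_R||^2 + Tr(S_G + S_R - 2 (S_G S_R)^{1/2})`, the matrix
#' square root computed through the symmetrised product
#' `S_G^{1/2} S_R S_G^{1/2}`. Values in `[-1e-8, 0)` from round-off are
#' clipped to 0.
#'
#' @param a,b `activation_stats` of conforming dimension.
#' @return Non-negative scalar.
#' @export
fcd <- function(a, b) {
  stopifnot(inherits(a, "activation_stats"), inherits(b, "activation_stats"),
            length(a$mu) == length(b$mu))
  check_sigma <- function(s) {
    if (max(abs(s - t(s))) > 1e-9) {
      stop("Covariance matrix is not symmetric.", call. = FALSE)
    }
    ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("Covariance matrix is not positive semidefinite.", call. = FALSE)
    }
  }
  check_sigma(a$sigma)
  check_sigma(b$sigma)
  ea <- eigen((a$sigma + t(a$sigma)) / 2, symmetric = TRUE)
  sqa <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  M <- sqa %*% b$sigma %*% sqa
  M <- (M + t(M)) / 2
  tr_sqrt <- sum(sqrt(pmax(eigen(M, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  val <- sum((a$mu - b$mu)^2) + sum(diag(a$sigma)) + sum(diag(b$sigma)) -
    2 * tr_sqrt
  if (val < -1e-8) {
    stop("Frechet distance evaluated negative beyond tolerance (", val,
         ").", call. = FALSE)
  }
  max(val, 0)
}

#' Structure-conversion counting metrics
#'
#' Scores a source-aligned generated set: `valid` is the decoded fraction
#' of all sources; `filters`, `uniqueness`, `novelty` and `non_identity`
#' are conditioned on the valid outputs; `success_rate` is the fraction
#' of *all* sources whose output is valid, structurally different from
#' the source, and lands in the target domain's feature-count set (decode
#' failures count against it).
#'
#' @param sources `molecule_set` of starting molecules.
#' @param generated Character vector of generated SMILES aligned 1:1 with
#'   `sources` (`NA` = decode failure), or an aligned `molecule_set`.
#' @param train_set Character vector of canonical training-set SMILES
#'   (novelty reference for this direction).
#' @param spec A [domain_spec()].
#' @param direction `"x_to_y"` (target counts = `y_counts`) or
#'   `"y_to_x"`.
#' @return Named list of ratios, each in `[0, 1]` (`NA` when conditioned
#'   on an empty valid set).
#' @export
conversion_metrics <- function(sources, generated, train_set, spec,
                               direction = c("x_to_y", "y_to_x")) {
  direction <- match.arg(direction)
  stopifnot(inherits(sources, "molecule_set"), inherits(spec, "domain_spec"))
  gen <- if (inherits(generated, "molecule_set")) generated
         else parse_molecules(ifelse(is.na(generated), "", generated))
  if (nrow(gen) != nrow(sources)) {
    stop("generated must align 1:1 with sources (", nrow(gen), " vs ",
         nrow(sources), ").", call. = FALSE)
  }
  n <- nrow(sources)
  if (n == 0) stop("conversion_metrics() needs at least one source.",
                   call. = FALSE)
  ok <- gen$valid
  n_valid <- sum(ok)
  counts <- gen[[.feature_column(spec$feature)]]
  target <- if (direction == "x_to_y") spec$y_counts else spec$x_counts
  non_ident <- ok & gen$canonical != sources$canonical
  succ <- non_ident & counts %in% target
  ratio <- function(k) if (n_valid == 0) NA_real_ else k / n_valid
  list(
    valid = n_valid / n,
    filters = ratio(sum(ok & !gen$has_charged_atom)),
    uniqueness = ratio(length(unique(gen$canonical[ok]))),
    novelty = ratio(sum(ok & !(gen$canonical %in% train_set))),
    non_identity = ratio(sum(non_ident)),
    success_rate = sum(succ) / n
  )
}

#' Physicochemical property profile
#'
#' Per-molecule MW (g/mol), computed logP and synthetic-accessibility
#' score (in `[1, 10]`), with set-level summaries.
#'
#' @param mols A `molecule_set` of valid molecules.
#' @return List with `per_molecule` (data frame `canonical`, `mw`,
#'   `logp`, `sa`) and `summary` (mean and median of each property).
#' @export
property_profile <- function(mols) {
  stopifnot(inherits(mols, "molecule_set"), all(mols$valid))
  per <- data.frame(canonical = mols$canonical, mw = mols$mw,
                    logp = mols$logp, sa = mols$sa,
                    stringsAsFactors = FALSE)
  summ <- lapply(c(mw = "mw", logp = "logp", sa = "sa"), function(col) {
    c(mean = mean(per[[col]]), median = stats::median(per[[col]]))
  })
  list(per_molecule = per, summary = summ)
}

#' Pairwise Tanimoto similarities of aligned source/generated molecules
#'
#' One similarity per aligned pair (NA where generation failed); the raw
#' material of similarity density plots.
#'
#' @param sources `molecule_set` of starting molecules.
#' @param generated Aligned `molecule_set` (or character SMILES with NA
#'   failures).
#' @return Numeric vector of length `nrow(sources)`.
#' @export
tanimoto_profile <- function(sources, generated) {
  gen <- if (inherits(generated, "molecule_set")) generated
         else parse_molecules(ifelse(is.na(generated), "", generated))
  stopifnot(nrow(gen) == nrow(sources))
  out <- rep(NA_real_, nrow(sources))
  ok <- gen$valid
  if (!any(ok)) return(out)
  fps_s <- molecule_fingerprints(sources[ok, , drop = FALSE])
  fps_g <- molecule_fingerprints(gen[ok, , drop = FALSE])
  out[ok] <- mapply(tanimoto, fps_s, fps_g)
  out
}

#' Full evaluation of one translation direction
#'
#' Combines the conversion counts, the fingerprint statistics (SNN,
#' IntDiv_1/2), fragment/scaffold cosine similarities and the Frechet
#' activation distance of the valid generated set against a reference
#' set, plus property profiles. Optionally writes `report.csv`
#' (metric,value rows), `tanimoto_pairs.csv` and `properties.csv`.
#'
#' @inheritParams conversion_metrics
#' @param reference `molecule_set` the generated molecules are compared
#'   against (typically the target-domain test set).
#' @param out_dir Optional output directory.
#' @param as_distance Report Frag/Scaff as `1 - cos`.
#' @param provider Activation provider for the Frechet distance.
#' @return A `metric_report` list of scalars (ratios in `[0, 1]`,
#'   `fcd >= 0`) plus the provider label.
#' @export
evaluate_generation <- function(sources, generated, train_set, reference,
                                spec, direction = c("x_to_y", "y_to_x"),
                                out_dir = NULL, as_distance = FALSE,
                                provider = descriptor_activations) {
  direction <- match.arg(direction)
  gen <- if (inherits(generated, "molecule_set")) generated
         else parse_molecules(ifelse(is.na(generated), "", generated))
  conv <- conversion_metrics(sources, gen, train_set, spec, direction)
  okg <- gen[gen$valid, , drop = FALSE]
  report <- conv
  if (nrow(okg) >= 1 && nrow(reference) >= 1) {
    fps_g <- molecule_fingerprints(okg)
    fps_r <- molecule_fingerprints(reference)
    report$snn <- snn(fps_g, fps_r)
    report$intdiv1 <- intdiv(fps_g, 1)
    report$intdiv2 <- intdiv(fps_g, 2)
    report$frag <- frag_similarity(okg, reference, as_distance)
    report$scaff <- scaff_similarity(okg, reference, as_distance)
    report$fcd <- if (nrow(okg) >= 2 && nrow(reference) >= 2) {
      fcd(activation_stats(okg, provider),
          activation_stats(reference, provider))
    } else NA_real_
  } else {
    report[c("snn", "intdiv1", "intdiv2", "frag", "scaff", "fcd")] <-
      NA_real_
  }
  report$direction <- direction
  report$activation_provider <- "descriptor-surrogate (non-canonical FCD)"
  class(report) <- "metric_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    num <- vapply(report, is.numeric, logical(1))
    utils::write.csv(
      data.frame(metric = names(report)[num],
                 value = unlist(report[num], use.names = FALSE)),
      file.path(out_dir, "report.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(source = sources$canonical,
                 generated = ifelse(gen$valid, gen$canonical, NA),
                 tanimoto = tanimoto_profile(sources, gen)),
      file.path(out_dir, "tanimoto_pairs.csv"), row.names = FALSE)
    if (nrow(okg) > 0) {
      utils::write.csv(property_profile(okg)$per_molecule,
                       file.path(out_dir, "properties.csv"),
                       row.names = FALSE)
    }
  }
  report
}
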