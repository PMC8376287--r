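#' Parse SMILES into molecule records
#'
#' Each input string is parsed and, when chemically sane, annotated with its
#' canonical SMILES, the four pharmacophore feature counts used for domain
#' construction (aliphatic rings, aromatic rings, hydrogen-bond acceptors
#' and donors), the charged-atom flag, and the physicochemical properties
#' MW, logP and the synthetic-accessibility (SA) score.
#'
#' Ring counts are taken over the smallest set of smallest rings; a ring is
#' aromatic iff every one of its bonds is aromatic, aliphatic otherwise.
#' HBA counts N/O acceptors and HBD counts N-H/O-H groups (each heteroatom
#' once), both under the Lipinski descriptor convention.
#'
#' Parsing never raises on malformed input: invalid strings yield records
#' with `valid = FALSE` and `NA` annotation fields.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A `molecule_set`: a data frame with one row per input and columns
#'   `raw`, `valid`, `canonical`, `n_aliphatic_rings`, `n_aromatic_rings`,
#'   `n_hba`, `n_hbd`, `has_charged_atom`, `mw`, `logp`, `sa`.
#' @examples
#' \dontrun{
#' parse_molecules(c("CCO", "c1ccccc1", "C1CC"))
#' }
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  res <- if (n > 0) chem_call("parse", smiles) else list()
  num <- function(field) {
    vapply(res, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  lgl <- function(field) {
    vapply(res, function(r) {
      v <- r[[field]]
      if (is.null(v)) NA else as.logical(v)
    }, logical(1))
  }
  out <- data.frame(
    raw = as.character(smiles),
    valid = if (n > 0) lgl("valid") else logical(0),
    canonical = vapply(res, function(r)
      if (is.null(r$canonical)) NA_character_ else r$canonical, character(1)),
    n_aliphatic_rings = as.integer(num("n_aliphatic_rings")),
    n_aromatic_rings = as.integer(num("n_aromatic_rings")),
    n_hba = as.integer(num("n_hba")),
    n_hbd = as.integer(num("n_hbd")),
    has_charged_atom = lgl("has_charged_atom"),
    mw = num("mw"),
    logp = num("logp"),
    sa = num("sa"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("molecule_set", "data.frame")
  out
}

#' Parse a single molecule
#'
#' @param raw A single SMILES string.
#' @return A one-row `molecule_set` (see [parse_molecules()]).
#' @export
parse_molecule <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1, nzchar(raw))
  parse_molecules(raw)
}

#' Recompute pharmacophore feature counts for valid records
#'
#' Re-derives the four feature counts (and property fields) from each
#' record's canonical form. All records must be valid; passing invalid
#' records is a contract violation.
#'
#' @param rec A `molecule_set`.
#' @return `rec` with count columns repopulated.
#' @export
count_features <- function(rec) {
  stopifnot(inherits(rec, "molecule_set"))
  if (nrow(rec) == 0) return(rec)
  if (any(!rec$valid)) {
    stop("count_features() requires valid records; found ",
         sum(!rec$valid), " invalid.", call. = FALSE)
  }
  fresh <- parse_molecules(rec$canonical)
  cols <- c("n_aliphatic_rings", "n_aromatic_rings", "n_hba", "n_hbd",
            "has_charged_atom", "mw", "logp", "sa")
  rec[cols] <- fresh[cols]
  rec
}

#' Charged-atom filter
#'
#' Returns `TRUE` for molecules with no atom carrying nonzero formal
#' charge; this is the dataset-construction filter applied before domain
#' assignment.
#'
#' @param rec A `molecule_set` of valid records.
#' @return Logical vector, one element per record.
#' @export
passes_filters <- function(rec) {
  stopifnot(inherits(rec, "molecule_set"))
  if (any(!rec$valid)) {
    stop("passes_filters() requires valid records.", call. = FALSE)
  }
  !rec$has_charged_atom
}

.feature_levels <- c("aliphatic_rings", "aromatic_rings", "hba", "hbd")

.feature_column <- function(feature) {
  feature <- match.arg(feature, .feature_levels)
  c(aliphatic_rings = "n_aliphatic_rings",
    aromatic_rings = "n_aromatic_rings",
    hba = "n_hba", hbd = "n_hbd")[[feature]]
}

#' Domain specification for a structural-transformation task
#'
#' A `domain_spec` names a pharmacophore feature and the disjoint count
#' sets defining the source domain X and the target domain Y. Called with
#' only `feature`, the four preset tasks are returned:
#' \itemize{
#'   \item aliphatic_rings: X = \{1\}, Y = \{2, 3\}
#'   \item aromatic_rings: X = \{2\}, Y = \{1, 3, 4\}
#'   \item hba: X = \{1\}, Y = \{2, 3\}
#'   \item hbd: X = \{1\}, Y = \{2, 3, 4\}
#' }
#'
#' @param feature One of `"aliphatic_rings"`, `"aromatic_rings"`, `"hba"`,
#'   `"hbd"`.
#' @param x_counts,y_counts Optional non-empty disjoint sets of
#'   non-negative integers overriding the preset.
#' @return A `domain_spec` list with elements `feature`, `x_counts`,
#'   `y_counts`.
#' @export
domain_spec <- function(feature, x_counts = NULL, y_counts = NULL) {
  feature <- match.arg(feature, .feature_levels)
  presets <- list(
    aliphatic_rings = list(x = 1L, y = c(2L, 3L)),
    aromatic_rings = list(x = 2L, y = c(1L, 3L, 4L)),
    hba = list(x = 1L, y = c(2L, 3L)),
    hbd = list(x = 1L, y = c(2L, 3L, 4L))
  )
  if (is.null(x_counts)) x_counts <- presets[[feature]]$x
  if (is.null(y_counts)) y_counts <- presets[[feature]]$y
  x_counts <- sort(unique(as.integer(x_counts)))
  y_counts <- sort(unique(as.integer(y_counts)))
  if (length(x_counts) == 0 || length(y_counts) == 0) {
    stop("x_counts and y_counts must be non-empty.", call. = FALSE)
  }
  if (any(x_counts < 0) || any(y_counts < 0)) {
    stop("Feature counts must be non-negative.", call. = FALSE)
  }
  if (length(intersect(x_counts, y_counts)) > 0) {
    stop("x_counts and y_counts must be disjoint.", call. = FALSE)
  }
  structure(list(feature = feature, x_counts = x_counts,
                 y_counts = y_counts),
            class = "domain_spec")
}

#' Partition a molecule corpus into X/Y train and test domains
#'
#' Valid records are de-duplicated by canonical SMILES (first occurrence
#' kept), charged molecules are excluded, and the remainder are assigned to
#' domain X or Y by their feature count under `spec`; molecules whose count
#' lies in neither set are excluded. Within each domain the training subset
#' is a uniform random sample of the requested size drawn with `seed`; the
#' test subset is the remainder. The whole procedure is deterministic given
#' the input order, spec, sizes and seed.
#'
#' @param mols A `molecule_set`. Invalid records are dropped with a
#'   warning.
#' @param spec A [domain_spec()].
#' @param train_sizes Integer pair `c(n_x_train, n_y_train)`.
#' @param seed Integer seed for the train/test draw.
#' @return A `domain_split` with `molecule_set` elements `x_train`,
#'   `x_test`, `y_train`, `y_test`, `excluded`, plus `spec`, `train_sizes`
#'   and `seed`.
#' @export
split_domains <- function(mols, spec, train_sizes, seed) {
  stopifnot(inherits(mols, "molecule_set"), inherits(spec, "domain_spec"),
            length(train_sizes) == 2)
  train_sizes <- as.integer(train_sizes)
  stopifnot(!anyNA(train_sizes), all(train_sizes >= 0))
  seed <- as.integer(seed)

  if (any(!mols$valid)) {
    warning(sum(!mols$valid), " invalid record(s) dropped before domain ",
            "assignment.", call. = FALSE)
    mols <- mols[mols$valid, , drop = FALSE]
  }
  mols <- mols[!duplicated(mols$canonical), , drop = FALSE]

  counts <- mols[[.feature_column(spec$feature)]]
  charged <- mols$has_charged_atom
  in_x <- !charged & counts %in% spec$x_counts
  in_y <- !charged & counts %in% spec$y_counts

  xpool <- mols[in_x, , drop = FALSE]
  ypool <- mols[in_y, , drop = FALSE]
  excluded <- mols[!in_x & !in_y, , drop = FALSE]

  if (train_sizes[1] > nrow(xpool)) {
    stop("Requested X train size ", train_sizes[1], " exceeds the ",
         nrow(xpool), " eligible X-domain molecule(s).", call. = FALSE)
  }
  if (train_sizes[2] > nrow(ypool)) {
    stop("Requested Y train size ", train_sizes[2], " exceeds the ",
         nrow(ypool), " eligible Y-domain molecule(s).", call. = FALSE)
  }

  pick <- with_seed(seed, {
    ix <- sort(sample.int(nrow(xpool), train_sizes[1]))
    iy <- sort(sample.int(nrow(ypool), train_sizes[2]))
    list(ix = ix, iy = iy)
  })

  take <- function(df, idx, invert = FALSE) {
    keep <- if (invert) setdiff(seq_len(nrow(df)), idx) else idx
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("molecule_set", "data.frame")
    out
  }

  structure(list(
    x_train = take(xpool, pick$ix),
    x_test = take(xpool, pick$ix, invert = TRUE),
    y_train = take(ypool, pick$iy),
    y_test = take(ypool, pick$iy, invert = TRUE),
    excluded = take(excluded, seq_len(nrow(excluded))),
    spec = spec, train_sizes = train_sizes, seed = seed
  ), class = "domain_split")
}

#' Frequency histogram of a feature count
#'
#' @param mols A `molecule_set` of valid records.
#' @param feature Feature name (see [domain_spec()]).
#' @return Data frame with columns `count` and `frequency`; counts absent
#'   from the input are omitted. Frequencies sum to `nrow(mols)`.
#' @export
feature_histogram <- function(mols, feature) {
  stopifnot(inherits(mols, "molecule_set"))
  if (any(!mols$valid)) {
    stop("feature_histogram() requires valid records.", call. = FALSE)
  }
  counts <- mols[[.feature_column(feature)]]
  if (length(counts) == 0) {
    return(data.frame(count = integer(0), frequency = integer(0)))
  }
  tab <- table(counts)
  data.frame(count = as.integer(names(tab)),
             frequency = as.integer(tab))
}

#' Read a SMILES line file
#'
#' Format: one record per line, `SMILES[<tab>ID]`; blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path File path.
#' @return Character vector of SMILES, named by ID where one was present.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "",
                character(1))
  names(smi) <- ifelse(nzchar(ids), ids, NA_character_)
  smi
}

#' Write molecules to a SMILES line file
#'
#' @param x A `molecule_set` (canonical SMILES are written) or a character
#'   vector; names, when present, are written as tab-separated IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(x, path) {
  if (inherits(x, "molecule_set")) {
    x <- ifelse(x$valid, x$canonical, x$raw)
  }
  ids <- names(x)
  lines <- if (is.null(ids)) {
    as.character(x)
  } else {
    ifelse(is.na(ids) | !nzchar(ids), as.character(x),
           paste(x, ids, sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a domain split to disk
#'
#' Emits `x_train.smi`, `x_test.smi`, `y_train.smi`, `y_test.smi`,
#' `excluded.smi` and `split_manifest.json` (spec, sizes, seed, bin
#' counts) into `dir`.
#'
#' @param split A [split_domains()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "domain_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- c("x_train", "x_test", "y_train", "y_test", "excluded")
  for (b in bins) {
    write_smiles(split[[b]], file.path(dir, paste0(b, ".smi")))
  }
  manifest <- list(
    feature = split$spec$feature,
    x_counts = split$spec$x_counts,
    y_counts = split$spec$y_counts,
    train_sizes = split$train_sizes,
    seed = split$seed,
    counts = as.list(stats::setNames(
      vapply(bins, function(b) nrow(split[[b]]), integer(1)), bins))
  )
  jsonlite::write_json(manifest, file.path(dir, "split_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a feature histogram as CSV
#'
#' @param hist A [feature_histogram()] result.
#' @param path Output path (`count,frequency` header).
#' @return `path`, invisibly.
#' @export
write_feature_histogram <- function(hist, path) {
  utils::write.csv(hist, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do
#' not disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
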