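#' @title RDKit bridge
#' @description Internal batch interface to the bundled Python chemistry
#'   helper. All chemistry (parsing, fingerprints, fragments, scaffolds,
#'   descriptor panels) flows through [chem_call()]; results are memoised
#'   per session so repeated queries for the same molecules cost one
#'   interpreter launch in total.
#' @name chem-bridge
#' @keywords internal
NULL

.chem_cache <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for chemistry
#'
#' Resolution order: the `cyclemol.python` option, the `CYCLEMOL_PYTHON`
#' environment variable, then `python` on the PATH. The interpreter must
#' have `rdkit` importable.
#'
#' @return Path to the interpreter.
#' @keywords internal
chem_python <- function() {
  p <- getOption("cyclemol.python", "")
  if (!nzchar(p)) p <- Sys.getenv("CYCLEMOL_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) {
    stop("No Python interpreter found; set options(cyclemol.python=...) ",
         "or put 'python' (with rdkit) on the PATH.", call. = FALSE)
  }
  unname(p)
}

chem_helper <- function() {
  path <- system.file("python", "chem_helper.py", package = "cyclemol")
  if (!nzchar(path) || !file.exists(path)) {
    stop("chem_helper.py not found in the installed package.", call. = FALSE)
  }
  path
}

#' Call the chemistry helper for a batch of SMILES
#'
#' @param op One of "parse", "fingerprints", "fragments", "scaffolds",
#'   "descriptors", "ping".
#' @param smiles Character vector (positional; may be empty).
#' @param ... Extra scalar options forwarded to the helper (e.g. `radius`,
#'   `nbits`).
#' @return The helper's `result` element, positionally aligned with
#'   `smiles`; parse failures are `NULL` entries (or `valid = FALSE`
#'   records for `op = "parse"`).
#' @keywords internal
chem_call <- function(op, smiles = character(), ...) {
  opts <- list(...)
  key <- paste(op,
               paste(vapply(opts, as.character, ""), collapse = ","),
               paste(smiles, collapse = "\x01"), sep = "\x02")
  hit <- get0(key, envir = .chem_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  req <- c(list(op = op, smiles = as.list(smiles)), opts)
  req_path <- tempfile(fileext = ".json")
  resp_path <- tempfile(fileext = ".json")
  on.exit(unlink(c(req_path, resp_path)), add = TRUE)
  jsonlite::write_json(req, req_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  err <- tempfile(fileext = ".log")
  status <- suppressWarnings(
    system2(chem_python(), c(shQuote(chem_helper()), shQuote(req_path),
                             shQuote(resp_path)),
            stdout = FALSE, stderr = err))
  if (!identical(status, 0L) || !file.exists(resp_path)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("Chemistry helper failed (op='", op, "', status=", status, "):\n",
         msg, call. = FALSE)
  }
  resp <- jsonlite::read_json(resp_path)
  out <- resp$result
  assign(key, out, envir = .chem_cache)
  out
}

#' Is the RDKit bridge operational?
#'
#' @return `TRUE` if the helper responds to a ping, else `FALSE`.
#' @export
chem_available <- function() {
  ok <- tryCatch(isTRUE(chem_call("ping")$ok), error = function(e) FALSE)
  ok
}

#' Names of the surrogate activation descriptors, in panel order.
#' @keywords internal
chem_descriptor_names <- function() {
  c("mw", "logp", "tpsa", "hba", "hbd", "rot",
    "rings", "arom_rings", "fcsp3", "heavy")
}
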