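## Subprocess bridge to the bundled RDKit helper.  Every chemistry call in
## the package funnels through rdkitBridge(); calls are batched over vectors
## of SMILES so the interpreter start-up cost is amortized.  All RNG
## decisions are made in R; the helper only receives explicit integer seeds.

.pythonBinary <- function() {
  py <- getOption("smilesaugment.python", "")
  if (!nzchar(py)) py <- Sys.getenv("SMILESAUGMENT_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no Python interpreter found; install one with rdkit and/or set ",
         "options(smilesaugment.python = ...)", call. = FALSE)
  }
  py
}

.bridgeScript <- function() {
  script <- system.file("python", "rdkit_bridge.py", package = "smilesaugment")
  if (!nzchar(script)) {
    stop("rdkit_bridge.py not found in the installed package", call. = FALSE)
  }
  script
}

#' Call the bundled RDKit helper
#'
#' Internal workhorse: serializes a request to JSON, runs the helper script,
#' and parses the JSON response.  Ragged list fields in `payload` must be
#' wrapped with [I()] element-wise by the caller so length-one vectors stay
#' JSON arrays.
#'
#' @param op Operation name understood by `inst/python/rdkit_bridge.py`.
#' @param payload Named list of operation arguments.
#' @return Parsed response as an R list.
#' @keywords internal
#' @noRd
rdkitBridge <- function(op, payload = list()) {
  payload$op <- op
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(payload, req, auto_unbox = TRUE, digits = NA,
                       null = "null")
  err <- tempfile(fileext = ".log")
  on.exit(unlink(err), add = TRUE)
  status <- system2(.pythonBinary(), c(shQuote(.bridgeScript()), shQuote(req),
                                       shQuote(res)),
                    stdout = FALSE, stderr = err)
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("RDKit bridge call '", op, "' failed (exit ", status, "):\n", msg,
         call. = FALSE)
  }
  jsonlite::fromJSON(res, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

## Wrap each element of a list so write_json keeps length-one vectors as
## arrays (the helper iterates over them).
.asJsonArrays <- function(x) lapply(x, I)
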