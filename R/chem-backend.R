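# Chemistry backend: a persistent RDKit worker process.
#
# All parsing, canonicalization, descriptor and fingerprint work is delegated
# to one Python/RDKit subprocess per R session, spoken to over a localhost
# socket with a JSON-line protocol (one request object per line, one response
# per line).  Results for pure functions of a SMILES string are memoized on
# the R side, which matters inside the search loop where the same product
# molecule is often proposed many times.

.molsculpt <- new.env(parent = emptyenv())

.chem_python <- function() {
  getOption("molsculpt.python",
            if (nzchar(Sys.getenv("MOLSCULPT_PYTHON"))) Sys.getenv("MOLSCULPT_PYTHON")
            else "python")
}

.chem_worker_script <- function() {
  p <- system.file("python", "chem_worker.py", package = "molsculpt")
  if (!nzchar(p)) stop("chem_worker.py not found; is molsculpt installed?")
  p
}

.chem_start <- function() {
  python <- .chem_python()
  script <- .chem_worker_script()
  logfile <- tempfile("molsculpt-chem-worker-", fileext = ".log")
  con <- NULL
  # deterministic port probing: must not touch the session RNG, since the
  # worker may be started lazily inside seeded code
  base_port <- 20000L + (as.integer(Sys.getpid()) * 7919L) %% 40000L
  for (attempt in 1:20) {
    port <- 20000L + (base_port - 20000L + attempt * 1031L) %% 40000L
    srv <- tryCatch(serverSocket(port), error = function(e) NULL)
    if (is.null(srv)) next
    system2(python, c(shQuote(script), port), wait = FALSE,
            stdout = logfile, stderr = logfile)
    con <- tryCatch(socketAccept(srv, blocking = TRUE, open = "r+",
                                 timeout = 120),
                    error = function(e) NULL)
    close(srv)
    if (!is.null(con)) break
  }
  if (is.null(con)) {
    stop("could not start the RDKit worker (python executable: '", python,
         "'); see log at ", logfile)
  }
  .molsculpt$chem_con <- con
  .molsculpt$chem_id <- 0L
  .molsculpt$cache <- new.env(parent = emptyenv(), hash = TRUE)
  # fail fast if rdkit is missing on the python side
  ok <- tryCatch(identical(.chem_call("ping"), "pong"), error = function(e) FALSE)
  if (!ok) {
    .chem_stop()
    stop("RDKit worker failed its handshake; see log at ", logfile)
  }
  invisible(con)
}

.chem_con <- function() {
  con <- .molsculpt$chem_con
  if (is.null(con) || !isOpen(con)) .chem_start() else con
  .molsculpt$chem_con
}

.chem_stop <- function() {
  con <- .molsculpt$chem_con
  if (!is.null(con)) {
    tryCatch({
      writeLines('{"cmd": "shutdown"}', con)
      flush(con)
      close(con)
    }, error = function(e) NULL)
  }
  .molsculpt$chem_con <- NULL
  invisible(NULL)
}

.chem_call <- function(cmd, args = NULL) {
  con <- .chem_con()
  .molsculpt$chem_id <- .molsculpt$chem_id + 1L
  req <- list(id = .molsculpt$chem_id, cmd = cmd)
  if (!is.null(args)) req$args <- args
  writeLines(jsonlite::toJSON(req, auto_unbox = TRUE, null = "null",
                              digits = NA), con)
  flush(con)
  line <- readLines(con, n = 1L)
  if (length(line) == 0L) {
    .chem_stop()
    stop("RDKit worker terminated unexpectedly during command '", cmd, "'")
  }
  res <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!isTRUE(res$ok)) stop("RDKit worker error: ", res$error)
  res$result
}

# Batched, memoized per-SMILES call.  `wrap` post-processes one worker result
# (which may be NULL for unparseable input).
.chem_batch <- function(cmd, smiles, wrap = identity, key = cmd) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(list())
  cache <- .molsculpt$cache
  if (is.null(cache)) { .chem_con(); cache <- .molsculpt$cache }
  keys <- paste0(key, "\r", smiles)
  out <- vector("list", length(smiles))
  hit <- vapply(keys, exists, logical(1), envir = cache, USE.NAMES = FALSE)
  if (any(hit)) out[hit] <- mget(keys[hit], envir = cache)
  miss <- which(!hit)
  if (length(miss)) {
    uq <- !duplicated(smiles[miss])
    ask <- smiles[miss][uq]
    res <- .chem_call(cmd, list(smiles = as.list(ask)))
    res <- lapply(res, wrap)
    names(res) <- paste0(key, "\r", ask)
    for (nm in names(res)) assign(nm, res[[nm]], envir = cache)
    out[miss] <- res[match(keys[miss], names(res))]
  }
  out
}

.null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Test whether SMILES strings parse as molecules
#'
#' Validity in the sense used for the generator's validity rate: a string is
#' valid iff the RDKit parser accepts it as a molecule.  Any parser failure
#' maps to `FALSE`; the function never throws on malformed input.
#'
#' @param smiles Character vector of candidate SMILES strings.
#' @return Logical vector the same length as `smiles`.
#' @examples \dontrun{
#' is_valid_smiles(c("CCO", "C(", "c1ccccc1"))
#' }
#' @export
is_valid_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(logical(0))
  bad <- is.na(smiles)
  smiles[bad] <- ""
  res <- .chem_batch("valid", as.character(smiles),
                     wrap = function(x) isTRUE(x))
  out <- vapply(res, identity, logical(1))
  out[bad] <- FALSE
  out
}

#' Canonical SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of RDKit canonical SMILES; `NA` where the input
#'   does not parse.
#' @export
canonical_smiles <- function(smiles) {
  res <- .chem_batch("canonical", as.character(smiles),
                     wrap = function(x) if (is.null(x)) NA_character_ else x)
  vapply(res, identity, character(1))
}

# -- internal descriptor accessors (NA / NULL for unparseable input) ---------

.chem_qed <- function(smiles) {
  vapply(.chem_batch("qed", smiles, wrap = .null2na), identity, numeric(1))
}

.chem_logp <- function(smiles) {
  vapply(.chem_batch("logp", smiles, wrap = .null2na), identity, numeric(1))
}

.chem_sa <- function(smiles) {
  vapply(.chem_batch("sa", smiles, wrap = .null2na), identity, numeric(1))
}

.chem_ring_sizes <- function(smiles) {
  .chem_batch("ring_sizes", smiles,
              wrap = function(x) if (is.null(x)) NULL else as.integer(unlist(x)))
}

.chem_morgan_bits <- function(smiles) {
  .chem_batch("morgan_bits", smiles,
              wrap = function(x) if (is.null(x)) NULL else as.integer(unlist(x)))
}

#' Stop the background RDKit worker
#'
#' The worker is started lazily on first use and normally lives for the whole
#' R session; this releases it explicitly (a new one starts on demand).
#'
#' @return Invisibly, `NULL`.
#' @export
chem_backend_stop <- function() .chem_stop()

.onUnload <- function(libpath) {
  .chem_stop()
}
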