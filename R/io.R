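# File formats: .smi lists, generation-record CSVs, and the YAML run
# configuration.

#' Read a .smi file
#'
#' One molecule per line: a SMILES string, optionally followed by
#' whitespace and an identifier.  Blank lines and lines starting with `#`
#' are skipped (counted in the `skipped` attribute); order is preserved.
#'
#' @param path File path.
#' @return Data frame with columns `smiles` and `id` (`NA` when absent) and
#'   attribute `skipped` (number of blank/comment lines).
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  skip <- trimmed == "" | startsWith(trimmed, "#")
  keep <- trimmed[!skip]
  parts <- strsplit(keep, "[ \t]+")
  out <- data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- sum(skip)
  out
}

#' Write a .smi file
#'
#' @param smiles Character vector of SMILES.
#' @param path Output path.
#' @param ids Optional identifiers (tab-separated second column).
#' @return Invisibly, `path`.
#' @export
write_smiles_file <- function(smiles, path, ids = NULL) {
  lines <- if (is.null(ids)) smiles else paste(smiles, ids, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write / load generation records
#'
#' CSV round trip for the per-step record table of an [run_search()] run;
#' all fields, including the `NA` score fields of invalid molecules, are
#' preserved exactly.
#'
#' @param records Records data frame (or an `"mcts_run"`).
#' @param path File path.
#' @return `write_records` returns `path` invisibly; `load_records` the
#'   data frame.
#' @export
write_records <- function(records, path) {
  records <- as.data.frame(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
load_records <- function(path) {
  cls <- c(step = "integer", cycle = "integer",
           replacement_start = "integer", replacement_length = "integer",
           fragment = "character", smiles = "character", valid = "logical",
           raw_score = "numeric", normalized_reward = "numeric",
           similarity_to_seed = "numeric")
  out <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA,
                         na.strings = "")
  for (nm in intersect(names(cls), names(out))) {
    out[[nm]] <- switch(cls[[nm]],
                        integer = as.integer(out[[nm]]),
                        numeric = as.numeric(out[[nm]]),
                        logical = as.logical(out[[nm]]),
                        character = {
                          v <- as.character(out[[nm]])
                          v[is.na(v)] <- ""  # empty fragment round trip
                          v
                        })
  }
  out
}

#' Download a reference SMILES corpus
#'
#' Optional convenience for fetching a large public corpus (e.g. a ZINC
#' 250k export) to use in place of the fixture generator.  Nothing in the
#' package or its tests requires network access or this helper.
#'
#' @param url Source URL of a plain-text SMILES list (one per line; a CSV
#'   with a `smiles` column also works if `csv_column` is given).
#' @param dest Destination .smi path.
#' @param csv_column Optional column name when the source is a CSV.
#' @return Invisibly, `dest`.
#' @export
fetch_reference_corpus <- function(url, dest, csv_column = NULL) {
  tmp <- tempfile()
  utils::download.file(url, tmp, quiet = TRUE)
  if (!is.null(csv_column)) {
    smi <- utils::read.csv(tmp, stringsAsFactors = FALSE)[[csv_column]]
    write_smiles_file(smi, dest)
  } else {
    file.copy(tmp, dest, overwrite = TRUE)
  }
  unlink(tmp)
  invisible(dest)
}

# ---- run configuration -----------------------------------------------------

.config_defaults <- function() {
  list(
    config_version = 1L,
    score = "qed",            # qed | plogp | constrained_plogp
    mode = "single",          # single | multi
    steps = 10000L,
    cycle_interval = 2000L,
    delta = 0.4,              # constrained similarity threshold
    c_p = 1 / sqrt(2),
    expansion_samples = 10L,
    max_fragment_len = 35L,
    invalid_reward = 0,
    max_removal_len = 10L,
    max_partial_len = 35L,    # fragment-extraction cap for dataset building
    epochs = 20L,
    hidden_size = 256L,
    learning_rate = 1e-3,
    batch_size = 128L,
    seed = 0L
  )
}

#' Run configuration
#'
#' All tunable parameters of dataset building, policy training and search,
#' each with a documented default (see the YAML written by
#' [write_run_config()]).  Unknown fields are rejected.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The file must carry `config_version: 1`; unknown keys are an error
#' (fail-fast), and the round trip `read_run_config(write_run_config(x))`
#' is lossless.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$config_version)) stop("missing config_version in ", path)
  if (raw$config_version != 1L) {
    stop("unsupported config_version ", raw$config_version)
  }
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration field(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw[setdiff(names(raw), "config_version")])
}

# search_config slice of a run_config
as_search_config <- function(cfg) {
  search_config(c_p = cfg$c_p, expansion_samples = cfg$expansion_samples,
                max_fragment_len = cfg$max_fragment_len,
                invalid_reward = cfg$invalid_reward,
                max_removal_len = cfg$max_removal_len,
                cycle_interval = cfg$cycle_interval)
}
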