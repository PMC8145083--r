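#' Pipeline configuration
#'
#' All tunables with their defaults: `window` (slice size in Q&A pairs, 7),
#' `d` (TextRank damping, 0.78), `tau` (semantic-match threshold, 0.6), `r`
#' (pruning context radius, 1), `K` (candidate paths per slice, 100),
#' `min_len` (minimum path length in words, 8), `alpha` and `iterations`
#' (retrofitting, 1 and 10), `log_floor` (LM floor log10 probability, -10),
#' `es_fraction` (AoES prefilter fraction, 0.5), `textrank_tol` (1e-6),
#' `textrank_max_iter` (100), `seed`, and `completion_map`.
#'
#' @param ... Overrides of the defaults; unknown keys are rejected.
#' @return Validated named list of class `kias_config`.
#' @export
kias_config <- function(...) {
  defaults <- list(window = 7L, d = 0.78, tau = 0.6, r = 1L, K = 100L,
                   min_len = 8L, alpha = 1, iterations = 10L,
                   log_floor = -10, es_fraction = 0.5,
                   textrank_tol = 1e-6, textrank_max_iter = 100L,
                   seed = 1L, completion_map = character())
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    kias_abort(sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")),
               "kias_validation_error")
  }
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = c("kias_config", "list"))
}

validate_config <- function(cfg) {
  chk <- function(ok, what) {
    if (!ok) kias_abort(sprintf("invalid config: %s", what),
                        "kias_validation_error")
  }
  chk(is.numeric(cfg$window) && cfg$window >= 1, "window must be >= 1")
  chk(is.numeric(cfg$d) && cfg$d > 0 && cfg$d < 1, "d must be in (0,1)")
  chk(is.numeric(cfg$tau) && cfg$tau > 0 && cfg$tau <= 1, "tau must be in (0,1]")
  chk(is.numeric(cfg$r) && cfg$r >= 0, "r must be >= 0")
  chk(is.numeric(cfg$K) && cfg$K >= 1, "K must be >= 1")
  chk(is.numeric(cfg$min_len) && cfg$min_len >= 1, "min_len must be >= 1")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0, "alpha must be > 0")
  chk(is.numeric(cfg$iterations) && cfg$iterations >= 1, "iterations must be >= 1")
  chk(is.numeric(cfg$log_floor) && cfg$log_floor < 0, "log_floor must be < 0")
  chk(is.numeric(cfg$es_fraction) && cfg$es_fraction > 0 && cfg$es_fraction <= 1,
      "es_fraction must be in (0,1]")
  invisible(cfg)
}

#' Load a configuration from YAML or JSON
#' @param path Config file (.yaml/.yml or .json).
#' @return A `kias_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) kias_abort(sprintf("config file not found: %s", path),
                                     "kias_io_error")
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(kias_config, as.list(vals))
}

#' Write a run manifest
#'
#' Records the effective configuration, the package version, input file
#' hashes, and the seed, so any run is reproducible from its manifest.
#'
#' @param config A `kias_config`.
#' @param out_dir Output directory (created if needed).
#' @param inputs Named character vector of input file paths to hash.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(config, out_dir, inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hashes <- vapply(inputs, function(p) {
    if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_
  }, character(1L))
  manifest <- list(
    package = "kias",
    version = as.character(utils::packageVersion("kias")),
    config = unclass(config)[setdiff(names(config), "completion_map")],
    inputs = as.list(hashes),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
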