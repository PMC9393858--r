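# configuration files, result tables and run metadata

.config_schema <- list(
  mode = list(type = "character", choices = c("liquid", "solid")),
  phase = list(type = "character", choices = c("liquid", "fcc_solid")),
  temperature = list(type = "numeric", positive = TRUE),
  reservoir_density = list(type = "numeric", positive = TRUE, default = 1),
  radius = list(type = "numeric", positive = TRUE),
  spacing = list(type = "numeric", positive = TRUE),
  pressure = list(type = "numeric"),
  cutoff = list(type = "numeric", positive = TRUE, default = 4.75),
  n_particles = list(type = "numeric", positive = TRUE),
  window = list(type = "list"),
  moves = list(type = "numeric", positive = TRUE),
  sweeps = list(type = "numeric", positive = TRUE),
  equil = list(type = "numeric"),
  max_displacement = list(type = "numeric", positive = TRUE, default = 0.2),
  seed = list(type = "numeric", required = TRUE),
  bias_file = list(type = "character"),
  lv_curve = list(type = "character"),
  out_dir = list(type = "character"))

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, checks types and
#' positivity, and fills defaults (`reservoir_density = 1`,
#' `cutoff = 4.75`, `max_displacement = 0.2`). A `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  errors <- character(0)
  for (key in names(.config_schema)) {
    rule <- .config_schema[[key]]
    if (!key %in% names(cfg)) {
      if (isTRUE(rule$required))
        errors <- c(errors, sprintf("missing required field '%s'", key))
      else if (!is.null(rule$default)) cfg[[key]] <- rule$default
      next
    }
    val <- cfg[[key]]
    ok_type <- switch(rule$type,
                      numeric = is.numeric(val),
                      character = is.character(val),
                      list = is.list(val))
    if (!ok_type) {
      errors <- c(errors, sprintf("field '%s' must be %s", key, rule$type))
      next
    }
    if (isTRUE(rule$positive) && any(val <= 0))
      errors <- c(errors, sprintf("field '%s' must be positive", key))
    if (!is.null(rule$choices) && !val %in% rule$choices)
      errors <- c(errors, sprintf("field '%s' must be one of: %s", key,
                                  paste(rule$choices, collapse = ", ")))
  }
  if (!is.null(cfg$window)) {
    w <- cfg$window
    if (!all(c("n_min", "n_max") %in% names(w)) ||
        !is.numeric(w$n_min) || !is.numeric(w$n_max) ||
        w$n_min < 1 || w$n_min > w$n_max)
      errors <- c(errors, "field 'window' needs 1 <= n_min <= n_max")
  }
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param config A `run_config` (or plain named list).
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a size histogram as TSV
#'
#' Long format with columns `n`, `block_id`, `count`.
#'
#' @param hist A [size_histogram()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_histogram_tsv <- function(hist, path) {
  nb <- ncol(hist$counts)
  d <- data.frame(n = rep(hist$n, nb),
                  block_id = rep(seq_len(nb), each = length(hist$n)),
                  count = as.vector(hist$counts))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_tsv
#' @export
read_histogram_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- sort(unique(d$n))
  blocks <- sort(unique(d$block_id))
  counts <- matrix(0, length(n), length(blocks))
  counts[cbind(match(d$n, n), match(d$block_id, blocks))] <- d$count
  size_histogram(n, counts)
}

#' Write a free-energy increment series as TSV
#'
#' Columns `n`, `x`, `dG`, `err`.
#'
#' @param series A `delta_g_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_series_tsv <- function(series, path) {
  d <- data.frame(n = series$n, x = series$x, dG = series$ddg,
                  err = series$se)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  out <- data.frame(n = d$n, x = d$x, ddg = d$dG, se = d$err)
  class(out) <- c("delta_g_series", "data.frame")
  out
}

#' Write / read a bias potential as TSV
#'
#' Columns `n`, `eta`.
#'
#' @param bias A [bias_potential()].
#' @param path File path.
#' @return Invisibly, `path` (write) or a [bias_potential()] (read).
#' @export
write_bias_tsv <- function(bias, path) {
  utils::write.table(as.data.frame(bias), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bias_tsv
#' @export
read_bias_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  bias_potential(d$n, d$eta)
}

#' Write run outputs and reproduction metadata
#'
#' Writes the histogram TSV, acceptance statistics TSV and a JSON metadata
#' file carrying every parameter and the seed needed to reproduce the run
#' bit-identically.
#'
#' @param run Output of [run_gc_cluster()].
#' @param dir Output directory (created if needed).
#' @param parameters Named list of run parameters to embed.
#' @return Invisibly, the directory.
#' @export
write_run_results <- function(run, dir, parameters = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_histogram_tsv(run$histogram, file.path(dir, "histogram.tsv"))
  utils::write.table(run$stats, file.path(dir, "move_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(package = "avbmclj",
               version = as.character(utils::packageVersion("avbmclj")),
               seed = run$seed, parameters = parameters,
               audit = run$audit)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
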