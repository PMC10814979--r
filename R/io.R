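#' Read a time series from a plain-text file
#'
#' Accepts either one numeric value per line or a single comma-separated row.
#' Blank lines and lines starting with `#` are ignored. Decimal points only
#' (no locale commas); scientific notation is accepted.
#'
#' @param path Path to the file.
#' @return A numeric vector of length at least 2.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 1L && grepl(",", lines[keep])) {
    tokens <- strsplit(lines[keep], ",", fixed = TRUE)[[1L]]
    token_lines <- rep(keep, length(tokens))
  } else {
    tokens <- lines[keep]
    token_lines <- keep
  }
  tokens <- trimws(tokens)
  vals <- suppressWarnings(as.numeric(tokens))
  bad <- which(is.na(vals))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at line %d of %s",
                 tokens[bad[1L]], token_lines[bad[1L]], path), call. = FALSE)
  }
  if (length(vals) < 2L) {
    stop(sprintf("series in %s has %d samples; at least 2 required",
                 path, length(vals)), call. = FALSE)
  }
  if (!all(is.finite(vals))) {
    stop(sprintf("series in %s contains non-finite values", path), call. = FALSE)
  }
  vals
}

#' Write a time series to a plain-text file
#'
#' One sample per line, at full double precision so that
#' `read_series(write_series(x, path))` round-trips exactly.
#'
#' @param x Numeric series.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  check_series(x)
  writeLines(sprintf("%.17g", x), path)
  invisible(path)
}

#' Load a labelled dataset from a manifest
#'
#' The manifest is a CSV with columns `file` (path relative to the manifest's
#' directory) and `label` (0 or 1). Every referenced file must parse with
#' [read_series()], and both classes must be present.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A dataset tibble with columns `id`, `label`, `series`.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: %s", manifest_path), call. = FALSE)
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  if (!all(c("file", "label") %in% names(manifest))) {
    stop("manifest must have columns `file` and `label`", call. = FALSE)
  }
  if (!all(manifest$label %in% c(0, 1))) {
    stop(sprintf("manifest contains labels other than 0/1: %s",
                 paste(unique(setdiff(manifest$label, c(0, 1))), collapse = ", ")),
         call. = FALSE)
  }
  if (length(unique(manifest$label)) < 2L) {
    stop("manifest describes a single class; both labels 0 and 1 are required",
         call. = FALSE)
  }
  root <- dirname(manifest_path)
  paths <- file.path(root, manifest$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf("manifest references missing file(s): %s",
                 paste(manifest$file[missing], collapse = ", ")), call. = FALSE)
  }
  labeled_dataset(
    series = lapply(paths, read_series),
    labels = as.integer(manifest$label),
    ids = as.character(manifest$file),
    name = basename(dirname(manifest_path))
  )
}

#' Write a labelled dataset to per-series files plus a manifest
#'
#' Each series goes to its own plain-text file (via [write_series()]) and a
#' `manifest.csv` maps files to class labels, in the layout [load_dataset()]
#' reads back.
#'
#' @param data A dataset tibble.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(data, dir) {
  check_dataset(data)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.txt", gsub("[^A-Za-z0-9_.-]", "_", data$id))
  purrr::walk2(data$series, files, function(x, f) write_series(x, file.path(dir, f)))
  manifest <- tibble::tibble(file = files, label = data$label)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path, progress = FALSE)
  invisible(manifest_path)
}

#' Read a grid specification from a YAML file
#'
#' Understands keys `variant`, `m`, `gamma_pos`, `gamma_neg`, `delta` and
#' `constrain_delta`. Each numeric field may be a scalar, a list of values, or
#' a mapping with `from`/`to`/`by` describing a range. Omitted fields fall
#' back to the [grid_spec()] defaults; `delta: ~` (null) combined with an
#' asymmetric variant selects the delta-omitted grid.
#'
#' @param path Path to the YAML file.
#' @return A [grid_spec()].
#' @export
read_grid_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  expand <- function(field) {
    v <- raw[[field]]
    if (is.null(v)) return(NULL)
    if (is.list(v) && all(c("from", "to") %in% names(v))) {
      return(seq(v$from, v$to, by = if (is.null(v$by)) 0.05 else v$by))
    }
    unlist(v)
  }
  args <- list()
  if (!is.null(raw$variant)) args$variant <- raw$variant
  for (pair in list(c("m", "m_values"), c("gamma_pos", "gamma_pos_values"),
                    c("gamma_neg", "gamma_neg_values"), c("delta", "delta_values"))) {
    v <- expand(pair[1L])
    if (!is.null(v)) args[[pair[2L]]] <- v
  }
  if (!is.null(raw$constrain_delta)) args$constrain_delta <- raw$constrain_delta
  do.call(grid_spec, args)
}
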