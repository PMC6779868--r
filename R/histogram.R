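#' FCSS fluorescence histogram
#'
#' One seed sample's binned DNA-fluorescence distribution: ordered channel
#' centers (linear fluorescence units) and non-negative event counts, plus
#' the sample metadata the screen needs downstream (species, number of
#' seeds pooled, preparation protocol, optional internal standard).
#'
#' @param channels Strictly increasing numeric vector of bin centers.
#' @param counts Non-negative integer counts, same length as `channels`.
#' @param sample_id,species Sample identifiers.
#' @param seeds_pooled Number of seeds chopped into the sample (>= 1).
#' @param protocol `"seed_buffer"` (one-step) or `"two_step_otto"`.
#' @param standard_species,standard_2C_pg Internal standard identity and
#'   2C DNA amount in pg, when the sample was co-processed with a leaf
#'   standard (e.g. Pisum sativum 'Ctirad', 2C = 9.09 pg, or
#'   Bellis perennis, 2C = 3.38 pg).
#' @return An object of class `fcss_histogram`.
#' @export
fcss_histogram <- function(channels, counts,
                           sample_id = "sample",
                           species = NA_character_,
                           seeds_pooled = 1L,
                           protocol = c("seed_buffer", "two_step_otto"),
                           standard_species = NA_character_,
                           standard_2C_pg = NA_real_) {
  protocol <- match.arg(protocol)
  channels <- as.numeric(channels)
  counts <- as.numeric(counts)
  if (length(channels) != length(counts)) {
    stop("channels and counts must have equal length", call. = FALSE)
  }
  if (any(diff(channels) <= 0)) {
    stop("channels must be strictly increasing", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("histogram is empty", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (!is.na(standard_2C_pg) && standard_2C_pg <= 0) {
    stop("standard_2C_pg must be positive", call. = FALSE)
  }
  structure(list(channels = channels, counts = counts,
                 sample_id = sample_id, species = species,
                 seeds_pooled = as.integer(seeds_pooled),
                 protocol = protocol,
                 standard_species = standard_species,
                 standard_2C_pg = standard_2C_pg),
            class = "fcss_histogram")
}

#' @export
print.fcss_histogram <- function(x, ...) {
  cat(sprintf("FCSS histogram '%s' (%s): %d channels, %d events, protocol %s\n",
              x$sample_id,
              if (is.na(x$species)) "species unknown" else x$species,
              length(x$channels), sum(x$counts), x$protocol))
  if (!is.na(x$standard_species)) {
    cat(sprintf("  internal standard: %s (2C = %g pg)\n",
                x$standard_species, x$standard_2C_pg))
  }
  invisible(x)
}

#' Read / write histograms as two-column delimited text
#'
#' The on-disk format is a plain two-column whitespace- or tab-delimited
#' file (channel, count), optionally with a header line, plus an optional
#' sidecar metadata file of `key: value` lines (written as
#' `<path>.meta`). `write_histogram()` and `read_histogram()` round-trip.
#'
#' @param path Path to the histogram text file.
#' @param metadata Optional named list overriding metadata fields
#'   (`sample_id`, `species`, `seeds_pooled`, `protocol`,
#'   `standard_species`, `standard_2C_pg`); values from the sidecar file
#'   are used otherwise.
#' @return `read_histogram()`: an `fcss_histogram`.
#' @export
read_histogram <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty histogram file: ", path, call. = FALSE)
  first <- strsplit(trimws(lines[[1L]]), "[ \t,]+")[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  data_lines <- if (has_header) lines[-1L] else lines
  if (length(data_lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  offset <- if (has_header) 1L else 0L
  rows <- lapply(seq_along(data_lines), function(i) {
    parts <- strsplit(trimws(data_lines[[i]]), "[ \t,]+")[[1L]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) != 2L || anyNA(v)) {
      stop(sprintf("malformed row at line %d of %s: '%s'",
                   i + offset, path, data_lines[[i]]), call. = FALSE)
    }
    if (v[[2L]] < 0) {
      stop(sprintf("negative count at line %d of %s", i + offset, path),
           call. = FALSE)
    }
    v
  })
  mat <- do.call(rbind, rows)

  meta <- list(sample_id = sub("\\.[^.]*$", "", basename(path)))
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    for (ln in readLines(meta_path, warn = FALSE)) {
      if (!nzchar(trimws(ln))) next
      kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1L]]
      if (length(kv) == 3L) meta[[trimws(kv[[2L]])]] <- trimws(kv[[3L]])
    }
  }
  meta[names(metadata)] <- metadata
  fcss_histogram(
    channels = mat[, 1L], counts = mat[, 2L],
    sample_id = meta$sample_id %||% "sample",
    species = meta$species %||% NA_character_,
    seeds_pooled = as.integer(meta$seeds_pooled %||% 1L),
    protocol = meta$protocol %||% "seed_buffer",
    standard_species = meta$standard_species %||% NA_character_,
    standard_2C_pg = as.numeric(meta$standard_2C_pg %||% NA_real_)
  )
}

#' @rdname read_histogram
#' @param h An `fcss_histogram`.
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "fcss_histogram"))
  utils::write.table(
    data.frame(channel = h$channels, count = h$counts),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- c(sample_id = h$sample_id, species = h$species,
            seeds_pooled = h$seeds_pooled, protocol = h$protocol,
            standard_species = h$standard_species,
            standard_2C_pg = h$standard_2C_pg)
  meta <- meta[!is.na(meta)]
  writeLines(paste0(names(meta), ": ", meta), paste0(path, ".meta"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
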