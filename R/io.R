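#' Read and write interval, density, flash-series and sweep files
#'
#' All formats are delimited text with one header line, seconds
#' throughout, written at 6-decimal precision:
#' \describe{
#'   \item{interval samples}{header `ibi_s`, one value per row}
#'   \item{density}{header `t_s,density`, one grid point per row}
#'   \item{flash series}{header `agent_id,t_start,t_end`, sorted by
#'     `t_start` (unsorted files are sorted with a warning)}
#'   \item{sweep}{header `N,beta,ks_D,ks_p`; best-fit summary
#'     `N,best_beta,min_D`}
#' }
#' Malformed rows are reported with their line numbers; missing headers
#' are an error naming the file.
#'
#' @param path File path (`.csv` comma-delimited, `.tsv` tab-delimited).
#' @param x Object to write.
#' @param t_min,t_max Support bounds when reading a density; default to
#'   the first/last grid point with positive density.
#' @name firesync-io
NULL

delim_for <- function(path) if (grepl("\\.tsv$", path)) "\t" else ","

read_checked <- function(path, expected_cols) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_delim(path,
    delim = delim_for(path), col_types = readr::cols(.default = readr::col_double()),
    show_col_types = FALSE, progress = FALSE
  )
  if (!identical(names(tbl), expected_cols)) {
    abort(sprintf(
      "%s: expected header `%s`, found `%s`.",
      path, paste(expected_cols, collapse = ","), paste(names(tbl), collapse = ",")
    ))
  }
  bad <- which(!stats::complete.cases(tbl))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: non-numeric or missing fields on data line(s) %s.",
      path, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  tbl
}

write_delim6 <- function(tbl, path) {
  num <- purrr::map(tbl, function(col) {
    if (is.double(col)) sprintf("%.6f", col) else col
  })
  readr::write_delim(tibble::as_tibble(num), path, delim = delim_for(path))
  invisible(path)
}

#' @rdname firesync-io
#' @export
read_ibi_samples <- function(path) {
  tbl <- read_checked(path, "ibi_s")
  structure(tbl,
    n_removed = 0L, cutoff = 0, label = basename(path),
    class = c("ibi_samples", class(tbl))
  )
}

#' @rdname firesync-io
#' @export
write_ibi_samples <- function(x, path) {
  write_delim6(tibble::tibble(ibi_s = interval_values(x)), path)
}

#' @rdname firesync-io
#' @export
read_ibi_density <- function(path, t_min = NULL, t_max = NULL) {
  tbl <- read_checked(path, c("t_s", "density"))
  pos <- which(tbl$density > 0)
  if (length(pos) == 0) abort(sprintf("%s: density is identically zero.", path))
  t_min <- t_min %||% tbl$t_s[pos[1]]
  t_max <- t_max %||% tbl$t_s[pos[length(pos)]]
  area <- trapz(tbl$t_s, tbl$density)
  if (abs(area - 1) > 1e-4) {
    warn(sprintf("%s: density integrates to %.6f, renormalizing to 1.", path, area))
  }
  ibi_density(tbl$t_s, tbl$density, t_min = t_min, t_max = t_max,
              label = basename(path))
}

#' @rdname firesync-io
#' @export
write_ibi_density <- function(x, path) {
  write_delim6(tibble::tibble(t_s = x$t_s, density = x$density), path)
}

#' @rdname firesync-io
#' @export
read_flash_series <- function(path) {
  tbl <- read_checked(path, c("agent_id", "t_start", "t_end"))
  if (is.unsorted(tbl$t_start)) {
    warn(sprintf("%s: flash series not sorted by t_start; sorting.", path))
  }
  flash_series(tbl$agent_id, tbl$t_start, tbl$t_end)
}

#' @rdname firesync-io
#' @export
write_flash_series <- function(x, path) {
  write_delim6(
    tibble::tibble(
      agent_id = as.integer(x$agent_id),
      t_start = x$t_start, t_end = x$t_end
    ),
    path
  )
}

#' @rdname firesync-io
#' @export
read_sweep <- function(path) {
  tbl <- read_checked(path, c("N", "beta", "ks_D", "ks_p"))
  out <- structure(
    list(sweep = dplyr::mutate(tbl, N = as.integer(.data$N)), n_trials = NA_integer_),
    class = "beta_sweep"
  )
  out$best <- select_best_beta(out)
  out
}

#' @rdname firesync-io
#' @export
write_sweep <- function(x, path) {
  write_delim6(x$sweep, path)
}

#' @rdname firesync-io
#' @export
write_best_beta <- function(x, path) {
  best <- if (inherits(x, "beta_sweep")) x$best else x
  write_delim6(best, path)
}
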