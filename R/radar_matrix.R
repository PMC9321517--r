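#' Radar amplitude matrix
#'
#' Container for an IR-UWB recording: an `M x N` real matrix of reflection
#' amplitudes with rows indexing slow time (one row per transmitted frame)
#' and columns indexing fast time (one column per range bin), plus the
#' slow-time sampling period. Fast time is treated as unitless bins; the
#' optional `fast_period` is carried as metadata only.
#'
#' @param samples numeric matrix, `M` slow-time frames by `N` range bins.
#' @param slow_period_s slow-time sampling period in seconds (`1/frame rate`).
#' @param fast_period optional fast-time sampling period (arbitrary units).
#' @param t0 optional acquisition start time (`POSIXct` or numeric), metadata.
#'
#' @return An object of class `radar_matrix`.
#' @examples
#' rm <- radar_matrix(matrix(rnorm(200), 50, 4), slow_period_s = 0.05)
#' n_frames(rm)
#' @export
radar_matrix <- function(samples, slow_period_s, fast_period = NA_real_,
                         t0 = NULL) {
  if (is.vector(samples) && is.numeric(samples)) {
    samples <- matrix(samples, ncol = 1L)
  }
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stopf("`samples` must be a numeric matrix", class = "sbdar_validation")
  }
  if (nrow(samples) < 1L || ncol(samples) < 1L) {
    stopf("`samples` must have at least one row and one column",
          class = "sbdar_validation")
  }
  if (!all(is.finite(samples))) {
    stopf("`samples` contains non-finite values", class = "sbdar_validation")
  }
  check_scalar(slow_period_s, "slow_period_s")
  if (slow_period_s <= 0) {
    stopf("`slow_period_s` must be positive", class = "sbdar_validation")
  }
  structure(
    list(samples = unname(samples), slow_period_s = slow_period_s,
         fast_period = fast_period, t0 = t0),
    class = "radar_matrix"
  )
}

#' @rdname radar_matrix
#' @param x a `radar_matrix`.
#' @export
n_frames <- function(x) nrow(x$samples)

#' @rdname radar_matrix
#' @export
n_bins <- function(x) ncol(x$samples)

#' @rdname radar_matrix
#' @export
slow_rate <- function(x) 1 / x$slow_period_s

#' Slow-time stamps of a radar matrix
#'
#' @param x a `radar_matrix`.
#' @return numeric vector of length `n_frames(x)`, seconds from the first
#'   frame (`0, Ts, 2 Ts, ...`).
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) * x$slow_period_s

#' @export
print.radar_matrix <- function(x, ...) {
  cat(sprintf(
    "<radar_matrix> %d slow-time frames x %d range bins (%.1f s at %.3g fps)\n",
    n_frames(x), n_bins(x), n_frames(x) * x$slow_period_s, slow_rate(x)))
  invisible(x)
}

MAGIC_BIN <- "SBDR"

#' Read and write radar matrix files
#'
#' Two on-disk dialects are supported. The text dialect is comma-delimited
#' with one slow-time frame per row and `#`-prefixed `key=value` header
#' lines carrying the timing metadata. The binary dialect is a fixed
#' little-endian layout: magic string `"SBDR"`, int32 version, int32 `M`,
#' int32 `N`, double `slow_period_s`, double `fast_period`, then `M * N`
#' doubles in row-major order. `read_radar_matrix()` sniffs the dialect from
#' the first four bytes.
#'
#' @param x a [radar_matrix()].
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @return `read_radar_matrix()` returns a `radar_matrix`;
#'   `write_radar_matrix()` returns `path` invisibly.
#' @export
write_radar_matrix <- function(x, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (!inherits(x, "radar_matrix")) {
    stopf("`x` must be a radar_matrix", class = "sbdar_validation")
  }
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    fp <- if (is.finite(x$fast_period)) sprintf("%.17g", x$fast_period)
          else "NA"
    writeLines(c(sprintf("# slow_period_s=%.17g", x$slow_period_s),
                 sprintf("# fast_period=%s", fp)), con)
    rows <- apply(x$samples, 1L, function(r) paste(sprintf("%.17g", r),
                                                   collapse = ","))
    writeLines(rows, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(MAGIC_BIN, con, nchars = 4L, eos = NULL)
    writeBin(c(1L, n_frames(x), n_bins(x)), con, size = 4L,
             endian = "little")
    writeBin(c(x$slow_period_s, as.double(x$fast_period)), con, size = 8L,
             endian = "little")
    writeBin(as.double(t(x$samples)), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_radar_matrix
#' @export
read_radar_matrix <- function(path) {
  if (!file.exists(path)) {
    stopf("file '%s' does not exist", path, class = "sbdar_io")
  }
  head4 <- readBin(path, "raw", n = 4L)
  if (length(head4) == 4L && rawToChar(head4) == MAGIC_BIN) {
    read_radar_matrix_bin(path)
  } else {
    read_radar_matrix_text(path)
  }
}

read_radar_matrix_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, nchars = 4L)
  meta <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (length(meta) < 3L || meta[1] != 1L) {
    stopf("malformed binary header in '%s' (bad version field)", path,
          class = "sbdar_io")
  }
  m <- meta[2]; n <- meta[3]
  periods <- readBin(con, "double", n = 2L, size = 8L, endian = "little")
  vals <- readBin(con, "double", n = m * n, size = 8L, endian = "little")
  if (length(vals) != m * n) {
    stopf("truncated binary payload in '%s': expected %d values, found %d",
          path, m * n, length(vals), class = "sbdar_io")
  }
  radar_matrix(matrix(vals, nrow = m, ncol = n, byrow = TRUE),
               slow_period_s = periods[1], fast_period = periods[2])
}

read_radar_matrix_text <- function(path) {
  lines <- readLines(path)
  header <- grepl("^#", lines)
  meta <- list(slow_period_s = NA_real_, fast_period = NA_real_)
  for (h in lines[header]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      meta[[trimws(kv[1])]] <- suppressWarnings(as.numeric(trimws(kv[2])))
    }
  }
  if (!is.finite(meta$slow_period_s)) {
    stopf("malformed header in '%s': missing slow_period_s", path,
          class = "sbdar_io")
  }
  body_idx <- which(!header & nzchar(trimws(lines)))
  if (length(body_idx) == 0L) {
    stopf("'%s' contains no data rows", path, class = "sbdar_io")
  }
  fields <- strsplit(lines[body_idx], ",", fixed = TRUE)
  ncols <- length(fields[[1]])
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != ncols) {
      stopf("ragged row at line %d of '%s': expected %d fields, found %d",
            body_idx[i], path, ncols, length(fields[[i]]),
            class = "sbdar_io")
    }
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(ncols)))
  vals <- if (ncols == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stopf("non-numeric cell at line %d, field %d of '%s'",
          body_idx[bad[1]], bad[2], path, class = "sbdar_io")
  }
  radar_matrix(vals, slow_period_s = meta$slow_period_s,
               fast_period = meta$fast_period)
}
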