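#' One-dimensional scattering profile
#'
#' Container for an experimental or computed SAXS curve: intensity I(q) on a
#' strictly increasing momentum-transfer grid q (in inverse Angstrom), with an
#' optional per-point uncertainty. Individual intensities may be negative
#' (buffer-subtracted data), but uncertainties must be positive wherever
#' present.
#'
#' @param q numeric, momentum transfer in 1/Angstrom; strictly increasing,
#'   all positive.
#' @param intensity numeric, same length as `q`; arbitrary units.
#' @param sigma optional numeric, per-point standard deviation of
#'   `intensity`; all positive when supplied.
#' @param label free-text identifier carried through reports.
#' @return An object of class `saxs_profile`: a data frame with columns `q`,
#'   `intensity` and (optionally) `sigma`, plus a `label` attribute.
#' @examples
#' p <- saxs_profile(q = c(0.01, 0.02), intensity = c(100, 90), sigma = c(1, 1))
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have the same length")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("all q must be finite and > 0")
  dq <- diff(q)
  if (any(dq <= 0)) {
    idx <- which(dq <= 0)[1] + 1L
    stop(sprintf("q must be strictly increasing; first violation at index %d", idx))
  }
  df <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must have the same length as q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("all sigma must be finite and > 0")
    df$sigma <- sigma
  }
  structure(df, label = as.character(label)[1],
            class = c("saxs_profile", "data.frame"))
}

has_sigma <- function(profile) "sigma" %in% names(profile)

require_sigma <- function(profile, what) {
  if (!has_sigma(profile))
    stop(sprintf("%s requires a profile with uncertainties (sigma)", what))
  invisible(profile)
}

#' @export
print.saxs_profile <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("SAXS profile%s: %d points, q in [%.4g, %.4g] 1/A, sigma %s\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "",
              nrow(x), min(x$q), max(x$q),
              if (has_sigma(x)) "present" else "absent"))
  invisible(x)
}

#' @export
plot.saxs_profile <- function(x, log = "y", ...) {
  graphics::plot(x$q, x$intensity, log = log, type = "l",
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q)", ...)
  invisible(x)
}

#' Read a SAXS profile from 3-column text
#'
#' Reads the de-facto `.dat` standard: whitespace-delimited rows of
#' `q I(q) sigma` (or just `q I(q)`), with `#`-prefixed or non-numeric lines
#' treated as comments and skipped. Two-column files yield a profile without
#' uncertainties; operations that need sigma then fail loudly rather than
#' inventing error bars.
#'
#' @param path file to read.
#' @param dialect input dialect; only `"plain3col"` is defined.
#' @param q_scale multiplier applied to the q column on input; pass `0.1` for
#'   curves recorded in 1/nm. Assumed unit conversions are the caller's
#'   declaration -- nothing is auto-detected.
#' @param label label for the profile; defaults to the file name.
#' @return A [saxs_profile].
#' @export
read_profile <- function(path, dialect = "plain3col", q_scale = 1,
                         label = basename(path)) {
  dialect <- match.arg(dialect, "plain3col")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "[[:space:],]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) next           # header / non-numeric line
    if (length(vals) < 2) next
    rows[[length(rows) + 1L]] <- vals[seq_len(min(3L, length(vals)))]
  }
  if (length(rows) == 0) stop("no numeric rows found in ", path)
  ncols <- min(vapply(rows, length, 1L))
  m <- do.call(rbind, lapply(rows, function(v) v[seq_len(ncols)]))
  saxs_profile(q = m[, 1] * q_scale, intensity = m[, 2],
               sigma = if (ncols >= 3) m[, 3], label = label)
}

#' Write a SAXS profile as 3-column text
#'
#' @param profile a [saxs_profile].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  header <- sprintf("# %s", attr(profile, "label"))
  cols <- c("q", "intensity", if (has_sigma(profile)) "sigma")
  body <- do.call(paste, c(lapply(cols, function(cn)
    formatC(profile[[cn]], format = "g", digits = 10)), sep = " "))
  writeLines(c(header, sprintf("# %s", paste(cols, collapse = " ")), body),
             path)
  invisible(path)
}

# Linear interpolation of a calculated profile onto an experimental q grid.
# Grids must overlap; points of `onto` outside the calculated range are
# dropped with a warning, and both returned curves share the overlap grid.
interp_profile <- function(calc, onto) {
  qe <- onto$q
  inside <- qe >= min(calc$q) & qe <= max(calc$q)
  if (!any(inside))
    stop("calculated and experimental q ranges do not overlap")
  if (!all(inside))
    warning(sprintf("calculated grid covers only %d of %d experimental points; using the overlap",
                    sum(inside), length(inside)))
  list(
    idx = which(inside),
    calc = stats::approx(calc$q, calc$intensity, xout = qe[inside])$y
  )
}
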