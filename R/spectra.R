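#' Read spectrometer export files into a tidy spectra table
#'
#' Reads two-column (wavelength, value) or multi-column (wavelength plus one
#' column per spectrum) delimited text exports of the kind produced by
#' spectrometer acquisition software. The separator (comma, tab or
#' whitespace) is autodetected per file and an optional single header line is
#' skipped.
#'
#' @param paths Character vector of file paths.
#' @param kind Kind of quantity stored: one of `"reflectance"`,
#'   `"irradiance"`, `"absorbance"`, `"sensitivity"`.
#' @param dialect `"two_column"` (one spectrum per file) or `"multi_column"`
#'   (first column wavelength, every further column one spectrum).
#' @param percent If `TRUE`, values are percentages and are divided by 100 so
#'   reflectance is stored as a fraction.
#' @param labels Optional character vector of labels, one per file
#'   (two-column dialect only); defaults to the file base names.
#'
#' @return A tibble with columns `label`, `wavelength` (nm), `value` and
#'   `kind`, one row per sample.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("300,0.10", "301,0.20", "302,0.30"), f)
#' read_spectra(f)
#' @export
read_spectra <- function(paths, kind = c("reflectance", "irradiance",
                                         "absorbance", "sensitivity"),
                         dialect = c("two_column", "multi_column"),
                         percent = FALSE, labels = NULL) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (!is.null(labels) && length(labels) != length(paths)) {
    abort("`labels` must have one entry per path")
  }
  out <- purrr::map2(paths, seq_along(paths), function(path, i) {
    mat <- parse_delim_numeric(path)
    if (ncol(mat) < 2) {
      abort(paste0(path, ": expected at least 2 numeric columns"))
    }
    wl <- mat[, 1]
    if (any(diff(wl) <= 0)) {
      abort(paste0(path, ": wavelengths must be strictly increasing"))
    }
    if (dialect == "two_column") {
      lab <- if (is.null(labels)) {
        tools::file_path_sans_ext(basename(path))
      } else {
        labels[i]
      }
      tibble(label = lab, wavelength = wl, value = mat[, 2])
    } else {
      cols <- colnames(mat)[-1]
      if (is.null(cols)) cols <- paste0("s", seq_len(ncol(mat) - 1))
      purrr::map(seq_along(cols), function(j) {
        tibble(label = paste0(tools::file_path_sans_ext(basename(path)),
                              "_", cols[j]),
               wavelength = wl, value = mat[, j + 1])
      }) |> bind_rows()
    }
  }) |> bind_rows()
  if (percent) out$value <- out$value / 100
  out$kind <- kind
  out
}

# Parse a delimited numeric file into a matrix, reporting the offending file
# and line on failure. Separator autodetected; one header line tolerated.
parse_delim_numeric <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0(path, ": file is empty"))
  sep_of <- function(x) {
    if (grepl(",", x)) "," else if (grepl("\t", x)) "\t" else "[[:space:]]+"
  }
  split1 <- function(x) strsplit(trimws(x), sep_of(x))[[1]]
  first <- suppressWarnings(as.numeric(split1(lines[1])))
  header <- NULL
  start <- 1L
  if (anyNA(first)) {
    header <- split1(lines[1])
    start <- 2L
    if (length(lines) < 2) abort(paste0(path, ": no data rows"))
  }
  rows <- lapply(seq(start, length(lines)), function(i) {
    vals <- suppressWarnings(as.numeric(split1(lines[i])))
    if (anyNA(vals)) {
      abort(paste0(path, ": non-numeric value on line ", i))
    }
    vals
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1) {
    abort(paste0(path, ": rows have differing numbers of columns"))
  }
  mat <- do.call(rbind, rows)
  if (!is.null(header) && length(header) == ncol(mat)) colnames(mat) <- header
  mat
}

#' Resample spectra onto a common wavelength grid
#'
#' Linear interpolation of each spectrum onto `grid`. By default the grid
#' must lie within the measured range of every spectrum; with
#' `extrapolate = TRUE` values outside the range are clamped to the end
#' values.
#'
#' @param spectra A spectra tibble (columns `wavelength`, `value`, optionally
#'   `label` and metadata).
#' @param grid Numeric vector of target wavelengths (nm), strictly increasing.
#' @param extrapolate Allow wavelengths outside the measured range
#'   (rule-2 clamping); default `FALSE` (error).
#' @return A tibble on the new grid with all other columns preserved.
#' @export
resample_spectra <- function(spectra, grid = default_grid(),
                             extrapolate = FALSE) {
  check_spectra(spectra)
  if (any(diff(grid) <= 0)) abort("`grid` must be strictly increasing")
  per_spectrum(spectra, function(df) {
    if (!extrapolate &&
        (min(grid) < min(df$wavelength) || max(grid) > max(df$wavelength))) {
      abort(paste0("grid extends outside the measured range [",
                   min(df$wavelength), ", ", max(df$wavelength),
                   "] nm; set `extrapolate = TRUE` to clamp"))
    }
    out <- df[rep(1L, length(grid)), , drop = FALSE]
    out$wavelength <- grid
    out$value <- approx(df$wavelength, df$value, xout = grid, rule = 2)$y
    out
  })
}

#' Smooth spectra and clip negative reflectance
#'
#' Default method is a centered moving average whose window is
#' `span * n` grid points (rounded to the nearest odd integer; edges use the
#' available partial window). `method = "loess"` uses locally weighted
#' regression with the same span. Negative values (spectrometer noise) are
#' clipped to 0 afterwards and the number of clipped points is reported via
#' a message.
#'
#' @inheritParams resample_spectra
#' @param span Fraction of the grid length used as the smoothing window,
#'   in (0, 1].
#' @param method `"ma"` (moving average, default) or `"loess"`.
#' @return The smoothed spectra tibble.
#' @export
smooth_spectra <- function(spectra, span = 0.2, method = c("ma", "loess")) {
  method <- match.arg(method)
  check_spectra(spectra)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    abort("`span` must be a single number in (0, 1]")
  }
  clipped <- 0L
  out <- per_spectrum(spectra, function(df) {
    n <- nrow(df)
    sm <- if (method == "ma") {
      w <- max(1L, round(span * n))
      if (w %% 2 == 0) w <- w + 1L
      moving_average(df$value, w)
    } else {
      stats::predict(stats::loess(value ~ wavelength, data = df, span = span,
                                  degree = 2))
    }
    neg <- sm < 0
    clipped <<- clipped + sum(neg)
    df$value <- ifelse(neg, 0, sm)
    df
  })
  if (clipped > 0) {
    message("smooth_spectra: clipped ", clipped, " negative value(s) to 0")
  }
  out
}

# centered moving average, window shrinks symmetrically at the edges
moving_average <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }, numeric(1))
}

#' Pointwise mean and standard deviation of grouped spectra
#'
#' Aggregates a set of spectra sharing a wavelength grid into per-group mean
#' and sample standard deviation curves (sd = 0 for singleton groups), the
#' summary drawn as solid lines with shaded bands in reflectance figures.
#'
#' @param spectra A spectra tibble; members of a group must share one grid.
#' @param ... Grouping columns (tidy-select), e.g. `species, patch`. If
#'   omitted, groups by `label`.
#' @return A tibble with the grouping columns, `wavelength`, `mean` and `sd`.
#' @export
aggregate_spectra <- function(spectra, ...) {
  check_spectra(spectra)
  if (nrow(spectra) == 0) abort("no spectra to aggregate")
  keys <- names(dplyr::select(dplyr::slice(spectra, 0), ...))
  if (length(keys) == 0) keys <- "label"
  spectra |>
    group_by(across(all_of(c(keys, "wavelength")))) |>
    summarise(n = dplyr::n(),
              sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
              mean = mean(.data$value),
              .groups = "drop") |>
    select(all_of(keys), "wavelength", "mean", "sd")
}

#' Write spectra as a tidy long-format delimited table
#'
#' @param spectra A spectra tibble.
#' @param path Output file; tab-separated with a header.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  check_spectra(spectra)
  utils::write.table(spectra, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

check_spectra <- function(spectra) {
  if (!is.data.frame(spectra) ||
      !all(c("wavelength", "value") %in% names(spectra))) {
    abort("spectra must be a data frame with `wavelength` and `value` columns")
  }
  invisible(spectra)
}

# apply fn per spectrum (split on label if present, else whole table)
per_spectrum <- function(spectra, fn) {
  if ("label" %in% names(spectra)) {
    spectra |>
      dplyr::group_split(.data$label) |>
      purrr::map(fn) |>
      bind_rows()
  } else {
    fn(spectra)
  }
}
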