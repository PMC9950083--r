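#' Spectrum record for file interchange
#'
#' A format-neutral container for one- or two-channel spectra (refractive
#' index carries two channels: real and imaginary part) together with
#' free-form metadata.
#'
#' @param grid strictly increasing wavenumbers (cm^-1)
#' @param values numeric vector (one channel) or matrix with one or two
#'   columns and \code{length(grid)} rows
#' @param kind one of \code{"refractive-index"}, \code{"extinction"},
#'   \code{"absorbance"}
#' @param metadata named list of character provenance values
#' @return an object of class \code{spectrum_record}
#' @export
spectrum_record <- function(grid, values,
                            kind = c("extinction", "refractive-index",
                                     "absorbance"),
                            metadata = list()) {
  check_grid(grid)
  kind <- match.arg(kind)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  stopifnot(is.matrix(values), nrow(values) == length(grid),
            ncol(values) %in% 1:2)
  if (any(!is.finite(values))) stop("spectrum values must be finite")
  stopifnot(is.list(metadata))
  structure(list(grid = grid, values = values, kind = kind,
                 metadata = metadata),
            class = "spectrum_record")
}

#' Convert package objects to spectrum records
#' @param x a \code{refindex_spectrum}, \code{extinction_spectrum} or
#'   \code{absorbance_spectrum}
#' @param ... unused
#' @return a \code{\link{spectrum_record}}
#' @export
as_spectrum_record <- function(x, ...) UseMethod("as_spectrum_record")

#' @export
as_spectrum_record.refindex_spectrum <- function(x, ...) {
  spectrum_record(x$grid, cbind(x$n, x$k), kind = "refractive-index")
}

#' @export
as_spectrum_record.extinction_spectrum <- function(x, ...) {
  md <- list(shape = x$geometry$shape, R_um = format(x$geometry$R),
             L_um = format(x$geometry$L), method = x$method)
  spectrum_record(x$grid, x$qext, kind = "extinction", metadata = md)
}

#' @export
as_spectrum_record.absorbance_spectrum <- function(x, ...) {
  spectrum_record(x$grid, x$z, kind = "absorbance",
                  metadata = list(form = if (x$linearized) "linearized"
                                  else "exact"))
}

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a spectrum to CSV or JCAMP-DX
#'
#' Output is byte-deterministic for identical records (fixed \code{\%.10g}
#' float formatting, LF line endings). The CSV dialect is comma-separated
#' UTF-8 with \code{#}-prefixed comment lines holding metadata
#' (\code{# key: value}) and the header row
#' \code{wavenumber_cm-1,value[,value_imag]}. JCAMP-DX files are written
#' as AFFN \code{XYPOINTS} tables; two-channel records become a compound
#' file with one block per channel.
#'
#' @param rec a \code{\link{spectrum_record}} (or an object convertible via
#'   \code{\link{as_spectrum_record}})
#' @param path output file path
#' @param format \code{"csv"} or \code{"jcamp-dx"}; default guessed from
#'   the file extension (\code{.jdx}/\code{.dx} mean JCAMP-DX)
#' @return \code{path}, invisibly
#' @export
write_spectrum <- function(rec, path, format = NULL) {
  if (!inherits(rec, "spectrum_record")) rec <- as_spectrum_record(rec)
  format <- guess_format(path, format)
  lines <- if (format == "csv") csv_lines(rec) else jcamp_lines(rec)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

guess_format <- function(path, format) {
  if (!is.null(format))
    return(match.arg(format, c("csv", "jcamp-dx")))
  if (grepl("\\.(jdx|dx)$", path, ignore.case = TRUE)) "jcamp-dx" else "csv"
}

csv_lines <- function(rec) {
  md <- c(list(kind = rec$kind), rec$metadata)
  header <- vapply(names(md), function(k)
    sprintf("# %s: %s", k, as.character(md[[k]])), character(1))
  cols <- if (ncol(rec$values) == 2L) "wavenumber_cm-1,value,value_imag"
          else "wavenumber_cm-1,value"
  rows <- apply(cbind(rec$grid, rec$values), 1L, function(r)
    paste(fmt_num(r), collapse = ","))
  c(header, cols, rows)
}

jcamp_block <- function(grid, y, title, kind, channel = NULL) {
  c(sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    sprintf("##DATA TYPE=%s", toupper(kind)),
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    if (!is.null(channel)) sprintf("##$CHANNEL=%s", channel),
    sprintf("##NPOINTS=%d", length(grid)),
    sprintf("##FIRSTX=%s", fmt_num(grid[1])),
    sprintf("##LASTX=%s", fmt_num(grid[length(grid)])),
    "##XYPOINTS=(XY..XY)",
    paste(fmt_num(grid), fmt_num(y), sep = ", "),
    "##END=")
}

jcamp_lines <- function(rec) {
  if (ncol(rec$values) == 1L) {
    jcamp_block(rec$grid, rec$values[, 1], title = rec$kind, kind = rec$kind)
  } else {
    c(sprintf("##TITLE=%s", rec$kind),
      "##JCAMP-DX=4.24",
      "##BLOCKS=2",
      jcamp_block(rec$grid, rec$values[, 1], paste0(rec$kind, " (real)"),
                  rec$kind, channel = "real"),
      jcamp_block(rec$grid, rec$values[, 2], paste0(rec$kind, " (imag)"),
                  rec$kind, channel = "imag"),
      "##END=")
  }
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' Reads files written by \code{\link{write_spectrum}} as well as plain
#' AFFN JCAMP-DX files with either \code{XYPOINTS=(XY..XY)} or
#' \code{XYDATA=(X++(Y..Y))} tables (applying XFACTOR/YFACTOR). Spectra
#' stored with a descending wavenumber axis, as infrared JCAMP-DX files
#' often are, come back with an ascending grid and co-reversed values.
#'
#' @param path input file path
#' @param format \code{"csv"} or \code{"jcamp-dx"}; default guessed from
#'   the extension
#' @return a \code{\link{spectrum_record}}
#' @export
read_spectrum <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- guess_format(path, format)
  lines <- readLines(path, warn = FALSE)
  if (format == "csv") parse_csv_spectrum(lines, path)
  else parse_jcamp_spectrum(lines, path)
}

parse_csv_spectrum <- function(lines, path) {
  meta <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^#", lines[i])) {
    mm <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(mm) == 3L) meta[[trimws(mm[2])]] <- trimws(mm[3])
    else meta[[sprintf("comment_%d", length(meta) + 1L)]] <-
        sub("^#\\s*", "", lines[i])
    i <- i + 1L
  }
  if (i > length(lines) || !grepl("^wavenumber", lines[i]))
    stop(sprintf("%s:%d: expected header row 'wavenumber_cm-1,value[,value_imag]'",
                 path, i))
  ncols <- length(strsplit(lines[i], ",")[[1]])
  i <- i + 1L
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  vals <- matrix(NA_real_, nrow = length(body), ncol = ncols)
  for (j in seq_along(body)) {
    fields <- suppressWarnings(as.numeric(strsplit(body[j], ",")[[1]]))
    if (length(fields) != ncols || anyNA(fields))
      stop(sprintf("%s:%d: malformed numeric row", path, i + j - 1L))
    vals[j, ] <- fields
  }
  kind <- if (!is.null(meta$kind)) meta$kind
          else if (ncols == 3L) "refractive-index" else "extinction"
  meta$kind <- NULL
  ord <- order(vals[, 1])
  spectrum_record(vals[ord, 1], vals[ord, -1, drop = FALSE], kind = kind,
                  metadata = meta)
}

jcamp_field <- function(lines, key) {
  hit <- grep(sprintf("^##\\$?%s=", key), lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  trimws(sub("^##[^=]*=", "", hit[1]))
}

parse_jcamp_numbers <- function(txt, path, lineno) {
  out <- suppressWarnings(as.numeric(strsplit(trimws(txt),
                                              "[,;[:space:]]+")[[1]]))
  if (anyNA(out))
    stop(sprintf("%s:%d: non-numeric JCAMP-DX data line", path, lineno))
  out
}

# Parse one JCAMP-DX block (a character vector from ##TITLE to ##END).
parse_jcamp_table <- function(lines, path, offset = 0L) {
  xf <- as.numeric(jcamp_field(lines, "XFACTOR") %||% "1")
  yf <- as.numeric(jcamp_field(lines, "YFACTOR") %||% "1")
  ixy <- grep("^##XYPOINTS=", lines)
  ixx <- grep("^##XYDATA=", lines)
  start <- c(ixy, ixx)[1]
  if (is.na(start)) stop(sprintf("%s: no XYPOINTS or XYDATA table found", path))
  end <- grep("^##", lines)
  end <- end[end > start]
  end <- if (length(end)) end[1] - 1L else length(lines)
  data_lines <- lines[(start + 1L):end]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(ixy) > 0L) {
    xs <- ys <- numeric(0)
    for (j in seq_along(data_lines)) {
      v <- parse_jcamp_numbers(data_lines[j], path, offset + start + j)
      if (length(v) %% 2L != 0L)
        stop(sprintf("%s:%d: odd number of values in XYPOINTS row",
                     path, offset + start + j))
      xs <- c(xs, v[seq(1L, length(v), by = 2L)])
      ys <- c(ys, v[seq(2L, length(v), by = 2L)])
    }
  } else {
    # X++(Y..Y): each line starts with an X value followed by Y values
    xs <- ys <- numeric(0)
    rows <- lapply(seq_along(data_lines), function(j)
      parse_jcamp_numbers(data_lines[j], path, offset + start + j))
    firstx <- vapply(rows, `[`, numeric(1), 1L)
    dx_line <- diff(firstx)
    for (j in seq_along(rows)) {
      yv <- rows[[j]][-1L]
      step <- if (length(yv) > 1L) {
        if (j < length(rows)) dx_line[j] / length(yv)
        else if (length(rows) > 1L) dx_line[j - 1L] / length(rows[[j - 1L]][-1L])
        else {
          lastx <- as.numeric(jcamp_field(lines, "LASTX") %||% NA)
          if (is.na(lastx)) stop(sprintf("%s: cannot infer X step", path))
          (lastx / xf - firstx[j]) / (length(yv) - 1L)
        }
      } else 0
      xs <- c(xs, firstx[j] + step * (seq_along(yv) - 1L))
      ys <- c(ys, yv)
    }
  }
  list(x = xs * xf, y = ys * yf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_jcamp_spectrum <- function(lines, path) {
  kind_raw <- tolower(paste(jcamp_field(lines, "DATA TYPE") %||% "",
                            jcamp_field(lines, "YUNITS") %||% ""))
  kind <- if (grepl("refractive", kind_raw)) "refractive-index"
          else if (grepl("absorbance", kind_raw)) "absorbance"
          else "extinction"
  nblocks <- as.integer(jcamp_field(lines, "BLOCKS") %||% "1")
  if (nblocks >= 2L) {
    titles <- grep("^##TITLE=", lines)
    ends <- grep("^##END=", lines)
    # child blocks are the 2nd and 3rd TITLEs in a compound file
    b1 <- lines[titles[2]:ends[1]]
    b2 <- lines[titles[3]:ends[2]]
    t1 <- parse_jcamp_table(b1, path, offset = titles[2] - 1L)
    t2 <- parse_jcamp_table(b2, path, offset = titles[3] - 1L)
    if (length(t1$x) != length(t2$x) || any(abs(t1$x - t2$x) > 1e-6))
      stop(path, ": channel blocks disagree on the wavenumber axis")
    ord <- order(t1$x)
    spectrum_record(t1$x[ord], cbind(t1$y[ord], t2$y[ord]), kind = kind)
  } else {
    tab <- parse_jcamp_table(lines, path)
    ord <- order(tab$x)
    spectrum_record(tab$x[ord], tab$y[ord], kind = kind)
  }
}
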