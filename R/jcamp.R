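# JCAMP-DX I/O, restricted to uncompressed AFFN numeric tables.
# Writer emits XYDATA (X++(Y..Y)) for real spectra and an NTUPLES record
# with real/imaginary pages for FIDs. Reader accepts those two layouts and
# rejects compressed dialects (SQZ/DIF/DUP "ASDF") with an explicit error.

jcamp_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write an FID or spectrum as JCAMP-DX
#'
#' FIDs are written as an NTUPLES record with separate real and imaginary
#' pages; spectra as a real XYDATA record. Data are uncompressed AFFN
#' (plain decimal numbers), so round trips are exact to write precision
#' (12 significant digits).
#'
#' @param x A \code{qnmr_fid} or \code{qnmr_spectrum}.
#' @param path Output path.
#' @param title Record title.
#' @return \code{path}, invisibly.
#' @export
write_jcamp <- function(x, path, title = "qnmradjust export") {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  if (inherits(x, "qnmr_fid")) {
    n <- length(x$samples)
    dt <- x$params$dwell_time
    t <- (seq_len(n) - 1) * dt
    w("##TITLE= ", title)
    w("##JCAMP-DX= 5.00")
    w("##DATA TYPE= NMR FID")
    w("##DATA CLASS= NTUPLES")
    w("##.OBSERVE FREQUENCY= ", jcamp_num(x$params$frequency_mhz))
    w("##$OFFSETPPM= ", jcamp_num(x$params$offset_ppm))
    w("##$DWELLTIME= ", jcamp_num(dt))
    w("##NTUPLES= NMR FID")
    w("##VAR_NAME= TIME, FID/REAL, FID/IMAG")
    w("##SYMBOL= X, R, I")
    w("##VAR_DIM= ", n, ", ", n, ", ", n)
    w("##UNITS= SECONDS, ARBITRARY UNITS, ARBITRARY UNITS")
    w("##FIRST= 0, ", jcamp_num(Re(x$samples[1])), ", ",
      jcamp_num(Im(x$samples[1])))
    w("##LAST= ", jcamp_num(t[n]), ", ", jcamp_num(Re(x$samples[n])), ", ",
      jcamp_num(Im(x$samples[n])))
    w("##FACTOR= 1, 1, 1")
    for (page in 1:2) {
      vals <- if (page == 1) Re(x$samples) else Im(x$samples)
      w("##PAGE= N=", page)
      w("##DATA TABLE= (X++(", if (page == 1) "R..R" else "I..I",
        ")), XYDATA")
      writeLines(affn_lines(t, vals), con)
    }
    w("##END NTUPLES= NMR FID")
    w("##END=")
  } else if (inherits(x, "qnmr_spectrum")) {
    n <- length(x$real)
    w("##TITLE= ", title)
    w("##JCAMP-DX= 5.00")
    w("##DATA TYPE= NMR SPECTRUM")
    w("##.OBSERVE FREQUENCY= ", jcamp_num(x$params$frequency_mhz))
    w("##$OFFSETPPM= ", jcamp_num(x$params$offset_ppm))
    w("##XUNITS= HZ")
    w("##YUNITS= ARBITRARY UNITS")
    w("##NPOINTS= ", n)
    w("##FIRSTX= ", jcamp_num(x$freq_hz[1]))
    w("##LASTX= ", jcamp_num(x$freq_hz[n]))
    w("##XFACTOR= 1")
    w("##YFACTOR= 1")
    w("##XYDATA= (X++(Y..Y))")
    writeLines(affn_lines(x$freq_hz, x$real), con)
    w("##END=")
  } else stop("x must be a qnmr_fid or qnmr_spectrum")
  invisible(path)
}

# groups of 6 ordinates per line, each line led by its abscissa
affn_lines <- function(xs, ys) {
  n <- length(ys)
  starts <- seq(1L, n, by = 6L)
  vapply(starts, function(s) {
    e <- min(s + 5L, n)
    paste(jcamp_num(xs[s]), paste(jcamp_num(ys[s:e]), collapse = " "))
  }, character(1))
}

parse_jcamp_ldrs <- function(lines) {
  lines <- sub("\\$\\$.*$", "", lines)  # strip comments
  hdr <- grepl("^\\s*##", lines)
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (hdr[i]) {
      m <- regmatches(lines[i],
                      regexec("^\\s*##([^=]*)=\\s*(.*)$", lines[i]))[[1]]
      if (length(m) == 3) {
        key <- toupper(gsub("[ _-]", "", m[2]))
        j <- i + 1L
        while (j <= length(lines) && !hdr[j]) j <- j + 1L
        recs[[length(recs) + 1L]] <- list(key = key, value = trimws(m[3]),
                                          data = lines[seq(i + 1L,
                                                           length.out = j - i - 1L)])
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  recs
}

first_value <- function(recs, key, default = NULL) {
  for (r in recs) if (r$key == key) return(r$value)
  default
}

parse_affn_block <- function(data_lines, what) {
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) stop("empty ", what, " data block")
  if (any(grepl("[A-DF-Za-df-z@%]", data_lines)))
    stop("compressed/ASDF-encoded JCAMP-DX data in ", what,
         " record is not supported; only uncompressed AFFN is readable")
  vals <- lapply(strsplit(trimws(data_lines), "[,;[:space:]]+"), as.numeric)
  if (any(vapply(vals, function(v) any(is.na(v)), TRUE)))
    stop("unparseable numeric data in ", what, " record")
  list(x = vapply(vals, `[[`, 0, 1),
       y = unlist(lapply(vals, `[`, -1)))
}

#' Read a JCAMP-DX file
#'
#' Recognizes the two record layouts the package writes: an NTUPLES NMR
#' FID (real + imaginary pages) returned as a \code{qnmr_fid}, and a real
#' XYDATA spectrum returned as a \code{qnmr_spectrum} (without complex
#' values, so it cannot be re-phased). Compressed (ASDF/SQZ/DIF) data
#' raise an explicit error. Acquisition parameters are populated from the
#' headers; a missing dwell time (or frequency axis) is an error, never a
#' silent default.
#'
#' @param path Path to a JCAMP-DX file.
#' @return A \code{qnmr_fid} or \code{qnmr_spectrum}.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*##TITLE", lines)))
    stop("not a JCAMP-DX file (no ##TITLE record): ", path)
  recs <- parse_jcamp_ldrs(lines)
  b0 <- as.numeric(first_value(recs, "OBSERVEFREQUENCY",
                               first_value(recs, ".OBSERVEFREQUENCY", "400")))
  f0 <- as.numeric(first_value(recs, "$OFFSETPPM", "0"))
  dtype <- toupper(first_value(recs, "DATATYPE", ""))
  tables <- Filter(function(r) r$key == "DATATABLE", recs)
  if (length(tables) >= 2 || grepl("FID", dtype)) {
    if (length(tables) < 2)
      stop("NMR FID record (type '", dtype,
           "') without real+imaginary NTUPLES data tables is not supported")
    re <- parse_affn_block(tables[[1]]$data, "real FID")
    im <- parse_affn_block(tables[[2]]$data, "imaginary FID")
    if (length(re$y) != length(im$y))
      stop("real and imaginary FID pages have different lengths")
    n <- length(re$y)
    dt <- as.numeric(first_value(recs, "$DWELLTIME", NA))
    if (is.na(dt)) {
      lastv <- first_value(recs, "LAST")
      if (!is.null(lastv)) {
        tlast <- as.numeric(strsplit(lastv, ",")[[1]][1])
        dt <- tlast / (n - 1)
      }
    }
    if (is.na(dt) || !is.finite(dt) || dt <= 0)
      stop("dwell time missing from JCAMP-DX headers ",
           "(##$DWELLTIME or ##LAST required)")
    ndecl <- first_value(recs, "VARDIM")
    if (!is.null(ndecl)) {
      nd <- as.numeric(strsplit(ndecl, ",")[[1]][1])
      if (is.finite(nd) && nd != n)
        stop("declared VAR_DIM (", nd, ") does not match data length (", n,
             "); file appears truncated")
    }
    return(nmr_fid(complex(real = re$y, imaginary = im$y),
                   acq_params(dt, n, b0, f0)))
  }
  xy <- Filter(function(r) r$key == "XYDATA", recs)
  if (!length(xy))
    stop("no supported data record found (XYDATA or NTUPLES DATA TABLE); ",
         "data type was '", dtype, "'")
  xf <- as.numeric(first_value(recs, "XFACTOR", "1"))
  yf <- as.numeric(first_value(recs, "YFACTOR", "1"))
  blk <- parse_affn_block(xy[[1]]$data, "XYDATA")
  y <- blk$y * yf
  n <- length(y)
  npts <- as.numeric(first_value(recs, "NPOINTS", NA))
  if (is.finite(npts) && npts != n)
    stop("declared NPOINTS (", npts, ") does not match data length (", n,
         "); file appears truncated")
  firstx <- as.numeric(first_value(recs, "FIRSTX", NA)) * xf
  lastx <- as.numeric(first_value(recs, "LASTX", NA)) * xf
  if (!is.finite(firstx) || !is.finite(lastx))
    stop("FIRSTX/LASTX missing; cannot construct the frequency grid")
  df <- (lastx - firstx) / (n - 1)
  if (df <= 0) stop("frequency axis must be ascending")
  dt <- 1 / (n * df)
  params <- acq_params(dt, n, b0, f0)
  sp <- nmr_spectrum(y, params)
  # honour the file's own grid even if not centred on zero
  sp$freq_hz <- firstx + (seq_len(n) - 1) * df
  sp
}
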