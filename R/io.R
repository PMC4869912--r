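## Plain-text interchange formats.  Traces: two-column delimited text
## (time_s, value) under a '#'-prefixed JSON header carrying units, dt and
## provenance.  Localizations: 'x_nm y_nm photons frame' table.  Stacks:
## a text container (JSON header + one whitespace row per pixel row per
## frame) since the analysis environment has no binary TIFF dependency.

#' Write / read a signal trace as delimited text
#'
#' The first line is a \code{#}-prefixed JSON header (units, dt, class,
#' optional preset and seed); the body has columns time_s and value.
#'
#' @param trace a [SignalTrace-class].
#' @param path output file.
#' @param meta optional named list merged into the header (e.g. preset,
#'   seed).
#' @return invisibly, the path (write) or the reconstructed trace (read).
#' @export
writeTrace <- function(trace, path, meta = list()) {
  stopifnot(is(trace, "SignalTrace"))
  hdr <- c(list(class = class(trace)[1], units = trace@units,
                dt = trace@dt, site_id = trace@siteId), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  df <- data.frame(time_s = (seq_along(trace@values) - 1) * trace@dt,
                   value = trace@values)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) stop("missing JSON header line")
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- read.table(path, header = TRUE, skip = 1L)
  cls <- if (hdr$class %in% c("CalciumTrace", "CurrentTrace", "BleachTrace"))
    hdr$class else "BleachTrace"
  new(cls, values = df$value, dt = hdr$dt, units = hdr$units,
      siteId = if (is.null(hdr$site_id)) "" else hdr$site_id)
}

#' Write / read a localization table
#'
#' Whitespace-delimited columns \code{x_nm y_nm photons frame} with a
#' \code{#}-prefixed JSON header carrying the DLR.
#'
#' @param locs a [LocalizationSet-class].
#' @param path file path.
#' @return invisibly the path (write); a [LocalizationSet-class] (read).
#' @export
writeLocalizations <- function(locs, path) {
  stopifnot(is(locs, "LocalizationSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(list(dlr = locs@dlr),
                                           auto_unbox = TRUE)), con)
  df <- locs@coords[, c("x", "y", "photons", "frame")]
  names(df) <- c("x_nm", "y_nm", "photons", "frame")
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLocalizations
#' @export
readLocalizations <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) stop("missing JSON header line")
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- read.table(path, header = TRUE, skip = 1L)
  names(df) <- sub("^x_nm$", "x", sub("^y_nm$", "y", names(df)))
  dlr <- if (is.null(hdr$dlr)) NA_real_ else as.numeric(hdr$dlr)
  localizationSet(df, dlr = if (length(dlr)) dlr else NA_real_)
}

#' Write / read an image stack as plain text
#'
#' JSON header (dimensions, pixel size, dt) followed by one
#' whitespace-delimited row per pixel row, frames concatenated in order.
#' A text stand-in for multi-page TIFF in dependency-free settings.
#'
#' @param stack an [ImageStack-class].
#' @param path file path.
#' @return invisibly the path (write); an [ImageStack-class] (read).
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- stack@data
  hdr <- list(rows = dim(d)[1], cols = dim(d)[2], frames = dim(d)[3],
              pixel_size_nm = stack@pixelSize, dt = stack@dt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(hdr, auto_unbox = TRUE)), con)
  for (f in seq_len(dim(d)[3]))
    write.table(d[, , f], con, sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# ")) stop("missing JSON header line")
  hdr <- jsonlite::fromJSON(sub("^# ", "", first))
  m <- as.matrix(read.table(path, header = FALSE, skip = 1L))
  d <- array(0, dim = c(hdr$rows, hdr$cols, hdr$frames))
  for (f in seq_len(hdr$frames))
    d[, , f] <- m[((f - 1) * hdr$rows + 1):(f * hdr$rows), ]
  imageStack(d, pixelSize = hdr$pixel_size_nm, dt = hdr$dt)
}
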