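# Minimal ENVI raw/header reader-writer (BIL and BSQ interleaves).
# Cubes are arrays with dims (lines, samples, bands); the header wavelength
# list is the authoritative nm axis.

.envi_dtype <- list(`4` = list(what = "double", size = 4),
                    `5` = list(what = "double", size = 8))

#' Write a hyperspectral cube as an ENVI raw/header pair
#'
#' @param cube numeric array `(lines, samples, bands)`.
#' @param wavelengths numeric vector of band centres in nm, length = bands.
#' @param path_base path without extension; `<path_base>.raw` and
#'   `<path_base>.hdr` are written.
#' @param interleave `"bil"` (band-interleaved-by-line) or `"bsq"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64, default —
#'   float64 keeps read/write an exact round trip).
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_envi <- function(cube, wavelengths, path_base,
                       interleave = c("bil", "bsq"), data_type = 5) {
  interleave <- match.arg(interleave)
  d <- dim(cube)
  if (length(d) != 3) stopf("cube must be a 3-d array, got %d dims", length(d))
  if (length(wavelengths) != d[3]) {
    stopf("wavelength list length %d != bands %d", length(wavelengths), d[3])
  }
  dt <- .envi_dtype[[as.character(data_type)]]
  if (is.null(dt)) stopf("unsupported ENVI data type %s", data_type)

  raw_path <- paste0(path_base, ".raw")
  hdr_path <- paste0(path_base, ".hdr")
  # disk order: fastest-varying first. bil = (samples, bands, lines),
  # bsq = (samples, lines, bands)
  perm <- if (interleave == "bil") c(2, 3, 1) else c(2, 1, 3)
  con <- file(raw_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(aperm(cube, perm)), con, size = dt$size)

  hdr <- c(
    "ENVI",
    "description = {vitaspec synthetic plate cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(wavelengths, trim = TRUE, digits = 12), collapse = ", "),
           " }")
  )
  writeLines(hdr, hdr_path)
  invisible(c(raw_path, hdr_path))
}

#' Read an ENVI raw/header pair into a cube
#'
#' @param path path to the `.hdr` file, or the base path without extension.
#' @return A list with `cube` (array `(lines, samples, bands)`) and
#'   `wavelengths` (nm vector from the header).
#' @export
read_envi <- function(path) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  raw_path <- sub("\\.hdr$", ".raw", hdr_path)
  if (!file.exists(hdr_path)) stopf("header not found: %s", hdr_path)
  if (!file.exists(raw_path)) stopf("raw file not found: %s", raw_path)

  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  field <- function(name, required = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", name,
                                        "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stopf("header field '%s' missing in %s", name, hdr_path)
      return(NULL)
    }
    trimws(m[2])
  }
  samples <- as.integer(field("samples"))
  lines_n <- as.integer(field("lines"))
  bands <- as.integer(field("bands"))
  data_type <- as.integer(field("data type"))
  interleave <- tolower(field("interleave"))
  if (!interleave %in% c("bil", "bsq")) {
    stopf("unsupported interleave '%s'", interleave)
  }
  dt <- .envi_dtype[[as.character(data_type)]]
  if (is.null(dt)) stopf("unsupported ENVI data type %d", data_type)
  wl_txt <- gsub("[{}]", "", field("wavelength"))
  wavelengths <- as.numeric(strsplit(wl_txt, ",")[[1]])
  if (length(wavelengths) != bands) {
    stopf("header wavelength list length %d != bands %d",
          length(wavelengths), bands)
  }

  n <- as.numeric(samples) * lines_n * bands
  vals <- readBin(raw_path, what = dt$what, n = n, size = dt$size)
  if (length(vals) != n) stopf("raw file %s truncated", raw_path)
  if (interleave == "bil") {
    cube <- aperm(array(vals, c(samples, bands, lines_n)), c(3, 1, 2))
  } else {
    cube <- aperm(array(vals, c(samples, lines_n, bands)), c(2, 1, 3))
  }
  list(cube = cube, wavelengths = wavelengths)
}

#' Write a label mask as an 8-bit PNG image
#'
#' Labels 0 (background) to 255 are stored as gray levels.
#' @param mask integer matrix of labels in `[0, 255]`.
#' @param path output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 255 || min(mask) < 0) stopf("labels must lie in [0, 255]")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read an 8-bit label mask written by [write_mask()]
#'
#' @param path `.png` path.
#' @return Integer matrix of labels.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
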