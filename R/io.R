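# Cube readers/writers. Two on-disk forms are supported, both 64-bit float
# end to end:
#   "envi"  - ENVI header (.hdr, text) + flat binary (.dat), BSQ/BIL/BIP
#             interleaves, wavelengths carried in the header;
#   "delim" - plain tab-delimited pixels x channels matrix (.tsv) with a
#             one-column wavenumber axis file (.wn.tsv) and a key=value
#             metadata sidecar (.meta).

#' Write a hyperspectral cube
#'
#' @param image A [hyper_image()].
#' @param path Base path (extensions are appended).
#' @param format `"envi"` or `"delim"`.
#' @param interleave ENVI interleave: `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path, format = c("envi", "delim"),
                       interleave = c("bsq", "bil", "bip")) {
  format <- match.arg(format)
  interleave <- match.arg(interleave)
  nr <- n_rows(image); nc <- n_cols(image); nb <- length(image$axis)
  if (format == "envi") {
    hdr <- c("ENVI",
             paste0("samples = ", nc),
             paste0("lines = ", nr),
             paste0("bands = ", nb),
             "header offset = 0",
             "file type = ENVI Standard",
             "data type = 5",
             paste0("interleave = ", interleave),
             "byte order = 0",
             paste0("derivative order = ", image$derivative_order),
             paste0("wavelength = { ",
                    paste(sprintf("%.2f", image$axis), collapse = ", "), " }"))
    writeLines(hdr, paste0(path, ".hdr"))
    perm <- switch(interleave,
                   bsq = c(2L, 1L, 3L),    # sample, line, band
                   bil = c(2L, 3L, 1L),    # sample, band, line
                   bip = c(3L, 2L, 1L))    # band, sample, line
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(aperm(image$cube, perm)), con, size = 8,
             endian = "little")
  } else {
    utils::write.table(cube_matrix(image), paste0(path, ".tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(image$axis, paste0(path, ".wn.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    writeLines(c(paste0("n_rows=", nr), paste0("n_cols=", nc),
                 paste0("derivative_order=", image$derivative_order)),
               paste0(path, ".meta"))
  }
  invisible(path)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (!length(m)) stop("format error in ", hdr_path, ": missing '", key, "'",
                         call. = FALSE)
    as.integer(sub(".*=\\s*", "", m))
  }
  get_str <- function(key, default = NULL) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[a-z]+"), txt))
    if (!length(m)) return(default)
    sub(".*=\\s*", "", m)
  }
  wl <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  if (!length(wl)) stop("format error in ", hdr_path, ": missing wavelengths",
                        call. = FALSE)
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl), ",")[[1]])
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       interleave = get_str("interleave", "bsq"),
       derivative_order = tryCatch(get_num("derivative order"),
                                   error = function(e) 0L),
       wavelength = wl)
}

#' Read a hyperspectral cube
#'
#' @param path Base path as used by [write_cube()].
#' @param format `"envi"` or `"delim"`.
#' @return A [hyper_image()].
#' @export
read_cube <- function(path, format = c("envi", "delim")) {
  format <- match.arg(format)
  if (format == "envi") {
    h <- parse_envi_header(paste0(path, ".hdr"))
    if (h$data_type != 5L)
      stop("format error: only data type 5 (float64) is supported", call. = FALSE)
    if (length(h$wavelength) != h$bands)
      stop("format error: wavelength count does not match bands", call. = FALSE)
    n <- h$samples * h$lines * h$bands
    raw <- readBin(paste0(path, ".dat"), "double", n = n + 1L, size = 8,
                   endian = "little")
    if (length(raw) != n)
      stop("format error: binary payload has ", length(raw),
           " values, expected ", n, call. = FALSE)
    dims <- switch(h$interleave,
                   bsq = c(h$samples, h$lines, h$bands),
                   bil = c(h$samples, h$bands, h$lines),
                   bip = c(h$bands, h$samples, h$lines),
                   stop("format error: unknown interleave", call. = FALSE))
    arr <- array(raw, dim = dims)
    cube <- switch(h$interleave,
                   bsq = aperm(arr, c(2L, 1L, 3L)),
                   bil = aperm(arr, c(3L, 1L, 2L)),
                   bip = aperm(arr, c(3L, 2L, 1L)))
    hyper_image(cube, h$wavelength, as.integer(h$derivative_order))
  } else {
    m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
    ax <- utils::read.table(paste0(path, ".wn.tsv"), sep = "\t")[[1]]
    meta <- readLines(paste0(path, ".meta"))
    kv <- strsplit(meta, "=")
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    nr <- as.integer(vals[["n_rows"]]); nc <- as.integer(vals[["n_cols"]])
    if (ncol(m) != length(ax))
      stop("format error: axis file length (", length(ax),
           ") does not match matrix columns (", ncol(m), ")", call. = FALSE)
    if (nrow(m) != nr * nc)
      stop("format error: matrix rows do not match n_rows x n_cols", call. = FALSE)
    dimnames(m) <- NULL
    hyper_image(matrix_cube(m, nr, nc), ax,
                as.integer(vals[["derivative_order"]]))
  }
}

#' Write / read a covariate table
#'
#' @param covariates Covariate data frame.
#' @param path CSV path.
#' @return `path` / the data frame.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
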