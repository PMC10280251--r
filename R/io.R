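#' Recording bundle
#'
#' Simple container used by every reader: a K x L channel matrix, the
#' sampling rate, channel names and a provenance tag.
#'
#' @param channels K x L numeric matrix (finite values only).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of length K.
#' @param provenance String, e.g. `"synthetic"`, `"wfdb:<record>"`,
#'   `"csv:<path>"`.
#' @return Object of class `recording_bundle`.
#' @export
recording_bundle <- function(channels, fs, channel_names = NULL,
                             provenance = "synthetic") {
  stopifnot(is.matrix(channels), is.numeric(channels))
  check_scalar_num(fs, "fs", positive = TRUE)
  if (any(!is.finite(channels))) {
    stop("channels contain non-finite (NaN/Inf/NA) samples", call. = FALSE)
  }
  channel_names <- channel_names %||% paste0("ch", seq_len(nrow(channels)))
  if (length(channel_names) != nrow(channels)) {
    abort_bad_arg("channel_names", "must have one name per channel")
  }
  structure(list(channels = channels, fs = fs,
                 channel_names = as.character(channel_names),
                 provenance = provenance),
            class = "recording_bundle")
}

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> %d x %d @ %g Hz (%s)\n",
              nrow(x$channels), ncol(x$channels), x$fs, x$provenance))
  invisible(x)
}

# ---- WFDB -------------------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) {
    stop(sprintf("WFDB header not found: %s", hea_path), call. = FALSE)
  }
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop(sprintf("corrupt WFDB header (too few lines): %s", hea_path),
         call. = FALSE)
  }
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 2) {
    stop(sprintf("corrupt WFDB header record line: %s", hea_path), call. = FALSE)
  }
  nsig <- suppressWarnings(as.integer(rec[2]))
  fs <- if (length(rec) >= 3) suppressWarnings(as.numeric(sub("/.*", "", rec[3]))) else 250
  nsamp <- if (length(rec) >= 4) suppressWarnings(as.numeric(rec[4])) else NA
  if (is.na(nsig) || nsig < 1 || is.na(fs)) {
    stop(sprintf("corrupt WFDB header record line: %s", hea_path), call. = FALSE)
  }
  sig <- lapply(lines[2:(1 + nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3) {
      stop(sprintf("corrupt WFDB signal line in %s: '%s'", hea_path, ln),
           call. = FALSE)
    }
    fmt <- sub("x.*", "", f[2])  # strip samples-per-frame suffix
    gain_field <- f[3]
    baseline <- NA_real_
    units <- "mV"
    if (grepl("/", gain_field)) {
      units <- sub(".*/", "", gain_field)
      gain_field <- sub("/.*", "", gain_field)
    }
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_field))
      gain_field <- sub("\\(.*", "", gain_field)
    }
    gain <- as.numeric(gain_field)
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default gain
    adczero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
    if (is.na(adczero)) adczero <- 0
    if (is.na(baseline)) baseline <- adczero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[1], format = fmt, gain = gain, baseline = baseline,
         units = units, description = desc)
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, nsig, nsamp) {
  sz <- file.info(path)$size
  n_avail <- floor(sz / (2 * nsig))
  if (!is.na(nsamp) && nsamp > 0) {
    if (n_avail < nsamp) {
      stop(sprintf("truncated WFDB signal file: %s (%d of %d samples)",
                   path, n_avail, nsamp), call. = FALSE)
    }
    n_avail <- nsamp
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n_avail * nsig, size = 2,
               signed = TRUE, endian = "little")
  matrix(v, nrow = nsig)
}

read_dat_212 <- function(path, nsig, nsamp) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  n_total <- floor(length(raw) / 3) * 2  # two samples per 3 bytes
  if (!is.na(nsamp) && nsamp > 0 && n_total < nsamp * nsig) {
    stop(sprintf("truncated WFDB signal file: %s", path), call. = FALSE)
  }
  b <- as.integer(raw[seq_len(floor(length(raw) / 3) * 3)])
  b1 <- b[seq(1, length(b), 3)]
  b2 <- b[seq(2, length(b), 3)]
  b3 <- b[seq(3, length(b), 3)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8)       # low nibble of byte2 = high bits
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4), 8)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))
  if (!is.na(nsamp) && nsamp > 0) v <- v[seq_len(nsamp * nsig)]
  n_keep <- floor(length(v) / nsig) * nsig
  matrix(v[seq_len(n_keep)], nrow = nsig)
}

#' Read a WFDB record (formats 16 and 212)
#'
#' Parses the `.hea` header, reads the interleaved `.dat` signal file and
#' applies the per-signal gain and baseline so values are in physical units.
#' Only single-segment records with all signals in one file, stored in
#' format 16 (16-bit two's complement) or format 212 (packed 12-bit), are
#' supported; anything else raises an explicit unsupported-format error.
#'
#' @param record_path Path to the record without extension (e.g. `"bw"` for
#'   `bw.hea` + `bw.dat`), or to the `.hea` file.
#' @return A [recording_bundle] in physical units.
#' @export
read_wfdb <- function(record_path) {
  record_path <- sub("\\.hea$", "", record_path)
  hdr <- parse_wfdb_header(paste0(record_path, ".hea"))
  fmts <- unique(vapply(hdr$signals, `[[`, "", "format"))
  files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(files) != 1) {
    stop("unsupported WFDB layout: signals split across multiple files",
         call. = FALSE)
  }
  if (length(fmts) != 1 || !fmts %in% c("16", "212")) {
    stop(sprintf("unsupported WFDB signal format '%s' (only 16 and 212 are supported)",
                 paste(fmts, collapse = ",")), call. = FALSE)
  }
  dat_path <- file.path(dirname(paste0(record_path, ".hea")), files)
  if (!file.exists(dat_path)) {
    stop(sprintf("WFDB signal file not found: %s", dat_path), call. = FALSE)
  }
  adc <- if (fmts == "16") read_dat_16(dat_path, hdr$nsig, hdr$nsamp)
         else read_dat_212(dat_path, hdr$nsig, hdr$nsamp)
  phys <- adc
  for (i in seq_len(hdr$nsig)) {
    phys[i, ] <- (adc[i, ] - hdr$signals[[i]]$baseline) / hdr$signals[[i]]$gain
  }
  if (any(!is.finite(phys))) {
    stop("WFDB record contains non-finite samples after calibration",
         call. = FALSE)
  }
  names_out <- vapply(seq_len(hdr$nsig), function(i) {
    d <- hdr$signals[[i]]$description
    if (is.na(d) || !nzchar(d)) paste0("sig", i) else d
  }, "")
  recording_bundle(phys, fs = hdr$fs, channel_names = names_out,
                   provenance = paste0("wfdb:", basename(record_path)))
}

# Minimal WFDB writer used to build test fixtures (formats 16 and 212).
write_wfdb <- function(adc, fs, record_path, format = "16",
                       gain = 200, baseline = 0, names = NULL) {
  stopifnot(is.matrix(adc), format %in% c("16", "212"))
  nsig <- nrow(adc)
  nsamp <- ncol(adc)
  gain <- rep_len(gain, nsig)
  baseline <- rep_len(baseline, nsig)
  names <- names %||% paste0("sig", seq_len(nsig))
  rec <- basename(record_path)
  hea <- c(sprintf("%s %d %g %d", rec, nsig, fs, nsamp),
           vapply(seq_len(nsig), function(i) {
             sprintf("%s.dat %s %g(%g)/mV 12 0 0 0 0 %s", rec, format,
                     gain[i], baseline[i], names[i])
           }, ""))
  writeLines(hea, paste0(record_path, ".hea"))
  v <- as.integer(round(as.vector(adc)))  # interleaved, column-major = by sample
  con <- file(paste0(record_path, ".dat"), "wb")
  on.exit(close(con))
  if (format == "16") {
    writeBin(v, con, size = 2, endian = "little")
  } else {
    if (length(v) %% 2 == 1) v <- c(v, 0L)
    v12 <- bitwAnd(v, 4095L)
    s1 <- v12[seq(1, length(v12), 2)]
    s2 <- v12[seq(2, length(v12), 2)]
    b1 <- bitwAnd(s1, 255L)
    b2 <- bitwOr(bitwShiftR(s1, 8), bitwShiftL(bitwShiftR(s2, 8), 4))
    b3 <- bitwAnd(s2, 255L)
    writeBin(as.raw(as.vector(rbind(b1, b2, b3))), con)
  }
  invisible(record_path)
}

# ---- CSV --------------------------------------------------------------------

#' Read a channels-in-columns CSV matrix
#'
#' Expects a header row of channel names followed by one sample per line; a
#' missing header (first line numeric) is tolerated with auto-generated
#' names `ch1..chK` and a warning. Ragged rows and non-finite values are
#' rejected.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz to attach to the bundle.
#' @return A [recording_bundle] (channels K x L, one channel per CSV column).
#' @export
read_csv_matrix <- function(path, fs = 360) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    stop(sprintf("empty CSV file: %s", path), call. = FALSE)
  }
  toks <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  if (!has_header) {
    warning(sprintf("no header row in %s; channels auto-named ch1..ch%d",
                    path, length(toks)))
  }
  df <- readr::read_csv(path, col_names = has_header,
                        col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in %s at line %d: %s", path,
                 probs$row[1] + as.integer(has_header), probs$expected[1]),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop(sprintf("no data rows in %s", path), call. = FALSE)
  m <- t(as.matrix(df))
  dimnames(m) <- NULL
  if (any(!is.finite(m))) {
    stop(sprintf("non-finite samples in %s", path), call. = FALSE)
  }
  nm <- if (has_header) colnames(df) else paste0("ch", nrow(m))
  if (!has_header) nm <- paste0("ch", seq_len(nrow(m)))
  recording_bundle(m, fs = fs, channel_names = nm,
                   provenance = paste0("csv:", path))
}

#' Write a recording bundle as CSV (channels in columns)
#'
#' Full double precision; `read_csv_matrix(write_csv_matrix(x))` round-trips
#' within 1e-12.
#'
#' @param bundle A [recording_bundle].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_matrix <- function(bundle, path) {
  stopifnot(inherits(bundle, "recording_bundle"))
  df <- as.data.frame(t(bundle$channels))
  names(df) <- bundle$channel_names
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Save / load a data-set collection or unmixing result
#'
#' Serializes the object to an `.rds` container with a JSON sidecar
#' (`<path>.json`) describing what it holds (class, dimensions, algorithm,
#' iteration count) so archives remain inspectable without R.
#'
#' @param x A `dataset_collection` or `unmixing_result`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_container <- function(x, path) {
  stopifnot(inherits(x, "dataset_collection") || inherits(x, "unmixing_result"))
  saveRDS(x, path)
  meta <- if (inherits(x, "dataset_collection")) {
    dims <- collection_dims(x)
    list(class = "dataset_collection", D = dims[["D"]], K = dims[["K"]],
         L = dims[["L"]], snr_db = x$snr_db, fs = x$fs, labels = x$labels)
  } else {
    list(class = "unmixing_result", algorithm = x$algorithm,
         D = length(x$W), K = nrow(x$W[[1]]),
         n_iterations = x$n_iterations, converged = x$converged)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_container
#' @export
load_container <- function(path) readRDS(path)
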