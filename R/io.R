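# EEG container I/O ------------------------------------------------------
#
# Three on-disk forms are supported:
#   * the internal HDF5 container (datasets /data /labels /fs
#     /channel_names /events, fixed names so fixtures are bit-stable),
#   * BrainVision triplets (.vhdr/.eeg/.vmrk), the acquisition-system
#     format, read and written (IEEE_FLOAT_32 or INT_16, multiplexed),
#   * GDF 2.x (the BCI-IV-2a container), read only.

#' Read a continuous EEG recording from disk
#'
#' @param path file path (the `.vhdr` file for BrainVision).
#' @param format one of `"auto"`, `"hdf5"`, `"brainvision"`, `"gdf"`;
#'   `"auto"` infers from the extension (`.h5`/`.hdf5`, `.vhdr`, `.gdf`).
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("auto", "hdf5", "brainvision",
                                            "gdf")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         hdf5 = read_recording_h5(path),
         brainvision = read_brainvision(path),
         gdf = read_gdf(path))
}

#' Write a continuous EEG recording to disk
#'
#' @param rec an [recording()].
#' @param path output path (`.h5` or `.vhdr`; the `.eeg`/`.vmrk` siblings
#'   of a BrainVision triplet are derived from it).
#' @param format `"auto"`, `"hdf5"` or `"brainvision"`.
#' @param binary_format BrainVision sample encoding, `"IEEE_FLOAT_32"`
#'   (default) or `"INT_16"` (0.1 microvolt resolution).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            format = c("auto", "hdf5", "brainvision"),
                            binary_format = "IEEE_FLOAT_32") {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         hdf5 = write_recording_h5(rec, path),
         brainvision = write_brainvision(rec, path, binary_format),
         stop("cannot write format: ", format))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         h5 = , hdf5 = "hdf5",
         vhdr = "brainvision",
         gdf = "gdf",
         stop("cannot infer format from extension: ", ext))
}

# internal HDF5 container -------------------------------------------------

h5_overwrite <- function(path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
}

read_recording_h5 <- function(path) {
  need <- c("data", "fs", "channel_names", "events")
  have <- rhdf5::h5ls(path)$name
  miss <- setdiff(need, have)
  if (length(miss))
    stop("malformed container ", path, ": missing dataset(s) ",
         paste(miss, collapse = ", "))
  ev <- rhdf5::h5read(path, "events")
  ev <- matrix(as.integer(ev), ncol = 2)
  recording(rhdf5::h5read(path, "data"),
            as.numeric(rhdf5::h5read(path, "fs")),
            as.character(rhdf5::h5read(path, "channel_names")),
            data.frame(sample = ev[, 1], code = ev[, 2]))
}

write_recording_h5 <- function(rec, path) {
  h5_overwrite(path)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$fs, path, "fs")
  rhdf5::h5write(rec$channel_names, path, "channel_names")
  rhdf5::h5write(cbind(rec$events$sample, rec$events$code), path, "events")
  rhdf5::h5closeAll()
}

#' Read / write the internal HDF5 trial container
#'
#' The container stores `/data` (n_trials x n_channels x n_samples),
#' `/labels`, `/fs` and `/channel_names` under fixed names.
#'
#' @param path file path (`.h5`).
#' @return [read_trialset()] returns a [trialset()];
#'   [write_trialset()] returns `path` invisibly.
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("data", "labels", "fs", "channel_names")
  miss <- setdiff(need, rhdf5::h5ls(path)$name)
  if (length(miss))
    stop("malformed container ", path, ": missing dataset(s) ",
         paste(miss, collapse = ", "))
  trialset(rhdf5::h5read(path, "data"),
           as.integer(rhdf5::h5read(path, "labels")),
           as.numeric(rhdf5::h5read(path, "fs")),
           as.character(rhdf5::h5read(path, "channel_names")))
}

#' @rdname read_trialset
#' @param ts a [trialset()].
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "trialset"))
  h5_overwrite(path)
  rhdf5::h5write(ts$trials, path, "data")
  rhdf5::h5write(ts$labels, path, "labels")
  rhdf5::h5write(ts$fs, path, "fs")
  rhdf5::h5write(ts$channel_names, path, "channel_names")
  rhdf5::h5closeAll()
  invisible(path)
}

# BrainVision -------------------------------------------------------------

parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

ini_field <- function(ini, section, key, file) {
  v <- ini[[section]][[key]]
  if (is.null(v))
    stop(sprintf("malformed %s: missing %s/%s", file, section, key))
  v
}

read_brainvision <- function(vhdr_path) {
  ini <- parse_ini(vhdr_path)
  dir <- dirname(vhdr_path)
  nchan <- as.integer(ini_field(ini, "Common Infos", "NumberOfChannels",
                                vhdr_path))
  sampint <- as.numeric(ini_field(ini, "Common Infos", "SamplingInterval",
                                  vhdr_path))
  fs <- 1e6 / sampint
  orient <- ini_field(ini, "Common Infos", "DataOrientation", vhdr_path)
  if (toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", orient)
  binfmt <- ini_field(ini, "Binary Infos", "BinaryFormat", vhdr_path)
  datafile <- file.path(dir, ini_field(ini, "Common Infos", "DataFile",
                                       vhdr_path))
  if (!file.exists(datafile)) stop("missing data file: ", datafile)

  chinfo <- ini[["Channel Infos"]]
  if (is.null(chinfo)) stop("malformed ", vhdr_path, ": no [Channel Infos]")
  ch_names <- character(nchan); resolution <- rep(1, nchan)
  for (i in seq_len(nchan)) {
    entry <- chinfo[[paste0("Ch", i)]]
    if (is.null(entry))
      stop(sprintf("malformed %s: missing Channel Infos/Ch%d", vhdr_path, i))
    parts <- strsplit(entry, ",")[[1]]
    ch_names[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resolution[i] <- as.numeric(parts[3])
  }

  sz <- file.info(datafile)$size
  if (toupper(binfmt) == "IEEE_FLOAT_32") {
    nsamp <- as.integer(sz / (4L * nchan))
    raw <- readBin(datafile, "numeric", n = nchan * nsamp, size = 4L,
                   endian = "little")
  } else if (toupper(binfmt) == "INT_16") {
    nsamp <- as.integer(sz / (2L * nchan))
    raw <- readBin(datafile, "integer", n = nchan * nsamp, size = 2L,
                   signed = TRUE, endian = "little")
  } else stop("unsupported BinaryFormat: ", binfmt)
  data <- matrix(raw, nrow = nchan)  # multiplexed: channel fastest
  data <- data * resolution

  mrkfile <- ini[["Common Infos"]][["MarkerFile"]]
  if (is.null(mrkfile))
    stop("malformed ", vhdr_path, ": missing Common Infos/MarkerFile")
  mrkpath <- file.path(dir, mrkfile)
  if (!file.exists(mrkpath))
    stop("missing BrainVision marker file: ", mrkpath)
  events <- read_vmrk(mrkpath)
  recording(data, fs, ch_names, events)
}

read_vmrk <- function(path) {
  ini <- parse_ini(path)
  mk <- ini[["Marker Infos"]]
  samples <- integer(0); codes <- integer(0)
  for (key in names(mk)) {
    if (!grepl("^Mk[0-9]+$", key)) next
    parts <- strsplit(mk[[key]], ",")[[1]]
    if (length(parts) < 3 || parts[1] != "Stimulus") next
    code <- suppressWarnings(as.integer(gsub("[^0-9]", "", parts[2])))
    if (is.na(code)) next
    samples <- c(samples, as.integer(parts[3]) - 1L)  # positions are 1-based
    codes <- c(codes, code)
  }
  data.frame(sample = samples, code = codes)
}

write_brainvision <- function(rec, vhdr_path, binary_format = "IEEE_FLOAT_32") {
  base <- tools::file_path_sans_ext(basename(vhdr_path))
  dir <- dirname(vhdr_path)
  eeg <- paste0(base, ".eeg"); vmrk <- paste0(base, ".vmrk")
  nchan <- nrow(rec$data)
  res <- if (binary_format == "INT_16") 0.1 else 1

  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", eeg),
           paste0("MarkerFile=", vmrk),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nchan),
           sprintf("SamplingInterval=%.6g", 1e6 / rec$fs),
           "[Binary Infos]",
           paste0("BinaryFormat=", binary_format),
           "[Channel Infos]",
           sprintf("Ch%d=%s,,%g,µV", seq_len(nchan), rec$channel_names,
                   res))
  writeLines(hdr, vhdr_path, useBytes = FALSE)

  con <- file(file.path(dir, eeg), "wb")
  on.exit(close(con), add = TRUE)
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  } else if (binary_format == "INT_16") {
    v <- as.integer(round(as.vector(rec$data) / res))
    v <- pmax(pmin(v, 32767L), -32768L)
    writeBin(v, con, size = 2L, endian = "little")
  } else stop("unsupported BinaryFormat: ", binary_format)

  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", eeg),
           "[Marker Infos]")
  if (nrow(rec$events)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                          seq_len(nrow(rec$events)), rec$events$code,
                          rec$events$sample + 1L))
  }
  writeLines(mrk, file.path(dir, vmrk))
  invisible(vhdr_path)
}

# GDF 2.x -----------------------------------------------------------------

gdf_str <- function(con, n) {
  r <- readBin(con, "raw", n = n)
  trimws(rawToChar(r[r != as.raw(0)]))
}

read_gdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  version <- rawToChar(readBin(con, "raw", 8L))
  if (!grepl("^GDF", version))
    stop("malformed GDF file ", path, ": bad version string '", version, "'")
  vnum <- suppressWarnings(as.numeric(substr(version, 5, 8)))
  if (is.na(vnum) || vnum < 1.9)
    stop("only GDF 2.x is supported (file reports '", version, "')")

  seek(con, 184)
  header_nbytes <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                           endian = "little") * 256L
  seek(con, 236)
  n_records <- readBin(con, "integer", 1L, size = 8L, endian = "little")
  rl <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (rl[2] == 0) stop("malformed GDF file: zero record-duration denominator")
  rec_dur <- rl[1] / rl[2]
  nchan <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                   endian = "little")

  seek(con, 256)
  ch_names <- vapply(seq_len(nchan), function(i) gdf_str(con, 16L), "")
  seek(con, 256 + nchan * (16L + 80L + 6L))
  unit_codes <- readBin(con, "integer", nchan, size = 2L, signed = FALSE,
                        endian = "little")
  physmin <- readBin(con, "numeric", nchan, size = 8L, endian = "little")
  physmax <- readBin(con, "numeric", nchan, size = 8L, endian = "little")
  digmin <- readBin(con, "numeric", nchan, size = 8L, endian = "little")
  digmax <- readBin(con, "numeric", nchan, size = 8L, endian = "little")
  seek(con, 68L * nchan + 12L * nchan, origin = "current")  # obsolete + lp/hp/notch
  n_samps <- readBin(con, "integer", nchan, size = 4L, endian = "little")
  dtypes <- readBin(con, "integer", nchan, size = 4L, endian = "little")

  if (length(unique(dtypes)) != 1L)
    stop("GDF files with mixed channel data types are not supported")
  if (length(unique(n_samps)) != 1L)
    stop("GDF files with per-channel sampling rates are not supported")
  dtype <- dtypes[1]; spr <- n_samps[1]
  fs <- spr / rec_dur

  read_block <- function(n) {
    switch(as.character(dtype),
           "3" = readBin(con, "integer", n, size = 2L, signed = TRUE,
                         endian = "little"),
           "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
           "17" = readBin(con, "numeric", n, size = 8L, endian = "little"),
           stop("unsupported GDF channel data type code: ", dtype))
  }

  seek(con, header_nbytes)
  nsamp_tot <- n_records * spr
  data <- matrix(0, nchan, nsamp_tot)
  for (r in seq_len(n_records)) {
    blk <- read_block(nchan * spr)
    # records are channel-blocked: spr samples of ch1, then ch2, ...
    data[, ((r - 1L) * spr + 1L):(r * spr)] <- t(matrix(blk, spr, nchan))
  }
  scale <- (physmax - physmin) / (digmax - digmin)
  data <- (data - digmin) * scale + physmin
  # convert to microvolts for the common unit codes (V / mV / uV)
  uv <- rep(1, nchan)
  uv[unit_codes == 4256L] <- 1e6
  uv[unit_codes == 4274L] <- 1e3
  data <- data * uv

  events <- data.frame(sample = integer(0), code = integer(0))
  etmode_raw <- readBin(con, "raw", 1L)
  if (length(etmode_raw) == 1L) {
    etmode <- as.integer(etmode_raw)
    if (etmode %in% c(1L, 3L)) {
      ne3 <- as.integer(readBin(con, "raw", 3L))
      n_events <- ne3[1] + ne3[2] * 256L + ne3[3] * 65536L
      readBin(con, "numeric", 1L, size = 4L, endian = "little")  # event fs
      pos <- readBin(con, "integer", n_events, size = 4L, endian = "little")
      typ <- readBin(con, "integer", n_events, size = 2L, signed = FALSE,
                     endian = "little")
      events <- data.frame(sample = pos - 1L, code = typ)  # 1-based positions
    }
  }
  recording(data, fs, ch_names, events)
}
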