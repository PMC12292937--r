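# Fixture builders shared across tests. Everything is generated in code;
# nothing binary ships with the package.

# small deterministic recording with named channels and a few markers
fixture_recording <- function(n_channels = 8, n_samples = 1000, fs = 250,
                              seed = 1, events = data.frame(
                                sample = c(100L, 400L, 700L),
                                code = c(1L, 2L, 3L))) {
  withr::with_seed(seed, {
    data <- matrix(rnorm(n_channels * n_samples), n_channels)
  })
  recording(data, fs, paste0("Ch", seq_len(n_channels)), events)
}

# trialset with per-class variance structure planted on chosen channels:
# `vars` is a classes x channels matrix of population variances
fixture_var_trialset <- function(vars, trials_per_class = 40,
                                 n_samples = 100, fs = 250, seed = 1) {
  ncls <- nrow(vars); nch <- ncol(vars)
  n <- trials_per_class * ncls
  labels <- rep(seq_len(ncls), each = trials_per_class)
  withr::with_seed(seed, {
    x <- array(0, c(n, nch, n_samples))
    for (i in seq_len(n))
      x[i, , ] <- matrix(rnorm(nch * n_samples), nch) *
        sqrt(vars[labels[i], ])
  })
  trialset(x, labels, fs)
}

# minimal GDF 2.20 writer (test oracle for the reader): float32 samples,
# one data record, event table mode 1
write_gdf_fixture <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nch <- nrow(rec$data); nsamp <- ncol(rec$data)
  wpad <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r)))),
             con)
  }
  zeros <- function(n) writeBin(raw(n), con)

  wpad("GDF 2.20", 8)           # version
  wpad("X X", 66)               # patient id
  zeros(10)                     # reserved
  zeros(4)                      # sadm, weight, height, ghi
  wpad("mi3deeg-fixture", 64)   # recording id
  zeros(4)                      # location precision block
  writeBin(c(0L, 0L), con, size = 4, endian = "little")  # lat, lon
  writeBin(0L, con, size = 4, endian = "little")         # altitude
  zeros(16)                     # meas_date, birthday
  writeBin(1L + nch, con, size = 2, endian = "little")   # header blocks
  zeros(6)
  zeros(8 + 6)                  # equipment, ip
  writeBin(rep(0L, 3), con, size = 2, endian = "little") # headsize
  writeBin(numeric(6), con, size = 4, endian = "little") # ref, gnd
  writeBin(1L, con, size = 8, endian = "little")         # n_records
  writeBin(c(nsamp, as.integer(rec$fs)), con, size = 4,
           endian = "little")                            # record duration
  writeBin(nch, con, size = 2, endian = "little")
  zeros(2)                      # pad fixed header to 256 bytes

  for (ch in rec$channel_names) wpad(ch, 16)
  zeros(80 * nch)                                        # transducer
  zeros(6 * nch)                                         # phys_dim
  writeBin(rep(4275L, nch), con, size = 2, endian = "little")  # uV
  writeBin(rep(-32768, nch), con, size = 8, endian = "little") # physmin
  writeBin(rep(32767, nch), con, size = 8, endian = "little")  # physmax
  writeBin(rep(-32768, nch), con, size = 8, endian = "little") # digmin
  writeBin(rep(32767, nch), con, size = 8, endian = "little")  # digmax
  zeros(68 * nch)
  writeBin(numeric(3 * nch), con, size = 4, endian = "little") # lp/hp/notch
  writeBin(rep(nsamp, nch), con, size = 4, endian = "little")  # n_samps
  writeBin(rep(16L, nch), con, size = 4, endian = "little")    # float32
  writeBin(numeric(3 * nch), con, size = 4, endian = "little") # xyz
  zeros(20 * nch)

  for (ch in seq_len(nch))                               # channel-blocked
    writeBin(as.vector(rec$data[ch, ]), con, size = 4, endian = "little")

  ne <- nrow(rec$events)
  writeBin(as.raw(1), con)                               # event mode 1
  writeBin(as.raw(c(ne %% 256, (ne %/% 256) %% 256, ne %/% 65536)), con)
  writeBin(as.numeric(rec$fs), con, size = 4, endian = "little")
  if (ne) {
    writeBin(rec$events$sample + 1L, con, size = 4, endian = "little")
    writeBin(rec$events$code, con, size = 2, endian = "little")
  }
  invisible(path)
}

# band power of one channel via the package Welch estimator
band_power <- function(x, fs, lo, hi) {
  w <- welch_params(fs, L = min(round(fs), length(x)), fmax = fs / 2)
  s <- welch_psd(x, w)
  sum(s$psd[s$freqs >= lo & s$freqs <= hi])
}

# mean over channels of the PSD value at a single frequency
peak_power <- function(rec, f0) {
  w <- welch_params(rec$fs, fmax = rec$fs / 2)
  mean(vapply(seq_len(nrow(rec$data)), function(ch) {
    s <- welch_psd(rec$data[ch, ], w)
    s$psd[which.min(abs(s$freqs - f0))]
  }, 0))
}
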