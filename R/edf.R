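# Minimal European Data Format (EDF) support: just enough to pull a single
# SpO2 channel out of a standard EDF file. 16-bit little-endian samples,
# physical values reconstructed from the per-signal digital/physical ranges.

read_edf_header <- function(con) {
  ascii <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  version <- ascii(8)
  patient <- ascii(80)
  recording <- ascii(80)
  startdate <- ascii(8)
  starttime <- ascii(8)
  header_bytes <- as.integer(ascii(8))
  reserved <- ascii(44)
  n_records <- as.integer(ascii(8))
  record_duration_s <- as.numeric(ascii(8))
  ns <- as.integer(ascii(4))
  field <- function(nbytes) vapply(seq_len(ns), function(i) ascii(nbytes), "")
  labels <- field(16)
  transducer <- field(80)
  phys_dim <- field(8)
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  prefilter <- field(80)
  n_samples <- as.integer(field(8))
  field(32)  # per-signal reserved
  list(version = version, patient = patient, recording = recording,
       startdate = startdate, starttime = starttime,
       header_bytes = header_bytes, n_records = n_records,
       record_duration_s = record_duration_s, ns = ns, labels = labels,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samples = n_samples)
}

read_edf_spo2 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  sig <- grep("spo2", h$labels, ignore.case = TRUE)
  if (!length(sig))
    stop("no SpO2 signal found in '", path, "' (labels: ",
         paste(h$labels, collapse = ", "), ")", call. = FALSE)
  sig <- sig[1]
  per_rec <- h$n_samples
  out <- numeric(h$n_records * per_rec[sig])
  pos <- 0L
  for (r in seq_len(h$n_records)) {
    for (s in seq_len(h$ns)) {
      dig <- readBin(con, "integer", n = per_rec[s], size = 2,
                     signed = TRUE, endian = "little")
      if (s == sig) {
        scale <- (h$phys_max[s] - h$phys_min[s]) / (h$dig_max[s] - h$dig_min[s])
        out[pos + seq_len(per_rec[s])] <- h$phys_min[s] + (dig - h$dig_min[s]) * scale
        pos <- pos + per_rec[s]
      }
    }
  }
  list(spo2 = out,
       sample_interval_s = h$record_duration_s / per_rec[sig])
}

# Internal single-channel EDF writer; exists so the EDF reading path can be
# exercised without shipping binary fixtures. NA samples are encoded below the
# digital minimum so they decode out of physical range and get masked invalid.
write_edf_spo2 <- function(path, spo2, sample_interval_s = 4,
                           samples_per_record = 16L) {
  n <- length(spo2)
  n_records <- ceiling(n / samples_per_record)
  pad <- n_records * samples_per_record - n
  x <- c(spo2, rep(NA_real_, pad))
  dig <- ifelse(is.na(x), -100L, as.integer(round(x * 10)))
  con <- file(path, "wb")
  on.exit(close(con))
  fixed <- function(s, nbytes) {
    s <- substr(sprintf("%-*s", nbytes, s), 1, nbytes)
    writeBin(charToRaw(s), con)
  }
  fixed("0", 8); fixed("X X X X", 80); fixed("Startdate X X X X", 80)
  fixed("01.01.20", 8); fixed("00.00.00", 8)
  fixed(as.character(256L + 256L), 8)  # header: fixed part + one signal block
  fixed("", 44)
  fixed(as.character(n_records), 8)
  fixed(format(sample_interval_s * samples_per_record, digits = 6), 8)
  fixed("1", 4)
  fixed("SpO2", 16); fixed("pulse oximeter", 80); fixed("%", 8)
  fixed("0", 8); fixed("100", 8)      # physical min/max
  fixed("0", 8); fixed("1000", 8)     # digital min/max
  fixed("", 80)
  fixed(as.character(samples_per_record), 8)
  fixed("", 32)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}
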