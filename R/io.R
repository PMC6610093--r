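# Recording container, label normalization, ASCII / EDF readers and writers,
# montage and region configuration.

#' EEG recording container
#'
#' Channels-by-samples matrix (microvolts) with a sampling rate and ordered
#' electrode labels of the 10-20 system.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param rate sampling rate in samples per second (> 0).
#' @param labels character vector of unique electrode names, one per row.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, labels) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("samples must be a finite numeric matrix")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  labels <- as.character(labels)
  if (length(labels) != nrow(samples))
    stop("label count (", length(labels), ") must equal channel count (",
         nrow(samples), ")")
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  rownames(samples) <- labels
  structure(list(samples = samples, rate = as.numeric(rate), labels = labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", nrow(x$samples), "channels x", ncol(x$samples),
      "samples @", x$rate, "Hz\n")
  invisible(x)
}

#' Standard 10-20 montage used throughout
#'
#' The 21-electrode cap order as recorded (including the ear electrodes
#' A1/A2 that are dropped before network analysis), and the 19-channel
#' analysis subset.
#'
#' @return Character vector of electrode labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "A1", "A2", "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Pz", "Cz")
}

#' @rdname montage_1020
#' @export
analysis_labels <- function() setdiff(montage_1020(), c("A1", "A2"))

# Canonicalize electrode names: case-insensitive match against the montage,
# tolerate "EEG " prefixes / "-REF" suffixes from EDF exports, and map the
# modern temporal names onto the older nomenclature used here.
normalize_labels <- function(labels) {
  canon <- montage_1020()
  lut <- setNames(canon, toupper(canon))
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  cleaned <- toupper(trimws(sub("-?REF$", "", sub("^EEG[ _]*", "",
                                                  trimws(labels),
                                                  ignore.case = TRUE),
                                ignore.case = TRUE)))
  cleaned <- ifelse(cleaned %in% names(alias), alias[cleaned], cleaned)
  out <- lut[cleaned]
  if (anyNA(out))
    stop("unknown electrode label(s): ",
         paste(labels[is.na(out)], collapse = ", "))
  unname(out)
}

#' Write / read a recording as a plain ASCII sample matrix
#'
#' Tab-separated text with one column per channel, a header row of labels
#' and a leading `# rate_hz:` comment so the sampling rate round-trips.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @export
write_eeg_ascii <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# rate_hz: ", format(rec$rate, digits = 15)),
               paste(rec$labels, collapse = "\t")), con)
  # column-major of the channels x samples matrix = one sample per text row;
  # %.17g so the matrix round-trips exactly through text
  write(sprintf("%.17g", rec$samples), file = con,
        ncolumns = length(rec$labels), sep = "\t")
  invisible(path)
}

read_eeg_ascii <- function(path, rate = NULL) {
  header <- readLines(path, n = 2L)
  skip <- 0L
  if (startsWith(header[1L], "#")) {
    parsed <- suppressWarnings(as.numeric(sub("^#[^0-9]*", "", header[1L])))
    if (is.finite(parsed)) rate <- parsed
    skip <- 1L
    labels <- strsplit(header[2L], "\t", fixed = TRUE)[[1L]]
  } else {
    labels <- strsplit(header[1L], "\t", fixed = TRUE)[[1L]]
  }
  if (is.null(rate))
    stop("sampling rate not stored in file; pass `rate` explicitly")
  vals <- scan(path, what = numeric(), skip = skip + 1L, quiet = TRUE)
  n_ch <- length(labels)
  if (length(vals) %% n_ch != 0L)
    stop("inconsistent channel lengths in ", path)
  eeg_recording(matrix(vals, nrow = n_ch), rate, labels)
}

#' Read a recording from disk
#'
#' Supports the package's ASCII matrix format and a minimal EDF
#' (European Data Format, 16-bit) subset.  Labels are normalized to the
#' canonical 10-20 names; unknown labels are an error.
#'
#' @param path file path.
#' @param format `"ascii"` or `"edf"`.
#' @param rate sampling rate override for headerless ASCII files.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("ascii", "edf"), rate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- switch(format,
                ascii = read_eeg_ascii(path, rate = rate),
                edf = read_edf(path))
  eeg_recording(rec$samples, rec$rate, normalize_labels(rec$labels))
}

# --- minimal EDF (16-bit) support ------------------------------------------
# Single-record layout on write; the reader handles the general multi-record
# case.  Physical min/max are stored as integers so the 8-character ASCII
# header fields never overflow.

#' Write a recording as a minimal EDF file
#'
#' @inheritParams write_eeg_ascii
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- length(rec$labels)
  n_samp <- ncol(rec$samples)
  dur <- n_samp / rec$rate
  dur_str <- formatC(dur, format = "fg", width = 1, digits = 7)
  if (nchar(dur_str) > 8L) stop("record duration does not fit EDF header")
  pad <- function(x, w) formatC(substr(as.character(x), 1L, w),
                                width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wrs <- function(s) writeChar(s, con, eos = NULL)
  wr <- function(x, w) wrs(paste(pad(x, w), collapse = ""))
  wr("0", 8); wr("X", 80); wr("Startdate X", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256L * (1L + ns), 8); wr("", 44); wr(1L, 8); wr(dur_str, 8); wr(ns, 4)
  pmin_ <- floor(apply(rec$samples, 1L, min))
  pmax_ <- ceiling(apply(rec$samples, 1L, max))
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  wr(rec$labels, 16); wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  wr(pmin_, 8); wr(pmax_, 8)
  wr(rep(-32767L, ns), 8); wr(rep(32767L, ns), 8)
  wr(rep("", ns), 80)
  wr(rep(n_samp, ns), 8); wr(rep("", ns), 32)
  for (ch in seq_len(ns)) {
    dig <- round((rec$samples[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) *
                   65534 - 32767)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1L))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  out <- vector("list", ns)
  for (i in seq_len(ns)) out[[i]] <- numeric(0L)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      out[[i]] <- c(out[[i]], (dig - dmin_[i]) *
                      (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) + pmin_[i])
    }
  }
  samples <- do.call(rbind, out)
  list(samples = samples, rate = spr[1L] / dur, labels = labels)
}

# --- region configuration ---------------------------------------------------

#' Anterior/posterior region assignment for regional centrality
#'
#' Default sets follow the convention of splitting the scalp into an
#' anterior set (Fp1, Fp2, F7, F8, F3, F4, Fz) and a posterior set
#' (T5, T6, P3, P4, Pz, O1, O2) of equal size, with the central row
#' (C3, C4, Cz) left out so every regional node is unambiguously frontal or
#' non-frontal.
#'
#' @param anterior,posterior,excluded character vectors of electrode labels;
#'   must be pairwise disjoint.
#' @return Object of class `region_config`.
#' @export
region_config <- function(anterior = c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz"),
                          posterior = c("T5", "T6", "P3", "P4", "Pz", "O1", "O2"),
                          excluded = c("C3", "C4", "Cz")) {
  sets <- list(anterior = anterior, posterior = posterior, excluded = excluded)
  all_lab <- unlist(sets)
  if (anyDuplicated(all_lab))
    stop("region sets must be disjoint; duplicated: ",
         paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  structure(sets, class = "region_config")
}

#' @rdname region_config
#' @param path JSON file with `anterior`/`posterior`/`excluded` arrays.
#' @export
read_region_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_config(anterior = cfg$anterior, posterior = cfg$posterior,
                excluded = if (is.null(cfg$excluded)) character(0) else cfg$excluded)
}

#' @rdname region_config
#' @param regions a `region_config` to serialize.
#' @export
write_region_config <- function(regions, path) {
  jsonlite::write_json(unclass(regions), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
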