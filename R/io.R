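# Plain-text I/O and multichannel orchestration.  Signals travel as
# delimited numeric columns (one column per channel, whitespace or comma
# separated, optional single header line); spectra as a frequency column
# followed by one value column per emission.

split_fields <- function(line) {
  line <- sub("^\\s+", "", sub("\\s+$", "", line))
  if (grepl(",", line, fixed = TRUE)) {
    trimws(strsplit(line, ",", fixed = TRUE)[[1]])
  } else {
    strsplit(line, "\\s+")[[1]]
  }
}

#' Read multichannel signals from a delimited text file
#'
#' Accepts whitespace- or comma-delimited numeric columns, one channel per
#' column, with an optional single header line.  Every data row must have
#' the same number of fields and every field must parse as a number.
#'
#' @param path file to read.
#' @param rate sample rate (Hz) to attach to every channel.
#' @return List of [nse_signal], one per column, `channel` set from the
#'   header (or column number).
#' @export
read_signals <- function(path, rate) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("input file is empty: %s", path))
  first <- split_fields(lines[[1]])
  header <- suppressWarnings(anyNA(as.numeric(first)))
  names_out <- if (header) first else NULL
  data_lines <- if (header) lines[-1] else lines
  offset <- if (header) 1L else 0L
  if (length(data_lines) == 0) stop("no data rows after header")
  ncol0 <- length(split_fields(data_lines[[1]]))
  cols <- matrix(NA_real_, nrow = length(data_lines), ncol = ncol0)
  for (r in seq_along(data_lines)) {
    fields <- split_fields(data_lines[[r]])
    if (length(fields) != ncol0) {
      stop(sprintf("ragged input: line %d has %d fields, expected %d",
                   r + offset, length(fields), ncol0))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("parse error at line %d: non-numeric token '%s'",
                   r + offset, fields[which(is.na(vals))[1]]))
    }
    cols[r, ] <- vals
  }
  lapply(seq_len(ncol0), function(j) {
    nse_signal(cols[, j], rate,
               channel = if (!is.null(names_out)) names_out[j] else j)
  })
}

#' Write multichannel signals as delimited text
#'
#' One column per channel, space separated, with a header row of channel
#' labels; the format round-trips through [read_signals()].
#'
#' @param signals list of [nse_signal] of equal length.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  if (length(signals) == 0) stop("no signals to write")
  lens <- vapply(signals, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1) stop("ragged input: signals have unequal lengths")
  m <- vapply(signals, `[[`, numeric(lens[1]), "samples")
  if (is.null(dim(m))) m <- matrix(m, ncol = length(signals))
  colnames(m) <- vapply(seq_along(signals), function(j) {
    ch <- signals[[j]]$channel
    lab <- if (is.null(ch)) as.character(j) else as.character(ch)
    # purely numeric labels would be indistinguishable from a data row
    if (grepl("^[0-9.eE+-]*$", lab)) paste0("ch", lab) else lab
  }, character(1))
  write.table(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spectra as delimited text
#'
#' First column is frequency in ascending Hz; each subsequent column holds
#' the spectral values at one emission, with a header row `frequency`
#' followed by the emission sample indices (`t<k>`).  Periods are
#' recoverable as `rate / frequency`.
#'
#' @param spectra an [nse_spectrum], a list of them (sharing one grid), or
#'   an [nse_spectrum_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  if (inherits(spectra, "nse_spectrum")) spectra <- list(spectra)
  if (inherits(spectra, "nse_spectrum_set")) {
    grid <- spectra$grid
    V <- spectra$values
    tk <- spectra$time_index
  } else {
    if (!is.list(spectra) || length(spectra) == 0 ||
        !all(vapply(spectra, inherits, logical(1), "nse_spectrum"))) {
      stop("write_spectra needs one or more spectra")
    }
    grid <- spectra[[1]]$grid
    V <- vapply(spectra, `[[`, numeric(length(grid$periods)), "values")
    if (is.null(dim(V))) V <- matrix(V, ncol = length(spectra))
    tk <- vapply(seq_along(spectra), function(i) {
      k <- spectra[[i]]$time_index
      if (is.null(k)) i else as.integer(k)
    }, integer(1))
  }
  out <- cbind(frequency = grid$frequencies, V)
  colnames(out) <- c("frequency", paste0("t", tk))
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra written by [write_spectra()]
#'
#' @param path file to read.
#' @param rate sample rate (Hz) used to rebuild the period grid.
#' @return An [nse_spectrum_set].
#' @export
read_spectra <- function(path, rate) {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  freqs <- tab[[1]]
  periods <- as.integer(round(rate / freqs))
  grid <- structure(list(periods = periods, frequencies = rate / periods,
                         rate = rate, band = range(rate / periods)),
                    class = "nse_grid")
  tk <- as.integer(sub("^t", "", names(tab)[-1]))
  m <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(m) <- NULL
  nse_spectrum_set(grid, m, tk)
}

#' Stream many channels and tabulate spectral parameters
#'
#' Runs an independent streaming estimator per channel (each with its own
#' ring buffers and running powers), extracts DA/DF/MP/SP at every
#' emission, and reports the mean wall-clock cost per sample update per
#' channel.  Timing is informational only — it depends entirely on the
#' host — and is never part of any correctness contract.
#'
#' @param signals list of normalized [nse_signal] of equal length and
#'   rate.
#' @param config an [nse_stream_config].
#' @param emit_every emission stride in samples (default: one final
#'   spectrum per channel).
#' @return List of class `nse_multichannel_result` with fields `params`
#'   (data.frame: channel, time_index, DA, DF, MP, SP), `final_spectra`
#'   (list of [nse_spectrum]) and `timing` (data.frame: channel, seconds,
#'   per_update_us).
#' @export
run_multichannel_stream <- function(signals, config, emit_every = NULL) {
  if (length(signals) == 0) stop("no channels supplied")
  stopifnot(all(vapply(signals, inherits, logical(1), "nse_signal")))
  lens <- vapply(signals, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1) stop("ragged input: channels have unequal lengths")
  rates <- vapply(signals, `[[`, numeric(1), "rate")
  if (length(unique(rates)) != 1) stop("channels have mixed sample rates")
  if (is.null(emit_every)) emit_every <- lens[1]
  params <- vector("list", length(signals))
  finals <- vector("list", length(signals))
  timing <- data.frame(channel = seq_along(signals), seconds = NA_real_,
                       per_update_us = NA_real_)
  for (ch in seq_along(signals)) {
    tt <- system.time({
      set <- run_stream(signals[[ch]], config, emit_every = emit_every)
      p <- spectral_params(set)
    })["elapsed"]
    p$channel <- ch
    params[[ch]] <- p[, c("channel", "time_index", "DA", "DF", "MP", "SP")]
    finals[[ch]] <- get_spectrum(set, length(set))
    timing$seconds[ch] <- unname(tt)
    timing$per_update_us[ch] <- unname(tt) / lens[1] * 1e6
  }
  structure(list(params = do.call(rbind, params), final_spectra = finals,
                 timing = timing),
            class = "nse_multichannel_result")
}

#' @export
print.nse_multichannel_result <- function(x, ...) {
  cat(sprintf("<nse_multichannel_result> %d channels, %d parameter rows; mean %.1f us/update/channel\n",
              length(x$final_spectra), nrow(x$params),
              mean(x$timing$per_update_us)))
  invisible(x)
}
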