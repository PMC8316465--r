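# Fixed-bin signal tracks: the package's representation of per-base ChIP-seq
# coverage. Values are reads per bin; RPM scaling (reads * 1e6 / library_size)
# is applied on demand so one track serves both count-based and
# density-based consumers.

#' Construct a fixed-bin signal track
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome; element `i` covers `[(i-1)*bin_size, i*bin_size)`.
#' @param bin_size Bin width in bp.
#' @param library_size Total mapped reads; defaults to the sum of all values.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, library_size = NULL) {
  if (is.numeric(values)) values <- list(chr = values)
  stopifnot(is.list(values), length(values) > 0, !is.null(names(values)))
  ok <- map_lgl(values, function(v) all(is.finite(v)) && all(v >= 0))
  if (!all(ok)) abort("signal_track: all values must be finite and >= 0")
  if (!is.numeric(bin_size) || bin_size <= 0) abort("signal_track: bin_size must be > 0")
  # an all-zero track is legitimate (RPM of zero is zero); only an explicit
  # non-positive library size is an error
  library_size <- library_size %||% max(sum(map_dbl(values, sum)), 1)
  if (library_size <= 0) abort("signal_track: library_size must be > 0")
  structure(
    list(values = values, bin_size = bin_size, library_size = library_size),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "<signal_track> %d chrom(s), bin %d bp, library %.3g reads\n",
    length(x$values), as.integer(x$bin_size), x$library_size
  ))
  invisible(x)
}

track_extent <- function(track, chrom) {
  if (!chrom %in% names(track$values)) {
    abort(sprintf("chromosome '%s' not present in track", chrom))
  }
  length(track$values[[chrom]]) * track$bin_size
}

# Vectorised windowed sums with linear proration of partial bins.
# values are per-bin; [starts, ends) in bp. Core of window_sum() and the
# TSS-window machinery.
window_sums_vec <- function(values, bin_size, starts, ends) {
  cs <- c(0, cumsum(values))
  n <- length(values)
  at <- function(x) {
    # prefix sum of the per-bp expansion, evaluated at bp coordinate x
    i <- pmin(pmax(floor(x / bin_size), 0), n)
    frac <- x / bin_size - i
    extra <- ifelse(i < n, values[pmin(i + 1, n)] * frac, 0)
    cs[i + 1] + extra
  }
  at(ends) - at(starts)
}

#' Sum signal over an interval
#'
#' Sums bin values overlapping `[start, end)`, prorating partial bins by
#' their overlap fraction, optionally scaled to reads per million.
#'
#' @param track A [signal_track()].
#' @param chrom,start,end Interval to sum over (0-based half-open bp).
#' @param as_rpm If `TRUE`, scale by `1e6 / library_size`.
#' @return A single non-negative number (vectorised over equal-length
#'   `start`/`end`).
#' @export
window_sum <- function(track, chrom, start, end, as_rpm = FALSE) {
  stopifnot(inherits(track, "signal_track"))
  ext <- track_extent(track, chrom)
  if (any(start < 0) || any(end > ext) || any(start >= end)) {
    abort(sprintf(
      "window_sum: interval outside track extent [0, %d) on %s", as.integer(ext), chrom
    ))
  }
  s <- window_sums_vec(track$values[[chrom]], track$bin_size, start, end)
  if (as_rpm) s <- s * 1e6 / track$library_size
  s
}

#' Read a fixed-bin bedGraph file into a signal track
#'
#' Expects every record to start and end on a multiple of `bin_size`
#' (the package's own bedGraph exports satisfy this); zero bins may be
#' omitted from the file.
#'
#' @param path bedGraph path.
#' @param bin_size Bin width in bp.
#' @param library_size Total mapped reads; defaults to the sum of values.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp used
#'   to right-pad with zero bins.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, bin_size, library_size = NULL, chrom_lengths = NULL) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = "ciid", comment = "#", progress = FALSE
  )
  if (nrow(x) == 0) abort("read_bedgraph: empty file")
  if (any(x$start %% bin_size != 0)) {
    abort("read_bedgraph: record not aligned to bin_size")
  }
  vals <- map(split(x, x$chrom), function(d) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[d$chrom[1]]] else max(d$end)
    v <- numeric(ceiling(len / bin_size))
    for (k in seq_len(nrow(d))) {
      i0 <- d$start[k] / bin_size + 1
      i1 <- ceiling(d$end[k] / bin_size)
      v[i0:i1] <- d$value[k]
    }
    v
  })
  signal_track(vals, bin_size, library_size)
}

#' Write a signal track as bedGraph
#'
#' Adjacent equal-valued bins are run-length collapsed; zero bins are omitted.
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  lines <- unlist(imap(track$values, function(v, chrom) {
    r <- rle(v)
    end_bin <- cumsum(r$lengths)
    start_bin <- end_bin - r$lengths
    keep <- r$values != 0
    sprintf(
      "%s\t%d\t%d\t%s",
      chrom,
      as.integer(start_bin[keep] * track$bin_size),
      as.integer(end_bin[keep] * track$bin_size),
      format(r$values[keep], trim = TRUE, scientific = FALSE)
    )
  }), use.names = FALSE)
  readr::write_lines(lines, path)
  invisible(path)
}
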