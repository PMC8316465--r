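# Interval algebra and readers/writers for the tabular genomic formats the
# pipeline consumes. All internal coordinates are 0-based half-open (BED
# convention); 1-based formats (GTF) are converted at the boundary.

#' Build a tibble of genomic intervals
#'
#' The atom of all interval work in markwise: a tibble with columns `chrom`,
#' `start`, `end` (0-based half-open) and optionally `strand`. Validates the
#' interval invariants (`0 <= start < end`, non-empty `chrom`).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors; 0-based half-open span.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."`.
#' @param ... Further columns carried along (e.g. `name`, `score`).
#' @return A tibble with one row per interval.
#' @export
#' @examples
#' genomic_interval("chr1", 100, 200)
genomic_interval <- function(chrom, start, end, strand = ".", ...) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = strand,
    ...
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, where = "intervals") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end) | is.na(x$chrom) | x$chrom == "")
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid interval at row %d (need 0 <= start < end and non-empty chrom)",
      where, bad[1]
    ))
  }
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
    abort(sprintf("%s: strand must be one of '+', '-', '.'", where))
  }
  invisible(x)
}

#' Read peaks from BED3/BED6/narrowPeak files
#'
#' Intervals are kept 0-based half-open exactly as in the file, in stable file
#' order. For narrowPeak input, column 10 (point-source offset) is mapped to
#' `summit_offset`; the conventional `-1` sentinel becomes `NA`.
#'
#' @param path Path to a BED3, BED6 or ENCODE narrowPeak file.
#' @return A tibble of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit_offset`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      name = character(), score = numeric(), strand = character(),
      summit_offset = numeric()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    abort(sprintf("read_bed: line %d has fewer than 3 columns", which(ncol < 3)[1]))
  }
  getcol <- function(i) map_chr(fields, function(f) if (length(f) >= i) f[i] else NA_character_)
  start <- suppressWarnings(as.numeric(getcol(2)))
  end <- suppressWarnings(as.numeric(getcol(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad) > 0) {
    abort(sprintf("read_bed: line %d has non-integer coordinates", bad[1]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("read_bed: line %d violates 0 <= start < end", bad[1]))
  }
  x <- tibble(
    chrom = getcol(1), start = start, end = end,
    name = if (max(ncol) >= 4) getcol(4) else NA_character_,
    score = if (max(ncol) >= 5) suppressWarnings(as.numeric(getcol(5))) else NA_real_,
    strand = if (max(ncol) >= 6) getcol(6) else "."
  )
  x$name[is.na(x$name)] <- paste0("peak_", which(is.na(x$name)))
  x$strand[is.na(x$strand) | !(x$strand %in% c("+", "-", "."))] <- "."
  # narrowPeak: 10 columns, 10th is the summit offset from start (-1 = absent)
  if (all(ncol == 10)) {
    so <- suppressWarnings(as.numeric(getcol(10)))
    so[!is.na(so) & so < 0] <- NA_real_
    bad <- which(!is.na(so) & so >= (end - start))
    if (length(bad) > 0) {
      abort(sprintf("read_bed: line %d summit offset outside peak", bad[1]))
    }
    x$summit_offset <- so
  } else {
    x$summit_offset <- NA_real_
  }
  validate_intervals(x, where = "read_bed")
  x
}

#' Write intervals to a BED6 file
#'
#' @param x Tibble of intervals; `name`, `score`, `strand` are filled with BED
#'   conventions (`.`, `0`, `.`) when missing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, where = "write_bed")
  nm <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  sc <- if ("score" %in% names(x)) x$score else rep(0, nrow(x))
  sc[is.na(sc)] <- 0
  st <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  sc_str <- if_else(
    sc == floor(sc),
    sprintf("%d", as.integer(sc)),
    sub("0+$", "", sprintf("%.6f", sc))
  )
  out <- sprintf(
    "%s\t%d\t%d\t%s\t%s\t%s",
    x$chrom, as.integer(x$start), as.integer(x$end), nm, sc_str, st
  )
  readr::write_lines(out, path)
  invisible(path)
}

#' Read gene annotations (GTF or TSV-of-TSS dialect)
#'
#' GTF coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention; the TSV dialect (columns `gene_id`, `gene_name`,
#' `chrom`, `start`, `end`, `strand`) is already 0-based. One record is kept
#' per `gene_id`; when a gene has several transcripts the first-listed TSS is
#' used and a warning is emitted. The TSS of a `-` strand gene is `end - 1`
#' (the last covered base).
#'
#' @param path Path to the annotation file.
#' @param dialect `"gtf"` or `"tsv"`.
#' @return A tibble with `gene_id`, `gene_name`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") {
    raw <- readr::read_tsv(
      path,
      comment = "#",
      col_names = c(
        "chrom", "source", "feature", "start", "end",
        "score", "strand", "frame", "attributes"
      ),
      col_types = "ccciicccc",
      progress = FALSE
    )
    raw <- filter(raw, .data$feature %in% c("gene", "transcript"))
    get_attr <- function(a, key) {
      m <- stringr::str_match(a, paste0(key, "[ =]+\"?([^\";]+)\"?"))
      m[, 2]
    }
    x <- tibble(
      gene_id = get_attr(raw$attributes, "gene_id"),
      gene_name = get_attr(raw$attributes, "gene_name"),
      chrom = raw$chrom,
      start = raw$start - 1, # 1-based inclusive -> 0-based half-open
      end = as.numeric(raw$end),
      strand = raw$strand
    )
    x$gene_name[is.na(x$gene_name)] <- x$gene_id[is.na(x$gene_name)]
  } else {
    x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(x))) {
      abort(sprintf(
        "read_gene_annotation: tsv dialect needs columns %s",
        paste(need, collapse = ", ")
      ))
    }
    if (!"gene_name" %in% names(x)) x$gene_name <- x$gene_id
    x <- select(
      x, "gene_id", "gene_name", "chrom", "start", "end", "strand",
      dplyr::any_of("tss")
    )
  }
  conflicting <- x |>
    distinct(.data$gene_id, .data$strand) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(conflicting) > 0) {
    abort(sprintf(
      "read_gene_annotation: gene_id '%s' has conflicting strands",
      conflicting$gene_id[1]
    ))
  }
  dup <- duplicated(x$gene_id)
  if (any(dup)) {
    warn(sprintf(
      "read_gene_annotation: %d gene_id(s) with multiple records; keeping the first-listed TSS",
      length(unique(x$gene_id[dup]))
    ))
    x <- x[!dup, , drop = FALSE]
  }
  if (!"tss" %in% names(x)) {
    x$tss <- if_else(x$strand == "-", x$end - 1, x$start)
  }
  validate_intervals(x, where = "read_gene_annotation")
  stopifnot(all(x$tss >= x$start & x$tss < x$end))
  x
}

#' Merge intervals closer than a maximum gap
#'
#' The shared kernel behind enhancer stitching: intervals whose gap
#' (`next.start - prev.end`) is at most `max_gap` are unioned. With
#' `max_gap = 0` this is the classic overlap-union. Delegates to
#' [IRanges::reduce()] per chromosome.
#'
#' @param x Tibble of intervals.
#' @param max_gap Maximum gap (bp) across which to merge; `>= 0`.
#' @return A tibble of merged intervals sorted by (`chrom`, `start`), with a
#'   column `n_merged` counting constituent input intervals.
#' @export
#' @examples
#' merge_intervals(genomic_interval("chr1", c(0, 5000), c(1000, 6000)), 12500)
merge_intervals <- function(x, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || max_gap < 0) {
    abort("merge_intervals: max_gap must be a single number >= 0")
  }
  validate_intervals(x, where = "merge_intervals")
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(), n_merged = integer()))
  }
  x |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(start = d$start + 1, end = d$end) # to 1-based closed
      red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1, with.revmap = TRUE)
      tibble(
        start = as.numeric(IRanges::start(red)) - 1,
        end = as.numeric(IRanges::end(red)),
        n_merged = lengths(S4Vectors::mcols(red)$revmap)
      )
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}
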