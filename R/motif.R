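# PWM construction from JASPAR-style count matrices and strand-aware
# scanning at a relative-score threshold. The relative score is the min-max
# scaled log2-odds score, the convention under which a ">95% consensus" site
# means relative_score >= 0.95.

BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from base counts
#'
#' Column probabilities are `(count + pseudocount * bg) / (colsum +
#' pseudocount)` and entries are `log2(p / bg)`. The default pseudocount of
#' 0.8 split by the background follows common JASPAR tooling practice.
#'
#' @param counts A 4 x L numeric matrix (rows A, C, G, T) of base counts.
#' @param pseudocount Total pseudocount per column (> 0 unless every column
#'   has all four bases observed).
#' @param background Background base probabilities (length 4, sums to 1).
#' @param motif_id Identifier carried in the result.
#' @return A `pwm` object with the log2-odds `matrix`, per-position score
#'   bounds, and the consensus sequence.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.8,
                            background = rep(0.25, 4), motif_id = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("pwm_from_counts: counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort("pwm_from_counts: negative counts")
  if (abs(sum(background) - 1) > 1e-8) abort("pwm_from_counts: background must sum to 1")
  if (pseudocount <= 0 && any(colSums(counts > 0) < 4)) {
    abort("pwm_from_counts: zero counts need a positive pseudocount")
  }
  rownames(counts) <- BASES
  p <- sweep(counts, 1, background * pseudocount, "+")
  p <- sweep(p, 2, colSums(counts) + pseudocount, "/")
  mat <- log2(sweep(p, 1, background, "/"))
  structure(
    list(
      motif_id = motif_id, matrix = mat, background = background,
      pseudocount = pseudocount, length = ncol(mat),
      min_score = sum(apply(mat, 2, min)),
      max_score = sum(apply(mat, 2, max)),
      consensus = paste(BASES[apply(mat, 2, which.max)], collapse = "")
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "<pwm> %s, length %d, consensus %s, score range [%.3f, %.3f]\n",
    x$motif_id, x$length, x$consensus, x$min_score, x$max_score
  ))
  invisible(x)
}

#' Read motif count matrices in JASPAR PFM text format
#'
#' Accepts both the bracketed (`A [ 1 2 3 ]`) and the raw 4-row layout; files
#' may contain several motifs, each introduced by a `>` header.
#'
#' @param path Path to a JASPAR .pfm / .jaspar text file.
#' @return A named list of count matrices (4 x L, rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) {
    heads <- 0
    lines <- c(">motif", lines)
    heads <- 1
  }
  out <- list()
  bounds <- c(heads, length(lines) + 1)
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(bounds[k] + 1):(bounds[k + 1] - 1)]
    if (length(body) != 4) {
      abort(sprintf("read_jaspar: motif '%s' does not have 4 matrix rows", id))
    }
    rows <- map(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      abort(sprintf("read_jaspar: ragged matrix for motif '%s'", id))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- BASES
    out[[id]] <- m
  }
  out
}

#' Write a count matrix in JASPAR PFM text format
#'
#' @param counts 4 x L matrix.
#' @param motif_id Header identifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(counts, motif_id, path) {
  lines <- c(
    paste0(">", motif_id),
    sprintf(
      "%s  [ %s ]", BASES,
      apply(counts, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# integer-encode A/C/G/T as 1..4, N and anything else as NA
encode_seq <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], BASES)
  v
}

scan_one_strand <- function(codes, mat) {
  L <- ncol(mat)
  n <- length(codes) - L + 1
  if (n < 1) {
    return(numeric(0))
  }
  score <- numeric(n)
  valid <- rep(TRUE, n)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n - 1)]
    ok <- !is.na(cj)
    valid <- valid & ok
    idx <- cj
    idx[!ok] <- 1
    score <- score + mat[cbind(idx, j)]
  }
  score[!valid] <- NA_real_
  score
}

#' Scan a sequence for motif hits at a relative-score threshold
#'
#' Every length-L window is scored on the forward strand and against the
#' reverse complement; hits are windows with
#' `relative_score = (raw - min) / (max - min) >= min_relative_score`.
#' Windows containing N are skipped. Coordinates are 0-based half-open on the
#' forward strand.
#'
#' @param seq A character DNA sequence (A/C/G/T/N).
#' @param pwm A [pwm_from_counts()] object.
#' @param min_relative_score Threshold in `[0, 1]`; default 0.95 (the ">95%
#'   consensus" operating point).
#' @param both_strands Also scan the reverse strand (default `TRUE`).
#' @param chrom Chromosome label for the output intervals.
#' @param offset Added to the output coordinates (for scanning a subsequence
#'   of a chromosome).
#' @return Tibble of hits: `chrom`, `start`, `end`, `strand`, `raw_score`,
#'   `relative_score`, ordered by `start` then strand.
#' @export
scan_motif <- function(seq, pwm, min_relative_score = 0.95,
                       both_strands = TRUE, chrom = "seq", offset = 0) {
  stopifnot(inherits(pwm, "pwm"))
  if (min_relative_score < 0 || min_relative_score > 1) {
    abort("scan_motif: min_relative_score must be in [0, 1]")
  }
  L <- pwm$length
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    strand = character(), raw_score = numeric(), relative_score = numeric()
  )
  if (nchar(seq) < L) {
    warn("scan_motif: sequence shorter than motif; no windows to scan")
    return(empty)
  }
  codes <- encode_seq(seq)
  denom <- pwm$max_score - pwm$min_score
  rel <- function(raw) (raw - pwm$min_score) / denom
  collect <- function(scores, strand) {
    r <- rel(scores)
    i <- which(!is.na(r) & r >= min_relative_score)
    if (length(i) == 0) {
      return(empty)
    }
    tibble(
      chrom = chrom, start = offset + i - 1, end = offset + i - 1 + L,
      strand = strand, raw_score = scores[i], relative_score = r[i]
    )
  }
  fwd <- collect(scan_one_strand(codes, pwm$matrix), "+")
  out <- fwd
  if (both_strands) {
    # scanning with the reverse-complemented matrix on the forward sequence
    # equals scanning the reverse strand
    rc_mat <- pwm$matrix[4:1, L:1, drop = FALSE]
    rev_hits <- collect(scan_one_strand(codes, rc_mat), "-")
    out <- bind_rows(fwd, rev_hits)
  }
  arrange(out, .data$start, .data$strand)
}
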