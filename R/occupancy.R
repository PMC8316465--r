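# Peak-to-TSS assignment, TSS-window signal matrices, and per-gene per-mark
# differential occupancy. Windows default to TSS +/- 2 kb (promoter-proximal)
# with TSS +/- 5 kb available for broader aggregates.

#' Histone marks and their polarity
#'
#' The active marks H3K4me3 (promoters), H3K4me1 and H3K27ac (enhancers) carry
#' polarity +1; the Polycomb-associated repressive mark H3K27me3 carries -1.
#' Polarity drives the congruence rule in [congruence_classify()].
#'
#' @return A tibble with columns `mark` and `polarity`.
#' @export
mark_polarity <- function() {
  tibble(
    mark = c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3"),
    polarity = c(1, 1, 1, -1)
  )
}

#' Assign each peak to its nearest TSS
#'
#' The reference point is the peak summit when `summit_offset` is present,
#' otherwise the midpoint `floor((start + end) / 2)`. Each peak gets the gene
#' minimizing `|reference - tss|`; exact ties go to the smaller TSS
#' coordinate. Distance is reported signed as `tss - reference`. Peaks on
#' chromosomes absent from the annotation are returned unassigned with a
#' message.
#'
#' @param peaks Tibble of peaks (`chrom`, `start`, `end`, optionally
#'   `summit_offset`).
#' @param annotation Gene annotation tibble with `gene_id`, `chrom`, `tss`.
#' @return `peaks` with columns `gene_id` and `tss_distance` added.
#' @export
assign_nearest_tss <- function(peaks, annotation) {
  validate_intervals(peaks, "assign_nearest_tss")
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(annotation)))
  mid <- floor((peaks$start + peaks$end) / 2)
  if ("summit_offset" %in% names(peaks)) {
    has <- !is.na(peaks$summit_offset)
    mid[has] <- peaks$start[has] + peaks$summit_offset[has]
  }
  out_gene <- rep(NA_character_, nrow(peaks))
  out_dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (nrow(ann) == 0) next
    ord <- order(ann$tss, ann$gene_id)
    tss <- ann$tss[ord]
    ids <- ann$gene_id[ord]
    m <- mid[pi]
    # index of rightmost tss <= m
    left <- findInterval(m, tss)
    right <- pmin(left + 1, length(tss))
    left <- pmax(left, 1)
    dl <- abs(m - tss[left])
    dr <- abs(m - tss[right])
    pick <- if_else(dl <= dr, left, right) # tie -> left = smaller tss
    out_gene[pi] <- ids[pick]
    out_dist[pi] <- tss[pick] - m
  }
  if (anyNA(out_gene)) {
    inform(sprintf(
      "assign_nearest_tss: %d peak(s) on chromosomes absent from annotation left unassigned",
      sum(is.na(out_gene))
    ))
  }
  mutate(peaks, gene_id = out_gene, tss_distance = out_dist)
}

#' Per-gene TSS-window signal matrix
#'
#' RPM per bin over `[tss - halfwidth, tss + halfwidth)` for every gene,
#' orientation flipped for `-` strand genes so that bin 1 is always the
#' upstream edge. Windows running off a chromosome end are zero-padded with a
#' warning.
#'
#' @param track A [signal_track()].
#' @param annotation Gene annotation tibble.
#' @param halfwidth Window half-width in bp (2000 and 5000 are the
#'   conventional promoter-proximal and broad choices).
#' @param n_bins Number of output bins; must divide `2 * halfwidth`.
#' @param as_rpm Scale to reads per million (default) or raw sums.
#' @return A genes x bins matrix with `gene_id` rownames.
#' @export
tss_window_matrix <- function(track, annotation, halfwidth = 2000, n_bins = 40,
                              as_rpm = TRUE) {
  stopifnot(inherits(track, "signal_track"))
  if ((2 * halfwidth) %% n_bins != 0) {
    abort("tss_window_matrix: n_bins must divide 2 * halfwidth")
  }
  w <- 2 * halfwidth / n_bins
  out <- matrix(0, nrow(annotation), n_bins,
    dimnames = list(annotation$gene_id, NULL)
  )
  clipped <- 0
  for (ch in unique(annotation$chrom)) {
    ai <- which(annotation$chrom == ch)
    ext <- track_extent(track, ch)
    vals <- track$values[[ch]]
    for (i in ai) {
      lo <- annotation$tss[i] - halfwidth
      edges <- lo + (0:n_bins) * w
      cl_edges <- pmin(pmax(edges, 0), ext)
      if (edges[1] < 0 || edges[n_bins + 1] > ext) clipped <- clipped + 1
      s <- window_sums_vec(vals, track$bin_size, cl_edges[-(n_bins + 1)], cl_edges[-1])
      s[cl_edges[-(n_bins + 1)] >= cl_edges[-1]] <- 0
      if (annotation$strand[i] == "-") s <- rev(s)
      out[i, ] <- s
    }
  }
  if (clipped > 0) {
    warn(sprintf("tss_window_matrix: %d window(s) clipped at a chromosome edge (zero-padded)", clipped))
  }
  if (as_rpm) out <- out * 1e6 / track$library_size
  out
}

#' Metaprofile plot over TSS windows
#'
#' @param mat A matrix from [tss_window_matrix()].
#' @param halfwidth The half-width used to build it (for the x axis).
#' @param label Optional series label.
#' @return A ggplot object showing the column-mean signal profile.
#' @export
plot_tss_profile <- function(mat, halfwidth = 2000, label = "signal") {
  d <- tibble(
    pos = seq(-halfwidth, halfwidth, length.out = ncol(mat) + 1)[-1] -
      halfwidth / ncol(mat),
    mean_rpm = colMeans(mat),
    series = label
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$pos, .data$mean_rpm, color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean RPM", color = NULL) +
    ggplot2::theme_minimal()
}

#' Differential histone-mark occupancy in TSS windows
#'
#' Window read counts are reconstructed from each replicate track (raw bin
#' sums over `[tss - halfwidth, tss + halfwidth)`, rounded) and tested with
#' the package's NB-Wald engine using median-of-ratios size factors computed
#' on the window counts (library-size factors as fallback), robust to
#' composition shifts between conditions;
#' Benjamini-Hochberg FDR is computed within the mark. `direction_call` is
#' `increased` / `decreased` when `fdr <= occupancy_fdr_max` (default 0.05),
#' else `ns`.
#'
#' @param case_tracks,control_tracks Lists of replicate [signal_track()]s
#'   (>= 2 each for a p-value); all tracks must share `bin_size`.
#' @param annotation Gene annotation tibble.
#' @param mark Mark name (stored in the output).
#' @param halfwidth Window half-width in bp.
#' @param occupancy_fdr_max FDR threshold for the direction call.
#' @return A tibble with `gene_id`, `mark`, `window`, `rpm_control`,
#'   `rpm_case`, `log2_ratio`, `p`, `fdr`, `direction_call`.
#' @export
differential_occupancy <- function(case_tracks, control_tracks, annotation,
                                   mark = "mark", halfwidth = 2000,
                                   occupancy_fdr_max = 0.05) {
  all_tracks <- c(control_tracks, case_tracks)
  bs <- unique(map_dbl(all_tracks, function(t) t$bin_size))
  if (length(bs) != 1) abort("differential_occupancy: tracks have mismatched bin sizes")
  window_counts <- function(track) {
    sums <- numeric(nrow(annotation))
    for (ch in unique(annotation$chrom)) {
      ai <- which(annotation$chrom == ch)
      ext <- track_extent(track, ch)
      lo <- pmax(annotation$tss[ai] - halfwidth, 0)
      hi <- pmin(annotation$tss[ai] + halfwidth, ext)
      sums[ai] <- window_sums_vec(track$values[[ch]], track$bin_size, lo, hi)
    }
    sums
  }
  cnt <- vapply(all_tracks, window_counts, numeric(nrow(annotation)))
  cnt <- round(cnt)
  colnames(cnt) <- c(
    paste0("control_", seq_along(control_tracks)),
    paste0("case_", seq_along(case_tracks))
  )
  rownames(cnt) <- annotation$gene_id
  groups <- rep(c("control", "case"), c(length(control_tracks), length(case_tracks)))
  libs <- map_dbl(all_tracks, function(t) t$library_size)
  # median-of-ratios on the window counts themselves: robust to composition
  # shifts (a strongly amplified region inflates a library-size denominator
  # and would make every other window look depleted)
  sf <- tryCatch(size_factors(cnt), error = function(e) {
    setNames(libs / exp(mean(log(libs))), colnames(cnt))
  })

  rpm <- sweep(cnt, 2, libs / 1e6, "/")
  rpm_control <- rowMeans(rpm[, groups == "control", drop = FALSE])
  rpm_case <- rowMeans(rpm[, groups == "case", drop = FALSE])
  # the reported effect size is the RPM ratio (pseudocount keeps it finite);
  # the p-value comes from the count-based engine below
  rpm_control <- unname(rpm_control)
  rpm_case <- unname(rpm_case)
  log2_rpm_ratio <- log2((rpm_case + 0.5) / (rpm_control + 0.5))

  can_test <- length(case_tracks) >= 2 && length(control_tracks) >= 2
  if (can_test) {
    fit <- test_two_group(cnt, groups, ref = "control", sf = sf)
    tab <- fit$table
  } else {
    norm <- sweep(cnt, 2, sf, "/")
    m1 <- rowMeans(norm[, groups == "control", drop = FALSE])
    m2 <- rowMeans(norm[, groups == "case", drop = FALSE])
    tab <- tibble(
      gene_id = rownames(cnt),
      log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
      p = NA_real_, fdr = NA_real_
    )
  }
  out <- tibble(gene_id = annotation$gene_id) |>
    left_join(select(tab, "gene_id", "p", "fdr"), by = "gene_id") |>
    mutate(
      log2_ratio = log2_rpm_ratio,
      mark = mark,
      window = paste0("tss_pm_", halfwidth),
      rpm_control = rpm_control,
      rpm_case = rpm_case,
      direction_call = factor(
        case_when(
          !is.na(.data$fdr) & .data$fdr <= occupancy_fdr_max & .data$log2_ratio > 0 ~ "increased",
          !is.na(.data$fdr) & .data$fdr <= occupancy_fdr_max & .data$log2_ratio < 0 ~ "decreased",
          TRUE ~ "ns"
        ),
        levels = c("increased", "decreased", "ns")
      )
    ) |>
    select(
      "gene_id", "mark", "window", "rpm_control", "rpm_case",
      "log2_ratio", "p", "fdr", "direction_call"
    )
  out
}
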