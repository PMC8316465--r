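# ROSE-style super-enhancer calling: remove promoter-contained peaks, stitch
# the rest across <= 12.5 kb gaps, score stitched regions by
# input-subtracted RPM, rank, and cut the min-max-scaled curve at the first
# point where its forward-difference slope exceeds 1 (the discrete version of
# the "tangent slope 1" hockey-stick geometry).

#' Stitch enhancer peaks into candidate regions
#'
#' Peaks fully contained within `[tss - tss_exclusion, tss + tss_exclusion)`
#' of any TSS are removed before stitching (promoter exclusion; removal is
#' reported); the remainder are merged whenever their gap is at most
#' `stitch_distance`. Defaults are the published ROSE constants.
#'
#' @param peaks Tibble of peaks.
#' @param annotation Gene annotation tibble (used for promoter exclusion);
#'   `NULL` disables exclusion.
#' @param stitch_distance Maximum gap to merge across (bp).
#' @param tss_exclusion Promoter half-width for peak removal (bp).
#' @return A tibble of stitched regions (`chrom`, `start`, `end`,
#'   `n_members`), with the retained member peaks as an attribute
#'   `"members"` mapping each retained peak to its region.
#' @export
stitch <- function(peaks, annotation = NULL, stitch_distance = 12500,
                   tss_exclusion = 2500) {
  if (stitch_distance < 0) abort("stitch: stitch_distance must be >= 0")
  validate_intervals(peaks, "stitch")
  if (nrow(peaks) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(), n_members = integer())
    attr(out, "members") <- mutate(peaks, region = integer(0))
    return(out)
  }
  keep <- rep(TRUE, nrow(peaks))
  if (!is.null(annotation) && tss_exclusion > 0) {
    for (ch in unique(peaks$chrom)) {
      tss <- sort(annotation$tss[annotation$chrom == ch])
      if (length(tss) == 0) next
      pi <- which(peaks$chrom == ch)
      # peak [s, e) is contained in some promoter window iff a tss exists in
      # [e - tss_exclusion, s + tss_exclusion]
      lo <- peaks$end[pi] - tss_exclusion
      hi <- peaks$start[pi] + tss_exclusion
      n_le <- function(x) findInterval(x, tss)
      contained <- hi >= lo & (n_le(hi) - n_le(lo - 1e-9)) > 0
      keep[pi][contained] <- FALSE
    }
    if (any(!keep)) {
      inform(sprintf(
        "stitch: removed %d promoter-contained peak(s) (tss_exclusion %d bp)",
        sum(!keep), as.integer(tss_exclusion)
      ))
    }
  }
  kept <- peaks[keep, , drop = FALSE]
  regions <- merge_intervals(kept, max_gap = stitch_distance)
  regions <- rename(regions, n_members = "n_merged")
  # map members to regions (each retained peak falls in exactly one region)
  members <- kept
  members$region <- NA_integer_
  for (r in seq_len(nrow(regions))) {
    hit <- members$chrom == regions$chrom[r] &
      members$start >= regions$start[r] & members$end <= regions$end[r]
    members$region[hit] <- r
  }
  attr(regions, "members") <- members
  regions
}

#' Score stitched regions by input-subtracted signal
#'
#' `net_signal = max(0, RPM_case(region) - RPM_input(region))`; with no input
#' track the case RPM is used as-is.
#'
#' @param regions Stitched regions from [stitch()].
#' @param case_track Signal track scored (typically pooled H3K27ac).
#' @param input_track Optional input/control track.
#' @return `regions` with `signal_case`, `signal_input`, `net_signal` added.
#' @export
score_regions <- function(regions, case_track, input_track = NULL) {
  if (!is.null(input_track) && input_track$bin_size != case_track$bin_size) {
    abort("score_regions: tracks must share bin_size")
  }
  sig <- map_dbl(seq_len(nrow(regions)), function(i) {
    window_sum(case_track, regions$chrom[i], regions$start[i], regions$end[i], as_rpm = TRUE)
  })
  inp <- if (is.null(input_track)) {
    rep(0, nrow(regions))
  } else {
    map_dbl(seq_len(nrow(regions)), function(i) {
      window_sum(input_track, regions$chrom[i], regions$start[i], regions$end[i], as_rpm = TRUE)
    })
  }
  mutate(regions,
    signal_case = sig, signal_input = inp,
    net_signal = pmax(.data$signal_case - .data$signal_input, 0)
  )
}

#' Rank regions and cut the hockey stick
#'
#' Regions are sorted ascending by `net_signal`; with
#' `x_i = i / (n - 1)` and `y_i = (s_i - s_min) / (s_max - s_min)` the cutoff
#' is the smallest index where the forward-difference slope
#' `(y_(i+1) - y_i) / (x_(i+1) - x_i)` exceeds 1, and regions with
#' `net_signal > cutoff_signal` are super-enhancers. Degenerate inputs (all
#' signals equal, or fewer than 3 regions) yield zero super-enhancers.
#'
#' @param regions Scored regions from [score_regions()].
#' @return An `se_ranking` object; [tidy()] returns the table with `rank`
#'   (1 = strongest), `scaled_x`, `scaled_y`, `is_super`.
#' @export
rank_and_cut <- function(regions) {
  stopifnot(all(c("chrom", "start", "end", "net_signal") %in% names(regions)))
  if (any(regions$net_signal < 0)) abort("rank_and_cut: negative net_signal")
  n <- nrow(regions)
  d <- arrange(regions, .data$net_signal, .data$chrom, .data$start)
  s <- d$net_signal
  degenerate <- n < 3 || diff(range(s)) == 0
  if (degenerate) {
    inform("rank_and_cut: degenerate ranking (n < 3 or constant signal); zero super-enhancers")
    d <- mutate(d,
      scaled_x = if (n > 1) (row_number() - 1) / (n - 1) else 0.5,
      scaled_y = 0, is_super = FALSE
    )
    cutoff <- Inf
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - min(s)) / (max(s) - min(s))
    slope <- diff(y) / diff(x)
    idx <- which(slope > 1)
    if (length(idx) == 0) {
      cutoff <- Inf
    } else {
      cutoff <- s[idx[1]]
    }
    d <- mutate(d, scaled_x = x, scaled_y = y, is_super = .data$net_signal > cutoff)
  }
  d <- mutate(d, rank = rank(-.data$net_signal, ties.method = "first"))
  structure(
    list(table = d, cutoff_signal = cutoff, n_super = sum(d$is_super)),
    class = "se_ranking"
  )
}

#' @export
print.se_ranking <- function(x, ...) {
  cat(sprintf(
    "<se_ranking> %d regions, %d super-enhancer(s), cutoff %.4g\n",
    nrow(x$table), x$n_super, x$cutoff_signal
  ))
  invisible(x)
}

#' @rdname rank_and_cut
#' @param x An `se_ranking`.
#' @param ... Unused.
#' @export
tidy.se_ranking <- function(x, ...) x$table

#' @rdname rank_and_cut
#' @export
glance.se_ranking <- function(x, ...) {
  tibble(
    n_regions = nrow(x$table), n_super = x$n_super,
    cutoff_signal = x$cutoff_signal
  )
}

#' Annotated super-enhancer ranking report
#'
#' Adds the nearest gene (by region midpoint) to each ranked region.
#'
#' @param ranking An `se_ranking`.
#' @param annotation Gene annotation tibble.
#' @return A tibble: one row per region with `rank`, `net_signal`,
#'   `is_super`, `nearest_gene`, `tss_distance`.
#' @export
rank_report <- function(ranking, annotation) {
  stopifnot(inherits(ranking, "se_ranking"))
  d <- ranking$table
  assigned <- assign_nearest_tss(
    select(d, "chrom", "start", "end"), annotation
  )
  d |>
    mutate(
      nearest_gene = assigned$gene_id,
      tss_distance = assigned$tss_distance
    ) |>
    arrange(.data$rank)
}

#' Hockey-stick plot of a super-enhancer ranking
#'
#' @param object An `se_ranking`.
#' @param ... Unused.
#' @return A ggplot of signal vs ascending rank with the cutoff marked.
#' @export
autoplot.se_ranking <- function(object, ...) {
  d <- arrange(object$table, .data$net_signal) |>
    mutate(i = row_number())
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$i, .data$net_signal)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$is_super), size = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey50")) +
    ggplot2::labs(
      x = "regions ranked by signal", y = "input-subtracted signal (RPM)",
      color = "super-enhancer"
    ) +
    ggplot2::theme_minimal()
  if (is.finite(object$cutoff_signal)) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$cutoff_signal,
      linetype = "dashed", color = "grey30"
    )
  }
  p
}
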