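# Viewpoint (4C) interaction profiling with a power-law distance-decay
# background, targeted 3C relative interaction frequencies, and ChIP-qPCR
# percent-input quantification.

#' In-silico restriction digest
#'
#' Cuts a sequence at every occurrence of the recognition site (cut at the
#' site start); the first and last fragments span the chromosome ends.
#' Case-insensitive. With zero sites the whole chromosome is a single
#' fragment (with a warning).
#'
#' @param seq DNA sequence (character) to digest, or `NULL` when
#'   `fragment_lengths` is given.
#' @param site Recognition site over A/C/G/T, length >= 4.
#' @param fragment_lengths Alternative to `seq`: explicit fragment lengths in
#'   bp, used verbatim.
#' @param chrom Chromosome label.
#' @return A tibble fragment map: `frag_id`, `chrom`, `start`, `end`
#'   (0-based half-open, contiguous, sorted).
#' @export
digest <- function(seq = NULL, site = "GATC", fragment_lengths = NULL,
                   chrom = "chr") {
  if (!is.null(fragment_lengths)) {
    stopifnot(all(fragment_lengths > 0))
    ends <- cumsum(fragment_lengths)
    return(tibble(
      frag_id = seq_along(fragment_lengths), chrom = chrom,
      start = c(0, ends[-length(ends)]), end = ends
    ))
  }
  site <- toupper(site)
  if (nchar(site) < 4 || grepl("[^ACGT]", site)) {
    abort("digest: recognition site must be >= 4 bp over A/C/G/T")
  }
  s <- toupper(seq)
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(s))
  cuts <- Biostrings::start(hits) - 1 # 0-based cut positions at site starts
  cuts <- cuts[cuts > 0]
  if (length(cuts) == 0) {
    warn("digest: recognition site absent; returning one whole-chromosome fragment")
  }
  bounds <- c(0, cuts, nchar(s))
  tibble(
    frag_id = seq_len(length(bounds) - 1), chrom = chrom,
    start = bounds[-length(bounds)], end = bounds[-1]
  )
}

#' Build a viewpoint interaction profile
#'
#' Masks the viewpoint fragment and its `exclude_k` neighbours on each side
#' (self-ligation/undigested artifacts), scales the remaining counts to sum
#' to 1e6 (cis normalization), computes midpoint-to-midpoint distances to the
#' viewpoint, and stores a running-mean smoothed profile (window
#' `smooth_w`).
#'
#' @param counts Per-fragment raw counts (one per fragment map row).
#' @param fragments Fragment map from [digest()].
#' @param viewpoint Viewpoint fragment index (row of `fragments`).
#' @param exclude_k Fragments masked on each side of the viewpoint.
#' @param smooth_w Running-mean window (fragments).
#' @param condition Optional condition label.
#' @return An `interaction_profile` object; [tidy()] returns the
#'   per-fragment tibble (`frag_id`, coordinates, `count`, `masked`,
#'   `norm_count`, `smoothed`, `distance`).
#' @export
fourc_profile <- function(counts, fragments, viewpoint, exclude_k = 2,
                          smooth_w = 5, condition = NA_character_) {
  if (length(counts) != nrow(fragments)) {
    abort("fourc_profile: need exactly one count per fragment")
  }
  if (any(counts < 0)) abort("fourc_profile: negative counts")
  if (viewpoint < 1 || viewpoint > nrow(fragments)) {
    abort("fourc_profile: viewpoint index out of range")
  }
  n <- nrow(fragments)
  masked <- abs(seq_len(n) - viewpoint) <= exclude_k
  total <- sum(counts[!masked])
  if (total <= 0) abort("fourc_profile: all unmasked counts are zero")
  norm <- ifelse(masked, NA_real_, counts / total * 1e6)
  mid <- (fragments$start + fragments$end) / 2
  d <- abs(mid - mid[viewpoint])
  sm <- as.numeric(stats::filter(
    tidyr::replace_na(norm, 0),
    rep(1 / smooth_w, smooth_w),
    sides = 2
  ))
  tab <- fragments |>
    mutate(
      count = as.numeric(counts), masked = masked, norm_count = norm,
      smoothed = sm, distance = d
    )
  structure(
    list(
      table = tab, viewpoint = viewpoint, exclude_k = exclude_k,
      condition = condition, decay = NULL
    ),
    class = "interaction_profile"
  )
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf(
    "<interaction_profile> %d fragments, viewpoint %d (+/-%d masked)%s\n",
    nrow(x$table), x$viewpoint, x$exclude_k,
    if (!is.null(x$decay)) {
      sprintf(", decay a=%.3g b=%.3f", x$decay$a, x$decay$b)
    } else {
      ""
    }
  ))
  invisible(x)
}

#' @rdname fourc_profile
#' @param x An `interaction_profile`.
#' @param ... Unused.
#' @export
tidy.interaction_profile <- function(x, ...) x$table

#' Fit a power-law distance-decay background
#'
#' Least squares of `log(count + 1)` on `log(distance)` over unmasked
#' fragments with positive count and distance; the expectation is
#' `a * d^(-b)` with `b` constrained to be positive (a non-decaying fit is
#' flagged). Residual z-scores `(log(obs + 1) - log(exp + 1)) / sd(resid)`
#' are stored per fragment.
#'
#' @param profile An [fourc_profile()] result.
#' @return The profile with `decay = list(a, b, sigma, flat)` filled and
#'   columns `expected` and `z` added to the table.
#' @export
fit_decay <- function(profile) {
  stopifnot(inherits(profile, "interaction_profile"))
  tab <- profile$table
  use <- !tab$masked & tab$count > 0 & tab$distance > 0
  if (sum(use) < 10) abort("fit_decay: need >= 10 unmasked fragments with count > 0")
  fit <- lm(log(count + 1) ~ log(distance), data = tab[use, ])
  slope <- unname(coef(fit)[2])
  b <- max(-slope, 0)
  flat <- b < 1e-6
  if (flat) {
    warn("fit_decay: no distance decay detected (b at the 0 boundary)")
    b <- 1e-6
  }
  a <- exp(unname(coef(fit)[1]))
  sigma <- sd(resid(fit))
  expected <- ifelse(tab$distance > 0, a * tab$distance^(-b), NA_real_)
  z <- (log(tab$count + 1) - log(expected + 1)) / sigma
  z[tab$masked | !is.finite(z)] <- NA_real_
  profile$table <- mutate(tab, expected = expected, z = z)
  profile$decay <- list(a = a, b = b, sigma = sigma, flat = flat)
  profile
}

#' @rdname fit_decay
#' @export
glance.interaction_profile <- function(x, ...) {
  if (is.null(x$decay)) {
    return(tibble(a = NA_real_, b = NA_real_, sigma = NA_real_, flat = NA))
  }
  tibble(
    a = x$decay$a, b = x$decay$b, sigma = x$decay$sigma, flat = x$decay$flat
  )
}

#' Call enriched interaction regions
#'
#' Maximal runs of at least `min_run` consecutive unmasked fragments with
#' residual `z >= z_min`, merged to genomic intervals.
#'
#' @param profile A decay-fitted [fourc_profile()] (see [fit_decay()]).
#' @param z_min Minimum residual z.
#' @param min_run Minimum run length in fragments.
#' @return Tibble of enriched intervals: `chrom`, `start`, `end`,
#'   `n_fragments`, `max_z`.
#' @export
call_interactions <- function(profile, z_min = 2.0, min_run = 3) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (is.null(profile$decay)) abort("call_interactions: fit the decay model first")
  tab <- profile$table
  pass <- !is.na(tab$z) & tab$z >= z_min
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_fragments = integer(), max_z = numeric()
    ))
  }
  list_rbind(map(keep, function(k) {
    i <- starts[k]:ends[k]
    tibble(
      chrom = tab$chrom[i[1]], start = min(tab$start[i]), end = max(tab$end[i]),
      n_fragments = length(i), max_z = max(tab$z[i])
    )
  }))
}

#' Interaction profile plot
#'
#' @param object A (possibly decay-fitted) `interaction_profile`.
#' @param z_min,min_run Passed to [call_interactions()] for shading when the
#'   decay has been fitted.
#' @param ... Unused.
#' @return A ggplot of normalized counts vs genomic position, with the decay
#'   expectation and called regions when available.
#' @export
autoplot.interaction_profile <- function(object, z_min = 2.0, min_run = 3, ...) {
  tab <- tidy(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes((.data$start + .data$end) / 2, .data$norm_count)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6, na.rm = TRUE) +
    ggplot2::labs(x = "position (bp)", y = "cis-normalized count") +
    ggplot2::theme_minimal()
  if (!is.null(object$decay)) {
    calls <- call_interactions(object, z_min = z_min, min_run = min_run)
    if (nrow(calls) > 0) {
      p <- p + ggplot2::geom_rect(
        data = calls,
        ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "#b2182b", alpha = 0.15
      )
    }
  }
  p
}

#' Relative interaction frequency against a control site
#'
#' 3C-style normalization: every site's value divided by the control site's
#' value; the control's own ratio is exactly 1.
#'
#' @param values Tibble with `site` and `value` columns.
#' @param control_site Identifier of the control site (value > 0).
#' @return `values` with a `ratio` column.
#' @export
relative_interaction_frequency <- function(values, control_site) {
  stopifnot(all(c("site", "value") %in% names(values)))
  ctrl <- values$value[values$site == control_site]
  if (length(ctrl) != 1) abort("relative_interaction_frequency: control site must appear exactly once")
  if (ctrl <= 0) abort("relative_interaction_frequency: control value must be > 0")
  mutate(values, ratio = .data$value / ctrl)
}

#' ChIP-qPCR percent input
#'
#' `PI = 100 * 2^((Ct_input - log2(1 / input_fraction)) - Ct_IP)`: the input
#' Ct is first adjusted for the input dilution, then compared with the IP Ct.
#'
#' @param table Tibble with `site`, `ct_ip`, `ct_input`, `input_fraction`
#'   (fraction of chromatin used as input, in (0, 1]).
#' @return `table` with a `percent_input` column.
#' @export
percent_input <- function(table) {
  stopifnot(all(c("site", "ct_ip", "ct_input", "input_fraction") %in% names(table)))
  if (any(table$input_fraction <= 0 | table$input_fraction > 1)) {
    abort("percent_input: input_fraction must be in (0, 1]")
  }
  if (any(!is.finite(table$ct_ip) | !is.finite(table$ct_input)) ||
    any(table$ct_ip <= 0 | table$ct_input <= 0)) {
    abort("percent_input: Ct values must be finite and positive")
  }
  mutate(
    table,
    percent_input = 100 * 2^((.data$ct_input - log2(1 / .data$input_fraction)) - .data$ct_ip)
  )
}
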