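# Two-group count-based differential expression: median-of-ratios
# normalization, a method-of-moments negative-binomial dispersion estimate
# shrunk toward a fitted mean-dispersion trend, and a Wald test on log2 fold
# change. Deliberately self-contained (no DESeq2/edgeR internals) so its
# calibration can be verified by simulation within the package.

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    id_col <- intersect(c("gene_id", "gene"), names(counts))[1]
    if (is.na(id_col)) abort("counts: data frame input needs a 'gene_id' column")
    m <- as.matrix(counts[setdiff(names(counts), id_col)])
    rownames(m) <- counts[[id_col]]
  } else {
    m <- as.matrix(counts)
    if (is.null(rownames(m))) rownames(m) <- paste0("gene_", seq_len(nrow(m)))
  }
  storage.mode(m) <- "double"
  if (any(m < 0) || any(!is.finite(m))) abort("counts must be finite and non-negative")
  if (anyDuplicated(rownames(m))) abort("counts: gene ids must be unique")
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of the
#' ratio of each sample's count to the per-gene geometric-mean reference.
#' Genes with a zero in any sample are excluded from the reference.
#'
#' @param counts Genes x samples matrix, or a tibble with a `gene_id` column.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' size_factors(matrix(c(10, 30, 20, 60), nrow = 2))
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  use <- rowSums(m == 0) == 0
  if (!any(use)) {
    abort(paste(
      "size_factors: no gene is nonzero in all samples;",
      "consider a pseudo-reference (e.g. add a pseudocount) before normalization"
    ))
  }
  logm <- log(m[use, , drop = FALSE])
  ref <- rowMeans(logm) # log geometric mean
  sf <- apply(logm, 2, function(col) exp(median(col - ref)))
  if (any(!is.finite(sf)) || any(sf <= 0)) abort("size_factors: non-finite factor")
  if (is.null(names(sf))) names(sf) <- colnames(m)
  sf
}

# Moment dispersion shrunk toward an a0 + a1/mu trend. Returns per-gene alpha.
estimate_dispersion <- function(norm, g1, g2, prior_df = 20) {
  n1 <- length(g1)
  n2 <- length(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- if (n1 > 1) apply(norm[, g1, drop = FALSE], 1, var) else rep(NA_real_, nrow(norm))
  v2 <- if (n2 > 1) apply(norm[, g2, drop = FALSE], 1, var) else rep(NA_real_, nrow(norm))
  df <- (n1 - 1) + (n2 - 1)
  v_pool <- ((if (n1 > 1) (n1 - 1) * v1 else 0) + (if (n2 > 1) (n2 - 1) * v2 else 0)) / df
  mu <- (m1 + m2) / 2
  alpha_raw <- (v_pool - mu) / mu^2
  alpha_raw[!is.finite(alpha_raw)] <- 0
  alpha_raw <- pmax(alpha_raw, 0)
  # mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted to genes with signal
  ok <- mu > 0
  a0 <- a1 <- 0
  if (sum(ok) >= 10) {
    fit <- lm(alpha_raw[ok] ~ I(1 / mu[ok]))
    a0 <- max(coef(fit)[1], 0)
    a1 <- max(coef(fit)[2], 0)
    if (!is.finite(a0)) a0 <- 0
    if (!is.finite(a1)) a1 <- 0
  } else {
    a0 <- mean(alpha_raw[ok])
  }
  alpha_trend <- a0 + a1 / pmax(mu, 1e-8)
  alpha <- (df * alpha_raw + prior_df * alpha_trend) / (df + prior_df)
  list(
    alpha = pmax(alpha, 1e-8), alpha_raw = alpha_raw,
    alpha_trend = alpha_trend, trend_coef = c(a0 = a0, a1 = a1)
  )
}

#' Two-group negative-binomial Wald test
#'
#' Fits a per-gene NB model with a trend-shrunk moment dispersion and tests
#' the log2 fold change (second group vs reference) with a Wald statistic.
#' The reported `log2fc` point estimate uses normalized counts plus a
#' pseudocount; the Benjamini-Hochberg FDR is computed across tested genes.
#' Genes with all-zero counts are dropped before testing (and before BH).
#'
#' @param counts Genes x samples matrix or tibble with `gene_id` column.
#' @param groups Length-`ncol` vector with exactly two levels; the reference
#'   (control) level is `ref`, defaulting to the first factor level.
#' @param ref Reference group label.
#' @param pseudocount Added to normalized group means for the `log2fc` point
#'   estimate (default 0.5).
#' @param sf Optional externally supplied size factors (e.g. library-size
#'   based for window counts); defaults to [size_factors()].
#' @param prior_df Weight (in residual degrees of freedom) of the dispersion
#'   trend in the shrinkage; larger values shrink harder.
#' @return A `de_result` object; use [tidy()] for the per-gene table with
#'   columns `gene_id`, `base_mean`, `log2fc`, `se_log2fc`, `stat`, `p`,
#'   `fdr`, and [classify_de()] to add the `call` column.
#' @export
test_two_group <- function(counts, groups, ref = NULL, pseudocount = 0.5,
                           sf = NULL, prior_df = 10) {
  m <- as_count_matrix(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) abort("test_two_group: groups must have exactly two levels")
  if (length(groups) != ncol(m)) abort("test_two_group: length(groups) != ncol(counts)")
  ref <- ref %||% lev[1]
  if (!ref %in% lev) abort(sprintf("test_two_group: ref '%s' not a group level", ref))
  case <- setdiff(lev, ref)
  g1 <- which(groups == ref)
  g2 <- which(groups == case)

  nonzero <- rowSums(m) > 0
  n_dropped <- sum(!nonzero)
  if (n_dropped > 0) {
    inform(sprintf("test_two_group: dropped %d all-zero gene(s) before testing", n_dropped))
  }
  mk <- m[nonzero, , drop = FALSE]
  sf <- sf %||% size_factors(m)
  norm <- sweep(mk, 2, sf, "/")

  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  log2fc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  base_mean <- rowMeans(norm)

  can_test <- length(g1) >= 2 && length(g2) >= 2
  if (can_test) {
    disp <- estimate_dispersion(norm, g1, g2, prior_df = prior_df)
    alpha <- disp$alpha
    # Var of a normalized-count group mean under NB(mu, alpha) with size factors
    var_mean <- function(mm, gg) {
      mu <- pmax(mm, pseudocount)
      (mu * sum(1 / sf[gg]) / length(gg)^2) + alpha * mu^2 / length(gg)
    }
    v1 <- var_mean(m1, g1)
    v2 <- var_mean(m2, g2)
    ln2sq <- log(2)^2
    se <- sqrt(v1 / (pmax(m1, pseudocount)^2 * ln2sq) +
      v2 / (pmax(m2, pseudocount)^2 * ln2sq))
    stat <- log2fc / se
    p <- 2 * pnorm(-abs(stat))
    fdr <- p.adjust(p, method = "BH")
  } else {
    disp <- list(alpha = rep(NA_real_, nrow(mk)), trend_coef = c(a0 = NA, a1 = NA))
    se <- stat <- p <- fdr <- rep(NA_real_, nrow(mk))
  }

  tab <- tibble(
    gene_id = rownames(mk),
    base_mean = unname(base_mean),
    log2fc = unname(log2fc),
    se_log2fc = unname(se),
    stat = unname(stat),
    p = unname(p),
    fdr = unname(fdr)
  )
  structure(
    list(
      table = tab, size_factors = sf, groups = setNames(groups, colnames(m)),
      ref = ref, case = case, dispersion = disp$alpha,
      dispersion_trend = disp$trend_coef, n_dropped = n_dropped,
      pseudocount = pseudocount
    ),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(
    "<de_result> %d genes tested (%s vs %s), %d all-zero dropped\n",
    nrow(x$table), x$case, x$ref, x$n_dropped
  ))
  print(x$table, n = 6)
  invisible(x)
}

#' @rdname test_two_group
#' @param x A `de_result`.
#' @param ... Unused.
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname test_two_group
#' @export
glance.de_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_dropped = x$n_dropped,
    median_dispersion = median(x$dispersion),
    ref = x$ref,
    case = x$case
  )
}

#' Classify differential-expression calls at fixed thresholds
#'
#' Adds a `call` column: `up` iff `fdr <= fdr_max` and `log2fc >= lfc_min`,
#' `down` iff `fdr <= fdr_max` and `log2fc <= -lfc_min`, otherwise `ns`.
#' The defaults are the conventional strict cutoffs FDR <= 0.01 and
#' |log2 fold change| >= 1.5 (note: 1.5 on the log2 scale, i.e. a ~2.8-fold
#' change).
#'
#' @param de A `de_result` or its [tidy()] table.
#' @param fdr_max,lfc_min Significance thresholds; `fdr_max` in (0, 1],
#'   `lfc_min >= 0`.
#' @return The per-gene tibble with a `call` factor column.
#' @export
classify_de <- function(de, fdr_max = 0.01, lfc_min = 1.5) {
  if (inherits(de, "de_result")) de <- de$table
  if (!is.numeric(fdr_max) || fdr_max <= 0 || fdr_max > 1) {
    abort("classify_de: fdr_max must be in (0, 1]")
  }
  if (!is.numeric(lfc_min) || lfc_min < 0) abort("classify_de: lfc_min must be >= 0")
  mutate(de, call = factor(
    case_when(
      !is.na(.data$fdr) & .data$fdr <= fdr_max & .data$log2fc >= lfc_min ~ "up",
      !is.na(.data$fdr) & .data$fdr <= fdr_max & .data$log2fc <= -lfc_min ~ "down",
      TRUE ~ "ns"
    ),
    levels = c("up", "down", "ns")
  ))
}

#' Volcano plot for a differential-expression result
#'
#' @param object A `de_result`.
#' @param fdr_max,lfc_min Thresholds passed to [classify_de()] for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, fdr_max = 0.01, lfc_min = 1.5, ...) {
  d <- classify_de(object, fdr_max = fdr_max, lfc_min = lfc_min)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2fc, -log10(pmax(.data$p, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(color = .data$call), size = 0.6, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = NULL) +
    ggplot2::theme_minimal()
}
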