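# Gene-set enrichment: the classic weighted running-sum enrichment score
# with a gene-label permutation null for NES/FDR, hypergeometric
# over-representation, and a simplified upstream-regulator activation
# z-score (unit target weights; a documented simplification of proprietary
# weighted forms).

#' Read gene sets from a GMT file
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- imap(sets, function(g, nm) {
    paste(c(nm, "na", g), collapse = "\t")
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

check_ranked <- function(ranked) {
  stopifnot(all(c("gene_id", "metric") %in% names(ranked)))
  if (anyDuplicated(ranked$gene_id)) abort("ranked list: gene ids must be unique")
  if (any(!is.finite(ranked$metric))) abort("ranked list: metric must be finite")
  arrange(ranked, dplyr::desc(.data$metric), .data$gene_id)
}

# ES from sorted |metric| weights and hit positions; O(k log k) per call.
es_from_positions <- function(absw, pos, weight_p = 1) {
  N <- length(absw)
  k <- length(pos)
  pos <- sort(pos)
  w <- absw[pos]^weight_p
  nr <- sum(w)
  if (nr == 0) {
    # all-zero metrics inside the set: fall back to unweighted increments
    w <- rep(1, k)
    nr <- k
  }
  miss <- 1 / (N - k)
  cw <- cumsum(w) / nr
  before <- c(0, cw[-k]) - (pos - seq_len(k) + 1 - 1) * miss
  after <- cw - (pos - seq_len(k)) * miss
  dev <- c(before, after, 0)
  dev[which.max(abs(dev))]
}

#' GSEA enrichment score
#'
#' The classic weighted running sum: walking down the ranking, hits increment
#' by `|metric|^p / sum_hits |metric|^p` and misses decrement by
#' `1 / (N - N_hits)`; the ES is the signed maximum deviation from zero.
#'
#' @param ranked Tibble with `gene_id` and `metric`; sorted descending
#'   internally (ties broken by gene id).
#' @param gene_set Character vector of gene ids.
#' @param weight_p Metric weight exponent (default 1).
#' @return The enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, gene_set, weight_p = 1) {
  ranked <- check_ranked(ranked)
  pos <- which(ranked$gene_id %in% gene_set)
  if (length(pos) == 0) abort("gsea_es: empty overlap between set and ranking")
  if (length(pos) == nrow(ranked)) abort("gsea_es: gene set covers the whole ranking")
  es_from_positions(abs(ranked$metric), pos, weight_p)
}

#' Permutation significance for gene-set enrichment
#'
#' A gene-label permutation null per set size: for each set, `n_perm` random
#' same-size gene sets are scored; `NES = ES / mean(|ES_perm| of matching
#' sign)`, the one-sided p-value has a +1 continuity correction, and FDR
#' follows the sign-stratified NES procedure (fraction of permuted NES at
#' least as extreme, divided by the fraction of observed NES at least as
#' extreme, clamped to `[0, 1]`).
#'
#' @param ranked Tibble with `gene_id` and `metric`.
#' @param gene_sets Named list of gene-id vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param weight_p Metric weight exponent.
#' @param min_size Sets with fewer than this many ranked genes are skipped.
#' @param seed Integer seed making the permutations reproducible.
#' @return A tibble: `set_id`, `n_overlap`, `es`, `nes`, `p_perm`, `fdr`.
#' @export
gsea_significance <- function(ranked, gene_sets, n_perm = 1000, weight_p = 1,
                              min_size = 5, seed = 1) {
  if (n_perm < 100) abort("gsea_significance: n_perm must be >= 100")
  ranked <- check_ranked(ranked)
  absw <- abs(ranked$metric)
  N <- nrow(ranked)
  set.seed(seed)

  sizes <- map_int(gene_sets, function(g) sum(ranked$gene_id %in% g))
  usable <- sizes >= min_size & sizes < N
  if (any(!usable)) {
    inform(sprintf(
      "gsea_significance: skipped %d set(s) with overlap < %d or covering the ranking",
      sum(!usable), min_size
    ))
  }
  gene_sets <- gene_sets[usable]
  sizes <- sizes[usable]
  if (length(gene_sets) == 0) {
    return(tibble(
      set_id = character(), n_overlap = integer(), es = numeric(),
      nes = numeric(), p_perm = numeric(), fdr = numeric()
    ))
  }

  es_obs <- map_dbl(gene_sets, function(g) {
    es_from_positions(absw, which(ranked$gene_id %in% g), weight_p)
  })
  # one permutation block per distinct set size
  perm_by_size <- map(unique(sizes), function(k) {
    vapply(
      seq_len(n_perm),
      function(i) es_from_positions(absw, sample.int(N, k), weight_p),
      numeric(1)
    )
  })
  names(perm_by_size) <- as.character(unique(sizes))

  stats <- imap(gene_sets, function(g, nm) {
    k <- sizes[[nm]]
    es <- es_obs[[nm]]
    perm <- perm_by_size[[as.character(k)]]
    same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
    denom <- mean(abs(same))
    nes <- if (length(same) > 0 && denom > 0) es / denom else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes_perm <- if (length(same) > 0 && denom > 0) same / denom else numeric(0)
    tibble(
      set_id = nm, n_overlap = k, es = es, nes = nes, p_perm = p,
      nes_perm = list(nes_perm)
    )
  }) |> list_rbind()

  all_perm_nes <- unlist(stats$nes_perm)
  obs_nes <- stats$nes
  fdr <- map_dbl(seq_len(nrow(stats)), function(i) {
    nes <- obs_nes[i]
    if (is.na(nes)) {
      return(NA_real_)
    }
    if (nes >= 0) {
      num <- mean(all_perm_nes[all_perm_nes >= 0] >= nes)
      den <- mean(obs_nes[!is.na(obs_nes) & obs_nes >= 0] >= nes)
    } else {
      num <- mean(all_perm_nes[all_perm_nes < 0] <= nes)
      den <- mean(obs_nes[!is.na(obs_nes) & obs_nes < 0] <= nes)
    }
    if (!is.finite(num / den)) {
      return(1)
    }
    min(1, num / den)
  })
  stats |>
    mutate(fdr = fdr) |>
    select("set_id", "n_overlap", "es", "nes", "p_perm", "fdr")
}

#' Hypergeometric over-representation
#'
#' Right-tailed hypergeometric test `P(X >= k)` of the overlap between a hit
#' list and each gene set within a universe, with BH correction across sets.
#'
#' @param hit_genes Character vector of hits; must be a subset of `universe`.
#' @param universe Character vector of all considered genes.
#' @param gene_sets Named list of gene-id vectors (intersected with the
#'   universe).
#' @return A tibble: `set_id`, `n_set`, `n_overlap`, `enrichment` (observed /
#'   expected overlap), `p`, `fdr`.
#' @export
overrepresentation <- function(hit_genes, universe, gene_sets) {
  hit_genes <- unique(hit_genes)
  universe <- unique(universe)
  if (!all(hit_genes %in% universe)) {
    abort("overrepresentation: hit_genes must be a subset of universe")
  }
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  N <- length(universe)
  n <- length(hit_genes)
  rows <- imap(gene_sets, function(g, nm) {
    set <- intersect(unique(g), universe)
    m <- length(set)
    k <- length(intersect(hit_genes, set))
    p <- if (m == 0) 1 else phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    expected <- n * m / N
    tibble(
      set_id = nm, n_set = m, n_overlap = k,
      enrichment = if (expected > 0) k / expected else NA_real_, p = p
    )
  })
  out <- list_rbind(rows)
  mutate(out, fdr = p.adjust(.data$p, method = "BH"))
}

#' Simplified upstream-regulator activation z-score
#'
#' Over a regulator's targets with informative (non-ns) expression calls,
#' `z = (n_concordant - n_discordant) / sqrt(n_concordant + n_discordant)`,
#' where concordance compares the observed direction with the regulator
#' model's expected sign. Unit target weights (a simplification relative to
#' weighted commercial implementations, stated in the output).
#'
#' @param model Tibble with `regulator`, `target`, `sign` (+1/-1 expected
#'   effect).
#' @param de_calls Output of [classify_de()] (`gene_id`, `call`).
#' @return A tibble: `regulator`, `n_concordant`, `n_discordant`, `z`
#'   (NA when no informative target), plus a `method` column recording the
#'   unit-weight simplification.
#' @export
regulator_z <- function(model, de_calls) {
  stopifnot(all(c("regulator", "target", "sign") %in% names(model)))
  if (!all(model$sign %in% c(-1, 1))) abort("regulator_z: sign must be +1 or -1")
  obs <- de_calls |>
    mutate(obs_sign = case_when(
      .data$call == "up" ~ 1, .data$call == "down" ~ -1, TRUE ~ 0
    )) |>
    select(target = "gene_id", "obs_sign")
  model |>
    inner_join(obs, by = "target") |>
    filter(.data$obs_sign != 0) |>
    group_by(.data$regulator) |>
    summarise(
      n_concordant = sum(.data$sign == .data$obs_sign),
      n_discordant = sum(.data$sign != .data$obs_sign),
      .groups = "drop"
    ) |>
    mutate(
      z = if_else(
        .data$n_concordant + .data$n_discordant > 0,
        (.data$n_concordant - .data$n_discordant) /
          sqrt(.data$n_concordant + .data$n_discordant),
        NA_real_
      ),
      method = "unit-weight activation z"
    )
}
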