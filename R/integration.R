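# Congruence classification: does a differentially expressed gene carry
# concordant histone-mark changes at its promoter window? An up gene is
# supported by any active mark increasing or by H3K27me3 decreasing; a down
# gene by the mirror image. Non-significant occupancy never supports.

#' Classify DE genes as congruent with their histone-mark changes
#'
#' @param de_calls Output of [classify_de()] (needs `gene_id`, `call`).
#' @param occupancy_tables A list of tibbles from [differential_occupancy()]
#'   (one per mark), or a single row-bound tibble.
#' @param min_supporting_marks Minimum number of concordant significant marks
#'   required for congruence (default 1).
#' @return A `congruence` object; [tidy()] gives the per-gene call table,
#'   [glance()] the summary counts (`n_up`, `n_up_congruent`, `n_down`,
#'   `n_down_congruent`).
#' @export
congruence_classify <- function(de_calls, occupancy_tables,
                                min_supporting_marks = 1) {
  if (inherits(de_calls, "de_result")) {
    abort("congruence_classify: run classify_de() first to obtain calls")
  }
  stopifnot(all(c("gene_id", "call") %in% names(de_calls)))
  occ <- if (is.data.frame(occupancy_tables)) {
    occupancy_tables
  } else {
    list_rbind(unname(map(occupancy_tables, as_tibble)))
  }
  stopifnot(all(c("gene_id", "mark", "direction_call") %in% names(occ)))

  n_unknown <- length(setdiff(unique(occ$gene_id), de_calls$gene_id))
  if (n_unknown > 0) {
    inform(sprintf(
      "congruence_classify: %d gene(s) present in occupancy but absent from DE ignored",
      n_unknown
    ))
  }

  pol <- mark_polarity()
  de <- filter(de_calls, .data$call %in% c("up", "down"))
  support <- occ |>
    inner_join(select(de, "gene_id", de_call = "call"), by = "gene_id") |>
    left_join(pol, by = "mark") |>
    mutate(
      polarity = if_else(is.na(.data$polarity), 1, .data$polarity),
      occ_sign = case_when(
        .data$direction_call == "increased" ~ 1,
        .data$direction_call == "decreased" ~ -1,
        TRUE ~ 0
      ),
      de_sign = if_else(.data$de_call == "up", 1, -1),
      supports = .data$occ_sign != 0 &
        .data$occ_sign * .data$polarity == .data$de_sign
    )
  per_gene <- support |>
    group_by(.data$gene_id) |>
    summarise(
      n_support = sum(.data$supports),
      supporting_marks = paste(
        sprintf(
          "%s:%s", .data$mark[.data$supports],
          as.character(.data$direction_call[.data$supports])
        ),
        collapse = ";"
      ),
      .groups = "drop"
    )
  calls <- de |>
    select("gene_id", de_call = "call") |>
    left_join(per_gene, by = "gene_id") |>
    mutate(
      n_support = dplyr::coalesce(.data$n_support, 0L),
      supporting_marks = dplyr::coalesce(.data$supporting_marks, ""),
      congruent = .data$n_support >= min_supporting_marks
    )
  structure(
    list(
      calls = calls,
      occupancy = support,
      min_supporting_marks = min_supporting_marks,
      n_ignored = n_unknown
    ),
    class = "congruence"
  )
}

#' @export
print.congruence <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<congruence> up: %d/%d congruent; down: %d/%d congruent\n",
    g$n_up_congruent, g$n_up, g$n_down_congruent, g$n_down
  ))
  invisible(x)
}

#' @rdname congruence_classify
#' @param x A `congruence` object.
#' @param ... Unused.
#' @export
tidy.congruence <- function(x, ...) x$calls

#' @rdname congruence_classify
#' @export
glance.congruence <- function(x, ...) {
  tibble(
    n_up = sum(x$calls$de_call == "up"),
    n_up_congruent = sum(x$calls$de_call == "up" & x$calls$congruent),
    n_down = sum(x$calls$de_call == "down"),
    n_down_congruent = sum(x$calls$de_call == "down" & x$calls$congruent)
  )
}

#' Summarize an integration result
#'
#' Per-direction counts, per-mark support frequencies, and a heatmap-ready
#' genes x marks matrix of signed log2 occupancy ratios for the congruent
#' genes.
#'
#' @param x A `congruence` object.
#' @return A list with `summary` (one-row tibble), `mark_support` (per-mark
#'   support frequencies among DE genes), and `heatmap_matrix`.
#' @export
summarize_integration <- function(x) {
  stopifnot(inherits(x, "congruence"))
  summary <- glance(x)
  if (nrow(x$calls) == 0) {
    return(list(
      summary = summary,
      mark_support = tibble(mark = character(), support_frequency = numeric()),
      heatmap_matrix = matrix(0, 0, 0)
    ))
  }
  mark_support <- x$occupancy |>
    group_by(.data$mark) |>
    summarise(support_frequency = mean(.data$supports), .groups = "drop")
  hm <- x$occupancy |>
    select("gene_id", "mark", "log2_ratio") |>
    tidyr::pivot_wider(names_from = "mark", values_from = "log2_ratio") |>
    tibble::column_to_rownames("gene_id") |>
    as.matrix()
  list(summary = summary, mark_support = mark_support, heatmap_matrix = hm)
}

#' Congruence support plot
#'
#' @param object A `congruence` object.
#' @param ... Unused.
#' @return A ggplot bar chart of congruent vs non-congruent counts by DE
#'   direction.
#' @export
autoplot.congruence <- function(object, ...) {
  d <- object$calls |>
    dplyr::count(.data$de_call, .data$congruent)
  ggplot2::ggplot(d, ggplot2::aes(.data$de_call, .data$n, fill = .data$congruent)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "expression call", y = "genes", fill = "congruent") +
    ggplot2::theme_minimal()
}
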