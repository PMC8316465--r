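# Configuration-driven end-to-end orchestration. Stages communicate only via
# the files they write (every stage is runnable standalone on its TSV/BED
# inputs); a run manifest records the thresholds used and a checksum per
# output file. One global seed is split per stage in a fixed, documented
# order (simulate, de, occupancy, integrate, enrichment, rose, motif, fourc).

pipeline_defaults <- function() {
  list(
    fdr_max = 0.01, lfc_min = 1.5, occupancy_fdr_max = 0.05,
    min_relative_score = 0.95, stitch_distance = 12500, tss_exclusion = 2500,
    z_min = 2.0, exclude_k = 2, min_run = 3, halfwidth = 2000,
    n_perm = 200, min_supporting_marks = 1
  )
}

threshold_ranges <- function() {
  list(
    fdr_max = c(0, 1), lfc_min = c(0, Inf), occupancy_fdr_max = c(0, 1),
    min_relative_score = c(0, 1), stitch_distance = c(0, Inf),
    tss_exclusion = c(0, Inf), z_min = c(0, Inf), exclude_k = c(0, Inf),
    min_run = c(1, Inf), halfwidth = c(100, Inf), n_perm = c(100, Inf),
    min_supporting_marks = c(1, Inf)
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) with keys `seed`, `output_dir`, and
#' either a `simulate:` block (arguments to [simulation_config()]) or a
#' `fixture_dir:` pointing at a [write_fixture()] directory, plus an optional
#' `thresholds:` block. Unknown keys are rejected with a suggestion; every
#' threshold is range-checked; referenced paths must exist.
#'
#' @param config Path to a YAML file, or a config list.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("validate_config: file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  known_top <- c("seed", "output_dir", "simulate", "fixture_dir", "thresholds")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown) > 0) {
    hint <- agrep(unknown[1], known_top, max.distance = 0.3, value = TRUE)
    abort(sprintf(
      "validate_config: unknown key '%s'%s", unknown[1],
      if (length(hint) > 0) sprintf(" (did you mean '%s'?)", hint[1]) else ""
    ))
  }
  if (is.null(config$output_dir)) abort("validate_config: missing required key 'output_dir'")
  config$seed <- as.integer(config$seed %||% 1)

  th <- pipeline_defaults()
  if (!is.null(config$thresholds)) {
    unknown <- setdiff(names(config$thresholds), names(th))
    if (length(unknown) > 0) {
      hint <- agrep(unknown[1], names(th), max.distance = 0.3, value = TRUE)
      abort(sprintf(
        "validate_config: unknown threshold '%s'%s", unknown[1],
        if (length(hint) > 0) sprintf(" (did you mean '%s'?)", hint[1]) else ""
      ))
    }
    th <- modifyList(th, config$thresholds)
  }
  rng <- threshold_ranges()
  for (k in names(rng)) {
    v <- th[[k]]
    if (!is.numeric(v) || v < rng[[k]][1] || v > rng[[k]][2]) {
      abort(sprintf(
        "validate_config: threshold '%s' = %s outside [%g, %g]",
        k, format(v), rng[[k]][1], rng[[k]][2]
      ))
    }
  }
  config$thresholds <- th

  if (is.null(config$simulate) && is.null(config$fixture_dir)) {
    abort("validate_config: need either a 'simulate' block or 'fixture_dir'")
  }
  if (!is.null(config$fixture_dir) && !dir.exists(config$fixture_dir)) {
    abort(sprintf("validate_config: fixture_dir '%s' does not exist", config$fixture_dir))
  }
  if (!is.null(config$simulate)) {
    bad <- setdiff(names(config$simulate), names(formals(simulation_config)))
    if (length(bad) > 0) {
      abort(sprintf("validate_config: unknown simulate key '%s'", bad[1]))
    }
  }
  structure(config, class = "pipeline_config")
}

#' Read a fixture directory back into a study bundle
#'
#' The inverse of [write_fixture()]: reconstructs annotation, counts, peaks,
#' replicate signal tracks, the 4C profile inputs, the promoter sequence,
#' gene sets, the regulator model and the motif matrix from their on-disk
#' formats. Ground truth is loaded when `truth.json` is present.
#'
#' @param dir A directory produced by [write_fixture()].
#' @return A list shaped like a [simulate_study()] bundle.
#' @export
read_fixture <- function(dir) {
  p <- function(...) file.path(dir, ...)
  info <- jsonlite::read_json(p("study_info.json"), simplifyVector = TRUE)
  annotation <- read_gene_annotation(p("annotation.tsv"), dialect = "tsv")
  counts <- readr::read_tsv(p("counts.tsv"), col_types = readr::cols(), progress = FALSE)
  samples <- readr::read_tsv(p("samples.tsv"), col_types = "cc", progress = FALSE)
  chrom_lengths <- setNames(info$genome_length, info$chrom)

  peaks <- list()
  for (f in list.files(dir, pattern = "^peaks_.*\\.bed$")) {
    mark <- sub("^peaks_(.*)\\.bed$", "\\1", f)
    peaks[[mark]] <- read_bed(p(f))
  }
  tm <- readr::read_tsv(p("track_manifest.tsv"), col_types = readr::cols(), progress = FALSE)
  tracks <- list()
  for (i in seq_len(nrow(tm))) {
    tr <- read_bedgraph(p(tm$file[i]),
      bin_size = tm$bin_size[i],
      library_size = tm$library_size[i], chrom_lengths = chrom_lengths
    )
    tracks[[tm$mark[i]]][[tm$condition[i]]][[tm$replicate[i]]] <- tr
  }
  pooled <- map(tracks, function(by_cond) {
    map(by_cond, function(reps) {
      vals <- Reduce(`+`, map(reps, function(t) t$values[[info$chrom]]))
      signal_track(setNames(list(vals), info$chrom), reps[[1]]$bin_size)
    })
  })
  input_track <- read_bedgraph(p("track_input.bedgraph"),
    bin_size = info$bin_size, chrom_lengths = chrom_lengths
  )

  fragments <- readr::read_tsv(p("fourc_fragments.tsv"), col_types = readr::cols(), progress = FALSE)
  fourc_counts <- readr::read_tsv(p("fourc_counts.tsv"), col_types = readr::cols(), progress = FALSE)

  fa <- readr::read_lines(p("promoter.fa"))
  seq <- paste(fa[!grepl("^>", fa)], collapse = "")

  truth <- NULL
  if (file.exists(p("truth.json"))) {
    truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  }
  list(
    annotation = annotation, counts = counts, groups = samples$group,
    tracks = tracks, pooled_tracks = pooled, input_track = input_track,
    peaks = peaks,
    fourc = list(
      fragments = fragments, viewpoint = info$fourc_viewpoint,
      counts = fourc_counts
    ),
    sequence = list(chrom = info$chrom, offset = info$sequence_offset, seq = seq),
    gene_sets = read_gmt(p("gene_sets.gmt")),
    regulator_model = readr::read_tsv(p("regulator_models.tsv"),
      col_types = readr::cols(), progress = FALSE
    ),
    motif_counts = read_jaspar(p("motif.pfm")),
    truth = truth, info = info
  )
}

#' Run the full pipeline
#'
#' Simulates (or loads) the study fixture, then runs differential expression,
#' per-mark differential occupancy, congruence integration, enrichment
#' (GSEA, over-representation, regulator z), super-enhancer calling on both
#' conditions, motif scanning of the promoter sequence, and 4C interaction
#' calling — each stage reading the files the previous stages wrote and
#' writing its own outputs under `output_dir`. A failure in any stage aborts
#' with the stage name while earlier outputs are preserved.
#'
#' @param config A `pipeline_config` (or path/list accepted by
#'   [validate_config()]).
#' @return A run manifest list (`config_hash`, `version`, `thresholds`,
#'   `stages` with wall times, `files` tibble with md5 checksums), also
#'   written to `manifest.json`.
#' @export
run_all <- function(config) {
  config <- validate_config(unclass(config))
  th <- config$thresholds
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(out, ...)
  stage_order <- c(
    "simulate", "de", "occupancy", "integrate", "enrichment",
    "rose", "motif", "fourc"
  )
  stage_seed <- function(stage) config$seed + match(stage, stage_order) - 1L
  timings <- list()
  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  # -- simulate / load --------------------------------------------------------
  fixture_dir <- config$fixture_dir
  run_stage("simulate", function() {
    if (is.null(fixture_dir)) {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% stage_seed("simulate")
      cfg <- do.call(simulation_config, sim_args)
      study <- simulate_study(cfg)
      fixture_dir <<- o("fixture")
      write_fixture(study, fixture_dir)
    }
    invisible(NULL)
  })
  bundle <- read_fixture(fixture_dir)

  # -- differential expression ------------------------------------------------
  de_calls <- run_stage("de", function() {
    fit <- test_two_group(bundle$counts, bundle$groups, ref = "control")
    calls <- classify_de(fit, fdr_max = th$fdr_max, lfc_min = th$lfc_min)
    readr::write_tsv(calls, o("de_results.tsv"))
    calls
  })

  # -- occupancy --------------------------------------------------------------
  occ_tables <- run_stage("occupancy", function() {
    tabs <- map(names(bundle$tracks), function(mark) {
      tab <- differential_occupancy(
        case_tracks = bundle$tracks[[mark]][["case"]],
        control_tracks = bundle$tracks[[mark]][["control"]],
        annotation = bundle$annotation, mark = mark,
        halfwidth = th$halfwidth, occupancy_fdr_max = th$occupancy_fdr_max
      )
      readr::write_tsv(tab, o(sprintf("occupancy_%s.tsv", mark)))
      tab
    })
    setNames(tabs, names(bundle$tracks))
  })

  # -- integration ------------------------------------------------------------
  run_stage("integrate", function() {
    de_tab <- readr::read_tsv(o("de_results.tsv"), col_types = readr::cols(), progress = FALSE)
    occ <- map(
      list.files(out, pattern = "^occupancy_.*\\.tsv$"),
      function(f) readr::read_tsv(o(f), col_types = readr::cols(), progress = FALSE)
    )
    cong <- congruence_classify(de_tab, occ,
      min_supporting_marks = th$min_supporting_marks
    )
    readr::write_tsv(tidy(cong), o("integration_calls.tsv"))
    readr::write_tsv(glance(cong), o("integration_summary.tsv"))
    invisible(NULL)
  })

  # -- enrichment -------------------------------------------------------------
  run_stage("enrichment", function() {
    de_tab <- readr::read_tsv(o("de_results.tsv"), col_types = readr::cols(), progress = FALSE)
    ranked <- de_tab |>
      filter(is.finite(.data$stat)) |>
      select("gene_id", metric = "stat")
    gsea <- gsea_significance(ranked, bundle$gene_sets,
      n_perm = th$n_perm, seed = stage_seed("enrichment")
    )
    readr::write_tsv(gsea, o("gsea_results.tsv"))
    hits <- de_tab$gene_id[de_tab$call != "ns"]
    ora <- overrepresentation(hits, de_tab$gene_id, bundle$gene_sets)
    readr::write_tsv(ora, o("ora_results.tsv"))
    rz <- regulator_z(bundle$regulator_model, de_tab)
    readr::write_tsv(rz, o("regulator_z.tsv"))
    invisible(NULL)
  })

  # -- super-enhancers (both conditions, H3K27ac) -----------------------------
  run_stage("rose", function() {
    regions <- stitch(bundle$peaks$H3K27ac, bundle$annotation,
      stitch_distance = th$stitch_distance, tss_exclusion = th$tss_exclusion
    )
    for (condition in c("control", "case")) {
      scored <- score_regions(
        regions, bundle$pooled_tracks$H3K27ac[[condition]], bundle$input_track
      )
      ranking <- rank_and_cut(scored)
      rep_tab <- rank_report(ranking, bundle$annotation)
      readr::write_tsv(
        select(rep_tab, -dplyr::any_of("kind")),
        o(sprintf("se_ranking_%s.tsv", condition))
      )
      super <- filter(rep_tab, .data$is_super)
      write_bed(
        mutate(super, name = paste0("SE_", .data$rank), score = .data$net_signal),
        o(sprintf("super_enhancers_%s.bed", condition))
      )
    }
    invisible(NULL)
  })

  # -- motif scan -------------------------------------------------------------
  run_stage("motif", function() {
    pwm <- pwm_from_counts(bundle$motif_counts[[1]],
      motif_id = names(bundle$motif_counts)[1]
    )
    hits <- scan_motif(bundle$sequence$seq, pwm,
      min_relative_score = th$min_relative_score,
      chrom = bundle$sequence$chrom, offset = bundle$sequence$offset
    )
    write_bed(
      mutate(hits, name = pwm$motif_id, score = round(.data$relative_score * 1000)),
      o("motif_hits.bed")
    )
    invisible(NULL)
  })

  # -- 4C ---------------------------------------------------------------------
  run_stage("fourc", function() {
    for (condition in c("control", "case")) {
      prof <- fourc_profile(
        bundle$fourc$counts[[condition]], bundle$fourc$fragments,
        viewpoint = bundle$fourc$viewpoint, exclude_k = th$exclude_k,
        condition = condition
      )
      prof <- fit_decay(prof)
      readr::write_tsv(tidy(prof), o(sprintf("fourc_profile_%s.tsv", condition)))
      readr::write_tsv(glance(prof), o(sprintf("fourc_decay_%s.tsv", condition)))
      calls <- call_interactions(prof, z_min = th$z_min, min_run = th$min_run)
      readr::write_tsv(calls, o(sprintf("fourc_calls_%s.tsv", condition)))
    }
    invisible(NULL)
  })

  # -- manifest ---------------------------------------------------------------
  files <- sort(setdiff(
    list.files(out, recursive = TRUE),
    c("manifest.json", "manifest.tsv")
  ))
  file_tab <- tibble(
    file = files, md5 = unname(tools::md5sum(file.path(out, files)))
  )
  manifest <- list(
    config_hash = rlang::hash(list(
      seed = config$seed, simulate = config$simulate,
      fixture = config$fixture_dir, thresholds = th
    )),
    version = as.character(utils::packageVersion("markwise")),
    seed = config$seed,
    thresholds = th,
    stages = timings,
    files = file_tab
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(file_tab, o("manifest.tsv"))
  invisible(manifest)
}
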