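# Seeded generator of a toy two-condition study: NB expression counts with
# planted fold changes, histone-mark signal tracks with condition-dependent
# promoter amplitudes, an amplified enhancer cluster for super-enhancer
# recovery, a 4C profile with power-law distance decay plus a planted
# interaction, and a promoter sequence with planted motif sites. Ground truth
# for every planted structure is returned alongside the data.

#' Configuration for the synthetic two-condition study
#'
#' Defaults describe the study the package's recovery tests assume: 4 control
#' vs 5 case samples, 2000 genes with NB(mean 500, dispersion 0.05) counts,
#' 5% up / 5% down planted at |log2FC| = 3, half of the planted genes given
#' concordant histone-mark changes, one amplified enhancer cluster, and a 4C
#' decay exponent of 1 with a 5-fold interaction bump over 6 fragments.
#'
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @param n_genes Number of genes.
#' @param n_control,n_case Samples per group (RNA-seq and per-mark ChIP
#'   replicates).
#' @param genome_length Length of the single toy chromosome (bp).
#' @param nb_mean,nb_dispersion NB mean and dispersion (variance
#'   `mu + alpha mu^2`).
#' @param frac_up,frac_down Fractions of genes planted up/down.
#' @param planted_lfc Planted |log2 fold change| (> 0).
#' @param congruent_fraction Fraction of planted DE genes whose promoter mark
#'   amplitudes change concordantly.
#' @param mark_lfc log2 change of promoter mark amplitude for congruent genes
#'   (sign follows expression for active marks, is opposite for H3K27me3).
#' @param libsize_range Per-sample depth factors drawn uniformly from
#'   `[1/libsize_range, libsize_range]`.
#' @param bin_size Signal-track bin width (bp).
#' @param background_rate Poisson background reads per bin.
#' @param promoter_sigma Gaussian promoter-peak width (bp, sd).
#' @param promoter_reads Named baseline promoter reads per mark.
#' @param enhancer_cluster List: `n_members`, `member_width`, `member_gap`,
#'   `member_reads`, `amplification` (fold applied in the case condition).
#' @param n_typical_enhancers,typical_reads Isolated enhancer peaks providing
#'   the body of the rank-ordering curve.
#' @param n_decoy_clusters,decoy_members,decoy_reads Constitutive strong
#'   clusters (same both conditions) that outrank the planted cluster until it
#'   is amplified.
#' @param fourc List: `frag_length`, `span` (bp covered around the viewpoint),
#'   `decay_a`, `decay_b`, `bump_fold`, `bump_n_fragments`.
#' @param motif List: `consensus` (planted sequence), `n_planted`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 2000,
                              n_control = 4,
                              n_case = 5,
                              genome_length = 1e7,
                              nb_mean = 500,
                              nb_dispersion = 0.05,
                              frac_up = 0.05,
                              frac_down = 0.05,
                              planted_lfc = 3,
                              congruent_fraction = 0.5,
                              mark_lfc = 2,
                              libsize_range = 1.3,
                              bin_size = 50,
                              background_rate = 0.1,
                              promoter_sigma = 300,
                              promoter_reads = c(
                                H3K4me3 = 300, H3K4me1 = 120,
                                H3K27ac = 200, H3K27me3 = 150
                              ),
                              enhancer_cluster = list(),
                              n_typical_enhancers = 40,
                              typical_reads = 500,
                              n_decoy_clusters = 3,
                              decoy_members = 4,
                              decoy_reads = 1500,
                              fourc = list(),
                              motif = list()) {
  cfg <- list(
    seed = as.integer(seed), n_genes = n_genes, n_control = n_control,
    n_case = n_case, genome_length = genome_length, nb_mean = nb_mean,
    nb_dispersion = nb_dispersion, frac_up = frac_up, frac_down = frac_down,
    planted_lfc = planted_lfc, congruent_fraction = congruent_fraction,
    mark_lfc = mark_lfc, libsize_range = libsize_range, bin_size = bin_size,
    background_rate = background_rate, promoter_sigma = promoter_sigma,
    promoter_reads = promoter_reads,
    enhancer_cluster = modifyList(list(
      n_members = 8, member_width = 1500, member_gap = 6000,
      member_reads = 500, amplification = 3
    ), enhancer_cluster),
    n_typical_enhancers = n_typical_enhancers, typical_reads = typical_reads,
    n_decoy_clusters = n_decoy_clusters, decoy_members = decoy_members,
    decoy_reads = decoy_reads,
    fourc = modifyList(list(
      frag_length = 4000, span = 3e6, decay_a = 1.5e7, decay_b = 1,
      bump_fold = 5, bump_n_fragments = 6
    ), fourc),
    motif = modifyList(list(consensus = "GGGACTTTCC", n_planted = 3), motif),
    chrom = "chrS", marks = c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_genes >= 1, n_control >= 1, n_case >= 1, genome_length > 0,
      nb_mean > 0, nb_dispersion >= 0, planted_lfc > 0,
      frac_up >= 0, frac_down >= 0, frac_up + frac_down <= 1,
      congruent_fraction >= 0, congruent_fraction <= 1,
      libsize_range >= 1, fourc$decay_b > 0, fourc$bump_fold >= 1
    )
  })
  ec <- cfg$enhancer_cluster
  span <- ec$n_members * ec$member_width + (ec$n_members - 1) * ec$member_gap
  if (span > 0.1 * cfg$genome_length) {
    abort("simulation_config: enhancer cluster span exceeds 10% of the genome; enlarge genome_length")
  }
  if (cfg$n_genes * 4000 > 0.85 * cfg$genome_length) {
    abort("simulation_config: too many genes for genome_length (need ~4 kb per gene)")
  }
  plan_layout(cfg) # aborts when the gene desert cannot hold the enhancer layout
  invisible(cfg)
}

# Deterministic genome layout: genes occupy [0, 0.35L) and [0.5L, L) with a
# 0.15L gene desert in between holding the typical enhancers, the decoy
# clusters and the planted cluster. The desert is laid out backwards from the
# planted cluster (right edge, nearest the target gene) with separations
# larger than the stitching distance so no planted structure merges with
# another.
plan_layout <- function(cfg) {
  L <- cfg$genome_length
  desert <- c(floor(0.35 * L), floor(0.5 * L))
  left_n <- floor(cfg$n_genes * 0.4)
  right_n <- cfg$n_genes - left_n
  margin <- 25000
  tss_left <- if (left_n > 0) {
    floor(seq(margin, desert[1] - margin, length.out = left_n))
  } else {
    numeric(0)
  }
  tss_right <- floor(seq(desert[2] + margin, L - margin, length.out = right_n))
  ec <- cfg$enhancer_cluster
  cluster_span <- ec$n_members * ec$member_width + (ec$n_members - 1) * ec$member_gap
  cluster_start <- desert[2] - 40000 - cluster_span
  decoy_span <- cfg$decoy_members * ec$member_width + (cfg$decoy_members - 1) * 4000
  decoy_slot <- decoy_span + 20000 # > stitch default so decoys stay separate
  decoy_starts <- cluster_start - 40000 - seq_len(cfg$n_decoy_clusters) * decoy_slot
  typ_lo <- desert[1] + 10000
  typ_hi <- (if (cfg$n_decoy_clusters > 0) min(decoy_starts) else cluster_start - 40000) - 20000
  min_typ_spacing <- 15000
  if (cfg$n_typical_enhancers > 0 &&
    (typ_hi - typ_lo) < cfg$n_typical_enhancers * min_typ_spacing) {
    abort(paste(
      "simulation_config: gene desert too small for the enhancer layout;",
      "enlarge genome_length or reduce n_typical_enhancers/n_decoy_clusters"
    ))
  }
  list(
    desert = desert, tss = c(tss_left, tss_right),
    cluster_start = cluster_start, cluster_span = cluster_span,
    decoy_starts = decoy_starts,
    typical_region = c(typ_lo, typ_hi),
    target_gene_index = left_n + 1 # first gene right of the desert
  )
}

#' Simulate the full synthetic study
#'
#' Generates gene annotation, an RNA-seq count matrix, per-mark per-condition
#' replicate signal tracks and peak calls, a 4C interaction profile per
#' condition, a promoter sequence with planted motif sites, and the ground
#' truth of every planted structure. Identical config and seed give identical
#' output.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_study` list with elements `annotation`, `counts`,
#'   `groups`, `tracks`, `pooled_tracks`, `input_track`, `peaks`, `fourc`,
#'   `sequence`, `truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  cfg <- config
  validate_simulation_config(cfg)
  set.seed(cfg$seed)
  layout <- plan_layout(cfg)
  chrom <- cfg$chrom
  L <- cfg$genome_length
  n <- cfg$n_genes

  # --- annotation (stream 1) -------------------------------------------------
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- layout$tss
  gene_len <- 2000
  start <- if_else(strand == "-", tss - gene_len + 1, tss)
  start <- pmax(start, 0)
  end <- pmin(start + gene_len, L)
  annotation <- tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    gene_name = sprintf("G%04d", seq_len(n)),
    chrom = chrom, start = as.numeric(start), end = as.numeric(end),
    strand = strand, tss = as.numeric(tss)
  )

  # --- planted DE truth (stream 2) ------------------------------------------
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  de_idx <- sample(seq_len(n), n_up + n_down)
  status <- rep("null", n)
  status[de_idx[seq_len(n_up)]] <- "up"
  status[de_idx[n_up + seq_len(n_down)]] <- "down"
  true_lfc <- dplyr::case_when(
    status == "up" ~ cfg$planted_lfc,
    status == "down" ~ -cfg$planted_lfc,
    TRUE ~ 0
  )
  congruent <- rep(FALSE, n)
  if (length(de_idx) > 0 && cfg$congruent_fraction > 0) {
    n_cong <- round(cfg$congruent_fraction * length(de_idx))
    congruent[sample(de_idx, n_cong)] <- TRUE
  }

  # --- RNA-seq counts (stream 3) --------------------------------------------
  n_samp <- cfg$n_control + cfg$n_case
  groups <- rep(c("control", "case"), c(cfg$n_control, cfg$n_case))
  depth <- runif(n_samp, 1 / cfg$libsize_range, cfg$libsize_range)
  mu <- outer(rep(cfg$nb_mean, n), depth)
  case_cols <- which(groups == "case")
  mu[, case_cols] <- mu[, case_cols] * 2^true_lfc
  counts <- if (cfg$nb_dispersion > 0) {
    matrix(rnbinom(n * n_samp, mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = n, ncol = n_samp
    )
  } else {
    matrix(rpois(n * n_samp, mu), nrow = n, ncol = n_samp)
  }
  sample_ids <- paste0(
    rep(c("ctl_", "case_"), c(cfg$n_control, cfg$n_case)),
    c(seq_len(cfg$n_control), seq_len(cfg$n_case))
  )
  colnames(counts) <- sample_ids
  count_tbl <- bind_cols(tibble(gene_id = annotation$gene_id), as_tibble(counts))

  # --- enhancer geometry (deterministic given layout) ------------------------
  ec <- cfg$enhancer_cluster
  member_start <- layout$cluster_start +
    (seq_len(ec$n_members) - 1) * (ec$member_width + ec$member_gap)
  cluster_members <- tibble(
    chrom = chrom, start = member_start, end = member_start + ec$member_width,
    name = sprintf("SE_member_%d", seq_len(ec$n_members)), kind = "planted_cluster"
  )
  typ_pos <- floor(seq(layout$typical_region[1], layout$typical_region[2],
    length.out = cfg$n_typical_enhancers
  ))
  typical <- tibble(
    chrom = chrom, start = typ_pos, end = typ_pos + ec$member_width,
    name = sprintf("enh_%d", seq_along(typ_pos)), kind = "typical"
  )
  decoys <- purrr::map(seq_len(cfg$n_decoy_clusters), function(k) {
    s0 <- layout$decoy_starts[k]
    s <- s0 + (seq_len(cfg$decoy_members) - 1) * (ec$member_width + 4000)
    tibble(
      chrom = chrom, start = s, end = s + ec$member_width,
      name = sprintf("decoy%d_m%d", k, seq_len(cfg$decoy_members)),
      kind = sprintf("decoy_%d", k)
    )
  }) |> list_rbind()
  enhancers <- bind_rows(typical, decoys, cluster_members)
  enh_reads <- c(
    rep(cfg$typical_reads, nrow(typical)),
    rep(cfg$decoy_reads, nrow(decoys)),
    rep(ec$member_reads, nrow(cluster_members))
  )
  enh_case_fold <- c(
    rep(1, nrow(typical) + nrow(decoys)),
    rep(ec$amplification, nrow(cluster_members))
  )

  # --- signal tracks (stream 4; marks in cfg$marks order, control then case) -
  n_bins <- ceiling(L / cfg$bin_size)
  bin_centers <- (seq_len(n_bins) - 0.5) * cfg$bin_size
  gauss_profile <- function(centers, total_reads, sigma) {
    v <- numeric(n_bins)
    half <- ceiling(4 * sigma / cfg$bin_size)
    for (i in seq_along(centers)) {
      if (total_reads[i] <= 0) next
      c_bin <- floor(centers[i] / cfg$bin_size) + 1
      idx <- max(1, c_bin - half):min(n_bins, c_bin + half)
      v[idx] <- v[idx] + total_reads[i] * cfg$bin_size *
        stats::dnorm(bin_centers[idx], centers[i], sigma)
    }
    v
  }
  mark_sign <- c(H3K4me3 = 1, H3K4me1 = 1, H3K27ac = 1, H3K27me3 = -1)
  enh_marks <- c("H3K27ac", "H3K4me1")
  enh_centers <- (enhancers$start + enhancers$end) / 2
  enh_sigma <- ec$member_width / 4

  expectation <- function(mark, condition) {
    amp <- rep(cfg$promoter_reads[[mark]], n)
    if (condition == "case") {
      s <- mark_sign[[mark]] * sign(true_lfc)
      chg <- congruent & status != "null"
      amp[chg] <- amp[chg] * 2^(s[chg] * cfg$mark_lfc)
    }
    v <- gauss_profile(annotation$tss, amp, cfg$promoter_sigma)
    if (mark %in% enh_marks) {
      er <- enh_reads * (if (mark == "H3K4me1") 0.6 else 1)
      if (condition == "case") er <- er * enh_case_fold
      v <- v + gauss_profile(enh_centers, er, enh_sigma)
    }
    v + cfg$background_rate
  }

  tracks <- list()
  pooled <- list()
  for (mark in cfg$marks) {
    tracks[[mark]] <- list()
    pooled[[mark]] <- list()
    for (condition in c("control", "case")) {
      lambda <- expectation(mark, condition)
      n_rep <- if (condition == "control") cfg$n_control else cfg$n_case
      reps <- map(seq_len(n_rep), function(r) {
        f <- runif(1, 1 / cfg$libsize_range, cfg$libsize_range)
        vals <- rpois(n_bins, lambda * f)
        signal_track(setNames(list(vals), chrom), cfg$bin_size)
      })
      names(reps) <- paste0(condition, "_", seq_len(n_rep))
      tracks[[mark]][[condition]] <- reps
      pool_vals <- Reduce(`+`, map(reps, function(t) t$values[[chrom]]))
      pooled[[mark]][[condition]] <- signal_track(
        setNames(list(pool_vals), chrom), cfg$bin_size
      )
    }
  }
  input_track <- signal_track(
    setNames(list(rpois(n_bins, cfg$background_rate)), chrom), cfg$bin_size
  )

  # --- peak calls (deterministic from truth) ---------------------------------
  promoter_peaks <- tibble(
    chrom = chrom,
    start = pmax(annotation$tss - 500, 0), end = pmin(annotation$tss + 500, L),
    name = paste0(annotation$gene_id, "_prom"), score = 100, strand = ".",
    summit_offset = NA_real_
  )
  enhancer_peaks <- tibble(
    chrom = enhancers$chrom, start = enhancers$start, end = enhancers$end,
    name = enhancers$name, score = 100, strand = ".", summit_offset = NA_real_
  )
  peaks <- list(
    H3K4me3 = promoter_peaks,
    H3K4me1 = bind_rows(promoter_peaks, enhancer_peaks) |> arrange(.data$start),
    H3K27ac = bind_rows(promoter_peaks, enhancer_peaks) |> arrange(.data$start),
    H3K27me3 = promoter_peaks
  )

  # --- 4C profile (stream 5) -------------------------------------------------
  fc <- cfg$fourc
  target_tss <- annotation$tss[layout$target_gene_index]
  span_lo <- max(0, target_tss - fc$span / 2)
  span_hi <- min(L, target_tss + fc$span / 2)
  frag_bounds <- seq(span_lo, span_hi, by = fc$frag_length)
  fragments <- tibble(
    frag_id = seq_len(length(frag_bounds) - 1),
    chrom = chrom,
    start = frag_bounds[-length(frag_bounds)],
    end = frag_bounds[-1]
  )
  frag_mid <- (fragments$start + fragments$end) / 2
  viewpoint <- which.min(abs(frag_mid - target_tss))
  d <- abs(frag_mid - frag_mid[viewpoint])
  lambda4c <- fc$decay_a * pmax(d, fc$frag_length)^(-fc$decay_b)
  cluster_mid <- layout$cluster_start + layout$cluster_span / 2
  bump_center <- which.min(abs(frag_mid - cluster_mid))
  bump_idx <- seq(
    bump_center - floor((fc$bump_n_fragments - 1) / 2),
    length.out = fc$bump_n_fragments
  )
  bump_idx <- bump_idx[bump_idx >= 1 & bump_idx <= nrow(fragments)]
  lam_ctl <- lambda4c
  lam_case <- lambda4c
  lam_case[bump_idx] <- lam_case[bump_idx] * fc$bump_fold
  fourc_counts <- tibble(
    frag_id = fragments$frag_id,
    control = rpois(nrow(fragments), lam_ctl),
    case = rpois(nrow(fragments), lam_case)
  )

  # --- promoter sequence with planted motifs (stream 6) ----------------------
  mo <- cfg$motif
  seq_lo <- max(0, target_tss - 5000)
  seq_hi <- min(L, target_tss + 5000)
  seq_len_bp <- seq_hi - seq_lo
  bases <- sample(c("A", "C", "G", "T"), seq_len_bp, replace = TRUE)
  cons <- strsplit(toupper(mo$consensus), "")[[1]]
  motif_offsets <- integer(0)
  if (mo$n_planted > 0) {
    cand <- floor(seq(500, seq_len_bp - 500 - length(cons), length.out = mo$n_planted))
    for (off in cand) bases[(off + 1):(off + length(cons))] <- cons
    motif_offsets <- as.integer(cand)
  }
  sequence <- list(
    chrom = chrom, offset = seq_lo, seq = paste(bases, collapse = "")
  )

  truth <- list(
    genes = tibble(
      gene_id = annotation$gene_id, status = status, true_lfc = true_lfc,
      congruent = congruent
    ),
    super_enhancer = list(
      interval = tibble(
        chrom = chrom, start = layout$cluster_start,
        end = layout$cluster_start + layout$cluster_span
      ),
      members = cluster_members
    ),
    fourc_bump = list(
      fragment_indices = bump_idx,
      interval = tibble(
        chrom = chrom, start = min(fragments$start[bump_idx]),
        end = max(fragments$end[bump_idx])
      )
    ),
    motif_positions = tibble(
      chrom = chrom,
      start = seq_lo + motif_offsets,
      end = seq_lo + motif_offsets + length(cons),
      offset = motif_offsets
    ),
    target_gene = annotation$gene_id[layout$target_gene_index]
  )

  structure(
    list(
      annotation = annotation, counts = count_tbl, groups = groups,
      tracks = tracks, pooled_tracks = pooled, input_track = input_track,
      peaks = peaks,
      fourc = list(
        fragments = fragments, viewpoint = viewpoint, counts = fourc_counts
      ),
      sequence = sequence, truth = truth,
      depth_factors = setNames(depth, sample_ids), config = cfg
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d genes, %d+%d samples, genome %.3g bp, seed %d\n",
    nrow(x$annotation), x$config$n_control, x$config$n_case,
    x$config$genome_length, x$config$seed
  ))
  invisible(x)
}

#' Write a synthetic study to standard file formats
#'
#' Emits TSV counts and annotation, BED peaks per mark, bedGraph tracks per
#' mark/condition/replicate, the 4C fragment map and counts as TSV, the
#' promoter sequence as FASTA, the ground truth as JSON, and a manifest TSV
#' with an md5 checksum per file.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return A tibble manifest (`file`, `md5`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_fixture <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  readr::write_tsv(study$annotation, p("annotation.tsv"))
  readr::write_tsv(study$counts, p("counts.tsv"))
  readr::write_tsv(
    tibble(sample = names(study$counts)[-1], group = study$groups),
    p("samples.tsv")
  )
  for (mark in names(study$peaks)) {
    write_bed(study$peaks[[mark]], p(sprintf("peaks_%s.bed", mark)))
  }
  manifest_tracks <- list()
  for (mark in names(study$tracks)) {
    for (condition in names(study$tracks[[mark]])) {
      reps <- study$tracks[[mark]][[condition]]
      for (rn in names(reps)) {
        f <- sprintf("track_%s_%s.bedgraph", mark, rn)
        write_bedgraph(reps[[rn]], p(f))
        manifest_tracks[[f]] <- tibble(
          file = f, mark = mark, condition = condition, replicate = rn,
          library_size = reps[[rn]]$library_size,
          bin_size = reps[[rn]]$bin_size
        )
      }
    }
  }
  write_bedgraph(study$input_track, p("track_input.bedgraph"))
  readr::write_tsv(list_rbind(unname(manifest_tracks)), p("track_manifest.tsv"))
  readr::write_tsv(study$fourc$fragments, p("fourc_fragments.tsv"))
  readr::write_tsv(
    mutate(study$fourc$counts, viewpoint = .data$frag_id == study$fourc$viewpoint),
    p("fourc_counts.tsv")
  )
  writeLines(
    c(
      sprintf(
        ">%s:%d-%d planted_promoter", study$sequence$chrom,
        study$sequence$offset, study$sequence$offset + nchar(study$sequence$seq)
      ),
      gsub("(.{80})", "\\1\n", study$sequence$seq)
    ),
    p("promoter.fa")
  )
  # gene sets and a regulator model derived from the planted truth: the
  # "pathway" inputs a real study would bring along
  tg <- study$truth$genes
  up_ids <- tg$gene_id[tg$status == "up"]
  down_ids <- tg$gene_id[tg$status == "down"]
  null_ids <- tg$gene_id[tg$status == "null"]
  n_rand <- max(5, min(length(up_ids), 50))
  rand_ids <- null_ids[seq_len(min(n_rand, length(null_ids)))]
  sets <- list(
    planted_up = up_ids, planted_down = down_ids, random_set = rand_ids
  )
  write_gmt(sets[lengths(sets) > 0], p("gene_sets.gmt"))
  reg <- bind_rows(
    tibble(
      regulator = "planted_activator",
      target = c(up_ids, down_ids),
      sign = c(rep(1, length(up_ids)), rep(-1, length(down_ids)))
    )
  )
  readr::write_tsv(reg, p("regulator_models.tsv"))
  cons <- strsplit(toupper(study$config$motif$consensus), "")[[1]]
  pfm <- matrix(1, 4, length(cons), dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm[cbind(match(cons, c("A", "C", "G", "T")), seq_along(cons))] <- 17
  write_jaspar(pfm, "planted_motif", p("motif.pfm"))
  jsonlite::write_json(
    list(
      chrom = study$config$chrom,
      genome_length = study$config$genome_length,
      bin_size = study$config$bin_size,
      n_control = study$config$n_control,
      n_case = study$config$n_case,
      fourc_viewpoint = study$fourc$viewpoint,
      sequence_offset = study$sequence$offset,
      marks = study$config$marks
    ),
    p("study_info.json"),
    auto_unbox = TRUE, digits = NA
  )

  truth_json <- list(
    genes = study$truth$genes,
    super_enhancer = study$truth$super_enhancer$interval,
    super_enhancer_members = study$truth$super_enhancer$members,
    fourc_bump_fragments = study$truth$fourc_bump$fragment_indices,
    fourc_bump_interval = study$truth$fourc_bump$interval,
    motif_positions = study$truth$motif_positions,
    target_gene = study$truth$target_gene,
    config_hash = rlang::hash(study$config)
  )
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(setdiff(list.files(dir), "manifest.tsv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files)))
  )
  readr::write_tsv(manifest, p("manifest.tsv"))
  manifest
}
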