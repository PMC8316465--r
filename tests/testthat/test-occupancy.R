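test_that("nearest-TSS assignment matches the exhaustive search and its tie-break", {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "c", tss = c(120, 400)
  )
  pk <- genomic_interval("c", 100, 200)
  out <- assign_nearest_tss(pk, ann)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$tss_distance, -30) # tss 120 - midpoint 150

  # midpoint exactly between two TSS -> smaller coordinate
  ann2 <- tibble::tibble(gene_id = c("hi", "lo"), chrom = "c", tss = c(200, 100))
  pk2 <- genomic_interval("c", 100, 200) # midpoint 150
  expect_equal(assign_nearest_tss(pk2, ann2)$gene_id, "lo")

  # single gene annotation: always that gene
  ann3 <- tibble::tibble(gene_id = "only", chrom = "c", tss = 5)
  pks <- genomic_interval("c", c(0, 500, 9000), c(10, 600, 9100))
  expect_equal(assign_nearest_tss(pks, ann3)$gene_id, rep("only", 3))

  # random instances against the brute-force oracle
  set.seed(30)
  for (rep in 1:110) {
    ng <- sample(2:200, 1)
    np <- sample(1:50, 1)
    ann <- tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(ng)), chrom = "c",
      tss = sample(0:20000, ng)
    )
    s <- sample(0:20000, np)
    pk <- genomic_interval("c", s, s + sample(1:500, np, replace = TRUE))
    got <- assign_nearest_tss(pk, ann)
    mid <- floor((pk$start + pk$end) / 2)
    expect_equal(got$gene_id, bf_nearest(mid, ann$tss, ann$gene_id))
  }
})

test_that("summit overrides midpoint and off-annotation chromosomes stay unassigned", {
  ann <- tibble::tibble(gene_id = c("a", "b"), chrom = "c", tss = c(0, 1000))
  pk <- genomic_interval("c", 0, 900)
  pk$summit_offset <- 880 # summit at 880, midpoint 450
  expect_equal(assign_nearest_tss(pk, ann)$gene_id, "b")

  pk2 <- genomic_interval(c("c", "cX"), c(0, 0), c(10, 10))
  expect_message(out <- assign_nearest_tss(pk2, ann), "unassigned")
  expect_true(is.na(out$gene_id[2]))
})

test_that("TSS-window matrices are zero for empty tracks and flat for uniform ones", {
  ann <- tibble::tibble(
    gene_id = c("g1", "g2"), gene_name = c("g1", "g2"), chrom = "c",
    start = c(4000, 8000), end = c(6000, 10000), strand = c("+", "-"),
    tss = c(4000, 9999)
  )
  z <- signal_track(list(c = rep(0, 400)), bin_size = 50)
  expect_equal(sum(tss_window_matrix(z, ann, 2000, 20)), 0)

  u <- signal_track(list(c = rep(2, 400)), bin_size = 50)
  m <- tss_window_matrix(u, ann, 2000, 20, as_rpm = FALSE)
  expect_true(all(abs(m - m[1, 1]) < 1e-9))
})

test_that("row sums equal the whole-window sum and planted peaks center correctly", {
  set.seed(31)
  v <- rpois(400, 2)
  tr <- signal_track(list(c = v), bin_size = 50)
  ann <- tibble::tibble(
    gene_id = "g", gene_name = "g", chrom = "c", start = 9000, end = 11000,
    strand = "+", tss = 9000
  )
  m <- tss_window_matrix(tr, ann, 2000, 40, as_rpm = FALSE)
  expect_equal(sum(m), window_sum(tr, "c", 7000, 11000), tolerance = 1e-9)

  # a Gaussian bump at the TSS peaks in the central bins, and a - strand gene
  # with an upstream bump shows it in the early (upstream) bins
  bump <- function(center) {
    x <- (seq_len(400) - 0.5) * 50
    1000 * 50 * dnorm(x, center, 300)
  }
  tr2 <- signal_track(list(c = bump(9000)), bin_size = 50)
  m2 <- tss_window_matrix(tr2, ann, 2000, 40, as_rpm = FALSE)
  expect_true(which.max(m2[1, ]) %in% 20:21)

  ann_m <- dplyr::mutate(ann, strand = "-")
  tr3 <- signal_track(list(c = bump(10500)), bin_size = 50) # downstream in + terms
  m3 <- tss_window_matrix(tr3, ann_m, 2000, 40, as_rpm = FALSE)
  expect_lt(which.max(m3[1, ]), 15) # flipped to the upstream side
})

test_that("edge windows are zero-padded with a warning", {
  tr <- signal_track(list(c = rep(1, 40)), bin_size = 50)
  ann <- tibble::tibble(
    gene_id = "g", gene_name = "g", chrom = "c", start = 100, end = 600,
    strand = "+", tss = 100
  )
  expect_warning(m <- tss_window_matrix(tr, ann, 2000, 20, as_rpm = FALSE), "clipped")
  # window [-1900, 2100): bins fully left of the chromosome are zero, the
  # last bin is clipped at the right edge (100 of 200 bp remain)
  expect_equal(sum(m[1, 1:9]), 0)
  expect_equal(unname(m[1, 20]), 2)
})

test_that("differential occupancy is null on identical tracks and exact on doubling", {
  set.seed(32)
  ann <- tibble::tibble(
    gene_id = sprintf("g%d", 1:5), gene_name = sprintf("g%d", 1:5), chrom = "c",
    start = seq(10000, 90000, by = 20000), end = seq(12000, 92000, by = 20000),
    strand = "+", tss = seq(10000, 90000, by = 20000)
  )
  mk <- function(f = 1) {
    v <- rpois(2000, 5) * f
    signal_track(list(c = v), bin_size = 50)
  }
  base <- list(mk(), mk(), mk())
  same <- suppressMessages(differential_occupancy(base, base, ann, "H3K27ac"))
  expect_true(all(same$log2_ratio == 0))
  expect_true(all(same$direction_call == "ns"))

  # doubled occupancy at constant sequencing depth: log2_ratio ~ 1 everywhere
  doubled <- purrr::map(base, function(t) {
    signal_track(list(c = t$values$c * 2), t$bin_size, library_size = t$library_size)
  })
  occ <- suppressMessages(differential_occupancy(doubled, base, ann, "H3K27ac"))
  expect_equal(occ$log2_ratio, rep(1, nrow(occ)), tolerance = 0.02)
  expect_error(
    differential_occupancy(base, list(signal_track(list(c = 1:10), 25)), ann, "x"),
    "bin sizes"
  )
})

test_that("planted congruent promoter changes are recovered per mark", {
  s <- scaled_study(seed = 33)
  tg <- s$truth$genes
  occ <- suppressMessages(differential_occupancy(
    s$tracks$H3K27ac$case, s$tracks$H3K27ac$control, s$annotation, "H3K27ac"
  ))
  up_cong <- tg$status == "up" & tg$congruent
  expect_gte(mean(occ$direction_call[up_cong] == "increased"), 0.8)
  occ3 <- suppressMessages(differential_occupancy(
    s$tracks$H3K27me3$case, s$tracks$H3K27me3$control, s$annotation, "H3K27me3"
  ))
  expect_gte(mean(occ3$direction_call[up_cong] == "decreased"), 0.8)
  null_genes <- tg$status == "null"
  expect_lte(mean(occ$direction_call[null_genes] != "ns"), 0.1)
})
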