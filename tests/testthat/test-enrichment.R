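mk_ranked <- function(ids, metric) tibble::tibble(gene_id = ids, metric = metric)

test_that("enrichment score reproduces hand-computed running sums", {
  r <- mk_ranked(c("g1", "g2", "g3", "g4"), c(3, 2, 1, 0.5))
  expect_equal(gsea_es(r, "g1"), 1.0)
  expect_equal(gsea_es(r, "g4"), -1.0)
  expect_error(gsea_es(r, c("g1", "g2", "g3", "g4")), "whole")
  expect_error(gsea_es(r, "absent"), "empty overlap")
})

test_that("enrichment score equals exhaustive prefix enumeration on random lists", {
  set.seed(70)
  for (rep in 1:120) {
    N <- sample(10:400, 1)
    ids <- sprintf("g%04d", seq_len(N))
    metric <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    k <- sample(1:(N - 1), 1)
    set <- sample(ids, k)
    p <- sample(c(0, 1, 2), 1)
    got <- gsea_es(mk_ranked(ids, metric), set, weight_p = p)
    want <- bf_gsea_es(metric, ids %in% set, weight_p = p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  for (rep in 1:20) {
    N <- 100
    ids <- sprintf("g%03d", 1:N)
    metric <- sort(rnorm(N, sd = 1.5), decreasing = TRUE)
    set <- sample(ids, 15)
    got <- gsea_es(mk_ranked(ids, metric), set, weight_p = 1)
    stats <- setNames(metric, ids)
    want <- fgsea::calcGseaStat(stats, selectedStats = which(ids %in% set))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("reversing the ranking negates the enrichment score", {
  set.seed(72)
  N <- 60
  ids <- sprintf("g%02d", 1:N)
  metric <- sort(rexp(N), decreasing = TRUE)
  set <- sample(ids, 10)
  a <- gsea_es(mk_ranked(ids, metric), set)
  b <- gsea_es(mk_ranked(rev(ids), rev(-metric)), set)
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("permutation significance flags a planted top set and is deterministic", {
  set.seed(73)
  N <- 300
  ids <- sprintf("g%03d", 1:N)
  metric <- sort(rnorm(N), decreasing = TRUE)
  sets <- list(top = ids[1:20], rand = sample(ids, 20))
  r <- mk_ranked(ids, metric)
  out <- gsea_significance(r, sets, n_perm = 1000, seed = 7)
  top <- out[out$set_id == "top", ]
  expect_gt(top$nes, 0)
  expect_lte(top$p_perm, 0.01)
  out2 <- gsea_significance(r, sets, n_perm = 1000, seed = 7)
  expect_identical(out, out2)
  expect_message(
    gsea_significance(r, list(tiny = ids[1:2]), n_perm = 100, seed = 1),
    "skipped"
  )
  expect_error(gsea_significance(r, sets, n_perm = 10), "n_perm")
})

test_that("permutation p-values for random sets are roughly uniform", {
  set.seed(74)
  N <- 150
  ids <- sprintf("g%03d", 1:N)
  metric <- sort(rnorm(N), decreasing = TRUE)
  r <- mk_ranked(ids, metric)
  ps <- vapply(1:60, function(i) {
    out <- gsea_significance(r, list(s = sample(ids, 15)),
      n_perm = 200, seed = 1000 + i
    )
    out$p_perm
  }, numeric(1))
  # for uniform p, ~95% fall inside [0.025, 0.975]
  expect_gte(mean(ps >= 0.025 & ps <= 0.975), 0.85)
})

test_that("hypergeometric over-representation matches exact combinatorics", {
  # all 5 hits inside a 5-gene set from a 20-gene universe: p = 1 / C(20,5)
  uni <- sprintf("u%02d", 1:20)
  out <- overrepresentation(uni[1:5], uni, list(s = uni[1:5]))
  expect_equal(out$p, 1 / choose(20, 5), tolerance = 1e-12)

  # zero overlap: right tail P(X >= 0) = 1
  out0 <- overrepresentation(uni[1:3], uni, list(s = uni[10:12]))
  expect_equal(out0$p, 1)

  # overlap at its maximum equals the single-term probability
  out_max <- overrepresentation(uni[1:4], uni, list(s = uni[1:6]))
  k <- 4
  single_tail <- sum(dhyper(k, 6, 14, 4))
  expect_equal(out_max$p, single_tail, tolerance = 1e-12)

  expect_error(overrepresentation(c("zz"), uni, list(s = uni[1:2])), "subset")
  # BH across sets
  many <- list(a = uni[1:5], b = uni[6:10], c = uni[1:10])
  res <- overrepresentation(uni[1:5], uni, many)
  expect_equal(res$fdr, bf_bh(res$p))
})

test_that("regulator z follows its closed form and antisymmetry", {
  de <- tibble::tibble(
    gene_id = sprintf("t%02d", 1:20),
    call = c(rep("up", 16), rep("down", 4))
  )
  model16 <- tibble::tibble(
    regulator = "r", target = sprintf("t%02d", 1:16), sign = 1
  )
  expect_equal(regulator_z(model16, de)$z, 4)

  model_split <- tibble::tibble(
    regulator = "r", target = sprintf("t%02d", c(1:2, 17:18)),
    sign = c(1, 1, 1, 1)
  ) # 2 concordant (up), 2 discordant (down)
  expect_equal(regulator_z(model_split, de)$z, 0)

  model94 <- tibble::tibble(
    regulator = "r", target = sprintf("t%02d", 1:13),
    sign = c(rep(1, 9), rep(-1, 4))
  )
  expect_equal(regulator_z(model94, de)$z, 5 / sqrt(13), tolerance = 1e-12)

  flipped <- dplyr::mutate(model94, sign = -sign)
  expect_equal(regulator_z(flipped, de)$z, -5 / sqrt(13), tolerance = 1e-12)

  # only ns targets: no informative rows
  ns_de <- tibble::tibble(gene_id = "t01", call = "ns")
  expect_equal(nrow(regulator_z(model16, ns_de)), 0)
  expect_error(regulator_z(dplyr::mutate(model16, sign = 2), de), "sign")
})

test_that("GMT files round-trip", {
  f <- withr::local_tempfile()
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
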