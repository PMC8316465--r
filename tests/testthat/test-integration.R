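mk_de <- function(gene_id, call) {
  tibble::tibble(gene_id = gene_id, call = call)
}
mk_occ <- function(gene_id, mark, dir, fdr = 0.01) {
  tibble::tibble(
    gene_id = gene_id, mark = mark, window = "tss_pm_2000",
    rpm_control = 1, rpm_case = 2, log2_ratio = ifelse(dir == "increased", 1,
      ifelse(dir == "decreased", -1, 0)
    ),
    p = fdr, fdr = fdr, direction_call = dir
  )
}

test_that("the polarity rule decides congruence", {
  de <- mk_de(c("g1", "g2", "g3"), c("up", "up", "down"))
  occ <- dplyr::bind_rows(
    mk_occ("g1", "H3K27ac", "increased"), # supports up
    mk_occ("g2", "H3K27me3", "increased"), # repressive up: does NOT support up
    mk_occ("g3", "H3K27me3", "increased") # supports down
  )
  cong <- congruence_classify(de, occ)
  calls <- tidy(cong)
  expect_equal(calls$congruent[calls$gene_id == "g1"], TRUE)
  expect_equal(calls$supporting_marks[calls$gene_id == "g1"], "H3K27ac:increased")
  expect_equal(calls$congruent[calls$gene_id == "g2"], FALSE)
  expect_equal(calls$congruent[calls$gene_id == "g3"], TRUE)

  # ns occupancy never supports
  cong2 <- congruence_classify(de, mk_occ("g1", "H3K27ac", "ns"))
  expect_false(any(tidy(cong2)$congruent))
})

test_that("summary counts are conserved and bounded by the DE counts", {
  set.seed(40)
  genes <- sprintf("g%03d", 1:60)
  de <- mk_de(genes, sample(c("up", "down", "ns"), 60, replace = TRUE))
  occ <- dplyr::bind_rows(
    mk_occ(genes, "H3K27ac", sample(c("increased", "decreased", "ns"), 60, TRUE)),
    mk_occ(genes, "H3K27me3", sample(c("increased", "decreased", "ns"), 60, TRUE))
  )
  cong <- congruence_classify(de, occ)
  g <- glance(cong)
  expect_lte(g$n_up_congruent, g$n_up)
  expect_lte(g$n_down_congruent, g$n_down)
  expect_equal(g$n_up, sum(de$call == "up"))
  calls <- tidy(cong)
  expect_equal(g$n_up_congruent, sum(calls$de_call == "up" & calls$congruent))

  rep <- summarize_integration(cong)
  expect_equal(rep$summary, g)
  expect_true(all(rep$mark_support$support_frequency >= 0 &
    rep$mark_support$support_frequency <= 1))
})

test_that("adding a mark table never reduces congruent counts", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:50)
  de <- mk_de(genes, sample(c("up", "down"), 50, replace = TRUE))
  occ1 <- mk_occ(genes, "H3K4me3", sample(c("increased", "decreased", "ns"), 50, TRUE))
  occ2 <- mk_occ(genes, "H3K27ac", sample(c("increased", "decreased", "ns"), 50, TRUE))
  g1 <- glance(congruence_classify(de, occ1))
  g12 <- glance(congruence_classify(de, list(occ1, occ2)))
  expect_gte(g12$n_up_congruent, g1$n_up_congruent)
  expect_gte(g12$n_down_congruent, g1$n_down_congruent)
})

test_that("relabeling conditions swaps directions but leaves congruence invariant", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:80)
  de <- mk_de(genes, sample(c("up", "down"), 80, replace = TRUE))
  occ <- dplyr::bind_rows(
    mk_occ(genes, "H3K27ac", sample(c("increased", "decreased", "ns"), 80, TRUE)),
    mk_occ(genes, "H3K27me3", sample(c("increased", "decreased", "ns"), 80, TRUE))
  )
  swap_de <- dplyr::mutate(de, call = dplyr::recode(call, up = "down", down = "up"))
  swap_occ <- dplyr::mutate(occ,
    direction_call = dplyr::recode(direction_call,
      increased = "decreased", decreased = "increased"
    ),
    log2_ratio = -log2_ratio
  )
  a <- tidy(congruence_classify(de, occ))
  b <- tidy(congruence_classify(swap_de, swap_occ))
  expect_equal(a$congruent, b$congruent)
  expect_equal(a$de_call == "up", b$de_call == "down")
})

test_that("occupancy-only genes are ignored with a message and empty input is safe", {
  de <- mk_de("g1", "up")
  occ <- mk_occ(c("g1", "g9"), "H3K27ac", "increased")
  expect_message(cong <- congruence_classify(de, occ), "ignored")
  expect_equal(nrow(tidy(cong)), 1)

  empty <- congruence_classify(mk_de(character(0), character(0)), occ[0, ])
  rep <- summarize_integration(empty)
  expect_equal(rep$summary$n_up, 0)
  expect_equal(nrow(rep$mark_support), 0)
})

test_that("the planted congruent fraction is recovered on the synthetic study", {
  s <- scaled_study(seed = 43, n_genes = 800)
  fit <- suppressMessages(test_two_group(s$counts, s$groups, ref = "control"))
  de <- classify_de(fit)
  occ <- purrr::map(names(s$tracks), function(mark) {
    suppressMessages(differential_occupancy(
      s$tracks[[mark]]$case, s$tracks[[mark]]$control, s$annotation, mark
    ))
  })
  cong <- suppressMessages(congruence_classify(de, occ))
  tg <- s$truth$genes
  true_de <- tg$gene_id[tg$status != "null"]
  calls <- tidy(cong)
  frac <- mean(calls$congruent[calls$gene_id %in% true_de])
  expect_lt(abs(frac - 0.5), 0.1)
  # and the recovered congruent set matches the planted one closely
  planted_cong <- tg$gene_id[tg$congruent]
  got_cong <- calls$gene_id[calls$congruent]
  expect_gt(length(intersect(got_cong, planted_cong)) /
    length(union(got_cong, planted_cong)), 0.8)
})
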