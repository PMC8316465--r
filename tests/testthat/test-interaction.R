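mk_fragmap <- function(n = 40, len = 10) {
  digest(fragment_lengths = rep(len, n), chrom = "c")
}

test_that("digest cuts at recognition-site starts with end fragments intact", {
  fm <- digest("AAGATCAAGATCAA", site = "GATC")
  expect_equal(fm$start, c(0, 2, 8))
  expect_equal(fm$end, c(2, 8, 14))

  expect_warning(one <- digest("AAAATTTT", site = "GATC"), "absent")
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(0, 8))

  expect_identical(
    digest("aagatcaagatcaa", site = "gatc")$start,
    digest("AAGATCAAGATCAA", site = "GATC")$start
  )
  expect_error(digest("ACGT", site = "AC"), "site")

  # brute-force site search oracle on random sequences
  set.seed(80)
  for (rep in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    fm <- suppressWarnings(digest(s, site = "GATC"))
    cuts <- c()
    for (i in 1:(nchar(s) - 3)) {
      if (substr(s, i, i + 3) == "GATC") cuts <- c(cuts, i - 1)
    }
    cuts <- cuts[cuts > 0]
    expect_equal(fm$start, c(0, cuts))
  }
})

test_that("profile normalization masks the viewpoint and conserves 1e6 mass", {
  fm <- mk_fragmap(20)
  counts <- rep(5, 20)
  prof <- fourc_profile(counts, fm, viewpoint = 10, exclude_k = 2)
  tab <- tidy(prof)
  expect_equal(sum(tab$masked), 5)
  expect_true(all(is.na(tab$norm_count[tab$masked])))
  un <- tab$norm_count[!tab$masked]
  expect_equal(sum(un), 1e6, tolerance = 1e-6)
  expect_true(all(abs(un - un[1]) < 1e-9)) # uniform in, uniform out

  # scale invariance of the normalized profile
  prof2 <- fourc_profile(counts * 2, fm, viewpoint = 10, exclude_k = 2)
  expect_equal(tidy(prof2)$norm_count, tab$norm_count)

  expect_error(fourc_profile(rep(-1, 20), fm, 10), "negative")
  expect_error(fourc_profile(counts[-1], fm, 10), "one count per fragment")
})

test_that("decay exponent is recovered on noiseless and noisy power-law profiles", {
  fm <- mk_fragmap(n = 201, len = 10)
  vp <- 101
  mid <- (fm$start + fm$end) / 2
  d <- abs(mid - mid[vp])
  # scale chosen so counts stay well above the +1 regularizer over the whole
  # distance range (10 .. 1000 bp -> expected counts 1000 .. 10)
  lambda <- 1e4 * pmax(d, 1)^-1

  # noiseless: counts exactly a * d^-b
  prof <- fit_decay(fourc_profile(lambda, fm, vp))
  expect_lt(abs(prof$decay$b - 1), 0.05)

  # Poisson noise at the same scale, seeded
  set.seed(81)
  noisy <- rpois(length(lambda), lambda)
  profn <- fit_decay(fourc_profile(noisy, fm, vp))
  expect_lt(abs(profn$decay$b - 1), 0.2)

  # constant counts: b collapses to the zero boundary and is flagged
  expect_warning(flat <- fit_decay(fourc_profile(rep(50, 201), fm, vp)), "decay")
  expect_true(flat$decay$flat)

  expect_error(
    fit_decay(fourc_profile(c(rep(0, 200), 5), fm, vp)),
    "count > 0"
  )
})

test_that("interaction calls recover a planted bump and respect run thresholds", {
  fm <- mk_fragmap(n = 201, len = 10)
  vp <- 101
  mid <- (fm$start + fm$end) / 2
  d <- abs(mid - mid[vp])
  lambda <- 5000 * pmax(d, 1)^-1
  bump <- 150:155
  lam2 <- lambda
  lam2[bump] <- lam2[bump] * 5
  set.seed(82)
  counts <- rpois(length(lam2), lam2)
  prof <- fit_decay(fourc_profile(counts, fm, vp))
  calls <- call_interactions(prof, z_min = 2, min_run = 3)
  expect_equal(nrow(calls), 1)
  expect_lte(calls$start, fm$start[155])
  expect_gte(calls$end, fm$end[150])

  # no bump: no calls; raising z_min never adds calls
  counts0 <- rpois(length(lambda), lambda)
  prof0 <- fit_decay(fourc_profile(counts0, fm, vp))
  expect_equal(nrow(call_interactions(prof0, z_min = 2.5, min_run = 3)), 0)
  n_low <- nrow(call_interactions(prof, z_min = 1.5))
  n_high <- nrow(call_interactions(prof, z_min = 3))
  expect_lte(n_high, n_low)

  # structural: calls are disjoint and each spans >= min_run fragments
  expect_true(all(calls$n_fragments >= 3))
  expect_error(call_interactions(fourc_profile(counts, fm, vp)), "decay")
})

test_that("relative interaction frequency normalizes to the control site", {
  v <- tibble::tibble(site = c("a", "b", "c", "ctrl"), value = c(3, 6, 1.5, 3))
  out <- relative_interaction_frequency(v, "ctrl")
  expect_equal(out$ratio, c(1, 2, 0.5, 1))
  same <- relative_interaction_frequency(
    tibble::tibble(site = c("x", "ctrl"), value = c(4, 4)), "ctrl"
  )
  expect_equal(same$ratio, c(1, 1))
  expect_error(
    relative_interaction_frequency(
      tibble::tibble(site = c("x", "ctrl"), value = c(1, 0)), "ctrl"
    ),
    "> 0"
  )
})

test_that("percent input follows the dilution-adjusted delta-Ct closed form", {
  tab <- tibble::tibble(
    site = c("s1", "s2", "s3"),
    ct_ip = c(20, 20, 12.356),
    ct_input = c(20, 20, 20),
    input_fraction = c(1, 0.01, 0.01)
  )
  out <- percent_input(tab)
  expect_equal(out$percent_input[1], 100)
  expect_equal(out$percent_input[2], 1.0, tolerance = 1e-9)
  expect_equal(out$percent_input[3], 100 * 2^((20 - log2(100)) - 12.356), tolerance = 1e-12)
  expect_equal(out$percent_input[3], 200, tolerance = 1e-3) # ~2-fold over input

  # strictly decreasing in Ct_IP; invariant to shifting both Ct columns
  base <- percent_input(tibble::tibble(
    site = "s", ct_ip = 15, ct_input = 18, input_fraction = 0.02
  ))$percent_input
  higher <- percent_input(tibble::tibble(
    site = "s", ct_ip = 16, ct_input = 18, input_fraction = 0.02
  ))$percent_input
  shifted <- percent_input(tibble::tibble(
    site = "s", ct_ip = 18, ct_input = 21, input_fraction = 0.02
  ))$percent_input
  expect_lt(higher, base)
  expect_equal(shifted, base, tolerance = 1e-12)

  expect_error(
    percent_input(dplyr::mutate(tab, input_fraction = 0)),
    "input_fraction"
  )
})
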