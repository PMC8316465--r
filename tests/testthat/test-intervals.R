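test_that("read_bed maps BED and narrowPeak fields and rejects malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr2\t0\t50"), f)
  x <- read_bed(f)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(100, 0))
  expect_equal(x$end, c(200, 50))

  np <- withr::local_tempfile()
  writeLines(c(
    "chr1\t100\t200\tp1\t500\t+\t3.2\t5.1\t4.4\t50",
    "chr1\t300\t400\tp2\t200\t-\t3.2\t5.1\t4.4\t-1"
  ), np)
  x <- read_bed(np)
  expect_equal(x$summit_offset, c(50, NA))
  expect_equal(x$strand, c("+", "-"))

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines("chr1\tx\t200", bad)
  expect_error(read_bed(bad), "non-integer")
})

test_that("BED6 round-trip preserves coordinates and names byte-identically", {
  f <- withr::local_tempfile()
  orig <- c("chr1\t100\t200\ta\t5\t+", "chr1\t400\t900\tb\t0\t-")
  writeLines(orig, f)
  out <- withr::local_tempfile()
  write_bed(read_bed(f), out)
  expect_identical(readLines(out), orig)
})

test_that("gene annotation converts GTF coordinates and resolves TSS by strand", {
  g <- withr::local_tempfile()
  writeLines(c(
    paste("chr1", "src", "gene", "101", "200", ".", "+", ".",
      'gene_id "g1"; gene_name "G1";',
      sep = "\t"
    ),
    paste("chr1", "src", "gene", "101", "200", ".", "-", ".",
      'gene_id "g2";',
      sep = "\t"
    )
  ), g)
  ann <- read_gene_annotation(g, dialect = "gtf")
  expect_equal(ann$start, c(100, 100))
  expect_equal(ann$end, c(200, 200))
  expect_equal(ann$tss, c(100, 199))

  # first-listed transcript wins, with a warning
  writeLines(c(
    paste("chr1", "src", "transcript", "101", "200", ".", "+", ".",
      'gene_id "g1";',
      sep = "\t"
    ),
    paste("chr1", "src", "transcript", "151", "300", ".", "+", ".",
      'gene_id "g1";',
      sep = "\t"
    )
  ), g)
  expect_warning(ann <- read_gene_annotation(g, dialect = "gtf"), "first-listed")
  expect_equal(ann$tss, 100)

  # conflicting strands are an error
  writeLines(c(
    paste("chr1", "src", "gene", "101", "200", ".", "+", ".", 'gene_id "g1";', sep = "\t"),
    paste("chr1", "src", "gene", "301", "400", ".", "-", ".", 'gene_id "g1";', sep = "\t")
  ), g)
  expect_error(read_gene_annotation(g, dialect = "gtf"), "conflicting strands")
})

test_that("merge_intervals matches the brute-force oracle and the stated examples", {
  x <- genomic_interval("chr1", c(0, 5000), c(1000, 6000))
  m <- merge_intervals(x, 12500)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 6000))

  m <- merge_intervals(genomic_interval("chr1", c(0, 30000), c(1000, 31000)), 12500)
  expect_equal(nrow(m), 2)

  one <- genomic_interval("chr1", 5, 10)
  expect_equal(merge_intervals(one, 99)[, c("start", "end")], one[, c("start", "end")])
  expect_error(merge_intervals(one, -1), "max_gap")

  set.seed(1)
  for (rep in 1:120) {
    n <- sample(2:20, 1)
    s <- sample(0:5000, n, replace = TRUE)
    e <- s + sample(1:800, n, replace = TRUE)
    gap <- sample(0:500, 1)
    got <- merge_intervals(genomic_interval("c", s, e), gap)
    want <- bf_merge(s, e, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("merge_intervals is idempotent and equals per-bp union at gap 0", {
  set.seed(2)
  for (rep in 1:30) {
    n <- sample(2:15, 1)
    s <- sample(0:2000, n, replace = TRUE)
    e <- s + sample(1:400, n, replace = TRUE)
    gap <- sample(0:200, 1)
    m <- merge_intervals(genomic_interval("c", s, e), gap)
    m2 <- merge_intervals(m, gap)
    expect_equal(m[, c("chrom", "start", "end")], m2[, c("chrom", "start", "end")])

    # per-bp boolean mask oracle for classic overlap-union
    m0 <- merge_intervals(genomic_interval("c", s, e), 0)
    mask <- logical(max(e))
    for (i in seq_len(n)) mask[(s[i] + 1):e[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    expect_equal(m0$start, starts[r$values])
    expect_equal(m0$end, ends[r$values])
  }
})

test_that("window_sum prorates partial bins and is additive over partitions", {
  tr <- uniform_track(value = 1, n_bins = 100, bin_size = 10)
  expect_equal(window_sum(tr, "chr1", 0, 100), 10)
  expect_equal(window_sum(tr, "chr1", 3, 103), 10) # proration keeps uniformity

  z <- uniform_track(value = 0)
  expect_equal(window_sum(z, "chr1", 0, 500), 0)

  tr4 <- signal_track(list(chr1 = c(0, 4, 0)), bin_size = 10)
  expect_equal(window_sum(tr4, "chr1", 15, 25), 2) # half of the value-4 bin

  expect_error(window_sum(tr, "chrX", 0, 10), "not present")
  expect_error(window_sum(tr, "chr1", 900, 1100), "extent")

  # per-bp expansion oracle on random tracks
  set.seed(3)
  for (rep in 1:25) {
    v <- rpois(50, 3)
    tr <- signal_track(list(c = v), bin_size = 7)
    perbp <- rep(v / 7, each = 7)
    s <- sample(0:340, 1)
    e <- s + sample(2:10, 1)
    expect_equal(window_sum(tr, "c", s, e), sum(perbp[(s + 1):e]), tolerance = 1e-10)
    # additivity over a partition
    mid <- s + sample(seq_len(e - s - 1), 1)
    if (mid > s && mid < e) {
      expect_equal(
        window_sum(tr, "c", s, e),
        window_sum(tr, "c", s, mid) + window_sum(tr, "c", mid, e),
        tolerance = 1e-10
      )
    }
  }

  # RPM scaling
  tr <- signal_track(list(c = rep(2, 10)), bin_size = 10, library_size = 2e6)
  expect_equal(window_sum(tr, "c", 0, 100, as_rpm = TRUE), 10)
})

test_that("bedGraph round-trip reproduces the track", {
  set.seed(4)
  v <- rpois(200, 1)
  tr <- signal_track(list(chrS = v), bin_size = 50)
  f <- withr::local_tempfile()
  write_bedgraph(tr, f)
  back <- read_bedgraph(f,
    bin_size = 50, library_size = tr$library_size,
    chrom_lengths = c(chrS = 200 * 50)
  )
  expect_equal(back$values$chrS, v)
  expect_equal(back$library_size, tr$library_size)
})
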