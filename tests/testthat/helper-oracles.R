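# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# O(n^2) pairwise interval merging: repeatedly union any two intervals whose
# gap is <= max_gap until a fixed point.
bf_merge <- function(start, end, max_gap) {
  iv <- data.frame(start = start, end = end)
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
        if (gap <= max_gap) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!merged) break
  }
  iv[order(iv$start), , drop = FALSE]
}

# exhaustive nearest-TSS search with the smaller-coordinate tie-break
bf_nearest <- function(mid, tss, ids) {
  vapply(mid, function(m) {
    d <- abs(m - tss)
    cand <- which(d == min(d))
    cand <- cand[order(tss[cand], ids[cand])]
    ids[cand[1]]
  }, character(1))
}

# Benjamini-Hochberg step-up from first principles
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# GSEA running sum evaluated at every position, O(N)
bf_gsea_es <- function(metric, is_hit, weight_p = 1) {
  N <- length(metric)
  nh <- sum(is_hit)
  w <- abs(metric)^weight_p
  nr <- sum(w[is_hit])
  steps <- ifelse(is_hit, w / nr, -1 / (N - nh))
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

# per-window PWM rescoring with string ops
bf_scan <- function(seq, mat, min_rel) {
  bases <- c("A", "C", "G", "T")
  L <- ncol(mat)
  smin <- sum(apply(mat, 2, min))
  smax <- sum(apply(mat, 2, max))
  rc <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  score_win <- function(win) {
    idx <- match(strsplit(win, "")[[1]], bases)
    if (anyNA(idx)) return(NA_real_)
    sum(mat[cbind(idx, seq_len(L))])
  }
  hits <- list()
  for (i in seq_len(nchar(seq) - L + 1)) {
    win <- substr(seq, i, i + L - 1)
    for (strand in c("+", "-")) {
      s <- score_win(if (strand == "+") win else rc(win))
      if (!is.na(s) && (s - smin) / (smax - smin) >= min_rel) {
        hits[[length(hits) + 1]] <- data.frame(
          start = i - 1, strand = strand, raw = s
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = numeric(0), strand = character(0), raw = numeric(0)))
  }
  do.call(rbind, hits)
}

# a small, quick synthetic study shared by recovery tests
scaled_study <- function(seed = 101, ...) {
  args <- modifyList(
    list(
      seed = seed, n_genes = 600, genome_length = 4e6,
      n_typical_enhancers = 20
    ),
    list(...)
  )
  suppressWarnings(suppressMessages(simulate_study(do.call(simulation_config, args))))
}

uniform_track <- function(value = 1, n_bins = 100, bin_size = 10, chrom = "chr1") {
  signal_track(setNames(list(rep(value, n_bins)), chrom), bin_size)
}
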