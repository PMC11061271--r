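# helper: minimal hand-built site table
mk_sites <- function(n, pos = seq_len(n) * 1000, g1 = 0L, g2 = 0L,
                     chrom = "chr1", filter = "PASS", dp = 30, gq = 99,
                     cm = pos / 1e6) {
  s <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                  g1 = rep_len(g1, n), g2 = rep_len(g2, n),
                  filter = rep_len(filter, n),
                  dp1 = rep_len(dp, n), dp2 = rep_len(dp, n),
                  gq1 = rep_len(gq, n), gq2 = rep_len(gq, n),
                  cm = cm, stringsAsFactors = FALSE)
  class(s) <- c("variant_sites", "data.frame")
  s
}

test_that("site filter applies strict DP/GQ/PASS/SNV rules", {
  s <- mk_sites(6)
  s$dp1[1] <- 10                    # DP must be strictly > 10
  s$gq2[2] <- 50                    # GQ strictly > 50
  s$filter[3] <- "LowQual"
  s$g1[4] <- NA
  s$alt[5] <- "CT"                  # not a SNV
  kept <- filter_sites(s)
  expect_identical(kept$pos, s$pos[6])
  expect_identical(nrow(filter_sites(s[0, ])), 0L)
  all_good <- mk_sites(3, dp = 11, gq = 51)
  expect_identical(nrow(filter_sites(all_good)), 3L)
})

test_that("IBS state equals the shared-allele multiset count", {
  # enumeration oracle: genotypes as allele multisets
  multiset_ibs <- function(g1, g2) {
    a <- c(rep(0, 2 - g1), rep(1, g1))
    b <- c(rep(0, 2 - g2), rep(1, g2))
    shared <- 0
    for (x in a) {
      hit <- match(x, b)
      if (!is.na(hit)) { shared <- shared + 1; b <- b[-hit] }
    }
    shared
  }
  for (g1 in 0:2) for (g2 in 0:2)
    expect_identical(ibs_state(g1, g2), as.integer(multiset_ibs(g1, g2)))
  expect_identical(ibs_state(0, 2), 0L)
  expect_identical(ibs_state(1, 1), 2L)
  expect_error(ibs_state(NA, 1), "missing")
})

test_that("w statistic equals a quadratic-time recount", {
  set.seed(88)
  n <- 1500
  s <- mk_sites(n, pos = sort(sample.int(3e7, n)),
                g1 = sample(0:2, n, replace = TRUE),
                g2 = sample(0:2, n, replace = TRUE))
  # include a second chromosome to exercise the per-chromosome windows
  s2 <- mk_sites(400, pos = sort(sample.int(8e6, 400)), chrom = "chr9",
                 g1 = sample(0:2, 400, replace = TRUE),
                 g2 = sample(0:2, 400, replace = TRUE))
  both <- rbind(s, s2)
  class(both) <- c("variant_sites", "data.frame")
  expect_equal(neighborhood_w(both), w_recount(both), tolerance = 1e-12)
  # trivial windows
  expect_equal(neighborhood_w(mk_sites(50, g1 = 1, g2 = 1)), rep(0, 50))
  expect_equal(neighborhood_w(mk_sites(50, g1 = 0, g2 = 2)), rep(1, 50))
  # crafted window: 50 sites within 1 Mb, exactly one discordant
  cr <- mk_sites(50, pos = seq_len(50) * 1000, g1 = 1, g2 = 1)
  cr$g1[25] <- 0; cr$g2[25] <- 2
  expect_equal(neighborhood_w(cr), rep(0.02, 50))
  # excluding the site itself is available and changes the discordant site
  w_excl <- neighborhood_w(cr, include_self = FALSE)
  expect_equal(w_excl[25], 0)
  expect_equal(w_excl[1], 1 / 49)
})

test_that("identical genotypes over 5 cM give exactly one covering segment", {
  set.seed(12)
  g <- sample(0:2, 500, replace = TRUE)
  s <- mk_sites(500, pos = seq_len(500) * 10000, g1 = g, g2 = g)
  segs <- call_ibd_segments(s)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_variants, 500L)
  expect_identical(segs$start_pos, s$pos[1])
  expect_identical(segs$end_pos, s$pos[500])
  expect_equal(segs$length_cm, s$cm[500] - s$cm[1])
  expect_identical(segs$max_w, 0)
})

test_that("runs below 100 variants or 1 cM are rejected", {
  g <- rep(1L, 99)
  s99 <- mk_sites(99, pos = seq_len(99) * 15000, g1 = g, g2 = g)  # 1.47 cM
  expect_identical(nrow(call_ibd_segments(s99)), 0L)
  s100 <- mk_sites(100, pos = seq_len(100) * 15000)               # 1.5 cM
  expect_identical(nrow(call_ibd_segments(s100)), 1L)
  short <- mk_sites(150, pos = seq_len(150) * 5000)               # 0.75 cM
  expect_identical(nrow(call_ibd_segments(short)), 0L)
})

test_that("no segments are called for unrelated simulated pairs", {
  for (seed in 1:3) {
    st <- filter_sites(sim_pair(length_bp = 3e7, seed = 800 + seed))
    expect_identical(nrow(call_ibd_segments(st)), 0L)
  }
})

test_that("planted segments are recovered and calls stay inside them", {
  hits <- 0; planted_n <- 0
  for (seed in 1:6) {
    st <- sim_pair(length_bp = 4e7,
                   segments = data.frame(start_bp = c(5e6, 2.5e7),
                                         length_cm = c(6, 12)),
                   seed = 900 + seed)
    segs <- call_ibd_segments(filter_sites(st))
    pl <- attr(st, "planted")
    planted_n <- planted_n + nrow(pl)
    for (k in seq_len(nrow(pl)))
      if (any(segs$start_cm <= pl$end_cm[k] & segs$end_cm >= pl$start_cm[k]))
        hits <- hits + 1
    mids <- (segs$start_cm + segs$end_cm) / 2
    for (m in mids)
      expect_true(any(m >= pl$start_cm & m <= pl$end_cm))
    # called segments satisfy their own invariants
    expect_true(all(segs$n_variants >= 100))
    expect_true(all(segs$max_w <= 0.005))
    expect_true(all(segs$length_cm >= 1))
  }
  expect_identical(hits, planted_n)
})

test_that("segment calls are symmetric in sample order", {
  st <- sim_pair(length_bp = 3e7,
                 segments = data.frame(start_bp = 1e7, length_cm = 8),
                 seed = 77)
  fs <- filter_sites(st)
  sw <- fs
  sw[, c("g1", "g2", "dp1", "dp2", "gq1", "gq2")] <-
    fs[, c("g2", "g1", "dp2", "dp1", "gq2", "gq1")]
  expect_equal(as.data.frame(call_ibd_segments(fs)),
               as.data.frame(call_ibd_segments(sw)))
})

test_that("genetic-map interpolation matches the piecewise-linear map", {
  map <- genetic_map("chr1", c(0, 1e6), c(0, 1))
  s <- mk_sites(1, pos = 5e5, cm = NA_real_)
  expect_equal(interpolate_cm(s, map)$cm, 0.5)
  # exact at map points
  s2 <- mk_sites(2, pos = c(0, 1e6), cm = NA_real_)
  expect_equal(interpolate_cm(s2, map)$cm, c(0, 1))
  # dense random sites against the analytic piecewise map
  set.seed(9)
  knots_pos <- c(0, 2e6, 5e6, 9e6, 2e7)
  knots_cm <- c(0, 1.2, 6.0, 7.5, 22)
  map3 <- genetic_map("chr5", knots_pos, knots_cm)
  pos <- sort(sample.int(2.4e7, 3000))  # includes beyond-map extrapolation
  s3 <- mk_sites(3000, pos = pos, chrom = "chr5", cm = NA_real_)
  got <- interpolate_cm(s3, map3)$cm
  analytic <- vapply(pos, function(p) {
    if (p >= 2e7) return(22 + (p - 2e7) * (22 - 7.5) / (2e7 - 9e6))
    i <- findInterval(p, knots_pos)
    knots_cm[i] + (p - knots_pos[i]) *
      (knots_cm[i + 1] - knots_cm[i]) / (knots_pos[i + 1] - knots_pos[i])
  }, numeric(1))
  expect_lt(max(abs(got - analytic)), 1e-9)
  expect_true(all(diff(got) >= 0))
  expect_error(interpolate_cm(mk_sites(1, chrom = "chrX", cm = NA_real_),
                              map3), "absent")
})
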