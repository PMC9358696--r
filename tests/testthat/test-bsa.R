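make_points <- function(chrom, pos, delta, depth = 50L) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), type = "SNP",
                 index_s1 = 0.5 - delta / 2, index_s2 = 0.5 + delta / 2,
                 depth_s1 = depth, depth_s2 = depth, delta = delta)
}

test_that("delta_index computes per-pool indices and excludes zero-depth markers", {
  v <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "T",
    type = "SNP",
    S1_ref = c(5L, 0L, 3L, 0L), S1_alt = c(5L, 12L, 0L, 0L),
    S2_ref = c(2L, 0L, 6L, 4L), S2_alt = c(8L, 12L, 2L, 4L)
  )
  expect_message(pts <- delta_index(v), "1 marker")
  expect_equal(nrow(pts), 3)                  # zero-depth marker dropped
  expect_equal(attr(pts, "n_zero_depth"), 1L)
  expect_equal(pts$index_s1, c(0.5, 1, 0))
  expect_equal(pts$index_s2[1], 0.8)
  expect_equal(pts$delta, pts$index_s2 - pts$index_s1)
  expect_true(all(pts$delta >= -1 & pts$delta <= 1))
  # extremes of the delta formula
  ve <- tibble::tibble(chrom = "c", pos = 1:2, ref = "A", alt = "T",
                       type = "SNP", S1_ref = c(9L, 0L), S1_alt = c(0L, 9L),
                       S2_ref = c(0L, 9L), S2_alt = c(9L, 0L))
  pe <- delta_index(ve)
  expect_equal(pe$delta, c(1, -1))
  expect_error(delta_index(v, s1 = "SX"), "SX")
})

test_that("min_depth_filter removes exactly the shallow markers", {
  pts <- make_points("chr1", c(10, 20, 30), c(0, 0.1, 0.2),
                     depth = c(5L, 50L, 50L))
  expect_identical(min_depth_filter(pts, 0), pts)
  expect_message(out <- min_depth_filter(pts, 10), "1 marker")
  expect_equal(out$pos, c(20L, 30L))
  expect_warning(expect_message(min_depth_filter(pts, 100)), "no markers")
})

test_that("sliding windows average markers per interval and mask sparse windows", {
  pts <- make_points("chr1", c(10, 20), c(0.2, 0.4))
  w <- sliding_windows(pts, window_bp = 100, step_bp = 100, min_markers = 2)
  expect_equal(w$mean_delta[1], 0.3)
  # sparse/empty windows masked
  w2 <- sliding_windows(pts, window_bp = 5, step_bp = 5, min_markers = 1,
                        chrom_lengths = c(chr1 = 40))
  expect_true(is.na(w2$mean_delta[w2$start == 30]))
  expect_error(sliding_windows(make_points("chr1", c(20, 10), c(0, 0))),
               "sorted")
})

test_that("sliding-window means equal a brute-force scan on simulated markers", {
  set.seed(101)
  pos <- sort(sample(1:50000, 100))
  pts <- make_points("chr1", pos, stats::runif(100, -1, 1))
  w <- sliding_windows(pts, window_bp = 7000, step_bp = 1300, min_markers = 1,
                       chrom_lengths = c(chr1 = 50000))
  for (i in seq_len(nrow(w))) {
    inside <- pts$pos > w$start[i] & pts$pos <= w$end[i]
    if (sum(inside) == 0) {
      expect_true(is.na(w$mean_delta[i]))
    } else {
      expect_equal(w$mean_delta[i], mean(pts$delta[inside]), tolerance = 1e-12)
    }
  }
})

test_that("null envelope is symmetric, narrows with depth and has a read-free limit", {
  env <- simulate_confidence_envelope(bulk_size = 50, depth_grid = c(10, 50, 100),
                                      n_sims = 10000, seed = 42)
  at50 <- env[env$depth == 50, ]
  expect_lt(abs(at50$ci95_upper + at50$ci95_lower), 0.02)
  expect_true(all(env$ci99_upper >= env$ci95_upper))
  # monotone narrowing
  expect_lte(env$ci95_upper[env$depth == 100], env$ci95_upper[env$depth == 10])
  # depth -> infinity: only bulk-composition variance remains; compare against
  # a direct no-read-noise simulation of bulk allele frequencies
  env_inf <- simulate_confidence_envelope(bulk_size = 50, depth_grid = 1e6,
                                          n_sims = 20000, seed = 43)
  set.seed(44)
  bulk_f <- function() {
    aa <- stats::rbinom(20000, 50, 0.25)
    het <- stats::rbinom(20000, 50 - aa, 2 / 3)
    (2 * aa + het) / 100
  }
  q <- stats::quantile(bulk_f() - bulk_f(), c(0.025, 0.975), names = FALSE)
  expect_equal(env_inf$ci95_lower, q[1], tolerance = 0.01)
  expect_equal(env_inf$ci95_upper, q[2], tolerance = 0.01)
  expect_warning(simulate_confidence_envelope(depth_grid = 50, n_sims = 50),
                 "unstable")
})

test_that("candidate region calling merges contiguous significant windows", {
  env <- tibble::tibble(depth = c(1, 1000), ci95_lower = -0.3, ci95_upper = 0.3,
                        ci99_lower = -0.4, ci99_upper = 0.4)
  w <- tibble::tibble(
    chrom = "chr1", start = seq(0, 900, 100), end = seq(100, 1000, 100),
    n_markers = 5L, mean_delta = c(0.1, 0.5, 0.6, 0.55, 0.1, 0.1, 0.7, 0.1, NA, 0.2),
    mean_depth = 50
  )
  reg <- call_candidate_regions(w, env)
  expect_equal(nrow(reg), 2)
  expect_equal(sort(reg$start), c(100, 600))
  expect_equal(reg$peak_delta[reg$start == 100], 0.6)
  # merge across one non-significant window
  reg2 <- call_candidate_regions(w, env, merge_gap = 3L)
  expect_equal(nrow(reg2), 1)
  # nothing significant -> empty
  w0 <- dplyr::mutate(w, mean_delta = 0.1)
  expect_equal(nrow(call_candidate_regions(w0, env)), 0)
})

test_that("pool-label swap negates deltas and mirrors calls to the low side", {
  sim <- simulate_f2_bulks(n_chromosomes = 2, causal_chrom = 1,
                           n_markers_per_chrom = 150, seed = 31)
  fwd <- suppressMessages(delta_index(sim$variants))
  rev <- suppressMessages(delta_index(sim$variants, s1 = "S2", s2 = "S1"))
  expect_equal(rev$delta, -fwd$delta)
  env <- simulate_confidence_envelope(bulk_size = 50, depth_grid = seq(20, 90, 5),
                                      n_sims = 4000, seed = 32)
  wf <- sliding_windows(fwd)
  wr <- sliding_windows(rev)
  high <- call_candidate_regions(wf, env, side = "high")
  low_only <- call_candidate_regions(wr, env, side = "high")
  two <- call_candidate_regions(wr, env, side = "two")
  expect_equal(nrow(low_only), 0)                       # signal now below zero
  expect_equal(sort(two$start), sort(high$start))       # recovered two-sided
})

test_that("fixed-marker selection honours the tolerance semantics", {
  pts <- tibble::tibble(
    chrom = "c", pos = 1:4, type = "SNP",
    index_s1 = c(0, 1 / 3, 0.01, 0), index_s2 = c(1, 1, 0.99, 0.5),
    depth_s1 = 50L, depth_s2 = 50L
  )
  pts$delta <- pts$index_s2 - pts$index_s1
  expect_equal(find_fixed_markers(pts)$pos, 1L)
  expect_equal(find_fixed_markers(pts, tol = 0.02)$pos, c(1L, 3L))
})

test_that("genes_in_regions matches half-open semantics and a quadratic oracle", {
  regions <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  genes <- tibble::tibble(
    gene_id = c("inside", "abut_end", "abut_start", "overlap_l"),
    chrom = "chr1", start = c(120L, 200L, 50L, 90L), end = c(180L, 260L, 100L, 150L)
  )
  res <- genes_in_regions(regions, genes)
  expect_setequal(res$gene_ids[[1]], c("inside", "overlap_l"))

  set.seed(55)
  rg <- tibble::tibble(chrom = sample(c("c1", "c2"), 40, TRUE),
                       start = sample(1:5000, 40))
  rg$end <- rg$start + sample(50:500, 40, TRUE)
  gn <- tibble::tibble(gene_id = sprintf("g%03d", 1:500),
                       chrom = sample(c("c1", "c2"), 500, TRUE),
                       start = sample(1:5000, 500))
  gn$end <- gn$start + sample(20:400, 500, TRUE)
  res2 <- genes_in_regions(rg, gn)
  oracle <- brute_force_overlaps(rg, gn)
  for (i in seq_len(nrow(rg))) {
    expect_setequal(res2$gene_ids[[i]], gn$gene_id[oracle$subject[oracle$query == i]])
  }
})

test_that("an end-to-end scan localises the causal locus", {
  sim <- simulate_f2_bulks(seed = 77)
  scan <- suppressMessages(bsa_scan(sim$variants, n_sims = 2000, seed = 77))
  expect_gt(nrow(scan$regions), 0)
  top <- scan$regions[1, ]
  expect_equal(top$chrom, sim$truth$causal_chrom)
  expect_lte(top$start, sim$truth$causal_pos)
  expect_gte(top$end, sim$truth$causal_pos)
  expect_true(all(scan$markers$index_s1 >= 0 & scan$markers$index_s1 <= 1))
  expect_true(all(abs(scan$markers$delta) <= 1))
  g <- glance(scan)
  expect_equal(g$n_regions, nrow(scan$regions))
  expect_s3_class(tidy(scan), "tbl_df")
})
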