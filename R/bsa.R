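#' Per-marker SNP-index and delta index
#'
#' For every marker, the SNP-index of a pool is the fraction of reads carrying
#' the alternate allele, `alt / (ref + alt)`; the delta index is the S2 pool's
#' index minus the S1 pool's. Markers where either pool has zero total depth
#' cannot be indexed: they are flagged and removed from the returned table
#' (never imputed as 0), with the number of exclusions reported via a message.
#'
#' @param variants Variant tibble with `<pool>_ref` / `<pool>_alt` depth
#'   columns (see [read_vcf_depths()]).
#' @param s1,s2 Pool (sample) names for the two bulks; the convention used
#'   throughout is that S2 is the bulk homozygous for the causal recessive
#'   allele, so linked markers push `delta` towards +1.
#' @return A tibble with columns `chrom`, `pos`, `type`, `index_s1`,
#'   `index_s2`, `delta`, `depth_s1`, `depth_s2`, sorted by (`chrom`, `pos`).
#'   The number of zero-depth exclusions is stored in attribute
#'   `n_zero_depth`.
#' @examples
#' v <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L), ref = "A",
#'                     alt = "T", type = "SNP",
#'                     S1_ref = c(5L, 9L), S1_alt = c(5L, 3L),
#'                     S2_ref = c(0L, 8L), S2_alt = c(12L, 4L))
#' delta_index(v)
#' @export
delta_index <- function(variants, s1 = "S1", s2 = "S2") {
  for (p in c(s1, s2)) {
    if (!all(paste0(p, c("_ref", "_alt")) %in% names(variants))) {
      stop("depth columns for pool '", p, "' not found")
    }
  }
  d1 <- variants[[paste0(s1, "_ref")]] + variants[[paste0(s1, "_alt")]]
  d2 <- variants[[paste0(s2, "_ref")]] + variants[[paste0(s2, "_alt")]]
  keep <- d1 > 0L & d2 > 0L
  n_zero <- sum(!keep)
  if (n_zero > 0L) {
    message(n_zero, " marker(s) excluded for zero depth in a pool")
  }
  out <- tibble::tibble(
    chrom = variants$chrom[keep],
    pos = variants$pos[keep],
    type = variants$type[keep],
    index_s1 = variants[[paste0(s1, "_alt")]][keep] / d1[keep],
    index_s2 = variants[[paste0(s2, "_alt")]][keep] / d2[keep],
    depth_s1 = d1[keep],
    depth_s2 = d2[keep]
  )
  out$delta <- out$index_s2 - out$index_s1
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "n_zero_depth") <- n_zero
  out
}

#' Filter markers by minimum pool depth
#'
#' @param points Index tibble from [delta_index()].
#' @param min_depth Markers with either pool's total depth below this are
#'   removed.
#' @return The filtered tibble; a message reports the number removed, and a
#'   warning is raised if nothing survives.
#' @export
min_depth_filter <- function(points, min_depth) {
  keep <- points$depth_s1 >= min_depth & points$depth_s2 >= min_depth
  n_removed <- sum(!keep)
  if (n_removed > 0L) message(n_removed, " marker(s) below min depth ", min_depth)
  out <- points[keep, ]
  if (nrow(out) == 0L) warning("no markers remain after depth filtering")
  out
}

#' Sliding-window means of the delta index
#'
#' Windows of width `window_bp` are advanced by `step_bp` along each
#' chromosome (0-based half-open intervals), and the mean `delta` and mean
#' pool depth over the markers contained in each window are computed.
#' Windows holding fewer than `min_markers` markers are masked
#' (`mean_delta = NA`). The defaults follow the common QTL-seq visualisation
#' of a 1-Mb interval advanced in 1-kb steps.
#'
#' @param points Index tibble sorted by (`chrom`, `pos`); an error is raised
#'   if unsorted.
#' @param window_bp,step_bp Window width and step in bp.
#' @param min_markers Minimum markers for a window to be scored.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the last marker position per chromosome.
#' @return A tibble with `chrom`, `start`, `end`, `n_markers`, `mean_delta`,
#'   `mean_depth`.
#' @export
sliding_windows <- function(points, window_bp = 1e6, step_bp = 1e3,
                            min_markers = 3L, chrom_lengths = NULL) {
  by_chrom <- split(points, points$chrom)
  res <- purrr::imap(by_chrom, function(pts, chrom) {
    if (is.unsorted(pts$pos)) stop("markers not sorted by position on ", chrom)
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(pts$pos)
    }
    starts <- seq(0, max(0, len - 1), by = step_bp)
    ends <- pmin(starts + window_bp, len)
    # marker with 1-based pos p lies in [s, e) iff s < p <= e
    cum_n <- seq_len(nrow(pts))
    cd <- cumsum(pts$delta)
    cdep <- cumsum((pts$depth_s1 + pts$depth_s2) / 2)
    lo <- findInterval(starts, pts$pos)          # markers with pos <= start
    hi <- findInterval(ends, pts$pos)            # markers with pos <= end
    n <- hi - lo
    sum_d <- cd[pmax(hi, 1L)] * (hi > 0) - cd[pmax(lo, 1L)] * (lo > 0)
    sum_dep <- cdep[pmax(hi, 1L)] * (hi > 0) - cdep[pmax(lo, 1L)] * (lo > 0)
    tibble::tibble(
      chrom = chrom, start = starts, end = ends, n_markers = n,
      mean_delta = ifelse(n >= min_markers, sum_d / n, NA_real_),
      mean_depth = ifelse(n >= min_markers, sum_dep / n, NA_real_)
    )
  })
  dplyr::bind_rows(res)
}

#' Monte-Carlo null confidence envelope for the delta index
#'
#' Reconstructs the two-level null simulation used to set QTL-seq
#' significance thresholds. At each read depth `d` in `depth_grid`, the null
#' of no linkage is simulated `n_sims` times: the genotype composition of
#' each 50-plant bulk is drawn from the F2 segregation ratio 1 AA : 2 Aa :
#' 1 aa, giving the bulk's true alternate-allele frequency; alternate read
#' counts are then drawn `Binomial(d, freq)` per pool; and the delta index is
#' the difference of the two simulated indices. The 2.5/97.5 and 0.5/99.5
#' percent quantiles define the 95% and 99% envelopes.
#'
#' @param bulk_size Plants per bulk (each contributing 2 sampled alleles).
#' @param depth_grid Integer vector of read depths to tabulate.
#' @param n_sims Simulations per depth; fewer than 100 triggers a warning.
#' @param population Population structure; only `"F2"` is implemented.
#' @param seed Integer seed for reproducibility.
#' @return A tibble with columns `depth`, `ci95_lower`, `ci95_upper`,
#'   `ci99_lower`, `ci99_upper`, of class `bsa_envelope`.
#' @export
simulate_confidence_envelope <- function(bulk_size = 50L, depth_grid = 10:150,
                                         n_sims = 10000L, population = "F2",
                                         seed = 1L) {
  stopifnot(bulk_size > 0, length(depth_grid) > 0)
  population <- match.arg(population, "F2")
  if (n_sims < 100L) warning("n_sims < 100: quantile estimates will be unstable")
  set.seed(seed)
  n_alleles <- 2L * bulk_size
  rows <- purrr::map(depth_grid, function(d) {
    # genotype counts ~ multinomial(1/4, 1/2, 1/4) per plant; bulk alt-allele
    # count = 2*aa + Aa. Aa | aa is Binomial(bulk_size - aa, 2/3).
    g1_aa <- stats::rbinom(n_sims, bulk_size, 0.25)
    g1_het <- stats::rbinom(n_sims, bulk_size - g1_aa, 2 / 3)
    g2_aa <- stats::rbinom(n_sims, bulk_size, 0.25)
    g2_het <- stats::rbinom(n_sims, bulk_size - g2_aa, 2 / 3)
    f1 <- (2 * g1_aa + g1_het) / n_alleles
    f2 <- (2 * g2_aa + g2_het) / n_alleles
    idx1 <- stats::rbinom(n_sims, d, f1) / d
    idx2 <- stats::rbinom(n_sims, d, f2) / d
    q <- stats::quantile(idx2 - idx1, c(0.025, 0.975, 0.005, 0.995), names = FALSE)
    tibble::tibble(depth = d, ci95_lower = q[1], ci95_upper = q[2],
                   ci99_lower = q[3], ci99_upper = q[4])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bsa_envelope", class(out))
  out
}

#' Look up envelope bounds at arbitrary depths
#'
#' Linear interpolation on the tabulated depth grid, with constant
#' extrapolation beyond its ends.
#'
#' @param envelope Envelope tibble from [simulate_confidence_envelope()].
#' @param depth Numeric vector of depths.
#' @return A tibble with one row per depth and the four bound columns.
#' @export
envelope_at <- function(envelope, depth) {
  interp <- function(col) {
    stats::approx(envelope$depth, envelope[[col]], xout = depth, rule = 2)$y
  }
  tibble::tibble(
    depth = depth,
    ci95_lower = interp("ci95_lower"), ci95_upper = interp("ci95_upper"),
    ci99_lower = interp("ci99_lower"), ci99_upper = interp("ci99_upper")
  )
}

#' Flag markers outside the null confidence envelope
#'
#' Compares each marker's delta index against the envelope evaluated at the
#' marker's effective read depth (the harmonic mean of the two pool depths,
#' which matches the read-sampling variance of the equal-depth null
#' simulation). Under a no-locus null about 5% of markers fall outside the
#' 95% envelope.
#'
#' @param points Index tibble from [delta_index()].
#' @param envelope Envelope from [simulate_confidence_envelope()].
#' @param level `"95"` or `"99"`.
#' @return `points` with logical column `outside_envelope`.
#' @export
markers_outside_envelope <- function(points, envelope, level = c("95", "99")) {
  level <- match.arg(level)
  eff_depth <- 2 / (1 / points$depth_s1 + 1 / points$depth_s2)
  b <- envelope_at(envelope, eff_depth)
  dplyr::mutate(points,
    outside_envelope = .data$delta > b[[paste0("ci", level, "_upper")]] |
      .data$delta < b[[paste0("ci", level, "_lower")]]
  )
}

#' Call candidate regions from significant windows
#'
#' Windows whose `mean_delta` exceeds the 95% envelope bound are merged into
#' candidate regions when contiguous (or separated by at most `merge_gap`
#' non-significant windows). By default the test is one-sided on the high
#' side, matching a design where the S2 bulk is homozygous for the causal
#' allele; `side = "two"` also calls windows below the lower bound.
#' With `threshold = "depth"` each window is compared against the envelope at
#' its own mean marker depth; `threshold = "global"` uses the envelope at
#' `global_depth`.
#'
#' @param windows Window tibble from [sliding_windows()].
#' @param envelope Envelope from [simulate_confidence_envelope()].
#' @param side `"high"` (default) or `"two"`.
#' @param level `"95"` or `"99"`.
#' @param threshold `"depth"` (per-window mean depth) or `"global"`.
#' @param global_depth Depth used when `threshold = "global"`.
#' @param merge_gap Number of intervening non-significant windows allowed
#'   inside one region.
#' @return A tibble of regions: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_delta`, `peak_pos`.
#' @export
call_candidate_regions <- function(windows, envelope, side = c("high", "two"),
                                   level = c("95", "99"),
                                   threshold = c("depth", "global"),
                                   global_depth = 50, merge_gap = 0L) {
  side <- match.arg(side)
  level <- match.arg(level)
  threshold <- match.arg(threshold)
  scored <- dplyr::filter(windows, !is.na(.data$mean_delta))
  if (nrow(scored) == 0L) return(empty_region_tibble())
  d <- if (threshold == "depth") scored$mean_depth else rep(global_depth, nrow(scored))
  bounds <- envelope_at(envelope, d)
  up <- bounds[[paste0("ci", level, "_upper")]]
  lo <- bounds[[paste0("ci", level, "_lower")]]
  sig <- scored$mean_delta > up
  if (side == "two") sig <- sig | scored$mean_delta < lo
  scored <- scored[sig, ]
  if (nrow(scored) == 0L) return(empty_region_tibble())

  # step between consecutive window starts, inferred from the full grid
  starts_all <- sort(unique(windows$start))
  step <- if (length(starts_all) > 1L) min(diff(starts_all)) else 1

  regions <- scored |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(
      gap_bp = .data$start - dplyr::lag(.data$start, default = dplyr::first(.data$start)),
      new_block = dplyr::row_number() == 1L |
        .data$gap_bp > (merge_gap + 1L) * step,
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_windows = dplyr::n(),
      peak_delta = max(.data$mean_delta),
      peak_pos = .data$start[which.max(.data$mean_delta)] +
        (.data$end[which.max(.data$mean_delta)] -
           .data$start[which.max(.data$mean_delta)]) / 2,
      .groups = "drop"
    ) |>
    dplyr::select(-"block") |>
    dplyr::arrange(dplyr::desc(.data$peak_delta))
  regions
}

empty_region_tibble <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 n_windows = integer(), peak_delta = numeric(),
                 peak_pos = numeric())
}

#' Find fixed (diagnostic) markers
#'
#' Markers whose index is ~0 in the S1 bulk and ~1 in the S2 bulk, i.e.
#' perfectly co-segregating polymorphisms.
#'
#' @param points Index tibble from [delta_index()].
#' @param tol Tolerance: selected iff `index_s1 <= tol` and
#'   `index_s2 >= 1 - tol`.
#' @return The selected rows of `points`.
#' @export
find_fixed_markers <- function(points, tol = 0) {
  dplyr::filter(points, .data$index_s1 <= tol, .data$index_s2 >= 1 - tol)
}

#' Genes overlapping candidate regions
#'
#' Any overlap between a gene span and a region (both 0-based half-open)
#' counts; abutting intervals do not overlap.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param gene_models Gene-model tibble from [read_gff3_models()] (gene rows
#'   are used), or any tibble with `gene_id`, `chrom`, `start`, `end`.
#' @return `regions` with an added list-column `gene_ids` and count `n_genes`.
#' @export
genes_in_regions <- function(regions, gene_models) {
  genes <- if ("feature" %in% names(gene_models)) {
    dplyr::filter(gene_models, .data$feature == "gene")
  } else {
    gene_models
  }
  gene_ids <- purrr::map(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    genes$gene_id[hit]
  })
  dplyr::mutate(regions, gene_ids = gene_ids,
                n_genes = lengths(gene_ids))
}

#' Run the full bulked-segregant scan
#'
#' Convenience wrapper chaining [delta_index()], [min_depth_filter()],
#' [sliding_windows()], [simulate_confidence_envelope()] and
#' [call_candidate_regions()], returning everything as one `bsa_scan`
#' object with [tidy()][generics::tidy], [glance()][generics::glance] and
#' [autoplot()][ggplot2::autoplot] methods.
#'
#' @inheritParams delta_index
#' @inheritParams sliding_windows
#' @inheritParams call_candidate_regions
#' @param min_depth Minimum per-pool depth for a marker to be used.
#' @param bulk_size Plants per bulk for the null envelope.
#' @param n_sims Null simulations per depth.
#' @param seed Seed for the envelope simulation.
#' @return A `bsa_scan` object: list with `markers`, `windows`, `regions`,
#'   `fixed_markers`, `envelope` and `params`.
#' @export
bsa_scan <- function(variants, s1 = "S1", s2 = "S2", min_depth = 10L,
                     window_bp = 1e6, step_bp = 1e3, min_markers = 3L,
                     chrom_lengths = NULL, bulk_size = 50L, n_sims = 10000L,
                     side = "high", threshold = "depth", merge_gap = 0L,
                     seed = 1L) {
  markers <- delta_index(variants, s1 = s1, s2 = s2)
  markers <- min_depth_filter(markers, min_depth)
  stopifnot(all(markers$index_s1 >= 0 & markers$index_s1 <= 1),
            all(abs(markers$delta) <= 1))
  windows <- sliding_windows(markers, window_bp = window_bp, step_bp = step_bp,
                             min_markers = min_markers,
                             chrom_lengths = chrom_lengths)
  depths <- c(markers$depth_s1, markers$depth_s2)
  grid <- seq(max(1L, floor(min(depths))), ceiling(max(depths)), by = 2L)
  envelope <- simulate_confidence_envelope(bulk_size = bulk_size,
                                           depth_grid = grid,
                                           n_sims = n_sims, seed = seed)
  regions <- call_candidate_regions(windows, envelope, side = side,
                                    threshold = threshold,
                                    merge_gap = merge_gap)
  structure(
    list(markers = markers, windows = windows, regions = regions,
         fixed_markers = find_fixed_markers(markers),
         envelope = envelope,
         params = list(s1 = s1, s2 = s2, min_depth = min_depth,
                       window_bp = window_bp, step_bp = step_bp,
                       min_markers = min_markers, bulk_size = bulk_size,
                       n_sims = n_sims, side = side, threshold = threshold,
                       seed = seed)),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("<bsa_scan>\n")
  cat("  markers:", nrow(x$markers), "  windows:", nrow(x$windows),
      "  candidate regions:", nrow(x$regions),
      "  fixed markers:", nrow(x$fixed_markers), "\n")
  if (nrow(x$regions) > 0) {
    top <- x$regions[1, ]
    cat(sprintf("  top region: %s:%d-%d (peak delta %.3f)\n",
                top$chrom, as.integer(top$start), as.integer(top$end),
                top$peak_delta))
  }
  invisible(x)
}

#' @rdname bsa_scan
#' @param x A `bsa_scan` object.
#' @param ... Unused.
#' @export
tidy.bsa_scan <- function(x, ...) {
  dplyr::filter(x$windows, !is.na(.data$mean_delta))
}

#' @rdname bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$markers),
    n_windows_scored = sum(!is.na(x$windows$mean_delta)),
    n_regions = nrow(x$regions),
    n_fixed_markers = nrow(x$fixed_markers),
    peak_delta = if (nrow(x$regions) > 0) x$regions$peak_delta[1] else NA_real_
  )
}
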