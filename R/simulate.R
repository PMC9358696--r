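#' Simulate an F2 bulked-segregant resequencing experiment
#'
#' Emulates the design of a bulked-segregant scan for a single recessive
#' locus: an F2 population segregating 3:1 (glaucous : glossy), from which a
#' bulk of `bulk_size` glossy plants (S2, all `aa` at the causal locus) and a
#' bulk of `bulk_size` glaucous plants (S1, `AA` or `Aa` in ratio 1:2) are
#' resequenced at ~`mean_depth`x. Marker genotypes co-segregate with the
#' causal locus with recombination fraction given by the Haldane map
#' `r = 0.5 * (1 - exp(-2 d))`, with `d` the marker-causal distance in
#' Morgans (`morgans_per_chrom` genetic length spread uniformly along each
#' chromosome); markers on other chromosomes are unlinked (`r = 0.5`).
#' Read depths are `Poisson(mean_depth)` per pool and alternate read counts
#' `Binomial(depth, bulk allele frequency)`, with an optional base-error rate
#' flipping alleles.
#'
#' The alternate allele is, by construction, the allele from the glossy donor
#' parent, so the expected delta index at the causal marker is
#' `1 - 1/3 = 2/3` and 0 for unlinked markers.
#'
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param chrom_length_bp Physical length per chromosome.
#' @param n_markers_per_chrom Evenly spaced markers per chromosome; one
#'   marker is placed exactly at `causal_pos` on the causal chromosome.
#' @param causal_chrom Index of the chromosome carrying the causal locus, or
#'   `NA` for a null (no-locus) simulation.
#' @param causal_pos Position of the causal locus (default: mid-chromosome).
#' @param n_f2 F2 population size the bulks are drawn from.
#' @param bulk_size Plants per bulk (default 50).
#' @param mean_depth Mean sequencing depth per pool (default 50).
#' @param morgans_per_chrom Genetic length of each chromosome in Morgans.
#' @param indel_fraction Fraction of markers simulated as small indels (the
#'   delta-index formula is identical; this exercises the merged "all-index"
#'   marker set).
#' @param base_error Probability a read reports the wrong allele.
#' @param seed Integer seed; all randomness is local to this call.
#' @return A list with `variants` (tibble compatible with [delta_index()])
#'   and `truth` (list: `causal_chrom`, `causal_pos`, and per-marker tibble
#'   `expected` with expected indices and delta).
#' @examples
#' sim <- simulate_f2_bulks(n_chromosomes = 2, n_markers_per_chrom = 50, seed = 1)
#' head(sim$variants)
#' @export
simulate_f2_bulks <- function(n_chromosomes = 10L, chrom_length_bp = 30e6,
                              n_markers_per_chrom = 200L, causal_chrom = 9L,
                              causal_pos = NULL, n_f2 = 300L, bulk_size = 50L,
                              mean_depth = 50, morgans_per_chrom = 1,
                              indel_fraction = 0.1, base_error = 0,
                              seed = 1L) {
  stopifnot(bulk_size > 0, mean_depth > 0, n_f2 >= 2 * bulk_size)
  if (!is.na(causal_chrom)) stopifnot(causal_chrom >= 1, causal_chrom <= n_chromosomes)
  if (is.null(causal_pos)) causal_pos <- round(chrom_length_bp / 2)
  if (!is.na(causal_chrom)) stopifnot(causal_pos >= 1, causal_pos <= chrom_length_bp)
  set.seed(seed)

  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  pos <- round(seq(1, chrom_length_bp, length.out = n_markers_per_chrom))
  marker_tbl <- tidyr::expand_grid(chrom = chroms, pos = pos)
  if (!is.na(causal_chrom)) {
    cc <- chroms[causal_chrom]
    on_cc <- marker_tbl$chrom == cc
    # snap the marker nearest the causal locus onto it exactly
    nearest <- which(on_cc)[which.min(abs(marker_tbl$pos[on_cc] - causal_pos))]
    marker_tbl$pos[nearest] <- causal_pos
    marker_tbl <- dplyr::arrange(marker_tbl, .data$chrom, .data$pos)
  }
  n_markers <- nrow(marker_tbl)

  # causal-locus genotypes: per plant, number of 'a' alleles from two
  # independent F1 gametes
  causal_geno <- stats::rbinom(n_f2, 2L, 0.5)
  glossy <- causal_geno == 2L
  if (sum(glossy) < bulk_size || sum(!glossy) < bulk_size) {
    stop("fewer plants of a phenotype than bulk_size; increase n_f2")
  }
  s2_plants <- which(glossy)[seq_len(bulk_size)]
  s1_plants <- which(!glossy)[seq_len(bulk_size)]

  # recombination fraction of each marker to the causal locus
  r <- rep(0.5, n_markers)
  if (!is.na(causal_chrom)) {
    on_cc <- marker_tbl$chrom == chroms[causal_chrom]
    d_morgan <- abs(marker_tbl$pos[on_cc] - causal_pos) / chrom_length_bp *
      morgans_per_chrom
    r[on_cc] <- 0.5 * (1 - exp(-2 * d_morgan))
  }

  bulk_freq <- function(plants) {
    # per plant two gametes; each gamete's marker allele follows its causal
    # allele, flipped with prob r. Plant's causal alleles: geno 'a' count g
    # means g gametes carried 'a'.
    g <- causal_geno[plants]
    n <- length(plants)
    # allele-level simulation: matrix markers x (2n alleles)
    causal_alleles <- c(rep(1L, sum(g)), rep(0L, 2L * n - sum(g)))
    # gamete identity doesn't matter beyond its causal allele
    flips <- matrix(stats::runif(n_markers * 2L * n) < r, nrow = n_markers)
    alt <- sweep(flips, 2, causal_alleles, FUN = function(fl, a) ifelse(fl, 1L - a, a))
    rowMeans(alt)
  }
  f_s1 <- bulk_freq(s1_plants)
  f_s2 <- bulk_freq(s2_plants)

  read_counts <- function(freq) {
    depth <- stats::rpois(n_markers, mean_depth)
    p <- freq * (1 - base_error) + (1 - freq) * base_error
    alt <- stats::rbinom(n_markers, depth, p)
    list(ref = depth - alt, alt = alt)
  }
  rc1 <- read_counts(f_s1)
  rc2 <- read_counts(f_s2)

  is_indel <- stats::runif(n_markers) < indel_fraction
  variants <- tibble::tibble(
    chrom = marker_tbl$chrom, pos = as.integer(marker_tbl$pos),
    ref = ifelse(is_indel, "AT", "A"),
    alt = ifelse(is_indel, "A", "T"),
    type = ifelse(is_indel, "DEL", "SNP"),
    S1_ref = rc1$ref, S1_alt = rc1$alt,
    S2_ref = rc2$ref, S2_alt = rc2$alt
  )

  expected <- tibble::tibble(
    chrom = marker_tbl$chrom, pos = as.integer(marker_tbl$pos),
    r = r,
    expected_index_s1 = r + (1 - 2 * r) / 3,
    expected_index_s2 = 1 - r
  )
  expected$expected_delta <- expected$expected_index_s2 - expected$expected_index_s1

  list(
    variants = variants,
    truth = list(
      causal_chrom = if (is.na(causal_chrom)) NA_character_ else chroms[causal_chrom],
      causal_pos = causal_pos,
      phenotype_counts = c(glaucous = sum(!glossy), glossy = sum(glossy)),
      expected = expected
    )
  )
}

triad_category_levels <- function() {
  c("Balanced", "LF-dominant", "MF1-dominant", "MF2-dominant",
    "LF-suppressed", "MF1-suppressed", "MF2-suppressed")
}

triad_centroids <- function() {
  m <- rbind(
    Balanced = c(1, 1, 1) / 3,
    `LF-dominant` = c(1, 0, 0),
    `MF1-dominant` = c(0, 1, 0),
    `MF2-dominant` = c(0, 0, 1),
    `LF-suppressed` = c(0, 0.5, 0.5),
    `MF1-suppressed` = c(0.5, 0, 0.5),
    `MF2-suppressed` = c(0.5, 0.5, 0)
  )
  colnames(m) <- c("LF", "MF1", "MF2")
  m
}

#' Simulate triad expression with known bias categories
#'
#' Draws each triad's relative-abundance triple from a Dirichlet distribution
#' centred on its category's archetype (centroid on the ternary simplex) and
#' scales by a log-normal expression magnitude to obtain FPKMs. As the
#' concentration grows, triples converge to the centroids, so truth recovery
#' by [classify_triads()] approaches 100%.
#'
#' @param n_triads Number of triads.
#' @param proportions Named mixture proportions over the 7 categories (must
#'   sum to 1); the default mirrors a balanced-minority composition with
#'   28.7% balanced, 23.7% dominant and 47.6% suppressed triads split evenly
#'   within the dominant/suppressed groups.
#' @param concentration Dirichlet concentration (> 0); larger = less noise.
#' @param alpha_floor Small positive floor added to each Dirichlet parameter
#'   so zero-coordinate centroids remain proper.
#' @param magnitude_meanlog,magnitude_sdlog Log-normal parameters of the
#'   triad expression magnitude (sum of the three FPKMs).
#' @param n_replicates Replicate sample columns per homoeolog (multiplicative
#'   log-normal replicate noise, sd `replicate_sdlog`).
#' @param replicate_sdlog Replicate-level log-normal noise.
#' @param seed Integer seed.
#' @return A list with `expression` (tibble: `feature_id` + replicate
#'   columns), `triads` (tibble: `LF`, `MF1`, `MF2`) and `truth` (tibble:
#'   `triad_id`, `category`, true relative triple).
#' @export
simulate_triads <- function(n_triads = 1000L, proportions = NULL,
                            concentration = 50, alpha_floor = 0.1,
                            magnitude_meanlog = log(30), magnitude_sdlog = 1,
                            n_replicates = 2L, replicate_sdlog = 0.05,
                            seed = 1L) {
  if (concentration <= 0) stop("concentration must be > 0")
  lv <- triad_category_levels()
  if (is.null(proportions)) {
    proportions <- c(0.287, rep(0.237 / 3, 3), rep(0.476 / 3, 3))
    names(proportions) <- lv
  }
  if (abs(sum(proportions) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  proportions <- proportions[lv]
  set.seed(seed)

  cats <- sample(lv, n_triads, replace = TRUE, prob = proportions)
  cent <- triad_centroids()
  alpha <- cent[cats, , drop = FALSE] * concentration + alpha_floor
  # Dirichlet via independent gammas
  g <- matrix(stats::rgamma(3L * n_triads, shape = as.vector(alpha)), ncol = 3)
  rel <- g / rowSums(g)
  magnitude <- stats::rlnorm(n_triads, magnitude_meanlog, magnitude_sdlog)
  fpkm <- rel * magnitude

  triad_id <- sprintf("triad%04d", seq_len(n_triads))
  gene_ids <- cbind(paste0(triad_id, ".LF"), paste0(triad_id, ".MF1"),
                    paste0(triad_id, ".MF2"))
  feats <- as.vector(t(gene_ids))
  base <- as.vector(t(fpkm))
  expr <- tibble::tibble(feature_id = feats)
  for (j in seq_len(n_replicates)) {
    expr[[paste0("rep", j)]] <- base *
      stats::rlnorm(length(base), 0, replicate_sdlog)
  }

  list(
    expression = expr,
    triads = tibble::tibble(LF = gene_ids[, 1], MF1 = gene_ids[, 2],
                            MF2 = gene_ids[, 3]),
    truth = tibble::tibble(triad_id = triad_id, category = cats,
                           rel_lf = rel[, 1], rel_mf1 = rel[, 2],
                           rel_mf2 = rel[, 3])
  )
}

#' Simulate a gene/TE landscape with known flank context
#'
#' Lays out non-overlapping genes with generous spacing and, for a fraction
#' of genes, drops a TE into the 5' flank, gene body or 3' flank (respecting
#' strand). Background TEs are placed in dedicated intergenic zones more than
#' `flank_bp` away from any gene, so the per-gene truth flags are exact by
#' construction.
#'
#' @param n_genes,n_background_tes Numbers of genes and intergenic TEs.
#' @param flank_bp Flank width used for the truth flags (default 2000).
#' @param insertion_rate Probability a gene receives a TE insertion.
#' @param gene_length Gene span length.
#' @param te_length TE length (must be < `flank_bp` so flank insertions stay
#'   within one compartment).
#' @param seed Integer seed.
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`), `tes` (tibble: `chrom`, `start`, `end`, `name`, `te_class`,
#'   `superfamily`) and `truth` (tibble of per-gene flags).
#' @export
simulate_te_landscape <- function(n_genes = 200L, n_background_tes = 100L,
                                  flank_bp = 2000L, insertion_rate = 0.3,
                                  gene_length = 3000L, te_length = 500L,
                                  seed = 1L) {
  stopifnot(te_length < flank_bp)
  set.seed(seed)
  spacing <- gene_length + 2L * flank_bp + 20000L
  gene_start <- 10000L + (seq_len(n_genes) - 1L) * spacing
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)), chrom = "chr01",
    start = gene_start, end = gene_start + gene_length, strand = strand
  )

  has_ins <- stats::runif(n_genes) < insertion_rate
  compartment <- ifelse(has_ins,
                        sample(c("flank5", "body", "flank3"), n_genes, replace = TRUE),
                        NA_character_)
  te_rows <- purrr::map(which(has_ins), function(i) {
    comp <- compartment[i]
    g <- genes[i, ]
    left <- g$strand == "+"
    phys <- switch(comp,
      body = g$start + 100L,
      flank5 = if (left) g$start - flank_bp + 100L else g$end + flank_bp - te_length - 100L,
      flank3 = if (left) g$end + flank_bp - te_length - 100L else g$start - flank_bp + 100L
    )
    tibble::tibble(chrom = "chr01", start = phys, end = phys + te_length,
                   name = paste0("TEins_", g$gene_id))
  })
  # background TEs live in the dead zone between gene i's flank end and the
  # next gene's flank start
  bg_slots <- sample(n_genes, n_background_tes, replace = TRUE)
  bg_offset <- as.integer(stats::runif(n_background_tes, flank_bp + 1000L,
                                       spacing - gene_length - flank_bp - te_length - 1000L))
  bg <- tibble::tibble(
    chrom = "chr01",
    start = genes$end[bg_slots] + bg_offset,
    end = genes$end[bg_slots] + bg_offset + te_length,
    name = sprintf("TEbg%04d", seq_len(n_background_tes))
  )
  tes <- dplyr::bind_rows(c(te_rows, list(bg)))
  tes$te_class <- sample(c("retrotransposon", "DNA_transposon"), nrow(tes),
                         replace = TRUE, prob = c(0.8, 0.2))
  tes$superfamily <- ifelse(tes$te_class == "retrotransposon",
                            sample(c("Copia", "Gypsy"), nrow(tes), replace = TRUE),
                            "other")
  tes$strand <- "."

  truth <- tibble::tibble(
    gene_id = genes$gene_id,
    has_te_5prime_flank = !is.na(compartment) & compartment == "flank5",
    has_te_body = !is.na(compartment) & compartment == "body",
    has_te_3prime_flank = !is.na(compartment) & compartment == "flank3"
  )
  list(genes = genes, tes = tes, truth = truth)
}

#' Simulate a two-condition splicing dataset with known PSI
#'
#' Builds one two-isoform gene model per gene carrying a single local
#' splicing event (intron retention, exon skipping, alternative donor or
#' alternative acceptor), then draws per-replicate PSI values around
#' condition means and allocates transcript TPMs so that [compute_psi()]
#' recovers the drawn PSI exactly. A configurable fraction of genes receives
#' a condition effect (`delta_psi`); the rest are null.
#'
#' @param n_genes Number of genes (one event each).
#' @param event_mix Named probabilities over `c("IR","ES","A5","A3")`.
#' @param affected_fraction Fraction of genes with a true PSI shift.
#' @param delta_psi True PSI shift (condition 2 minus condition 1) for
#'   affected genes.
#' @param n_replicates Replicates per condition.
#' @param noise_sd Replicate-level PSI standard deviation (0 = noise-free).
#' @param total_tpm Total event abundance per sample.
#' @param seed Integer seed.
#' @return A list with `models` (gene-model tibble), `abundance` (tibble:
#'   `feature_id` + sample columns `c1_r1`, ...), `samples` (tibble:
#'   `sample`, `condition`, `replicate`), `truth` (tibble: `gene_id`,
#'   `event_type`, `psi_c1`, `psi_c2`, `delta_psi_true`, `affected`, and the
#'   per-sample drawn PSI as a nested list-column `psi_samples`).
#' @export
simulate_splicing_dataset <- function(n_genes = 100L,
                                      event_mix = c(IR = 0.46, ES = 0.24,
                                                    A5 = 0.15, A3 = 0.15),
                                      affected_fraction = 0.3,
                                      delta_psi = 0.3, n_replicates = 3L,
                                      noise_sd = 0.02, total_tpm = 100,
                                      seed = 1L) {
  set.seed(seed)
  event_mix <- event_mix / sum(event_mix)
  types <- sample(names(event_mix), n_genes, replace = TRUE, prob = event_mix)
  affected <- stats::runif(n_genes) < affected_fraction
  psi1 <- stats::runif(n_genes, 0.25, 0.75)
  psi2 <- pmin(pmax(psi1 + ifelse(affected, delta_psi, 0), 0.02), 0.98)

  offset <- (seq_len(n_genes) - 1L) * 10000L
  models <- purrr::pmap(list(seq_len(n_genes), types, offset), function(i, ty, off) {
    gid <- sprintf("sgene%04d", i)
    t_inc <- paste0(gid, ".t1")  # inclusion isoform
    t_exc <- paste0(gid, ".t2")  # exclusion isoform
    ex <- function(tx, s, e) tibble::tibble(
      gene_id = gid, transcript_id = tx, feature = "exon", chrom = "chr01",
      start = off + s, end = off + e, strand = "+", phase = NA_integer_
    )
    body <- switch(ty,
      IR = dplyr::bind_rows(  # t1 retains intron1: single exon 0-300
        ex(t_inc, 0L, 300L), ex(t_inc, 400L, 500L),
        ex(t_exc, 0L, 100L), ex(t_exc, 200L, 300L), ex(t_exc, 400L, 500L)
      ),
      ES = dplyr::bind_rows(  # t1 includes middle exon
        ex(t_inc, 0L, 100L), ex(t_inc, 200L, 300L), ex(t_inc, 400L, 500L),
        ex(t_exc, 0L, 100L), ex(t_exc, 400L, 500L)
      ),
      A5 = dplyr::bind_rows(  # t1 uses downstream donor (longer first exon)
        ex(t_inc, 0L, 150L), ex(t_inc, 200L, 300L),
        ex(t_exc, 0L, 100L), ex(t_exc, 200L, 300L)
      ),
      A3 = dplyr::bind_rows(  # t1 uses upstream acceptor (longer second exon)
        ex(t_inc, 0L, 100L), ex(t_inc, 150L, 300L),
        ex(t_exc, 0L, 100L), ex(t_exc, 200L, 300L)
      )
    )
    span <- dplyr::group_by(body, .data$transcript_id) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end))
    dplyr::bind_rows(
      tibble::tibble(gene_id = gid, transcript_id = NA_character_,
                     feature = "gene", chrom = "chr01",
                     start = min(span$start), end = max(span$end),
                     strand = "+", phase = NA_integer_),
      tibble::tibble(gene_id = gid, transcript_id = span$transcript_id,
                     feature = "mRNA", chrom = "chr01", start = span$start,
                     end = span$end, strand = "+", phase = NA_integer_),
      body
    )
  })
  models <- dplyr::bind_rows(models)

  samples <- tidyr::expand_grid(condition = c("c1", "c2"),
                                replicate = seq_len(n_replicates))
  samples$sample <- paste0(samples$condition, "_r", samples$replicate)
  psi_draws <- purrr::map(seq_len(n_genes), function(i) {
    mu <- ifelse(samples$condition == "c1", psi1[i], psi2[i])
    pmin(pmax(mu + stats::rnorm(nrow(samples), 0, noise_sd), 0), 1)
  })

  abundance <- tibble::tibble(
    feature_id = as.vector(rbind(sprintf("sgene%04d.t1", seq_len(n_genes)),
                                 sprintf("sgene%04d.t2", seq_len(n_genes))))
  )
  for (k in seq_len(nrow(samples))) {
    psi_k <- purrr::map_dbl(psi_draws, k)
    abundance[[samples$sample[k]]] <-
      as.vector(rbind(psi_k * total_tpm, (1 - psi_k) * total_tpm))
  }

  truth <- tibble::tibble(
    gene_id = sprintf("sgene%04d", seq_len(n_genes)), event_type = types,
    psi_c1 = psi1, psi_c2 = psi2, delta_psi_true = psi2 - psi1,
    affected = affected, psi_samples = psi_draws
  )
  list(models = models,
       abundance = abundance,
       samples = dplyr::select(samples, "sample", "condition", "replicate"),
       truth = truth)
}
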