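#' Detect local alternative-splicing events from transcript models
#'
#' Compares the exon chains of every transcript pair within a gene and emits
#' local events of four classes: intron retention (IR: one transcript's exon
#' fully covers an intron of the other), exon skipping (ES: an internal exon
#' of one transcript lies fully inside an intron of the other), and
#' alternative donor/acceptor (A5/A3: two introns share one boundary and
#' differ at the other, with the variable region exonic in the
#' shorter-intron transcript — this guard prevents the flanking introns of a
#' skipped exon from being double-reported as A5/A3). Events are
#' deduplicated by (gene, type, coordinates), accumulating transcripts into
#' inclusion (more exonic sequence) and exclusion sets. A5 and A3 labels are
#' strand-aware.
#'
#' @param models Gene-model tibble (see [read_gff3_models()]).
#' @return A tibble: `event_id`, `gene_id`, `event_type`, `chrom`,
#'   `var_start`, `var_end` (variable region, 0-based half-open),
#'   list-columns `inclusion` and `exclusion` of transcript IDs.
#' @export
detect_as_events <- function(models) {
  exons <- dplyr::filter(models, .data$feature == "exon")
  genes <- split(exons, exons$gene_id)
  all_events <- purrr::imap(genes, function(ex, gid) {
    txs <- split(ex, ex$transcript_id)
    if (length(txs) < 2L) return(NULL)
    txs <- purrr::map(txs, function(t) dplyr::arrange(t, .data$start))
    strand <- ex$strand[1]
    chrom <- ex$chrom[1]
    ids <- names(txs)
    ev <- list()
    add <- function(type, vs, ve, inc, exc) {
      ev[[length(ev) + 1L]] <<- tibble::tibble(
        gene_id = gid, event_type = type, chrom = chrom,
        var_start = vs, var_end = ve, inclusion = inc, exclusion = exc
      )
    }
    introns_of <- function(t) {
      if (nrow(t) < 2L) return(tibble::tibble(start = integer(), end = integer()))
      tibble::tibble(start = t$end[-nrow(t)], end = t$start[-1])
    }
    covers <- function(t, s, e) any(t$start <= s & t$end >= e)

    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i == j) next
        A <- txs[[i]]
        B <- txs[[j]]
        ib <- introns_of(B)
        # IR: A retains an intron of B
        for (k in seq_len(nrow(ib))) {
          if (covers(A, ib$start[k], ib$end[k])) {
            add("IR", ib$start[k], ib$end[k], ids[i], ids[j])
          }
        }
        # ES: internal exon of B inside an intron of A
        ia <- introns_of(A)
        if (nrow(B) >= 3L && nrow(ia) > 0L) {
          for (k in 2:(nrow(B) - 1L)) {
            inside <- ia$start <= B$start[k] & ia$end >= B$end[k]
            if (any(inside)) {
              add("ES", B$start[k], B$end[k], ids[j], ids[i])
            }
          }
        }
        # A5/A3: introns sharing exactly one boundary (i < j once suffices)
        if (i < j && nrow(ia) > 0L && nrow(ib) > 0L) {
          for (k in seq_len(nrow(ia))) {
            for (l in seq_len(nrow(ib))) {
              sa <- ia$start[k]; ea <- ia$end[k]
              sb <- ib$start[l]; eb <- ib$end[l]
              if (ea == eb && sa != sb) {
                # shared right boundary; region between the two left ends
                longer <- if (sa < sb) ids[i] else ids[j]   # longer intron
                shorter <- setdiff(c(ids[i], ids[j]), longer)
                sh_t <- txs[[shorter]]
                vs <- min(sa, sb); ve <- max(sa, sb)
                if (covers(sh_t, vs, ve)) {
                  type <- if (strand == "-") "A3" else "A5"
                  add(type, vs, ve, shorter, longer)
                }
              } else if (sa == sb && ea != eb) {
                longer <- if (ea > eb) ids[i] else ids[j]
                shorter <- setdiff(c(ids[i], ids[j]), longer)
                sh_t <- txs[[shorter]]
                vs <- min(ea, eb); ve <- max(ea, eb)
                if (covers(sh_t, vs, ve)) {
                  type <- if (strand == "-") "A5" else "A3"
                  add(type, vs, ve, shorter, longer)
                }
              }
            }
          }
        }
      }
    }
    if (length(ev) == 0L) return(NULL)
    dplyr::bind_rows(ev) |>
      dplyr::group_by(.data$gene_id, .data$event_type, .data$chrom,
                      .data$var_start, .data$var_end) |>
      dplyr::summarise(inclusion = list(sort(unique(.data$inclusion))),
                       exclusion = list(sort(unique(.data$exclusion))),
                       .groups = "drop")
  })
  out <- dplyr::bind_rows(all_events)
  if (nrow(out) == 0L) {
    return(tibble::tibble(event_id = character(), gene_id = character(),
                          event_type = character(), chrom = character(),
                          var_start = integer(), var_end = integer(),
                          inclusion = list(), exclusion = list()))
  }
  out <- dplyr::arrange(out, .data$gene_id, .data$var_start, .data$event_type)
  dplyr::mutate(out, event_id = sprintf("%s.%s.%d", .data$gene_id,
                                        .data$event_type,
                                        .data$var_start),
                .before = 1)
}

#' Percent-spliced-in (PSI) per event and sample
#'
#' `PSI = sum(inclusion abundance) / sum(inclusion + exclusion abundance)`
#' per sample; undefined (`NA`) when the event's total abundance does not
#' exceed `min_event_abundance`.
#'
#' @param events Event tibble from [detect_as_events()].
#' @param abundance Transcript abundance tibble (`feature_id` + sample
#'   columns, TPM or similar).
#' @param min_event_abundance Definedness threshold on the denominator.
#' @return A long tibble: `event_id`, `gene_id`, `event_type`, `sample`,
#'   `psi`, `total_abundance`.
#' @export
compute_psi <- function(events, abundance, min_event_abundance = 1) {
  sample_cols <- setdiff(names(abundance), "feature_id")
  amat <- as.matrix(abundance[sample_cols])
  rownames(amat) <- abundance$feature_id
  sum_rows <- function(ids) {
    ids <- intersect(ids, rownames(amat))
    if (length(ids) == 0L) return(rep(0, ncol(amat)))
    colSums(amat[ids, , drop = FALSE])
  }
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    inc <- sum_rows(events$inclusion[[i]])
    tot <- inc + sum_rows(events$exclusion[[i]])
    tibble::tibble(
      event_id = events$event_id[i], gene_id = events$gene_id[i],
      event_type = events$event_type[i], sample = sample_cols,
      psi = unname(ifelse(tot > min_event_abundance, inc / tot, NA_real_)),
      total_abundance = unname(tot)
    )
  })
  dplyr::bind_rows(rows)
}

# Pooled permutation p-values for |delta| between two conditions.
# values: units x samples matrix; cond: condition label per column.
# The null is built from residuals: each unit's values are centred within
# condition (removing any true condition effect), then condition labels are
# permuted and |delta| recomputed, pooling across units. Pooling gives
# p-value granularity 1/(n_units * n_permutations) rather than the handful
# of distinct label assignments a per-unit exact test allows, and centring
# keeps units with real effects from contaminating the null.
pooled_perm_pvalues <- function(values, cond, n_permutations = 100L, seed = 1L) {
  set.seed(seed)
  lv <- sort(unique(cond))   # delta = second condition minus first, sorted
  stopifnot(length(lv) == 2L)
  delta_for <- function(m, labels) {
    m1 <- rowMeans(m[, labels == lv[1], drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(m[, labels == lv[2], drop = FALSE], na.rm = TRUE)
    m2 - m1
  }
  obs <- delta_for(values, cond)
  centred <- values
  for (l in lv) {
    sel <- cond == l
    centred[, sel] <- values[, sel, drop = FALSE] -
      rowMeans(values[, sel, drop = FALSE], na.rm = TRUE)
  }
  null_pool <- unlist(purrr::map(seq_len(n_permutations), function(b) {
    abs(delta_for(centred, sample(cond)))
  }))
  null_pool <- null_pool[is.finite(null_pool)]
  pool_sorted <- sort(null_pool)
  n_ge <- length(pool_sorted) - findInterval(abs(obs) - 1e-12, pool_sorted)
  p <- (1 + n_ge) / (1 + length(pool_sorted))
  p[!is.finite(obs)] <- NA_real_
  list(delta = obs, p = p)
}

#' Call differential alternative splicing (DAS)
#'
#' Computes per-event delta PSI between two conditions (condition 2 minus
#' condition 1), assigns p-values by permutation of sample labels on
#' |delta PSI| with the null pooled across events, adjusts with
#' Benjamini-Hochberg, and calls an event DAS when `fdr < fdr_threshold`
#' and `|delta_psi| >= delta_threshold`. A DAS gene is a gene with at least
#' one DAS event. With `mode = "threshold_only"` (for designs without
#' replicates) only the delta-PSI threshold is applied and p/fdr are `NA`.
#'
#' @param psi Long PSI tibble from [compute_psi()].
#' @param sample_info Tibble with columns `sample`, `condition` (exactly two
#'   conditions).
#' @param delta_threshold Minimum |delta PSI| (default 0.10).
#' @param fdr_threshold BH-FDR cutoff (default 0.01).
#' @param n_permutations Label permutations for the pooled null.
#' @param mode `"permutation"` (default; needs >= 2 replicates per
#'   condition) or `"threshold_only"`.
#' @param seed Seed for the permutation draw.
#' @return An object of class `das_result`: list with `events` (tibble:
#'   `event_id`, `gene_id`, `event_type`, `psi_c1`, `psi_c2`, `delta_psi`,
#'   `p_value`, `fdr`, `das`), `das_genes` (character) and `params`.
#' @export
call_das <- function(psi, sample_info, delta_threshold = 0.10,
                     fdr_threshold = 0.01, n_permutations = 100L,
                     mode = c("permutation", "threshold_only"), seed = 1L) {
  mode <- match.arg(mode)
  conds <- sort(unique(sample_info$condition))
  if (length(conds) != 2L) stop("exactly two conditions required")
  wide <- tidyr::pivot_wider(
    psi[c("event_id", "gene_id", "event_type", "sample", "psi")],
    names_from = "sample", values_from = "psi"
  )
  cond <- sample_info$condition[match(setdiff(names(wide),
                                              c("event_id", "gene_id", "event_type")),
                                      sample_info$sample)]
  values <- as.matrix(wide[setdiff(names(wide),
                                   c("event_id", "gene_id", "event_type"))])
  if (mode == "permutation") {
    if (min(table(cond)) < 2L) {
      stop("permutation testing needs >= 2 replicates per condition; ",
           "use mode = \"threshold_only\"")
    }
    pp <- pooled_perm_pvalues(values, cond, n_permutations, seed)
    p <- pp$p
    delta <- pp$delta
  } else {
    m1 <- rowMeans(values[, cond == conds[1], drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(values[, cond == conds[2], drop = FALSE], na.rm = TRUE)
    delta <- m2 - m1
    p <- rep(NA_real_, length(delta))
  }
  fdr <- stats::p.adjust(p, method = "BH")
  das <- if (mode == "permutation") {
    !is.na(fdr) & fdr < fdr_threshold & abs(delta) >= delta_threshold
  } else {
    is.finite(delta) & abs(delta) >= delta_threshold
  }
  events <- tibble::tibble(
    event_id = wide$event_id, gene_id = wide$gene_id,
    event_type = wide$event_type,
    psi_c1 = rowMeans(values[, cond == conds[1], drop = FALSE], na.rm = TRUE),
    psi_c2 = rowMeans(values[, cond == conds[2], drop = FALSE], na.rm = TRUE),
    delta_psi = delta, p_value = p, fdr = fdr, das = das
  )
  structure(
    list(events = events,
         das_genes = sort(unique(events$gene_id[events$das])),
         params = list(delta_threshold = delta_threshold,
                       fdr_threshold = fdr_threshold, mode = mode,
                       n_permutations = n_permutations, seed = seed,
                       conditions = conds)),
    class = "das_result"
  )
}

#' @export
print.das_result <- function(x, ...) {
  cat("<das_result>", nrow(x$events), "events;",
      sum(x$events$das), "DAS events in", length(x$das_genes), "DAS genes\n")
  invisible(x)
}

#' @rdname call_das
#' @param x A `das_result` object.
#' @param ... Unused.
#' @export
tidy.das_result <- function(x, ...) x$events

#' @rdname call_das
#' @export
glance.das_result <- function(x, ...) {
  tibble::tibble(n_events = nrow(x$events), n_das_events = sum(x$events$das),
                 n_das_genes = length(x$das_genes),
                 delta_threshold = x$params$delta_threshold,
                 fdr_threshold = x$params$fdr_threshold, mode = x$params$mode)
}

#' Call differential transcript usage (DTU)
#'
#' Per transcript, the usage proportion is its abundance over the gene's
#' total per sample; the change in mean proportion between conditions is
#' tested with the same pooled permutation scheme as [call_das()] and a
#' transcript is DTU when `fdr < fdr_threshold` and
#' `|delta_proportion| > delta_threshold` (strict).
#'
#' @param abundance Transcript abundance tibble (`feature_id` + samples).
#' @param tx2gene Tibble with columns `transcript_id`, `gene_id`.
#' @param sample_info Tibble with `sample`, `condition`.
#' @param delta_threshold Strict minimum |delta proportion| (default 0.10).
#' @param fdr_threshold BH-FDR cutoff (default 0.01).
#' @param n_permutations,seed Permutation settings.
#' @return A tibble: `transcript_id`, `gene_id`, `prop_c1`, `prop_c2`,
#'   `delta_prop`, `p_value`, `fdr`, `dtu`.
#' @export
call_dtu <- function(abundance, tx2gene, sample_info, delta_threshold = 0.10,
                     fdr_threshold = 0.01, n_permutations = 100L, seed = 1L) {
  sample_cols <- setdiff(names(abundance), "feature_id")
  amat <- as.matrix(abundance[sample_cols])
  gene <- tx2gene$gene_id[match(abundance$feature_id, tx2gene$transcript_id)]
  if (anyNA(gene)) stop("transcripts missing from tx2gene: ",
                        paste(utils::head(abundance$feature_id[is.na(gene)], 5),
                              collapse = ", "))
  totals <- rowsum(amat, gene)
  prop <- amat / totals[gene, , drop = FALSE]
  prop[!is.finite(prop)] <- NA
  cond <- sample_info$condition[match(sample_cols, sample_info$sample)]
  conds <- sort(unique(sample_info$condition))
  pp <- pooled_perm_pvalues(prop, cond, n_permutations, seed)
  fdr <- stats::p.adjust(pp$p, method = "BH")
  tibble::tibble(
    transcript_id = abundance$feature_id, gene_id = gene,
    prop_c1 = rowMeans(prop[, cond == conds[1], drop = FALSE], na.rm = TRUE),
    prop_c2 = rowMeans(prop[, cond == conds[2], drop = FALSE], na.rm = TRUE),
    delta_prop = pp$delta, p_value = pp$p, fdr = fdr,
    dtu = !is.na(fdr) & fdr < fdr_threshold &
      abs(pp$delta) > delta_threshold
  )
}

#' Predict NMD-triggering transcripts (50-nt rule)
#'
#' A transcript is predicted to be degraded by nonsense-mediated decay when
#' its stop codon lies more than `nmd_rule_nt` nucleotides upstream of the
#' last exon-exon junction in spliced-transcript coordinates (and such a
#' junction exists downstream of the stop). Single-exon transcripts and
#' transcripts whose stop falls in the last exon are not PTC-bearing.
#'
#' @param models Gene-model tibble with exon and CDS rows.
#' @param genome Optional named character vector of chromosome sequences;
#'   when supplied, the last codon of each CDS is checked to be a stop and a
#'   warning names transcripts where it is not.
#' @param nmd_rule_nt Rule distance in nt (default 50).
#' @return A tibble: `transcript_id`, `gene_id`, `stop_tx_pos` (1-based
#'   transcript coordinate of the last CDS base), `last_junction_tx`,
#'   `junction_distance`, `is_ptc`.
#' @export
predict_nmd <- function(models, genome = NULL, nmd_rule_nt = 50L) {
  exons <- dplyr::filter(models, .data$feature == "exon")
  cds <- dplyr::filter(models, .data$feature == "CDS")
  txs <- intersect(unique(exons$transcript_id), unique(cds$transcript_id))
  rows <- purrr::map(txs, function(tx) {
    e <- dplyr::arrange(exons[exons$transcript_id == tx, ], .data$start)
    cc <- cds[cds$transcript_id == tx, ]
    strand <- e$strand[1]
    widths <- e$end - e$start
    # genomic position of the final CDS base (stop codon's 3'-most base)
    stop_g <- if (strand == "+") max(cc$end) - 1L else min(cc$start)
    # transcript coordinate (1-based, 5'->3')
    tx_coord <- function(gpos) {
      k <- which(e$start <= gpos & gpos < e$end)
      if (length(k) != 1L) stop("CDS position outside exons for ", tx)
      if (strand == "+") {
        sum(widths[seq_len(k - 1L)]) + (gpos - e$start[k]) + 1L
      } else {
        n <- nrow(e)
        sum(rev(widths)[seq_len(n - k)]) + (e$end[k] - gpos)
      }
    }
    stop_tx <- tx_coord(stop_g)
    n_ex <- nrow(e)
    junctions <- if (n_ex < 2L) integer() else {
      w_tx <- if (strand == "+") widths else rev(widths)
      cumsum(w_tx)[-n_ex]
    }
    if (!is.null(genome)) {
      seq_chr <- genome[[e$chrom[1]]]
      cds_sorted <- dplyr::arrange(cc, .data$start)
      cds_seq <- paste0(substring(seq_chr, cds_sorted$start + 1L, cds_sorted$end),
                        collapse = "")
      if (strand == "-") cds_seq <- revcomp(cds_seq)
      last_codon <- substr(cds_seq, nchar(cds_seq) - 2L, nchar(cds_seq))
      if (!last_codon %in% c("TAA", "TAG", "TGA")) {
        warning("CDS of ", tx, " does not end in a stop codon")
      }
    }
    last_j <- if (length(junctions)) max(junctions) else NA_integer_
    dist <- if (is.na(last_j)) NA_integer_ else last_j - stop_tx
    tibble::tibble(
      transcript_id = tx, gene_id = cc$gene_id[1], stop_tx_pos = stop_tx,
      last_junction_tx = last_j, junction_distance = dist,
      is_ptc = !is.na(dist) && dist > nmd_rule_nt
    )
  })
  dplyr::bind_rows(rows)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Partition gene sets by transcriptional vs splicing regulation
#'
#' Exact set algebra on differential-expression (DE) and differential
#' alternative splicing (DAS) gene ID sets.
#'
#' @param de_genes,das_genes Character vectors of gene IDs.
#' @return A tibble with rows `DE_only`, `DAS_only`, `DE_and_DAS`: columns
#'   `set`, `n`, and list-column `gene_ids`.
#' @examples
#' partition_gene_sets(c("g1", "g2", "g3"), c("g3", "g4"))
#' @export
partition_gene_sets <- function(de_genes, das_genes) {
  de <- unique(de_genes)
  das <- unique(das_genes)
  both <- intersect(de, das)
  tibble::tibble(
    set = c("DE_only", "DAS_only", "DE_and_DAS"),
    n = c(length(setdiff(de, das)), length(setdiff(das, de)), length(both)),
    gene_ids = list(sort(setdiff(de, das)), sort(setdiff(das, de)), sort(both))
  )
}
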