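#' TE context of genes: 2-kb flanks and gene body
#'
#' For each gene, tests whether any TE overlaps its 5' flank
#' `[start - flank_bp, start)`, its body `[start, end)` or its 3' flank
#' `[end, end + flank_bp)`, with the flank labels following gene orientation
#' (for a minus-strand gene the 5' flank is downstream in physical
#' coordinates). Flank windows are clipped at position 0. The gene body is
#' the full gene span, so intronic insertions count as body hits.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (gene rows of a gene-model tibble are accepted).
#' @param tes Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `te_class`, `superfamily`.
#' @param flank_bp Flank width (default 2000).
#' @param te_filter Optional predicate applied to `tes` rows first, e.g.
#'   `~ .x$te_class == "retrotransposon"` for an LTR-only context; `NULL`
#'   keeps all TEs.
#' @return A tibble: `gene_id`, `has_te_5prime_flank`, `has_te_body`,
#'   `has_te_3prime_flank`, and list-column `te_ids` of matched TE names.
#' @export
find_te_context <- function(genes, tes, flank_bp = 2000L, te_filter = NULL) {
  if ("feature" %in% names(genes)) {
    genes <- dplyr::filter(genes, .data$feature == "gene")
  }
  if (!is.null(te_filter)) {
    keep <- purrr::map_lgl(seq_len(nrow(tes)), ~ rlang::as_function(te_filter)(tes[.x, ]))
    tes <- tes[keep, ]
  }
  if (!"name" %in% names(tes)) tes$name <- sprintf("te%05d", seq_len(nrow(tes)))

  compartments <- dplyr::bind_rows(
    dplyr::transmute(genes, gene_id = .data$gene_id, chrom = .data$chrom,
                     end = .data$start,
                     start = pmax(.data$start - flank_bp, 0L),
                     comp = ifelse(.data$strand == "-", "flank3", "flank5")),
    dplyr::transmute(genes, gene_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$start, end = .data$end, comp = "body"),
    dplyr::transmute(genes, gene_id = .data$gene_id, chrom = .data$chrom,
                     start = .data$end, end = .data$end + flank_bp,
                     comp = ifelse(.data$strand == "-", "flank5", "flank3"))
  )
  compartments <- dplyr::filter(compartments, .data$end > .data$start)

  hits <- overlap_pairs(compartments, tes)
  hit_tbl <- tibble::tibble(
    gene_id = compartments$gene_id[hits$query],
    comp = compartments$comp[hits$query],
    te_id = tes$name[hits$subject]
  )
  per_gene <- hit_tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      has_te_5prime_flank = any(.data$comp == "flank5"),
      has_te_body = any(.data$comp == "body"),
      has_te_3prime_flank = any(.data$comp == "flank3"),
      te_ids = list(unique(.data$te_id)), .groups = "drop"
    )
  out <- tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      dplyr::across(dplyr::starts_with("has_te"), ~ !is.na(.x) & .x),
      te_ids = purrr::map(.data$te_ids, ~ if (is.null(.x)) character() else .x)
    )
  out
}

# chromosome-aware interval overlap via IRanges; returns query/subject index
# pairs (0-width queries never overlap, consistent with half-open semantics)
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  res <- purrr::map(intersect(unique(query$chrom), unique(subject$chrom)), function(ch) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    # half-open [start, end) -> closed [start+1, end] on integers
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    ov <- IRanges::findOverlaps(qr, sr)
    tibble::tibble(query = qi[S4Vectors::queryHits(ov)],
                   subject = si[S4Vectors::subjectHits(ov)])
  })
  dplyr::bind_rows(res)
}

#' Partition TEs into syntenic and non-syntenic compartments
#'
#' A TE is syntenic when its midpoint falls inside any synteny block
#' (midpoint membership makes the partition exact: every TE is counted once,
#' so copy numbers and total lengths are conserved). `rule = "overlap"`
#' instead calls a TE syntenic on any overlap with a block.
#'
#' @param tes TE tibble (`chrom`, `start`, `end`, optionally `te_class`,
#'   `superfamily`).
#' @param blocks Synteny-block tibble (`chrom`, `start`, `end`), 0-based
#'   half-open.
#' @param rule `"midpoint"` (default) or `"overlap"`.
#' @return A tibble grouped by `te_class`/`superfamily` (when present) and
#'   `compartment` (`"syntenic"`/`"non_syntenic"`), with `copies` and
#'   `total_bp`.
#' @export
partition_by_synteny <- function(tes, blocks, rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  if (rule == "midpoint") {
    mid <- floor((tes$start + tes$end) / 2)
    probe <- tibble::tibble(chrom = tes$chrom, start = mid, end = mid + 1L)
  } else {
    probe <- tes[c("chrom", "start", "end")]
  }
  hits <- overlap_pairs(probe, blocks)
  syntenic <- seq_len(nrow(tes)) %in% hits$query
  grouping <- intersect(c("te_class", "superfamily"), names(tes))
  tes |>
    dplyr::mutate(
      compartment = ifelse(syntenic, "syntenic", "non_syntenic"),
      te_length = .data$end - .data$start
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "compartment")))) |>
    dplyr::summarise(copies = dplyr::n(), total_bp = sum(.data$te_length),
                     .groups = "drop")
}

#' Compare expression of insertion-asymmetric homolog pairs
#'
#' For homolog pairs where one genome's copy carries an LTR insertion in its
#' flank or body and the other's carries none, tests whether the
#' insertion-free copy is expressed differently: a Welch two-sample t-test
#' on log2-scale replicate expression per pair, with fold change reported on
#' the mean scale, oriented as genome A (insertion-free) over genome B
#' (insertion-carrying). A pair is significant when `|log2 FC|` exceeds
#' `log2(fc_threshold)` and the raw p-value is below `p_threshold`;
#' Benjamini-Hochberg FDR across pairs is reported alongside.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` (pre-filtered to the
#'   insertion-asymmetric configuration; `gene_a` = insertion-free genome).
#' @param expr_a,expr_b Expression tibbles (`feature_id` + replicate
#'   columns) for the two genomes.
#' @param fc_threshold,p_threshold Significance thresholds (defaults 2 and
#'   0.05).
#' @param log_offset Offset added before log2 for the test.
#' @return A tibble: `gene_a`, `gene_b`, `mean_a`, `mean_b`, `fold_change`,
#'   `log2_fc`, `p_value`, `fdr`, `significant`, `tested` (FALSE when either
#'   side has < 2 replicates).
#' @export
compare_homolog_expression <- function(pairs, expr_a, expr_b,
                                       fc_threshold = 2, p_threshold = 0.05,
                                       log_offset = 1) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          mean_a = numeric(), mean_b = numeric(),
                          fold_change = numeric(), log2_fc = numeric(),
                          p_value = numeric(), fdr = numeric(),
                          significant = logical(), tested = logical()))
  }
  get_reps <- function(expr, id) {
    row <- expr[expr$feature_id == id, -1, drop = FALSE]
    if (nrow(row) == 0L) return(numeric())
    as.numeric(row[1, ])
  }
  rows <- purrr::map2(pairs$gene_a, pairs$gene_b, function(ga, gb) {
    a <- get_reps(expr_a, ga)
    b <- get_reps(expr_b, gb)
    tested <- length(a) >= 2L && length(b) >= 2L
    p <- NA_real_
    if (tested) {
      la <- log2(a + log_offset)
      lb <- log2(b + log_offset)
      p <- if (stats::sd(c(la, lb)) == 0) 1 else
        stats::t.test(la, lb)$p.value
    }
    ma <- mean(a)
    mb <- mean(b)
    fc <- ma / mb
    tibble::tibble(gene_a = ga, gene_b = gb, mean_a = ma, mean_b = mb,
                   fold_change = fc, log2_fc = log2(fc), p_value = p,
                   tested = tested)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$tested &
    abs(out$log2_fc) > log2(fc_threshold) &
    !is.na(out$p_value) & out$p_value < p_threshold
  dplyr::relocate(out, "fdr", .after = "p_value")
}
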