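effect_categories <- function() {
  c("splice_site", "stop_gain", "stop_loss", "frameshift_deletion",
    "frameshift_insertion", "inframe_deletion", "inframe_insertion",
    "missense", "synonymous", "utr5", "utr3", "intronic", "upstream",
    "downstream", "intergenic")
}

default_coding_categories <- function() {
  c("missense", "stop_gain", "stop_loss", "frameshift_insertion",
    "frameshift_deletion", "inframe_insertion", "inframe_deletion")
}

# 0-based half-open genomic footprint of a variant (VCF-anchored alleles)
variant_span <- function(pos, ref, alt, type) {
  switch(type,
    SNP = c(pos - 1L, pos),
    INS = c(pos - 1L, pos),                        # anchor base
    DEL = c(pos, pos + nchar(ref) - nchar(alt))    # bases after the anchor
  )
}

#' Annotate variant effects against gene models
#'
#' Re-implements CDS-aware effect annotation: each variant is classified,
#' per overlapping transcript, into one category from a precedence ladder
#' (`splice_site` > coding categories > `utr5`/`utr3` > `intronic` >
#' `upstream`/`downstream` > `intergenic`). Coding SNPs are translated on
#' the coding strand with the standard genetic code; deletions overlapping
#' CDS are `frameshift_deletion` when the number of coding bases removed is
#' not a multiple of 3 (`inframe_deletion` otherwise), and insertions
#' analogously by inserted length. A variant within `splice_window` bp of an
#' intron boundary is `splice_site`. Variants with no gene within
#' `flank_bp` are `intergenic`; transcripts without CDS receive non-coding
#' categories only.
#'
#' @param variants Variant tibble (`chrom`, `pos` 1-based, `ref`, `alt`,
#'   `type`).
#' @param models Gene-model tibble from [read_gff3_models()].
#' @param genome Named character vector of chromosome sequences (required
#'   for SNP codon translation).
#' @param flank_bp Upstream/downstream window (default 2000).
#' @param splice_window Distance from an intron boundary counted as
#'   `splice_site` (default 2).
#' @return A tibble with one row per (variant, overlapping transcript) —
#'   or a single `intergenic` row for variants near no gene: `chrom`, `pos`,
#'   `ref`, `alt`, `type`, `gene_id`, `transcript_id`, `category`, `detail`.
#' @export
annotate_effects <- function(variants, models, genome, flank_bp = 2000L,
                             splice_window = 2L) {
  gene_rows <- dplyr::filter(models, .data$feature == "gene")
  exon_rows <- dplyr::filter(models, .data$feature == "exon")
  cds_rows <- dplyr::filter(models, .data$feature == "CDS")
  mrna_rows <- dplyr::filter(models, .data$feature == "mRNA")

  rows <- purrr::map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!is.null(genome) && v$chrom %in% names(genome) &&
        v$pos > nchar(genome[[v$chrom]])) {
      stop("variant at ", v$chrom, ":", v$pos, " beyond chromosome end")
    }
    sp <- variant_span(v$pos, v$ref, v$alt, v$type)
    near <- gene_rows$chrom == v$chrom &
      gene_rows$start - flank_bp < sp[2] & gene_rows$end + flank_bp > sp[1]
    if (!any(near)) {
      return(tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref,
                            alt = v$alt, type = v$type,
                            gene_id = NA_character_,
                            transcript_id = NA_character_,
                            category = "intergenic", detail = ""))
    }
    purrr::map(which(near), function(g) {
      gene <- gene_rows[g, ]
      txs <- mrna_rows$transcript_id[mrna_rows$gene_id == gene$gene_id]
      if (length(txs) == 0L) txs <- NA_character_
      purrr::map(txs, function(tx) {
        cls <- classify_against_transcript(
          v, sp, gene, tx,
          exon_rows[!is.na(tx) & exon_rows$transcript_id %in% tx, ],
          cds_rows[!is.na(tx) & cds_rows$transcript_id %in% tx, ],
          genome, flank_bp, splice_window
        )
        tibble::tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                       type = v$type, gene_id = gene$gene_id,
                       transcript_id = tx, category = cls$category,
                       detail = cls$detail)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

classify_against_transcript <- function(v, sp, gene, tx, exons, cds, genome,
                                        flank_bp, splice_window) {
  strand <- gene$strand
  in_gene <- sp[1] < gene$end && sp[2] > gene$start
  if (!in_gene) {
    # flank only: upstream/downstream by strand
    before <- sp[2] <= gene$start
    cat <- if ((before && strand != "-") || (!before && strand == "-")) {
      "upstream"
    } else {
      "downstream"
    }
    return(list(category = cat, detail = ""))
  }
  exons <- dplyr::arrange(exons, .data$start)
  has_cds <- nrow(cds) > 0L
  cds_overlap_bp <- if (has_cds) {
    sum(pmax(0L, pmin(cds$end, sp[2]) - pmax(cds$start, sp[1])))
  } else 0L
  # variants that remove or interrupt coding sequence are classified by their
  # coding consequence even when they also touch a splice junction (a
  # deletion running from an exon into the intron is a frameshift, not a
  # splice_site call); pure splice-site variants have no CDS overlap
  if (has_cds && (cds_overlap_bp > 0L ||
                  (v$type == "INS" && ins_in_cds(sp, cds)))) {
    return(coding_effect(v, sp, cds, strand, genome, cds_overlap_bp))
  }
  # splice-site check: within splice_window of an intron boundary
  if (nrow(exons) >= 2L) {
    istart <- exons$end[-nrow(exons)]
    iend <- exons$start[-1]
    near_boundary <- any(
      (sp[1] < istart + splice_window & sp[2] > istart - splice_window) |
        (sp[1] < iend + splice_window & sp[2] > iend - splice_window)
    )
    in_intron_region <- any(sp[1] < iend & sp[2] > istart)
    if (near_boundary && in_intron_region) {
      # only boundary-adjacent positions inside/overlapping the intron count
      return(list(category = "splice_site", detail = ""))
    }
  }
  in_exon <- any(sp[1] < exons$end & sp[2] > exons$start)
  if (in_exon) {
    if (!has_cds) return(list(category = "intronic", detail = "non-coding transcript"))
    # UTR side relative to CDS on the coding strand
    cds_lo <- min(cds$start)
    cds_hi <- max(cds$end)
    before_cds <- sp[2] <= cds_lo
    cat <- if ((before_cds && strand != "-") || (!before_cds && strand == "-")) {
      "utr5"
    } else {
      "utr3"
    }
    return(list(category = cat, detail = ""))
  }
  list(category = "intronic", detail = "")
}

# an insertion interrupts the CDS when the insertion point (the boundary
# after the anchor base) lies strictly inside a CDS interval
ins_in_cds <- function(sp, cds) {
  any(cds$start < sp[2] & sp[2] < cds$end)
}

coding_effect <- function(v, sp, cds, strand, genome, cds_overlap_bp) {
  if (v$type == "SNP") {
    return(snp_coding_effect(v, cds, strand, genome))
  }
  if (v$type == "DEL") {
    L <- cds_overlap_bp
    spans_boundary <- sp[1] < min(cds$start) || sp[2] > max(cds$end) ||
      cds_overlap_bp < (sp[2] - sp[1])
    detail <- paste0("deleted CDS length ", L,
                     if (spans_boundary) ", spans exon/intron boundary" else "")
    cat <- if (L %% 3L != 0L) "frameshift_deletion" else "inframe_deletion"
    return(list(category = cat, detail = detail))
  }
  # insertion
  L <- nchar(v$alt) - nchar(v$ref)
  cat <- if (L %% 3L != 0L) "frameshift_insertion" else "inframe_insertion"
  list(category = cat, detail = paste0("inserted length ", L))
}

snp_coding_effect <- function(v, cds, strand, genome) {
  if (is.null(genome) || !(v$chrom %in% names(genome))) {
    stop("genome sequence required to translate coding SNPs on ", v$chrom)
  }
  chrom_seq <- genome[[v$chrom]]
  cds <- dplyr::arrange(cds, .data$start)
  cds_seq <- paste0(substring(chrom_seq, cds$start + 1L, cds$end), collapse = "")
  # position of the SNP within the concatenated forward-strand CDS
  g0 <- v$pos - 1L
  k <- which(cds$start <= g0 & g0 < cds$end)
  offset_fwd <- sum((cds$end - cds$start)[seq_len(k - 1L)]) + (g0 - cds$start[k])
  if (strand == "-") {
    cds_seq <- revcomp(cds_seq)
    pos_cds <- nchar(cds_seq) - offset_fwd         # 1-based on coding strand
    ref_c <- revcomp(v$ref)
    alt_c <- revcomp(v$alt)
  } else {
    pos_cds <- offset_fwd + 1L
    ref_c <- v$ref
    alt_c <- v$alt
  }
  if (substr(cds_seq, pos_cds, pos_cds) != ref_c) {
    warning("reference allele mismatch at ", v$chrom, ":", v$pos)
  }
  codon_i <- (pos_cds - 1L) %/% 3L
  within <- (pos_cds - 1L) %% 3L + 1L
  codon_ref <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_c
  aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  cat <- if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "stop_gain"
  } else if (aa_ref == "*") {
    "stop_loss"
  } else {
    "missense"
  }
  list(category = cat,
       detail = sprintf("%s%d%s (%s>%s)", aa_ref, codon_i + 1L, aa_alt,
                        codon_ref, codon_alt))
}

#' Gene-level summary of variant effects
#'
#' Collapses per-transcript effects to one row per gene carrying the most
#' severe category (severity follows the order of `effect_categories()`,
#' most severe first).
#'
#' @param effects Effect tibble from [annotate_effects()].
#' @return A tibble: `gene_id`, `category` (most severe), `n_effects`.
#' @export
summarize_gene_effects <- function(effects) {
  lv <- effect_categories()
  effects |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      category = lv[min(match(.data$category, lv))],
      n_effects = dplyr::n(), .groups = "drop"
    )
}

#' Filter candidate genes by mutation class
#'
#' Returns the genes carrying at least one effect in the requested
#' categories, optionally restricted to candidate regions.
#'
#' @param effects Effect tibble from [annotate_effects()].
#' @param categories Character vector of qualifying categories; the default
#'   covers non-synonymous point mutations plus coding insertions and
#'   deletions.
#' @param regions Optional region tibble (`chrom`, `start`, `end`); when
#'   given, only effects whose variant lies inside a region count.
#' @return A sorted character vector of gene IDs.
#' @export
filter_candidate_genes <- function(effects,
                                   categories = default_coding_categories(),
                                   regions = NULL) {
  hits <- dplyr::filter(effects, .data$category %in% categories,
                        !is.na(.data$gene_id))
  if (!is.null(regions) && nrow(hits) > 0L) {
    inside <- purrr::map_lgl(seq_len(nrow(hits)), function(i) {
      any(regions$chrom == hits$chrom[i] &
            regions$start < hits$pos[i] & hits$pos[i] <= regions$end)
    })
    hits <- hits[inside, ]
  }
  sort(unique(hits$gene_id))
}
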