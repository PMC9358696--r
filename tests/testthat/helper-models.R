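# Toy gene-model builders used across test files.

toy_model_row <- function(gene_id, transcript_id, feature, start, end,
                          chrom = "chr01", strand = "+", phase = NA_integer_) {
  tibble::tibble(gene_id = gene_id, transcript_id = transcript_id,
                 feature = feature, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, phase = phase)
}

# a gene with arbitrary exon/CDS interval lists (0-based half-open)
toy_gene <- function(gene_id, exons, cds = NULL, chrom = "chr01",
                     strand = "+", tx_suffix = ".t1") {
  tx <- paste0(gene_id, tx_suffix)
  span <- c(min(exons[, 1]), max(exons[, 2]))
  rows <- dplyr::bind_rows(
    toy_model_row(gene_id, NA_character_, "gene", span[1], span[2], chrom, strand),
    toy_model_row(gene_id, tx, "mRNA", span[1], span[2], chrom, strand),
    purrr::map2(exons[, 1], exons[, 2],
                ~ toy_model_row(gene_id, tx, "exon", .x, .y, chrom, strand)) |>
      dplyr::bind_rows()
  )
  if (!is.null(cds)) {
    rows <- dplyr::bind_rows(rows,
      purrr::map2(cds[, 1], cds[, 2],
                  ~ toy_model_row(gene_id, tx, "CDS", .x, .y, chrom, strand,
                                  phase = 0L)) |>
        dplyr::bind_rows()
    )
  }
  rows
}

# add an extra transcript (exon rows only) to an existing gene
toy_transcript <- function(gene_id, tx_id, exons, chrom = "chr01", strand = "+") {
  dplyr::bind_rows(
    toy_model_row(gene_id, tx_id, "mRNA", min(exons[, 1]), max(exons[, 2]),
                  chrom, strand),
    purrr::map2(exons[, 1], exons[, 2],
                ~ toy_model_row(gene_id, tx_id, "exon", .x, .y, chrom, strand)) |>
      dplyr::bind_rows()
  )
}

random_genome <- function(len, chrom = "chr01", rng_seed = 1) {
  set.seed(rng_seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), chrom)
}

# plant a specific subsequence into a genome string at a 0-based offset
plant_seq <- function(genome, offset, seq) {
  chrom <- names(genome)
  s <- genome[[1]]
  substr(s, offset + 1, offset + nchar(seq)) <- seq
  stats::setNames(s, chrom)
}
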