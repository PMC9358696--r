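#' Read a VCF with per-sample allele depths
#'
#' Parses a VCF 4.x file and extracts, for each biallelic record and each
#' requested pool (sample), the reference and alternate read depths from the
#' `FORMAT/AD` field. Multiallelic records are either decomposed into one row
#' per alternate allele (the default) or skipped.
#'
#' Positions stay 1-based as in the VCF; every other coordinate in this
#' package is 0-based half-open.
#'
#' @param path Path to an uncompressed VCF file.
#' @param pool_names Character vector of sample names to extract. All must be
#'   present in the VCF header.
#' @param multiallelic Either `"decompose"` (one row per alternate allele,
#'   sharing the position) or `"skip"`.
#' @return A tibble with one row per (record, alt allele): columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `type` (`"SNP"`, `"INS"` or `"DEL"`), and
#'   for every pool `P` two integer columns `P_ref` and `P_alt`.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "polyseg")
#' read_vcf_depths(vcf, c("S1", "S2"))
#' @export
read_vcf_depths <- function(path, pool_names, multiallelic = c("decompose", "skip")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readr::read_lines(path)
  header <- grep("^#CHROM", lines, value = TRUE)
  if (length(header) != 1L) stop("malformed VCF: expected exactly one #CHROM header line")
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  missing_pools <- setdiff(pool_names, cols)
  if (length(missing_pools) > 0L) {
    stop("sample(s) not present in VCF header: ", paste(missing_pools, collapse = ", "))
  }
  pool_idx <- match(pool_names, cols)
  body_idx <- which(!startsWith(lines, "#"))
  body <- lines[body_idx]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(empty_variant_tibble(pool_names))
  }

  rows <- purrr::map2(body, body_idx[nzchar(lines[body_idx])], function(line, lineno) {
    f <- strsplit(line, "\t")[[1]]
    if (length(f) < max(pool_idx)) {
      stop("malformed VCF line ", lineno, ": fewer fields than header columns")
    }
    fmt <- strsplit(f[9], ":")[[1]]
    ad_i <- match("AD", fmt)
    if (is.na(ad_i)) stop("FORMAT/AD missing at VCF line ", lineno)
    alts <- strsplit(f[5], ",")[[1]]
    if (length(alts) > 1L && multiallelic == "skip") return(NULL)
    ads <- purrr::map(f[pool_idx], function(s) {
      v <- suppressWarnings(as.integer(strsplit(strsplit(s, ":")[[1]][ad_i], ",")[[1]]))
      if (anyNA(v)) stop("unparseable AD value at VCF line ", lineno)
      v
    })
    purrr::imap(alts, function(alt, ai) {
      depth <- purrr::map(ads, function(v) c(ref = v[1], alt = v[ai + 1L]))
      tibble::tibble(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alt,
        type = variant_type(f[4], alt),
        !!!stats::setNames(
          purrr::flatten(purrr::map(depth, function(d) list(d[["ref"]], d[["alt"]]))),
          paste0(rep(pool_names, each = 2), c("_ref", "_alt"))
        )
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

variant_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNP",
    nchar(alt) > nchar(ref) ~ "INS",
    TRUE ~ "DEL"
  )
}

empty_variant_tibble <- function(pool_names) {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    type = character(),
    !!!stats::setNames(
      rep(list(integer()), 2L * length(pool_names)),
      paste0(rep(pool_names, each = 2), c("_ref", "_alt"))
    )
  )
}

#' Write variants with allele depths as a minimal VCF
#'
#' Companion writer for [read_vcf_depths()]; emits a minimal VCF 4.2 header,
#' one sample column per pool and a `GT:AD` FORMAT (genotypes written as
#' `./.` since only depths are modelled).
#'
#' @param variants A variant tibble as returned by [read_vcf_depths()] or
#'   [simulate_f2_bulks()].
#' @param path Output path.
#' @param pool_names Pools to write; defaults to all `*_ref`/`*_alt` column
#'   pairs found.
#' @return `path`, invisibly.
#' @export
write_vcf_depths <- function(variants, path, pool_names = NULL) {
  if (is.null(pool_names)) {
    pool_names <- unique(sub("_ref$", "", grep("_ref$", names(variants), value = TRUE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            pool_names), collapse = "\t")
  ), con)
  if (nrow(variants) > 0L) {
    sample_cols <- purrr::map(pool_names, function(p) {
      paste0("./.:", variants[[paste0(p, "_ref")]], ",", variants[[paste0(p, "_alt")]])
    })
    writeLines(do.call(paste, c(
      list(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
           ".", ".", ".", "GT:AD"),
      sample_cols, sep = "\t"
    )), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads `gene`, `mRNA`, `exon` and `CDS` features linked by `ID`/`Parent`
#' attributes and returns them as a flat feature tibble in the package's
#' internal 0-based half-open convention. Exons are sorted by coordinate
#' within each transcript. Features whose `Parent` cannot be resolved are
#' dropped and reported in the `orphans` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble with columns `gene_id`, `transcript_id`
#'   (`NA` for gene rows), `feature` (`"gene"`, `"mRNA"`, `"exon"`, `"CDS"`),
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `phase`.
#'   Attribute `orphans` lists unresolved features.
#' @export
read_gff3_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  raw <- readr::read_tsv(
    path, comment = "#", col_names = c(
      "chrom", "source", "feature", "start1", "end1", "score", "strand",
      "phase", "attributes"
    ),
    col_types = "ccciicccc", progress = FALSE
  )
  raw <- dplyr::filter(raw, .data$feature %in% c("gene", "mRNA", "transcript", "exon", "CDS"))
  raw$feature[raw$feature == "transcript"] <- "mRNA"
  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]+)"))[, 2]
    m
  }
  raw$id <- attr_field(raw$attributes, "ID")
  raw$parent <- attr_field(raw$attributes, "Parent")

  genes <- dplyr::filter(raw, .data$feature == "gene")
  mrnas <- dplyr::filter(raw, .data$feature == "mRNA")
  parts <- dplyr::filter(raw, .data$feature %in% c("exon", "CDS"))

  orphan_mrna <- mrnas$id[!(mrnas$parent %in% genes$id)]
  mrnas <- dplyr::filter(mrnas, .data$parent %in% genes$id)
  orphan_parts <- parts$id[!(parts$parent %in% mrnas$id)]
  orphan_parts <- orphan_parts[!is.na(orphan_parts)]
  parts <- dplyr::filter(parts, .data$parent %in% mrnas$id)

  tx2gene <- stats::setNames(mrnas$parent, mrnas$id)
  out <- dplyr::bind_rows(
    dplyr::transmute(genes,
      gene_id = .data$id, transcript_id = NA_character_, feature = "gene",
      chrom = .data$chrom, start = .data$start1 - 1L, end = .data$end1,
      strand = .data$strand, phase = NA_integer_
    ),
    dplyr::transmute(mrnas,
      gene_id = .data$parent, transcript_id = .data$id, feature = "mRNA",
      chrom = .data$chrom, start = .data$start1 - 1L, end = .data$end1,
      strand = .data$strand, phase = NA_integer_
    ),
    dplyr::transmute(parts,
      gene_id = unname(tx2gene[.data$parent]), transcript_id = .data$parent,
      feature = .data$feature, chrom = .data$chrom,
      start = .data$start1 - 1L, end = .data$end1, strand = .data$strand,
      phase = suppressWarnings(as.integer(.data$phase))
    )
  )
  out <- dplyr::arrange(out, .data$gene_id, .data$transcript_id, .data$feature,
                        .data$start)
  validate_gene_models(out)
  out <- tibble::as_tibble(out)
  attr(out, "orphans") <- c(orphan_mrna, orphan_parts)
  out
}

validate_gene_models <- function(models) {
  bad <- dplyr::filter(models, .data$start < 0L | .data$start >= .data$end)
  if (nrow(bad) > 0L) {
    stop("invalid feature intervals for: ",
         paste(utils::head(unique(stats::na.omit(c(bad$transcript_id, bad$gene_id))), 5),
               collapse = ", "))
  }
  cds <- dplyr::filter(models, .data$feature == "CDS")
  if (nrow(cds) > 0L) {
    exons <- dplyr::filter(models, .data$feature == "exon")
    offenders <- purrr::map_lgl(seq_len(nrow(cds)), function(i) {
      e <- exons[exons$transcript_id == cds$transcript_id[i], ]
      !any(e$start <= cds$start[i] & e$end >= cds$end[i])
    })
    if (any(offenders)) {
      stop("CDS outside exon bounds for transcript(s): ",
           paste(unique(cds$transcript_id[offenders]), collapse = ", "))
    }
  }
  invisible(models)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3_models()]: converts the internal 0-based half-open
#' coordinates back to 1-based inclusive GFF3.
#'
#' @param models A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  id <- dplyr::case_when(
    models$feature == "gene" ~ paste0("ID=", models$gene_id),
    models$feature == "mRNA" ~ paste0("ID=", models$transcript_id, ";Parent=", models$gene_id),
    TRUE ~ paste0("Parent=", models$transcript_id)
  )
  phase <- ifelse(is.na(models$phase), ".", as.character(models$phase))
  writeLines(paste(models$chrom, "polyseg", models$feature, models$start + 1L,
                   models$end, ".", models$strand, phase, id, sep = "\t"), con)
  invisible(path)
}

#' Read and write BED intervals
#'
#' BED is already 0-based half-open, so no coordinate conversion is applied.
#' Three to six columns are supported; absent name/score/strand columns are
#' filled with defaults (`.`/`0`/`.`).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE)
  if (ncol(raw) < 3L) stop("BED requires at least 3 columns")
  out <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    name = if (ncol(raw) >= 4) as.character(raw[[4]]) else ".",
    score = if (ncol(raw) >= 5) as.numeric(raw[[5]]) else 0,
    strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else "."
  )
  if (any(out$start >= out$end)) {
    stop("BED interval with start >= end at row(s): ",
         paste(utils::head(which(out$start >= out$end), 5), collapse = ", "))
  }
  out
}

#' @rdname read_bed
#' @param intervals Tibble with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("BED interval with start >= end")
  df <- tibble::tibble(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = intervals[["name"]] %||% ".",
    score = intervals[["score"]] %||% 0,
    strand = intervals[["strand"]] %||% "."
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a FASTA file as upper-case sequences
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of upper-cased sequences (IUPAC letters
#'   preserved).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' First column is the feature (gene or transcript) ID; remaining columns are
#' samples holding non-negative FPKM/TPM values.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble whose first column is `feature_id`.
#' @export
read_expression_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(out)[1] <- "feature_id"
  if (anyDuplicated(out$feature_id)) {
    stop("duplicate feature IDs in expression matrix: ",
         paste(utils::head(unique(out$feature_id[duplicated(out$feature_id)]), 5),
               collapse = ", "))
  }
  vals <- as.matrix(out[-1])
  if (any(vals < 0, na.rm = TRUE)) stop("negative expression values")
  out
}

#' Read a triad table TSV
#'
#' Expects columns `LF`, `MF1`, `MF2` holding one gene ID per subgenome.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns `LF`, `MF1`, `MF2`.
#' @export
read_triads_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("LF", "MF1", "MF2") %in% names(out))) {
    stop("triad table must have columns LF, MF1, MF2")
  }
  dplyr::select(out, "LF", "MF1", "MF2")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
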