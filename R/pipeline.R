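#' Read a sectioned key = value pipeline configuration
#'
#' Plain-text configuration with `[section]` headers and `key = value`
#' lines; `#` starts a comment. Values that parse as numbers become numeric.
#' Flags given in `overrides` (named list, names as `section.key`) replace
#' file values.
#'
#' @param path Path to the config file.
#' @param overrides Named list of `section.key = value` overrides.
#' @return A nested named list: `config$section$key`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- stringr::str_match(ln, "^([^=]+)=(.*)$")
    if (is.na(kv[1, 1])) stop("malformed config line: ", ln)
    key <- trimws(kv[1, 2])
    val <- trimws(kv[1, 3])
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <- if (!is.na(num)) num else val
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  cfg
}

#' Run one pipeline stage on files
#'
#' Thin file-level orchestration over the package's functions: each stage
#' reads the paths named in the config, runs the corresponding analysis and
#' writes TSV/BED/VCF outputs plus a JSON manifest (inputs, parameters,
#' seed, output MD5 hashes) under the configured output directory, so a
#' rerun with the same config and seed reproduces identical hashes.
#'
#' Stages: `"simulate"` (write a simulated F2 bulk VCF), `"bsa"`
#' (delta-index scan to marker/window/region/fixed-marker tables),
#' `"effects"` (variant-effect annotation), `"triads"` (classification +
#' summary), `"kaks"` (per-pair Ka/Ks from aligned CDS FASTA),
#' `"kaks-compare"` (group contrast), `"te-context"` (flank/body context +
#' synteny partition), `"homolog-compare"` (insertion-asymmetric pair
#' tests), `"splice"` (events, PSI, DAS), `"sets"` (DE/DAS partition).
#'
#' @param stage Stage name.
#' @param config Nested config list from [read_pipeline_config()].
#' @return Invisibly, a list with `outputs` (paths) and `manifest_path`.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "bsa", "effects", "triads", "kaks",
                              "kaks-compare", "te-context", "homolog-compare",
                              "splice", "sets"))
  paths <- config$paths %||% list()
  thr <- config$thresholds %||% list()
  seed <- as.integer(config$seeds$seed %||% 1)
  out_dir <- config$paths$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(key) {
    p <- paths[[key]]
    if (is.null(p)) stop("config paths.", key, " is required for stage ", stage)
    if (!file.exists(p)) stop("input path does not exist: ", p)
    p
  }
  outputs <- character()
  emit <- function(df, name, writer = readr::write_tsv) {
    p <- file.path(out_dir, name)
    writer(df, p)
    outputs[[length(outputs) + 1L]] <<- p
    p
  }

  if (stage == "simulate") {
    sim <- simulate_f2_bulks(seed = seed)
    p <- file.path(out_dir, "simulated_bulks.vcf")
    write_vcf_depths(sim$variants, p)
    outputs <- c(outputs, p)
    emit(sim$truth$expected, "simulated_truth.tsv")
  } else if (stage == "bsa") {
    variants <- read_vcf_depths(need("vcf"), c(config$pools$s1 %||% "S1",
                                               config$pools$s2 %||% "S2"))
    scan <- bsa_scan(
      variants, s1 = config$pools$s1 %||% "S1", s2 = config$pools$s2 %||% "S2",
      min_depth = as.integer(thr$min_depth %||% 10),
      window_bp = thr$window_bp %||% 1e6, step_bp = thr$step_bp %||% 1e3,
      min_markers = as.integer(thr$min_markers %||% 3),
      n_sims = as.integer(thr$n_sims %||% 10000), seed = seed
    )
    emit(scan$markers, "markers.tsv")
    emit(dplyr::filter(scan$windows, !is.na(.data$mean_delta)), "windows.tsv")
    if (nrow(scan$regions) > 0) {
      p <- file.path(out_dir, "candidate_regions.bed")
      write_bed(dplyr::mutate(scan$regions, name = "region",
                              score = .data$peak_delta, strand = "."), p)
      outputs <- c(outputs, p)
    }
    emit(scan$fixed_markers, "fixed_markers.tsv")
  } else if (stage == "effects") {
    variants <- read_vcf_depths(need("vcf"), c(config$pools$s1 %||% "S1",
                                               config$pools$s2 %||% "S2"))
    models <- read_gff3_models(need("gff"))
    genome <- read_fasta(need("fasta"))
    eff <- annotate_effects(variants, models, genome,
                            flank_bp = as.integer(thr$flank_bp %||% 2000))
    regions <- if (!is.null(paths$regions)) read_bed(need("regions")) else NULL
    emit(eff, "variant_effects.tsv")
    emit(tibble::tibble(gene_id = filter_candidate_genes(eff, regions = regions)),
         "candidate_genes.tsv")
    message("effect category counts: ",
            paste(names(table(eff$category)), table(eff$category),
                  sep = "=", collapse = ", "))
  } else if (stage == "kaks") {
    seqs <- read_fasta(need("cds_fasta"))
    prs <- readr::read_tsv(need("pairs"), col_types = readr::cols(),
                           progress = FALSE)
    emit(ng86_kaks_pairs(prs, seqs), "kaks.tsv")
  } else if (stage == "kaks-compare") {
    groups <- readr::read_tsv(need("groups"), col_types = readr::cols(),
                              progress = FALSE)  # columns: ka_ks, group
    ct <- compare_kaks_groups(groups$ka_ks[groups$group == "balanced"],
                              groups$ka_ks[groups$group == "unbalanced"])
    emit(dplyr::bind_cols(glance(ct),
                          tidyr::pivot_wider(tidy(ct), names_from = "group",
                                             values_from = c("n", "median_ka_ks"))),
         "kaks_contrast.tsv")
  } else if (stage == "te-context") {
    models <- read_gff3_models(need("gff"))
    tes <- read_bed(need("te_bed"))
    ctx <- find_te_context(models, tes,
                           flank_bp = as.integer(thr$flank_bp %||% 2000))
    emit(dplyr::mutate(ctx, te_ids = purrr::map_chr(.data$te_ids, paste,
                                                    collapse = ",")),
         "te_context.tsv")
    if (!is.null(paths$blocks_bed)) {
      emit(partition_by_synteny(tes, read_bed(need("blocks_bed"))),
           "synteny_partition.tsv")
    }
  } else if (stage == "homolog-compare") {
    prs <- readr::read_tsv(need("pairs"), col_types = readr::cols(),
                           progress = FALSE)
    cmp <- compare_homolog_expression(
      prs, read_expression_tsv(need("expr_a")),
      read_expression_tsv(need("expr_b")),
      fc_threshold = thr$fc_threshold %||% 2,
      p_threshold = thr$p_threshold %||% 0.05
    )
    emit(cmp, "homolog_comparison.tsv")
  } else if (stage == "triads") {
    expr <- read_expression_tsv(need("expr"))
    triads <- read_triads_tsv(need("triads"))
    cls <- triads |>
      triad_expression(expr) |>
      filter_expressed_triads(min_sum = thr$triad_min_sum %||% 0.5) |>
      classify_triads()
    emit(dplyr::select(cls, -dplyr::any_of("tie")), "triad_classification.tsv")
    emit(summarize_categories(cls)$by_category, "triad_summary.tsv")
  } else if (stage == "splice") {
    models <- read_gff3_models(need("gff"))
    abundance <- read_expression_tsv(need("abundance"))
    sample_info <- readr::read_tsv(need("samples"), col_types = readr::cols(),
                                   progress = FALSE)
    events <- detect_as_events(models)
    psi <- compute_psi(events, abundance)
    das <- call_das(psi, sample_info,
                    delta_threshold = thr$psi_delta %||% 0.10,
                    fdr_threshold = thr$fdr %||% 0.01, seed = seed)
    emit(dplyr::select(events, -"inclusion", -"exclusion"), "as_events.tsv")
    emit(psi, "psi.tsv")
    emit(das$events, "das_events.tsv")
    emit(tibble::tibble(gene_id = das$das_genes), "das_genes.tsv")
  } else if (stage == "sets") {
    de <- readr::read_lines(need("de_list"))
    das <- readr::read_lines(need("das_list"))
    part <- partition_gene_sets(de, das)
    emit(dplyr::select(part, "set", "n"), "gene_set_partition.tsv")
  }

  manifest <- list(
    stage = stage, seed = seed,
    parameters = thr,
    inputs = paths[setdiff(names(paths), "out_dir")],
    outputs = lapply(stats::setNames(outputs, basename(unlist(outputs))),
                     function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(outputs = unlist(outputs), manifest_path = manifest_path))
}
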