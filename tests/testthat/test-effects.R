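# toy locus: + strand gene with two CDS exons on a random background
toy_locus <- function(rng_seed = 1) {
  genome <- random_genome(1000, rng_seed = rng_seed)
  # CDS: [100,130) + [150,180): 20 codons
  genome <- plant_seq(genome, 100, strrep("GAAGCT", 5))   # Glu-Ala repeats
  genome <- plant_seq(genome, 150, strrep("TTGGCA", 5))
  models <- toy_gene("g1", rbind(c(80, 130), c(150, 200)),
                     cds = rbind(c(100, 130), c(150, 180)))
  list(genome = genome, models = models)
}

test_that("coding SNPs are translated to the synonymous/missense/stop classes", {
  tl <- toy_locus()
  # GAA -> GAG (both Glu): third base of codon 1 at 1-based pos 103
  v <- tibble::tibble(chrom = "chr01", pos = 103L, ref = "A", alt = "G",
                      type = "SNP")
  eff <- annotate_effects(v, tl$models, tl$genome)
  expect_equal(eff$category, "synonymous")
  expect_match(eff$detail, "GAA>GAG")
  # GAA -> TAA introduces a stop
  v2 <- tibble::tibble(chrom = "chr01", pos = 101L, ref = "G", alt = "T",
                       type = "SNP")
  expect_equal(annotate_effects(v2, tl$models, tl$genome)$category, "stop_gain")
  # GCT -> CCT (Ala -> Pro)
  v3 <- tibble::tibble(chrom = "chr01", pos = 104L, ref = "G", alt = "C",
                       type = "SNP")
  expect_equal(annotate_effects(v3, tl$models, tl$genome)$category, "missense")
})

test_that("indel effects follow the mod-3 rule, including span deletions", {
  tl <- toy_locus()
  g <- tl$genome[[1]]
  # 7-bp deletion fully inside the first CDS exon
  del7 <- tibble::tibble(chrom = "chr01", pos = 105L,
                         ref = substr(g, 105, 112), alt = substr(g, 105, 105),
                         type = "DEL")
  e1 <- annotate_effects(del7, tl$models, tl$genome)
  expect_equal(e1$category, "frameshift_deletion")
  expect_match(e1$detail, "deleted CDS length 7")
  # 6-bp deletion: in-frame
  del6 <- tibble::tibble(chrom = "chr01", pos = 105L,
                         ref = substr(g, 105, 111), alt = substr(g, 105, 105),
                         type = "DEL")
  expect_equal(annotate_effects(del6, tl$models, tl$genome)$category,
               "inframe_deletion")
  # deletion removing the last 10 coding bases of exon 1 plus 15 intron bases
  span <- tibble::tibble(chrom = "chr01", pos = 120L,
                         ref = substr(g, 120, 145), alt = substr(g, 120, 120),
                         type = "DEL")
  es <- annotate_effects(span, tl$models, tl$genome)
  expect_equal(es$category, "frameshift_deletion")
  expect_match(es$detail, "deleted CDS length 10, spans exon/intron boundary")
  # insertions: 2-bp frameshift vs 3-bp in-frame
  ins <- tibble::tibble(chrom = "chr01", pos = 110L,
                        ref = substr(g, 110, 110),
                        alt = paste0(substr(g, 110, 110), "AT"), type = "INS")
  expect_equal(annotate_effects(ins, tl$models, tl$genome)$category,
               "frameshift_insertion")
  ins3 <- dplyr::mutate(ins, alt = paste0(ref, "ATG"))
  expect_equal(annotate_effects(ins3, tl$models, tl$genome)$category,
               "inframe_insertion")
})

test_that("non-coding compartments follow the precedence ladder", {
  tl <- toy_locus()
  at <- function(pos, ref = "A", alt = "T") {
    tibble::tibble(chrom = "chr01", pos = as.integer(pos),
                   ref = substr(tl$genome[[1]], pos, pos),
                   alt = setdiff(c("A", "T"), substr(tl$genome[[1]], pos, pos))[1],
                   type = "SNP")
  }
  cat_at <- function(pos) annotate_effects(at(pos), tl$models, tl$genome)$category
  expect_equal(cat_at(90), "utr5")          # exonic, before CDS, + strand
  expect_equal(cat_at(190), "utr3")         # exonic, after CDS
  expect_equal(cat_at(131), "splice_site")  # first intron base
  expect_equal(cat_at(140), "intronic")     # mid-intron
  expect_equal(cat_at(50), "upstream")
  expect_equal(cat_at(300), "downstream")
  far <- tibble::tibble(chrom = "chr09", pos = 10L, ref = "A", alt = "T",
                        type = "SNP")
  expect_equal(annotate_effects(far, tl$models, tl$genome)$category, "intergenic")
  beyond <- tibble::tibble(chrom = "chr01", pos = 2000L, ref = "A", alt = "T",
                           type = "SNP")
  expect_error(annotate_effects(beyond, tl$models, tl$genome), "beyond")
})

test_that("reverse-strand effects equal forward effects on the mirrored locus", {
  tl <- toy_locus(rng_seed = 7)
  g <- tl$genome[[1]]
  L <- nchar(g)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  genome_rc <- stats::setNames(rc, "chr01")
  models_rc <- dplyr::mutate(tl$models,
    new_start = L - end, end = L - start, strand = "-")
  models_rc$start <- models_rc$new_start
  models_rc$new_start <- NULL
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (pos in c(103L, 101L, 104L, 115L, 160L)) {
    ref <- substr(g, pos, pos)
    alt <- setdiff(c("A", "G", "C"), ref)[1]
    fwd <- annotate_effects(
      tibble::tibble(chrom = "chr01", pos = pos, ref = ref, alt = alt,
                     type = "SNP"), tl$models, tl$genome)
    rev_pos <- L - pos + 1L
    rev <- annotate_effects(
      tibble::tibble(chrom = "chr01", pos = rev_pos,
                     ref = unname(comp[ref]), alt = unname(comp[alt]),
                     type = "SNP"), models_rc, genome_rc)
    expect_equal(rev$category, fwd$category)
  }
})

test_that("coding SNP classes match whole-CDS translation on random variants", {
  tl <- toy_locus(rng_seed = 11)
  g <- tl$genome[[1]]
  cds_iv <- rbind(c(100, 130), c(150, 180))
  extract_cds <- function(seq) {
    paste0(substr(seq, 101, 130), substr(seq, 151, 180))
  }
  translate <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  set.seed(171)
  cds_positions <- c(101:130, 151:180)
  for (k in 1:200) {
    pos <- sample(cds_positions, 1)
    ref <- substr(g, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- annotate_effects(
      tibble::tibble(chrom = "chr01", pos = pos, ref = ref, alt = alt,
                     type = "SNP"), tl$models, tl$genome)$category
    mut <- g
    substr(mut, pos, pos) <- alt
    p_ref <- translate(extract_cds(g))
    p_alt <- translate(extract_cds(mut))
    diff_i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
    want <- if (length(diff_i) == 0) {
      "synonymous"
    } else if (substr(p_alt, diff_i, diff_i) == "*") {
      "stop_gain"
    } else if (substr(p_ref, diff_i, diff_i) == "*") {
      "stop_loss"
    } else {
      "missense"
    }
    expect_equal(got, want)
  }
})

test_that("candidate-gene filtering selects by category and region", {
  eff <- tibble::tibble(
    chrom = "c", pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "T",
    type = "SNP",
    gene_id = c("gA", "gA", "gB", "gC"), transcript_id = "t",
    category = c("intronic", "missense", "synonymous", "frameshift_deletion"),
    detail = ""
  )
  expect_equal(filter_candidate_genes(eff), c("gA", "gC"))
  expect_equal(filter_candidate_genes(eff, categories = "synonymous"), "gB")
  regions <- tibble::tibble(chrom = "c", start = 0, end = 25)
  expect_equal(filter_candidate_genes(eff, regions = regions), "gA")
  expect_equal(length(filter_candidate_genes(eff[0, ])), 0)
  # gene-level severity summary keeps the most severe category
  s <- summarize_gene_effects(eff)
  expect_equal(s$category[s$gene_id == "gA"], "missense")
})
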