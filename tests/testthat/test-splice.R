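test_that("event detection recognises the four local event classes", {
  # IR: t2 splices an intron that t1 retains
  ir_gene <- dplyr::bind_rows(
    toy_gene("gIR", rbind(c(0, 300), c(400, 500))),
    toy_transcript("gIR", "gIR.t2", rbind(c(0, 100), c(200, 300), c(400, 500)))
  )
  ev <- detect_as_events(ir_gene)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "IR")
  expect_equal(c(ev$var_start, ev$var_end), c(100L, 200L))
  expect_equal(ev$inclusion[[1]], "gIR.t1")
  expect_equal(ev$exclusion[[1]], "gIR.t2")

  # ES: middle exon of t1 skipped by t2 (no spurious A5/A3 from its introns)
  es_gene <- dplyr::bind_rows(
    toy_gene("gES", rbind(c(0, 100), c(200, 300), c(400, 500))),
    toy_transcript("gES", "gES.t2", rbind(c(0, 100), c(400, 500)))
  )
  ev2 <- detect_as_events(es_gene)
  expect_equal(ev2$event_type, "ES")
  expect_equal(ev2$inclusion[[1]], "gES.t1")

  # A5 on + strand: alternative donor at the first intron
  a5_gene <- dplyr::bind_rows(
    toy_gene("gA5", rbind(c(0, 150), c(200, 300))),
    toy_transcript("gA5", "gA5.t2", rbind(c(0, 100), c(200, 300)))
  )
  ev3 <- detect_as_events(a5_gene)
  expect_equal(ev3$event_type, "A5")
  expect_equal(ev3$inclusion[[1]], "gA5.t1")
  expect_equal(c(ev3$var_start, ev3$var_end), c(100L, 150L))
  # the same structure on the minus strand is an A3 event
  a3_gene <- dplyr::mutate(a5_gene, strand = "-")
  expect_equal(detect_as_events(a3_gene)$event_type, "A3")

  # single-transcript gene: no events
  expect_equal(nrow(detect_as_events(toy_gene("g1", rbind(c(0, 100))))), 0)
})

test_that("three-transcript genes match exhaustive pairwise enumeration", {
  g <- dplyr::bind_rows(
    toy_gene("gM", rbind(c(0, 100), c(200, 300), c(400, 500))),
    toy_transcript("gM", "gM.t2", rbind(c(0, 100), c(400, 500))),      # skips e2
    toy_transcript("gM", "gM.t3", rbind(c(0, 300), c(400, 500)))       # retains i1
  )
  ev <- detect_as_events(g)
  # expected events from pairwise comparison: ES (e2: t1 vs t2), IR (i1: t3
  # vs t1), and an A5 between t3's intron (300,400) and t2's intron
  # (100,400), which share the acceptor while t3's extra exonic sequence
  # extends the donor side
  expect_setequal(unique(ev$event_type), c("ES", "IR", "A5"))
  a5 <- ev[ev$event_type == "A5", ]
  expect_equal(c(a5$var_start, a5$var_end), c(100L, 300L))
  expect_equal(a5$inclusion[[1]], "gM.t3")
  ir <- ev[ev$event_type == "IR", ]
  expect_equal(nrow(ir), 1)  # deduplicated by coordinates
  expect_true("gM.t3" %in% ir$inclusion[[1]])
  es <- ev[ev$event_type == "ES", ]
  expect_equal(es$var_start, 200L)
  expect_true("gM.t2" %in% es$exclusion[[1]])
})

test_that("PSI is the inclusion share and undefined at zero abundance", {
  ev <- tibble::tibble(event_id = "e1", gene_id = "g", event_type = "IR",
                       chrom = "c", var_start = 0L, var_end = 1L,
                       inclusion = list("t1"), exclusion = list("t2"))
  ab <- tibble::tibble(feature_id = c("t1", "t2"),
                       s1 = c(8, 2), s2 = c(0, 4), s3 = c(0, 0))
  psi <- compute_psi(ev, ab)
  expect_equal(psi$psi[psi$sample == "s1"], 0.8)
  expect_equal(psi$psi[psi$sample == "s2"], 0)
  expect_true(is.na(psi$psi[psi$sample == "s3"]))
})

test_that("DAS calling recovers simulated shifts and applies the delta threshold", {
  sp <- simulate_splicing_dataset(n_genes = 120, delta_psi = 0.5,
                                  noise_sd = 0.02, seed = 121)
  ev <- detect_as_events(sp$models)
  psi <- compute_psi(ev, sp$abundance)
  das <- call_das(psi, sp$samples, seed = 122)
  truth <- sp$truth
  called <- truth$gene_id %in% das$das_genes
  expect_gte(mean(called[truth$affected]), 0.95)
  expect_lte(mean(called[!truth$affected]), 0.02)
  # |delta| below 0.10 is never DAS no matter the p-value
  small <- das$events[abs(das$events$delta_psi) < 0.10, ]
  expect_false(any(small$das))
  expect_s3_class(tidy(das), "tbl_df")
  expect_equal(glance(das)$n_das_genes, length(das$das_genes))
})

test_that("condition-label swap negates delta PSI but not DAS calls", {
  sp <- simulate_splicing_dataset(n_genes = 60, noise_sd = 0.02, seed = 131)
  ev <- detect_as_events(sp$models)
  psi <- compute_psi(ev, sp$abundance)
  das <- call_das(psi, sp$samples, seed = 7)
  swapped_info <- dplyr::mutate(sp$samples,
                                condition = ifelse(condition == "c1", "c2", "c1"))
  das_sw <- call_das(psi, swapped_info, seed = 7)
  expect_equal(das_sw$events$delta_psi, -das$events$delta_psi)
  expect_equal(das_sw$events$das, das$events$das)
})

test_that("replicate-free designs require threshold-only mode", {
  sp <- simulate_splicing_dataset(n_genes = 10, n_replicates = 1, seed = 141)
  ev <- detect_as_events(sp$models)
  psi <- compute_psi(ev, sp$abundance)
  expect_error(call_das(psi, sp$samples), "threshold_only")
  das <- call_das(psi, sp$samples, mode = "threshold_only")
  expect_true(all(is.na(das$events$p_value)))
  expect_equal(das$events$das, abs(das$events$delta_psi) >= 0.10)
})

test_that("DTU flags flipped isoform usage and respects its truth set", {
  ab <- tibble::tibble(
    feature_id = c("tA", "tB", "tC", "tD"),
    c1_r1 = c(90, 10, 50, 50), c1_r2 = c(88, 12, 51, 49), c1_r3 = c(91, 9, 49, 51),
    c2_r1 = c(10, 90, 50, 50), c2_r2 = c(12, 88, 52, 48), c2_r3 = c(9, 91, 50, 50)
  )
  t2g <- tibble::tibble(transcript_id = c("tA", "tB", "tC", "tD"),
                        gene_id = c("g1", "g1", "g2", "g2"))
  si <- tibble::tibble(sample = names(ab)[-1],
                       condition = rep(c("c1", "c2"), each = 3))
  dtu <- call_dtu(ab, t2g, si, seed = 3)
  expect_true(all(dtu$dtu[dtu$gene_id == "g1"]))     # 0.9/0.1 flip: both DTU
  expect_false(any(dtu$dtu[dtu$gene_id == "g2"]))    # constant proportions
  expect_equal(dtu$delta_prop[dtu$transcript_id == "tA"], -0.793, tolerance = 0.01)

  # simulated truth recovery (isoform proportions shift by delta_psi)
  sp <- simulate_splicing_dataset(n_genes = 100, delta_psi = 0.4,
                                  noise_sd = 0.02, seed = 151)
  t2g_sim <- tibble::tibble(transcript_id = sp$abundance$feature_id,
                            gene_id = sub("\\.t[12]$", "", sp$abundance$feature_id))
  dtu_sim <- call_dtu(sp$abundance, t2g_sim, sp$samples, seed = 152)
  truth_tx <- t2g_sim$gene_id %in% sp$truth$gene_id[sp$truth$affected]
  tp <- sum(dtu_sim$dtu & truth_tx)
  prec <- tp / sum(dtu_sim$dtu)
  rec <- tp / sum(truth_tx)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.9)
})

test_that("NMD prediction implements the 50-nt junction rule", {
  # stop in the last exon: not PTC
  ok <- toy_gene("gOK", rbind(c(0, 200), c(300, 500)),
                 cds = rbind(c(10, 200), c(300, 400)))
  res <- predict_nmd(ok)
  expect_false(res$is_ptc)
  # stop 100 nt upstream of the last junction: PTC
  ptc <- toy_gene("gP", rbind(c(0, 200), c(300, 500)),
                  cds = rbind(c(10, 100)))
  res2 <- predict_nmd(ptc)
  expect_equal(res2$junction_distance, 100L)
  expect_true(res2$is_ptc)
  # exactly at the rule boundary: distance must exceed the rule
  edge <- toy_gene("gE", rbind(c(0, 200), c(300, 500)),
                   cds = rbind(c(10, 150)))
  expect_equal(predict_nmd(edge)$junction_distance, 50L)
  expect_false(predict_nmd(edge)$is_ptc)
  expect_true(predict_nmd(edge, nmd_rule_nt = 49L)$is_ptc)
  # single-exon transcript: no junction, never PTC
  mono <- toy_gene("gM", rbind(c(0, 500)), cds = rbind(c(10, 100)))
  expect_false(predict_nmd(mono)$is_ptc)
  # minus-strand: stop is at the CDS start in genomic coordinates
  minus <- toy_gene("gR", rbind(c(0, 200), c(300, 500)),
                    cds = rbind(c(400, 490)), strand = "-")
  res_m <- predict_nmd(minus)
  # transcript runs 500->0; stop base at genomic 400, junction after exon2
  expect_equal(res_m$last_junction_tx, 200L)
  expect_equal(res_m$stop_tx_pos, 100L)
  expect_true(res_m$is_ptc)
})

test_that("gene-set partition performs exact set algebra", {
  part <- partition_gene_sets(c("a", "b", "c"), c("c", "d"))
  expect_equal(part$n, c(2L, 1L, 1L))
  expect_equal(part$gene_ids[[3]], "c")
  # disjoint and nested cases
  expect_equal(partition_gene_sets("a", "b")$n[3], 0L)
  nested <- partition_gene_sets(c("a", "b"), "a")
  expect_equal(nested$n[nested$set == "DAS_only"], 0L)
})
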