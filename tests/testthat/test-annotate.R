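M5 <- herbshotgun:::MOTIF_5_8S_END
M3 <- herbshotgun:::MOTIF_28S_START

test_that("ITS2 extraction returns the interior with exact coordinates", {
  set.seed(70)
  interior <- random_dna(1, 230, gc = 0.55)
  contig <- as_contig(paste0(M5, interior, M3))
  b <- extract_its2(contig)
  expect_equal(b$sequence, interior)
  expect_equal(b$start, 20L)
  expect_equal(b$end, 250L)
  expect_equal(b$flags, "")
  ## coordinate consistency: the recorded slice reproduces the sequence
  expect_equal(substr(contig$sequence, b$start + 1L, b$end), b$sequence)
})

test_that("a retained 28S tail behind a weak motif is cut and flagged", {
  set.seed(71)
  interior <- random_dna(1, 230, gc = 0.55)
  weak_m3 <- mutate_n(M3, 3, seed = 72)          # below threshold, above half
  tail28s <- substr(herbshotgun:::CONSERVED_28S_TAIL, 1, 60)
  contig <- as_contig(paste0(M5, interior, weak_m3, tail28s))
  b <- extract_its2(contig)
  expect_false(is.null(b))
  expect_match(b$flags, "conserved_tail_trimmed")
  expect_equal(b$sequence, interior)
  expect_false(grepl(tail28s, b$sequence, fixed = TRUE))
})

test_that("contigs lacking motifs return nothing; lone 5' motif is partial", {
  expect_null(extract_its2(as_contig(random_dna(1, 300))))
  set.seed(73)
  interior <- random_dna(1, 150, gc = 0.55)
  b <- extract_its2(as_contig(paste0(M5, interior)), tail_threshold_frac = 0)
  expect_match(b$flags, "partial")
  expect_equal(b$sequence, interior)
})

test_that("ITS2 extraction is strand-invariant", {
  set.seed(74)
  interior <- random_dna(1, 230, gc = 0.55)
  contig <- as_contig(paste0(M5, interior, M3))
  rc_contig <- as_contig(revcomp(contig$sequence))
  b1 <- extract_its2(contig)
  b2 <- extract_its2(rc_contig)
  expect_equal(b2$sequence, b1$sequence)
  expect_equal(b2$strand, "-")
  ## the recorded slice on the reverse-strand contig reproduces the sequence
  slice <- substr(rc_contig$sequence, b2$start + 1L, b2$end)
  expect_equal(revcomp(slice), b2$sequence)
})

test_that("plastid primer trimming handles exact, mismatched and absent primers", {
  ps <- default_markers()[["rbcL"]]$primer_set
  fwd <- herbshotgun:::concretize_iupac(ps$forward)
  rev_site <- revcomp(herbshotgun:::concretize_iupac(ps$reverse))
  set.seed(75)
  interior <- random_dna(1, 500, gc = 0.44)

  b <- trim_plastid_primers(as_contig(paste0(fwd, interior, rev_site),
                                      marker = "rbcL"), ps)
  expect_equal(b$sequence, interior)
  expect_equal(b$flags, "")

  fwd_mm <- mutate_n(fwd, 1, seed = 76)
  b2 <- trim_plastid_primers(as_contig(paste0(fwd_mm, interior, rev_site),
                                       marker = "rbcL"), ps)
  expect_equal(b2$sequence, interior)

  expect_null(trim_plastid_primers(as_contig(random_dna(1, 400),
                                             marker = "rbcL"), ps))

  b3 <- trim_plastid_primers(as_contig(paste0(fwd, interior),
                                       marker = "rbcL"), ps)
  expect_match(b3$flags, "partial")
  expect_match(b3$flags, "untrimmed_primer")

  ## strand invariance
  b4 <- trim_plastid_primers(as_contig(revcomp(paste0(fwd, interior, rev_site)),
                                       marker = "rbcL"), ps)
  expect_equal(b4$sequence, interior)
  expect_equal(b4$strand, "-")
})

test_that("annotate_contigs drops partial barcodes by default", {
  set.seed(77)
  interior <- random_dna(1, 230, gc = 0.55)
  full <- as_contig(paste0(M5, interior, M3), id = "full")
  part <- as_contig(paste0(M5, interior), id = "part")
  out_strict <- annotate_contigs(rbind(full, part), tail_threshold_frac = 0)
  expect_equal(out_strict$contig_id, "full")
  out_all <- annotate_contigs(rbind(full, part), keep_partial = TRUE,
                              tail_threshold_frac = 0)
  expect_setequal(out_all$contig_id, c("full", "part"))
})

test_that("constructed two-parent chimeras are found with accurate breakpoints", {
  set.seed(78)
  A <- random_dna(1, 600, gc = 0.45)
  B <- mutate_n(A, 30, seed = 79)               # 95% identity
  cand <- paste0(substr(A, 1, 300), substr(B, 301, 600))
  pool <- rbind(as_barcode(A, "A", n_reads = 50L),
                as_barcode(B, "B", n_reads = 40L))
  v <- detect_chimera(as_barcode(cand, "q", n_reads = 5L), pool)
  expect_true(v$is_chimera)
  expect_setequal(v$parents, c("A", "B"))
  expect_lte(abs(v$breakpoint - 300), 10)

  ## identical to a single parent -> not chimeric
  v2 <- detect_chimera(as_barcode(A, "q2", n_reads = 5L), pool)
  expect_false(v2$is_chimera)

  ## empty pool -> non-chimeric with score 0
  v3 <- detect_chimera(as_barcode(cand, "q3"), pool[0, ])
  expect_false(v3$is_chimera)
  expect_equal(v3$score, 0)
})

test_that("min_gain above the parents' divergence suppresses the verdict", {
  set.seed(80)
  A <- random_dna(1, 600, gc = 0.45)
  B <- mutate_n(A, 30, seed = 81)
  cand <- paste0(substr(A, 1, 300), substr(B, 301, 600))
  pool <- rbind(as_barcode(A, "A", n_reads = 50L),
                as_barcode(B, "B", n_reads = 40L))
  q <- as_barcode(cand, "q", n_reads = 5L)
  gain <- detect_chimera(q, pool)$score
  expect_true(detect_chimera(q, pool, min_gain = gain)$is_chimera)
  expect_false(detect_chimera(q, pool, min_gain = gain + 1)$is_chimera)
})

test_that("abundance rule: parents cannot be rarer than the candidate", {
  set.seed(82)
  A <- random_dna(1, 600)
  B <- mutate_n(A, 30, seed = 83)
  cand <- paste0(substr(A, 1, 300), substr(B, 301, 600))
  pool <- rbind(as_barcode(A, "A", n_reads = 3L),
                as_barcode(B, "B", n_reads = 3L))
  expect_false(detect_chimera(as_barcode(cand, "q", n_reads = 10L),
                              pool)$is_chimera)
  expect_true(detect_chimera(as_barcode(cand, "q", n_reads = 2L),
                             pool)$is_chimera)
})
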