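test_that("clustering separates a 4-difference pair at 1.00 but not 0.99", {
  set.seed(90)
  a <- random_dna(1, 703, gc = 0.44)
  b <- mutate_n(a, 4, seed = 91)
  bc <- rbind(as_barcode(a, "a", marker = "rbcL", n_reads = 20L),
              as_barcode(b, "b", marker = "rbcL", n_reads = 10L))
  expect_equal(nrow(cluster_otus(bc, identity = 0.99)), 1L)
  expect_equal(nrow(cluster_otus(bc, identity = 1.00)), 2L)

  ident <- rbind(as_barcode(a, "a", marker = "rbcL"),
                 as_barcode(a, "a2", marker = "rbcL"))
  expect_equal(nrow(cluster_otus(ident, identity = 1.00)), 1L)
  expect_equal(nrow(cluster_otus(ident, identity = 0.97)), 1L)
})

test_that("clustering at identity 1.0 equals exact string grouping", {
  set.seed(92)
  base <- replicate(8, random_dna(1, 120))
  seqs <- sample(base, 50, replace = TRUE)
  seqs[1:5] <- vapply(seqs[1:5], mutate_n, "", n_diff = 1)  # near-duplicates
  bc <- do.call(rbind, lapply(seq_along(seqs), function(i)
    as_barcode(seqs[i], sprintf("s%02d", i), marker = "ITS2",
               n_reads = sample(50, 1))))
  otus <- cluster_otus(bc, identity = 1.0)
  oracle <- split(bc$contig_id, bc$sequence)
  expect_equal(nrow(otus), length(oracle))
  got <- lapply(otus$members, sort)
  expect_setequal(lapply(unname(oracle), sort), got)
  ## representative is a member sequence
  for (i in seq_len(nrow(otus)))
    expect_true(otus$representative[i] %in%
                  bc$sequence[bc$contig_id %in% otus$members[[i]]])
})

test_that("greedy clustering is deterministic under input reordering", {
  set.seed(93)
  seqs <- replicate(12, random_dna(1, 150))
  bc <- do.call(rbind, lapply(seq_along(seqs), function(i)
    as_barcode(seqs[i], sprintf("s%02d", i), n_reads = i)))
  o1 <- cluster_otus(bc, 0.95)
  o2 <- cluster_otus(bc[sample(nrow(bc)), ], 0.95)
  expect_equal(o1$representative, o2$representative)
  expect_equal(o1$members, o2$members)
})

test_that("clustering rejects mixed markers and bad thresholds", {
  bc <- rbind(as_barcode(random_dna(1, 120), "x", marker = "ITS2"),
              as_barcode(random_dna(1, 120), "y", marker = "matK"))
  expect_error(cluster_otus(bc), "single marker")
  expect_error(cluster_otus(bc[1, ], identity = 0.5), "identity")
})

make_otus <- function(seqs, ids = sprintf("OTU%02d", seq_along(seqs)),
                      marker = "ITS2") {
  out <- data.frame(otu_id = ids, marker = marker, representative = seqs,
                    support = 10L, n_members = 1L, stringsAsFactors = FALSE)
  out$members <- as.list(ids)
  structure(out, class = c("otu_set", "data.frame"))
}

test_that("tiling reads map back with full coverage; no reads give zeros", {
  set.seed(94)
  rep_seq <- random_dna(1, 300)
  otus <- make_otus(rep_seq)
  pairs <- tiling_pairs(rep_seq, read_len = 100L, frag_len = 120L, by = 4L)
  prof <- map_read_pairs(pairs, otus, rng_seed = 1)
  expect_equal(prof$coverage, 1.0)
  expect_gt(prof$mean_depth, 1)
  expect_equal(prof$n_pairs_mapped, nrow(pairs))

  none <- data.frame(id = "z", seq1 = random_dna(1, 100),
                     seq2 = random_dna(1, 100), qual1 = strrep("I", 100),
                     qual2 = strrep("I", 100))
  p0 <- map_read_pairs(none, otus, rng_seed = 1)
  expect_equal(p0$coverage, 0)
  expect_true(all(p0$depth[[1]] == 0L))
})

test_that("multimap modes: 'all' counts shared reads in every tied target", {
  set.seed(95)
  shared <- random_dna(1, 120)
  r1 <- paste0(shared, random_dna(1, 180))
  r2 <- paste0(shared, random_dna(1, 180))
  otus <- make_otus(c(r1, r2))
  pairs <- data.frame(id = "s", seq1 = substr(shared, 1, 60),
                      seq2 = revcomp(substr(shared, 61, 120)),
                      qual1 = strrep("I", 60), qual2 = strrep("I", 60))
  pa <- map_read_pairs(pairs, otus, multimap_mode = "all", rng_seed = 1)
  expect_equal(pa$n_pairs_mapped, c(1L, 1L))
  expect_true(sum(pa$depth[[1]]) > 0 && sum(pa$depth[[2]]) > 0)

  pr <- map_read_pairs(pairs, otus, multimap_mode = "random", rng_seed = 1)
  expect_equal(sum(pr$n_pairs_mapped), 1L)

  ## positionwise, depth mass under 'all' dominates 'random'
  big <- tiling_pairs(r1, read_len = 100L, frag_len = 120L, by = 6L)
  pall <- map_read_pairs(big, otus, multimap_mode = "all", rng_seed = 2)
  prand <- map_read_pairs(big, otus, multimap_mode = "random", rng_seed = 2)
  for (k in 1:2)
    expect_true(all(pall$depth[[k]] >= prand$depth[[k]]))
})

test_that("QC filter applies the inclusive depth/coverage boundaries", {
  otus <- make_otus(replicate(3, random_dna(1, 200)))
  profiles <- rbind(as_profile("OTU01", rep(3L, 200)),          # depth 3.0
                    as_profile("OTU02", c(rep(10L, 190), rep(0L, 10))),
                    as_profile("OTU03", rep(3L, 200)))
  profiles$mean_depth <- c(3.0, 10, 3.01)
  profiles$coverage <- c(1.0, 0.95, 0.951)
  res <- qc_filter(otus, profiles)
  expect_equal(res$removed$otu_id, c("OTU01", "OTU02"))
  expect_equal(res$removed$reason, c("depth", "coverage"))
  expect_equal(res$kept$otu_id, "OTU03")

  ## idempotent: re-filtering the kept set removes nothing
  res2 <- qc_filter(res$kept, profiles[3, ])
  expect_equal(nrow(res2$removed), 0L)
  expect_equal(res2$kept$otu_id, "OTU03")

  expect_error(qc_filter(otus, profiles[1:2, ]), "OTU03")
})

test_that("evenness diagnostic flags conserved-flank pileups", {
  t <- qc_thresholds()
  ## two reads at the front, a 2000x wall at the tail
  d <- c(rep(2L, 170), rep(2000L, 40))
  ev <- evenness_diagnostic(as_profile("x", d), t)
  expect_true(ev$flagged)
  expect_true(ev$tail_end_signature)

  ev2 <- evenness_diagnostic(as_profile("y", rep(50L, 210)), t)
  expect_false(ev2$flagged)

  ## ratio exactly at the threshold is flagged (>= semantics)
  d3 <- c(rep(2L, 150), rep(100L, 30))     # median 2, max 100 -> ratio 50
  ev3 <- evenness_diagnostic(as_profile("z", d3), t)
  expect_equal(ev3$ratio, 50)
  expect_true(ev3$flagged)

  expect_error(evenness_diagnostic(as_profile("w", rep(1L, 40)), t),
               "two evenness windows")
})

test_that("a representative retaining the conserved 28S tail is flagged while its trimmed twin is not", {
  set.seed(96)
  tail28s <- herbshotgun:::CONSERVED_28S_TAIL            # shared across taxa
  interior <- random_dna(1, 240, gc = 0.55)
  rep_tail <- paste0(interior, tail28s)                  # wrongly untrimmed
  rep_trim <- interior
  otus <- make_otus(c(rep_tail, rep_trim), ids = c("tail", "trim"))

  ## reads from many other taxa's ITS2 tails multi-map onto the retained 28S
  other_tails <- vapply(1:40, function(i)
    paste0(random_dna(1, 100, gc = 0.55), tail28s), "")
  tail_pairs <- data.frame(
    id = sprintf("tp%03d", seq_along(other_tails)),
    seq1 = substr(other_tails, 101, 160),
    seq2 = revcomp(substr(other_tails, 101, 160)),
    qual1 = strrep("I", 60), qual2 = strrep("I", 60))
  own_pairs <- tiling_pairs(rep_trim, read_len = 60L, frag_len = 80L,
                            by = 60L, prefix = "own")
  prof <- map_read_pairs(rbind(tail_pairs, own_pairs), otus,
                         multimap_mode = "random", rng_seed = 3,
                         seed_k = 21L)
  t <- qc_thresholds()
  ev_tail <- evenness_diagnostic(prof[prof$otu_id == "tail", ], t)
  ev_trim <- evenness_diagnostic(prof[prof$otu_id == "trim", ], t)
  expect_true(ev_tail$flagged)
  expect_true(ev_tail$tail_end_signature)
  expect_false(ev_trim$flagged)
})
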