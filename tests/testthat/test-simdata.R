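trio_spec <- function(target, marker = "matK") {
  taxa <- data.frame(
    species = c("Sp one", "Sp two", "Sp three"),
    genus = c("Ga", "Ga", "Gb"), family = "Fam",
    kingdom = "Viridiplantae", stringsAsFactors = FALSE)
  M <- matrix(target, 3, 3, dimnames = list(taxa$species, taxa$species))
  diag(M) <- 1
  divergence_spec(taxa, identity = setNames(list(M), marker))
}

interior_of <- function(panel, marker, species) {
  co <- panel$report$interior[[marker]]
  rec <- panel$db$records
  key <- rec$marker == marker & rec$species == species
  substr(rec$sequence[key], co$start[co$species == species] + 1L,
         co$end[co$species == species])
}

test_that("panel realizes target pairwise identities within 0.005", {
  panel <- generate_species_panel(trio_spec(0.99), seed = 21)
  ints <- vapply(c("Sp one", "Sp two", "Sp three"),
                 function(s) interior_of(panel, "matK", s), character(1))
  for (i in 1:2) for (j in (i + 1):3) {
    ident <- pairwise_identity_and_differences(ints[i], ints[j])$identity
    expect_gte(ident, 0.985)
    expect_lte(ident, 0.995)
  }
  ## and the generator's own report agrees
  R <- panel$report$realized_identity$matK
  expect_true(all(abs(R[upper.tri(R)] - 0.99) <= 0.005))
})

test_that("identity target 1.0 yields identical sequences", {
  panel <- generate_species_panel(trio_spec(1.0), seed = 3)
  ints <- vapply(c("Sp one", "Sp two", "Sp three"),
                 function(s) interior_of(panel, "matK", s), character(1))
  expect_equal(unname(ints[1]), unname(ints[2]))
  expect_equal(unname(ints[1]), unname(ints[3]))
})

test_that("infeasible identity matrices are rejected", {
  sp <- trio_spec(0.99)
  sp$identity$matK["Sp one", "Sp three"] <- 0.92   # violates additivity
  sp$identity$matK["Sp three", "Sp one"] <- 0.92
  expect_error(generate_species_panel(sp, seed = 1), "infeasible")
})

test_that("AT-rich loci meet composition and carry the tandem repeat", {
  panel <- generate_species_panel(wuhusan_panel_spec(), seed = 5)
  ar <- panel$report$at_rich
  expect_gte(ar$realized_at, 0.70)
  expect_gte(ar$longest_at_run, 20)
})

test_that("ITS2 records are embedded between the conserved flank motifs", {
  panel <- generate_species_panel(wuhusan_panel_spec(), seed = 5)
  its2 <- panel$db$records[panel$db$records$marker == "ITS2", ]
  expect_true(all(grepl(herbshotgun:::MOTIF_5_8S_END, its2$sequence,
                        fixed = TRUE)))
  expect_true(all(grepl(herbshotgun:::MOTIF_28S_START, its2$sequence,
                        fixed = TRUE)))
})

test_that("panel generation is seed-deterministic", {
  p1 <- generate_species_panel(wuhusan_panel_spec(), seed = 77)
  p2 <- generate_species_panel(wuhusan_panel_spec(), seed = 77)
  expect_identical(p1$db$records, p2$db$records)
  p3 <- generate_species_panel(wuhusan_panel_spec(), seed = 78)
  expect_false(identical(p1$db$records$sequence, p3$db$records$sequence))
})

test_that("formulation fractions must sum to one", {
  expect_error(formulation_spec(c("A b" = 0.5, "C d" = 0.4)), "sum to 1")
  expect_silent(formulation_spec(c("A b" = 0.5, "C d" = 0.5)))
  f <- wuhusan_formulation(contaminant_fraction = 0.05, spike = TRUE)
  expect_equal(sum(f$ingredients, f$contaminants, f$spike_fraction), 1,
               tolerance = 1e-9)
})

test_that("read simulation respects mixture, chimera and determinism contracts", {
  panel <- generate_species_panel(wuhusan_panel_spec(), seed = 11)

  ## single-taxon formulation -> every truth row names that taxon
  f1 <- formulation_spec(c("Angelica sinensis" = 1), chimera_rate = 0)
  sim1 <- simulate_shotgun_reads(panel$db, f1, read_sim_params(300), seed = 2)
  expect_true(all(sim1$truth$taxon == "Angelica sinensis"))
  expect_equal(sum(sim1$truth$is_chimera), 0L)
  expect_equal(nrow(sim1$truth), 300L)          # one row per emitted pair
  expect_equal(nrow(sim1$pairs), 300L)

  ## chimera_rate zero -> zero flags even with many taxa
  f2 <- wuhusan_formulation(chimera_rate = 0)
  sim2 <- simulate_shotgun_reads(panel$db, f2, read_sim_params(500), seed = 2)
  expect_equal(sum(sim2$truth$is_chimera), 0L)

  ## same seed -> byte-identical FASTQ and identical truth
  f3 <- wuhusan_formulation(spike = TRUE)
  a <- simulate_shotgun_reads(panel$db, f3, read_sim_params(400), seed = 9)
  b <- simulate_shotgun_reads(panel$db, f3, read_sim_params(400), seed = 9)
  expect_identical(a$truth, b$truth)
  fa <- tempfile(); fb <- tempfile()
  write_fastq_pair(a, fa); write_fastq_pair(b, fb)
  expect_identical(readBin(paste0(fa, "_1.fastq"), "raw", 2e6),
                   readBin(paste0(fb, "_1.fastq"), "raw", 2e6))
  expect_identical(readBin(paste0(fa, "_2.fastq"), "raw", 2e6),
                   readBin(paste0(fb, "_2.fastq"), "raw", 2e6))

  ## chimeric rows name two distinct parents
  f4 <- wuhusan_formulation(chimera_rate = 0.2)
  sim4 <- simulate_shotgun_reads(panel$db, f4, read_sim_params(500), seed = 4)
  ch <- sim4$truth[sim4$truth$is_chimera, ]
  expect_gt(nrow(ch), 0)
  par <- strsplit(ch$parents, ";")
  expect_true(all(lengths(par) == 2))
  expect_true(all(vapply(par, function(p) p[1] != p[2], TRUE)))
})

test_that("empirical taxon fractions converge to formulation fractions", {
  panel <- generate_species_panel(wuhusan_panel_spec(), seed = 11)
  f <- wuhusan_formulation(spike = TRUE)
  sim <- simulate_shotgun_reads(panel$db, f, read_sim_params(20000), seed = 31)
  fr <- c(f$ingredients, f$contaminants,
          setNames(f$spike_fraction, f$spike_species))
  obs <- table(factor(sim$truth$taxon, levels = names(fr))) / 20000
  for (t in names(fr)) {
    bound <- 3 * sqrt(fr[[t]] * (1 - fr[[t]]) / 20000)
    expect_lte(abs(obs[[t]] - fr[[t]]), max(bound, 1e-3))
  }
})

test_that("read length above the minimum fragment length is rejected", {
  panel <- generate_species_panel(trio_spec(0.99), seed = 21)
  f <- formulation_spec(c("Sp one" = 1), fragment_min = 120)
  expect_error(
    simulate_shotgun_reads(panel$db, f, read_sim_params(10, read_length = 150),
                           seed = 1),
    "read length exceeds")
})

test_that("paired FASTQ round-trips through the reader", {
  panel <- generate_species_panel(trio_spec(0.99), seed = 21)
  f <- formulation_spec(c("Sp one" = 1))
  sim <- simulate_shotgun_reads(panel$db, f, read_sim_params(50), seed = 6)
  pre <- tempfile()
  write_fastq_pair(sim, pre)
  back <- read_fastq_pairs(paste0(pre, "_1.fastq"), paste0(pre, "_2.fastq"))
  expect_equal(back, sim$pairs)

  broken <- tempfile(fileext = ".fastq")
  writeLines(c("@r1/1", "ACGT", "+", "FFFF", "@r2/1", "ACGT"), broken)
  expect_error(read_fastq_pairs(broken, broken), "malformed FASTQ")
})
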