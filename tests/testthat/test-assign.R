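test_that("pairwise identity and base differences follow the declared convention", {
  set.seed(110)
  a <- random_dna(1, 700)
  r <- pairwise_identity_and_differences(a, a)
  expect_equal(r$identity, 1.0)
  expect_equal(r$differences, 0L)
  expect_equal(r$aligned_length, 700L)

  b100 <- random_dna(1, 100)
  r2 <- pairwise_identity_and_differences(b100, mutate_n(b100, 2, seed = 111))
  expect_equal(r2$identity, 0.98)
  expect_equal(r2$differences, 2L)
  expect_equal(r2$aligned_length, 100L)
  expect_equal(r2$substitutions, 2L)
  expect_equal(r2$gap_columns, 0L)

  expect_error(pairwise_identity_and_differences("", a), "empty|50")
  expect_error(pairwise_identity_and_differences("ACGTACGT", a), "50")
})

test_that("pairwise identity is symmetric and reverse-complement invariant", {
  set.seed(112)
  for (i in 1:4) {
    a <- random_dna(1, 300)
    b <- mutate_n(a, sample(3:15, 1))
    ab <- pairwise_identity_and_differences(a, b)
    ba <- pairwise_identity_and_differences(b, a)
    rc <- pairwise_identity_and_differences(revcomp(a), revcomp(b))
    expect_equal(ab$identity, ba$identity)
    expect_equal(ab$differences, rc$differences)
  }
})

test_that("overlap identity covers only the mutually covered region", {
  set.seed(113)
  core <- random_dna(1, 400)
  ## query extends beyond the reference on both sides: end gaps are free
  query <- paste0(random_dna(1, 30), core, random_dna(1, 30))
  r <- pairwise_identity_and_differences(query, core)
  expect_equal(r$identity, 1.0)
  expect_equal(r$aligned_length, 400L)
})

assign_db <- function() {
  set.seed(114)
  anc <- random_dna(1, 500)
  reference_db(data.frame(
    id = c("r1", "r2", "r3", "r4"),
    marker = "matK",
    species = c("Angelica alpha", "Angelica beta", "Saposhnikovia gamma",
                "Carthamus delta"),
    genus = c("Angelica", "Angelica", "Saposhnikovia", "Carthamus"),
    family = c("Apiaceae", "Apiaceae", "Apiaceae", "Asteraceae"),
    kingdom = "Viridiplantae",
    sequence = c(anc, mutate_n(anc, 10, seed = 115),
                 mutate_n(anc, 12, seed = 116), random_dna(1, 500)),
    stringsAsFactors = FALSE))
}

test_that("taxon assignment resolves rank by agreement among tied references", {
  db <- assign_db()
  otu <- function(seq) data.frame(otu_id = "q", marker = "matK",
                                  representative = seq,
                                  stringsAsFactors = FALSE)

  exact <- assign_taxon(otu(db$records$sequence[1]), db)
  expect_equal(exact$rank, "species")
  expect_equal(exact$species, "Angelica alpha")
  expect_equal(exact$best_identity, 1.0)

  ## equidistant from the two congeneric references -> genus rank
  a <- db$records$sequence[1]; b <- db$records$sequence[2]
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  half <- strsplit(a, "")[[1]]
  half[diffs[seq(1, length(diffs), by = 2)]] <-
    strsplit(b, "")[[1]][diffs[seq(1, length(diffs), by = 2)]]
  mid <- paste(half, collapse = "")
  tie <- assign_taxon(otu(mid), db, tie_margin = 0.002)
  expect_equal(tie$rank, "genus")
  expect_equal(tie$genus, "Angelica")

  ## identity below the floor -> unassigned
  far <- assign_taxon(otu(mutate_n(a, 100, seed = 117)), db,
                      min_identity = 0.90)
  expect_equal(far$rank, "unassigned")

  expect_error(assign_taxon(data.frame(otu_id = "q", marker = "rbcL",
                                       representative = a), db),
               "no reference")
})

test_that("tie_margin 0 on a unique-sequence DB gives species rank for exact queries", {
  db <- assign_db()
  for (i in seq_len(nrow(db$records))) {
    h <- assign_taxon(data.frame(otu_id = "q", marker = "matK",
                                 representative = db$records$sequence[i]),
                      db, tie_margin = 0)
    expect_equal(h$rank, "species")
    expect_equal(h$species, db$records$species[i])
  }
})

test_that("low query coverage blocks assignment of segmental matches", {
  db <- assign_db()
  a <- db$records$sequence[1]
  chimera_like <- paste0(substr(a, 1, 250), random_dna(1, 250))
  h <- assign_taxon(data.frame(otu_id = "q", marker = "matK",
                               representative = chimera_like), db)
  expect_equal(h$rank, "unassigned")
})

test_that("the Apiaceae pattern: ITS2 resolves species, collapsed matK only family", {
  panel <- generate_species_panel(wuhusan_panel_spec(), seed = 15)
  db <- subset_markers(panel$db)
  trio <- c("Angelica sinensis", "Saposhnikovia divaricata")
  get_seq <- function(m, sp) db$records$sequence[db$records$marker == m &
                                                   db$records$species == sp]
  ## ITS2: exact interiors -> species rank for all trio members
  for (sp in c(trio, "Angelica dahurica")) {
    h <- assign_taxon(data.frame(otu_id = "q", marker = "ITS2",
                                 representative = get_seq("ITS2", sp)), db)
    expect_equal(h$rank, "species")
    expect_equal(h$species, sp)
  }
  ## matK: a collapsed 50/50 mosaic of the trimmed interiors (what an OTU
  ## representative would be) ties across the two genera
  co <- panel$report$interior$matK
  interior_of <- function(sp) {
    s <- get_seq("matK", sp)
    substr(s, co$start[co$species == sp] + 1L, co$end[co$species == sp])
  }
  a <- interior_of(trio[1]); b <- interior_of(trio[2])
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diffs <- which(ca != cb)
  mosaic <- ca
  mosaic[diffs[seq(1, length(diffs), 2)]] <- cb[diffs[seq(1, length(diffs), 2)]]
  h <- assign_taxon(data.frame(otu_id = "q", marker = "matK",
                               representative = paste(mosaic, collapse = "")),
                    db, tie_margin = 0.005)
  expect_equal(h$rank, "family")
  expect_equal(h$family, "Apiaceae")
})

test_that("classification applies exactly one category with fixed precedence", {
  presc <- wuhusan_prescription()
  hit <- function(species, genus, family, kingdom = "Viridiplantae",
                  rank = "species", marker = "ITS2", n = 10) {
    data.frame(otu_id = paste0("o", species), marker = marker,
               best_identity = 1, rank = rank, species = species,
               genus = genus, family = family, kingdom = kingdom,
               tied_ids = "", n_reads = n, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    hit("Angelica sinensis", "Angelica", "Apiaceae"),
    hit("Ferula bungeana", "Ferula", "Apiaceae"),
    hit("Panax quinquefolius", "Panax", "Araliaceae"),
    hit("Rhizopus arrhizus", "Rhizopus", "Rhizopodaceae", "Fungi"),
    hit("Chenopodium album", "Chenopodium", "Amaranthaceae"))
  res <- consolidate_and_classify(hits, presc)
  cat_of <- setNames(res$calls$category, res$calls$taxon)
  expect_equal(cat_of[["Angelica sinensis"]], "authentic")
  expect_equal(cat_of[["Ferula bungeana"]], "adulterant")
  expect_equal(cat_of[["Panax quinquefolius"]], "positive-control")
  expect_equal(cat_of[["Rhizopus arrhizus"]], "contaminant-fungal")
  expect_equal(cat_of[["Chenopodium album"]], "contaminant-impurity")
  ## every call gets exactly one category; absences listed
  expect_true(all(res$calls$category %in%
                    c("authentic", "substitution", "adulterant",
                      "contaminant-fungal", "contaminant-impurity",
                      "positive-control")))
  expect_true("Angelica dahurica" %in% res$absent)

  ## a sanctioned substitution outranks the adulterant rule
  presc2 <- presc
  presc2$substitutions <- c("Ferula bungeana" = "Fangfeng")
  res2 <- consolidate_and_classify(hits, presc2)
  expect_equal(res2$calls$category[res2$calls$taxon == "Ferula bungeana"],
               "substitution")

  ## stable under hit reordering
  res3 <- consolidate_and_classify(hits[sample(nrow(hits)), ], presc)
  expect_equal(res3$calls[order(res3$calls$taxon),
                          c("taxon", "category", "n_reads")],
               res$calls[order(res$calls$taxon),
                         c("taxon", "category", "n_reads")],
               ignore_attr = TRUE)
})
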