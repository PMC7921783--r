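## ---------------------------------------------------------------------------
## End-to-end pipeline driver, study presets, report bundle
## ---------------------------------------------------------------------------

#' The five-ingredient Wuhu San prescription
#'
#' Danggui / Honghua / Fangfeng / Zhitiannanxing at 21.3% each and Baizhi at
#' 14.6% (recipe total 99.8%, normalized to fractions), with the known
#' Fangfeng adulterant (*Ferula bungeana*) and *Panax quinquefolius* as the
#' positive-control species.
#'
#' @return a [prescription()].
#' @export
wuhusan_prescription <- function() {
  ing <- data.frame(
    pinyin = c("Danggui", "Honghua", "Fangfeng", "Zhitiannanxing", "Baizhi"),
    proportion = c(21.3, 21.3, 21.3, 21.3, 14.6))
  ing$species <- list("Angelica sinensis", "Carthamus tinctorius",
                      "Saposhnikovia divaricata",
                      c("Arisaema amurense", "Arisaema erubescens",
                        "Arisaema heterophyllum"),
                      "Angelica dahurica")
  prescription(ing,
               adulterants = c("Ferula bungeana" = "Fangfeng"),
               positive_control = "Panax quinquefolius")
}

#' Divergence specification of the synthetic Wuhu San panel
#'
#' Six plant taxa and four fungal contaminants. The three Apiaceae
#' ingredients (the collapse-prone trio) carry matK/rbcL identities above
#' 98%, psbA-trnH at 96% and ITS2 at 95%; the Araceae taxon's psbA-trnH is
#' AT-rich (target 0.75) with an AT-dinucleotide tandem repeat, emulating
#' the locus that resists both amplification and assembly.
#'
#' @param trio_matk_rbcl,trio_psba,trio_its2 pairwise identity targets for
#'   the Apiaceae trio.
#' @return a [divergence_spec()].
#' @export
wuhusan_panel_spec <- function(trio_matk_rbcl = 0.985, trio_psba = 0.96,
                               trio_its2 = 0.95) {
  taxa <- data.frame(
    species = c("Angelica sinensis", "Angelica dahurica",
                "Saposhnikovia divaricata", "Carthamus tinctorius",
                "Arisaema amurense", "Panax quinquefolius",
                "Rhizopus arrhizus", "Fusarium oxysporum",
                "Aspergillus flavus", "Alternaria alternata"),
    genus = c("Angelica", "Angelica", "Saposhnikovia", "Carthamus",
              "Arisaema", "Panax", "Rhizopus", "Fusarium", "Aspergillus",
              "Alternaria"),
    family = c("Apiaceae", "Apiaceae", "Apiaceae", "Asteraceae", "Araceae",
               "Araliaceae", "Rhizopodaceae", "Nectriaceae",
               "Aspergillaceae", "Pleosporaceae"),
    kingdom = c(rep("Viridiplantae", 6), rep("Fungi", 4)),
    stringsAsFactors = FALSE)
  trio <- c("Angelica sinensis", "Angelica dahurica",
            "Saposhnikovia divaricata")
  trio_mat <- function(t) {
    M <- matrix(t, 3, 3, dimnames = list(trio, trio)); diag(M) <- 1; M
  }
  divergence_spec(
    taxa,
    identity = list("matK" = trio_mat(trio_matk_rbcl),
                    "rbcL" = trio_mat(trio_matk_rbcl),
                    "psbA-trnH" = trio_mat(trio_psba),
                    "ITS2" = trio_mat(trio_its2)),
    at_rich_loci = data.frame(species = "Arisaema amurense",
                              marker = "psbA-trnH", at_fraction = 0.75))
}

#' Formulation of a lab-made mock sample
#'
#' Maps the prescription proportions onto simulator fractions, adds the
#' fungal contaminant load (dominated by *Rhizopus*, as mould contamination
#' of stored herbal material typically is) and, optionally, a
#' positive-control spike at the mass of the smallest ingredient.
#'
#' @param prescription a [prescription()] (first official species per
#'   ingredient is simulated).
#' @param contaminant_fraction total fungal fraction of the library.
#' @param spike add the positive-control spike?
#' @param fungal_mix named fractions (summing to 1) of the fungal load.
#' @param ... passed to [formulation_spec()] (e.g. `degraded`,
#'   `chimera_rate`, `fragment_mean`).
#' @return a [formulation_spec()].
#' @export
wuhusan_formulation <- function(prescription = wuhusan_prescription(),
                                contaminant_fraction = 0.05, spike = FALSE,
                                fungal_mix = c("Rhizopus arrhizus" = 0.9433,
                                               "Fusarium oxysporum" = 0.0300,
                                               "Aspergillus flavus" = 0.0200,
                                               "Alternaria alternata" = 0.0067),
                                ...) {
  ing <- prescription$ingredients
  species <- vapply(ing$species, `[`, "", 1L)
  mass <- ing$proportion
  spike_mass <- if (spike) min(mass) else 0
  total <- sum(mass) + spike_mass
  plant_scale <- 1 - contaminant_fraction
  ingredients <- setNames(mass / total * plant_scale, species)
  contaminants <- fungal_mix / sum(fungal_mix) * contaminant_fraction
  formulation_spec(
    ingredients = ingredients,
    contaminants = contaminants,
    spike_species = if (spike) prescription$positive_control else NULL,
    spike_fraction = if (spike) spike_mass / total * plant_scale else 0,
    ...)
}

default_pipeline_params <- function() {
  list(k = 21L, min_shared_kmers = 3L,
       min_quality = 20L, min_length = 50L,
       min_overlap = c(30L, 50L), max_mismatch_rate = 0.02,
       min_contig_length = 150L, at_repeat_abort = 20L,
       keep_partial = FALSE,
       chimera_min_parent_identity = 0.99, chimera_min_gain = 4L,
       clustering_identity = 1.0,
       multimap_mode = "random", map_max_mismatch = 3L, map_seed_k = 21L,
       tie_margin = 0.002, assign_min_identity = 0.97,
       qc = list(max_removed_depth = 3, max_removed_coverage = 0.95,
                 evenness_window = 30L, evenness_ratio = 50))
}

merge_params <- function(user) {
  p <- default_pipeline_params()
  for (n in names(user)) {
    if (n == "qc") p$qc[names(user$qc)] <- user$qc else p[[n]] <- user[[n]]
  }
  p
}

#' Run the full shotgun-metabarcoding pipeline
#'
#' Executes trim -> enrich -> assemble (two overlap settings) -> dedup ->
#' annotate -> chimera screen -> cluster -> map -> QC -> assign -> classify
#' -> report, fully deterministically for a given configuration (all stage
#' seeds derive from the top-level `seed`). Input is either a simulation
#' block or paired FASTQ plus a reference database.
#'
#' The configuration (YAML file or list) understands:
#' \describe{
#'   \item{sample_id}{name used in reports.}
#'   \item{seed}{integer master seed.}
#'   \item{outdir}{artifact directory (`NULL` = write nothing).}
#'   \item{simulation}{list: `preset` (`"wuhusan"`), `n_pairs`,
#'     `read_length`, `error_rate`, `contaminant_fraction`, `spike`,
#'     `chimera_rate`, `degraded` (named fragment means, bp).}
#'   \item{inputs}{list: `fastq1`, `fastq2`, `reference_fasta`,
#'     `reference_taxonomy` (alternative to `simulation`).}
#'   \item{prescription}{path to a prescription YAML (defaults to the
#'     built-in five-ingredient preset).}
#'   \item{params}{overrides of the stage parameters, see
#'     the package vignette.}
#' }
#'
#' @param config path to a YAML config, or an equivalent list.
#' @return object of class `sample_report`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  sample_id <- cfg$sample_id %||% "sample"
  seed <- as.integer(cfg$seed %||% 1L)
  params <- merge_params(cfg$params %||% list())
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  presc <- if (!is.null(cfg$prescription)) load_prescription(cfg$prescription)
           else wuhusan_prescription()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- input: simulate or load ----
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sim_cfg <- cfg$simulation
    panel <- stage("simulate", {
      spec <- wuhusan_panel_spec()
      generate_species_panel(spec, seed = derive_seed(seed, 1L))
    })
    db <- panel$db
    formulation <- wuhusan_formulation(
      presc,
      contaminant_fraction = sim_cfg$contaminant_fraction %||% 0.05,
      spike = isTRUE(sim_cfg$spike),
      degraded = if (!is.null(sim_cfg$degraded)) unlist(sim_cfg$degraded),
      chimera_rate = sim_cfg$chimera_rate %||% 0.01)
    rsp <- read_sim_params(n_pairs = sim_cfg$n_pairs %||% 20000L,
                           read_length = sim_cfg$read_length %||% 150L,
                           error_rate = sim_cfg$error_rate %||% 0.01)
    sim <- stage("simulate",
                 simulate_shotgun_reads(db, formulation, rsp,
                                        seed = derive_seed(seed, 2L)))
    pairs <- sim$pairs
    truth <- sim$truth
    attr(truth, "sample_id") <- sample_id
    if (!is.null(outdir))
      write_fastq_pair(sim, file.path(outdir, sample_id))
  } else if (!is.null(cfg$inputs)) {
    pairs <- stage("read", read_fastq_pairs(cfg$inputs$fastq1,
                                            cfg$inputs$fastq2))
    db <- stage("read", load_reference_db(cfg$inputs$reference_fasta,
                                          cfg$inputs$reference_taxonomy))
  } else stop("config needs a 'simulation' or an 'inputs' block", call. = FALSE)

  barcode_db <- subset_markers(db, BARCODE_MARKERS)
  n_in <- nrow(pairs)

  ## ---- trim + enrich ----
  trimmed <- stage("trim", quality_trim_reads(pairs, params$min_quality,
                                              params$min_length))
  index <- stage("enrich", build_kmer_index(barcode_db, params$k))
  enriched <- stage("enrich", enrich_read_pairs(trimmed, index,
                                                params$min_shared_kmers))
  enr_summary <- enrichment_summary(enriched)

  ## ---- per-marker assembly .. assignment ----
  qc_t <- do.call(qc_thresholds, params$qc)
  all_contigs <- list(); all_barcodes <- list(); all_chim <- list()
  all_otus <- list(); all_profiles <- list(); all_hits <- list()
  evenness <- list(); barcode_members <- list()
  counts <- list(pairs_in = n_in, pairs_trimmed = nrow(trimmed),
                 pairs_enriched = sum(enr_summary$pairs_retained))

  for (mi in seq_along(BARCODE_MARKERS)) {
    m <- BARCODE_MARKERS[mi]
    pool <- marker_pool(enriched, m)
    if (!nrow(pool)) next
    contigs <- stage("assemble", {
      parts <- lapply(params$min_overlap, function(ov)
        assemble_reads(pool, m, min_overlap = ov,
                       max_mismatch_rate = params$max_mismatch_rate,
                       min_length = params$min_contig_length,
                       at_repeat_abort = params$at_repeat_abort))
      do.call(dedup_identical, parts)
    })
    all_contigs[[m]] <- contigs
    if (!nrow(contigs)) next
    barcodes <- stage("annotate",
                      annotate_contigs(contigs,
                                       keep_partial = params$keep_partial))
    if (!nrow(barcodes)) next
    for (i in seq_len(nrow(barcodes))) {
      mem <- contigs$members[[match(barcodes$contig_id[i], contigs$id)]]
      barcode_members[[barcodes$contig_id[i]]] <- mem
    }
    chim <- stage("chimera",
                  screen_chimeras(barcodes,
                                  params$chimera_min_parent_identity,
                                  params$chimera_min_gain))
    all_chim[[m]] <- chim
    barcodes <- barcodes[!chim$is_chimera, , drop = FALSE]
    all_barcodes[[m]] <- barcodes
    if (!nrow(barcodes)) next
    otus <- stage("cluster", cluster_otus(barcodes,
                                          params$clustering_identity))
    profiles <- stage("map",
                      map_read_pairs(pool, otus, seed_k = params$map_seed_k,
                                     multimap_mode = params$multimap_mode,
                                     rng_seed = derive_seed(seed, 10L + mi),
                                     max_mismatch = params$map_max_mismatch))
    qc <- stage("qc", qc_filter(otus, profiles, qc_t))
    all_otus[[m]] <- list(pre = otus, kept = qc$kept, removed = qc$removed)
    all_profiles[[m]] <- profiles
    for (i in seq_len(nrow(qc$kept))) {
      pid <- qc$kept$otu_id[i]
      pr <- profiles[profiles$otu_id == pid, , drop = FALSE]
      if (pr$length[1] >= 2L * qc_t$evenness_window)
        evenness[[pid]] <- evenness_diagnostic(pr, qc_t)
    }
    if (nrow(qc$kept)) {
      hits <- stage("assign", assign_otus(qc$kept, barcode_db,
                                          params$tie_margin,
                                          params$assign_min_identity))
      hits$n_reads <- profiles$n_pairs_mapped[match(hits$otu_id,
                                                    profiles$otu_id)]
      all_hits[[m]] <- hits
    }
  }

  hits <- if (length(all_hits)) do.call(rbind, all_hits) else
    data.frame(otu_id = character(0), marker = character(0),
               best_identity = numeric(0), rank = character(0),
               species = character(0), genus = character(0),
               family = character(0), kingdom = character(0),
               tied_ids = character(0), n_reads = numeric(0))
  rownames(hits) <- NULL
  cls <- stage("classify", consolidate_and_classify(hits, presc))
  detection <- detection_matrix(cls$calls, presc)
  fungal <- fungal_genus_table(cls$calls)

  counts$contigs <- sum(vapply(all_contigs, nrow, 1L))
  counts$barcodes <- sum(vapply(all_barcodes, nrow, 1L))
  counts$chimeras_removed <- sum(vapply(all_chim, function(x)
    sum(x$is_chimera), 1L))
  counts$otus_pre_qc <- sum(vapply(all_otus, function(x) nrow(x$pre), 1L))
  counts$otus_post_qc <- sum(vapply(all_otus, function(x) nrow(x$kept), 1L))

  report <- structure(list(
    sample_id = sample_id, counts = counts, enrichment = enr_summary,
    detection = detection, calls = cls$calls, absent = cls$absent,
    fungal = fungal,
    chimera_screen = if (length(all_chim)) do.call(rbind, all_chim) else NULL,
    evenness = evenness, hits = hits,
    otus = all_otus, profiles = all_profiles,
    barcode_members = barcode_members,
    truth = truth, config = cfg, params = params, seed = seed),
    class = "sample_report")
  if (!is.null(outdir)) write_report_artifacts(report, outdir)
  report
}

report_json <- function(report) {
  calls <- report$calls
  calls$marker_reads <- NULL
  jsonlite::toJSON(list(
    sample_id = report$sample_id,
    counts = report$counts,
    enrichment = report$enrichment,
    detection = as.data.frame(report$detection),
    calls = calls,
    absent = report$absent,
    fungal = report$fungal,
    seed = report$seed),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_report_artifacts <- function(report, outdir) {
  writeLines(as.character(report_json(report)),
             file.path(outdir, "report.json"))
  det <- data.frame(species = rownames(report$detection),
                    report$detection, check.names = FALSE)
  write.table(det, file.path(outdir, "detection_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  calls <- report$calls; calls$marker_reads <- NULL
  write.table(calls, file.path(outdir, "species_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$fungal, file.path(outdir, "fungal_genera.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$absent, file.path(outdir, "absent_ingredients.txt"))
  if (!is.null(report$chimera_screen))
    write.table(report$chimera_screen, file.path(outdir, "chimeras.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(report$profiles))
    write_profiles(report$profiles[[m]],
                   file.path(outdir, paste0("profiles_", m, ".tsv")))
  for (m in names(report$otus))
    if (nrow(report$otus[[m]]$kept))
      write_otus(report$otus[[m]]$kept,
                 file.path(outdir, paste0("otus_", m, ".fasta")))
  invisible(outdir)
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Sample report:", x$sample_id, "\n")
  cat(sprintf("  pairs in/trimmed/enriched: %d / %d / %d\n",
              x$counts$pairs_in, x$counts$pairs_trimmed,
              x$counts$pairs_enriched))
  cat(sprintf("  contigs %d, barcodes %d, chimeras removed %d, OTUs %d -> %d\n",
              x$counts$contigs, x$counts$barcodes, x$counts$chimeras_removed,
              x$counts$otus_pre_qc, x$counts$otus_post_qc))
  cat("  detection matrix:\n")
  print(x$detection)
  if (length(x$absent))
    cat("  absent ingredients:", paste(x$absent, collapse = ", "), "\n")
  if (nrow(x$fungal)) {
    cat("  fungal genera:\n")
    print(x$fungal, row.names = FALSE)
  }
  invisible(x)
}
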