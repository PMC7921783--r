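## ---------------------------------------------------------------------------
## Reference database, marker registry and prescription configuration
## ---------------------------------------------------------------------------

#' Marker registry
#'
#' The four DNA barcode regions recovered from shotgun data, plus the
#' `genomic-background` pseudo-marker used by the simulator. ITS2 is nuclear
#' and annotated by its conserved 5.8S/28S flanks; the three plastid markers
#' are annotated by their universal amplification primer binding sites.
#'
#' @format A character vector of marker names.
#' @export
BARCODE_MARKERS <- c("ITS2", "psbA-trnH", "matK", "rbcL")

KNOWN_MARKERS <- c(BARCODE_MARKERS, "genomic-background")

## Conserved flank constants used for ITS2 annotation and by the simulator.
## The 5.8S 3'-end and 28S (LSU) 5'-start are highly conserved across plants
## and fungi, which is precisely why reads multi-map there.
MOTIF_5_8S_END <- "TTGAACGCAAGTTGCGCCCG"
MOTIF_28S_START <- "TTGACCTCAAATCAGGTAGG"
CONSERVED_5_8S_LEAD <- "CGATGAAGAACGCAGCGAAATGCGATACGT"
CONSERVED_28S_TAIL <- paste0(
  "ACGGCGAGTGAAGCGGCAAAAGCTCAAATT",
  "TGAAATCTGGTACCTTCGGTGCCCGAGTTG"
)

#' Construct a primer set
#'
#' @param forward,reverse primer sequences, 5'->3', IUPAC codes allowed.
#' @param max_mismatch maximum substitutions tolerated when locating a primer.
#' @return object of class `primer_set`.
#' @export
primer_set <- function(forward, reverse, max_mismatch = 2L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 10 || nchar(reverse) < 10)
    stop("primers must be at least 10 bp", call. = FALSE)
  check_dna_alphabet(c(forward, reverse), IUPAC_CHARS, "primer")
  stopifnot(max_mismatch >= 0)
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_set")
}

#' Default marker loci
#'
#' Returns the marker table used throughout: genome compartment, universal
#' primer set (plastid markers) and conserved flank motifs (ITS2). Primer
#' sequences are the standard plant-barcoding sets (psbA3'f/trnHf, matK
#' KIM-3F/KIM-1R, rbcLa-F/rbcLa-R).
#'
#' @return named list of `marker_locus` objects.
#' @export
default_markers <- function() {
  list(
    "ITS2" = marker_locus("ITS2", "nuclear",
                          flank_motifs = default_flank_motifs()),
    "psbA-trnH" = marker_locus("psbA-trnH", "plastid",
      primer_set("GTTATGCATGAACGTAATGCTC", "CGCGCATGGTGGATTCACAATCC")),
    "matK" = marker_locus("matK", "plastid",
      primer_set("CGTACAGTACTTTTGTGTTTACGAG", "ACCCAGTCCATCTGGAAATCTTGGTTC")),
    "rbcL" = marker_locus("rbcL", "plastid",
      primer_set("ATGTCACCACAAACAGAGACTAAAGC", "GTAAAATCAAGTCCACCRCG"))
  )
}

#' @rdname default_markers
#' @param name marker name, one of `BARCODE_MARKERS`.
#' @param genome `"nuclear"` or `"plastid"`.
#' @param primer_set a `primer_set` (required for plastid markers).
#' @param flank_motifs pair of `motif_model`s (required for ITS2).
#' @export
marker_locus <- function(name, genome, primer_set = NULL, flank_motifs = NULL) {
  name <- match.arg(name, BARCODE_MARKERS)
  genome <- match.arg(genome, c("nuclear", "plastid"))
  if (name == "ITS2" && is.null(flank_motifs))
    stop("ITS2 requires flank_motifs", call. = FALSE)
  if (genome == "plastid" && is.null(primer_set))
    stop("plastid markers require a primer_set", call. = FALSE)
  structure(list(name = name, genome = genome, primer_set = primer_set,
                 flank_motifs = flank_motifs),
            class = "marker_locus")
}

validate_taxon_table <- function(tab) {
  stopifnot(all(c("species", "genus", "family", "kingdom") %in% names(tab)))
  bad_k <- !tab$kingdom %in% c("Viridiplantae", "Fungi")
  if (any(bad_k))
    stop("kingdom must be Viridiplantae or Fungi (offending record: ",
         tab$id[bad_k][1], ")", call. = FALSE)
  ## rank-limited records: species may be empty, but a named species must
  ## carry its genus and family
  named <- nzchar(tab$species)
  if (any(named & (!nzchar(tab$genus) | !nzchar(tab$family))))
    stop("records with a species name must also carry genus and family",
         call. = FALSE)
  if (any(!named & !nzchar(tab$family)))
    stop("rank-limited records must at least carry a family", call. = FALSE)
  invisible(TRUE)
}

#' Construct a reference database
#'
#' A taxon-labelled multi-marker barcode collection: the local stand-in for
#' remote barcode repositories. Each record carries an id, marker, 4-rank
#' taxon label and an uppercase DNA sequence.
#'
#' @param records data.frame with columns `id`, `marker`, `species`, `genus`,
#'   `family`, `kingdom`, `sequence`.
#' @return object of class `reference_db` with elements `records` and
#'   `by_marker` (map marker -> record ids).
#' @export
reference_db <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("id", "marker", "species", "genus", "family", "kingdom", "sequence")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  records <- records[, need]
  dup <- duplicated(records$id)
  if (any(dup))
    stop("duplicate record id: ", records$id[dup][1], call. = FALSE)
  unknown <- !records$marker %in% KNOWN_MARKERS
  if (any(unknown))
    stop("unknown marker token: ", records$marker[unknown][1], call. = FALSE)
  records$sequence <- toupper(records$sequence)
  check_dna_alphabet(records$sequence, c(DNA_BASES, "N"), "reference sequence")
  if (any(nchar(records$sequence) < 100))
    stop("reference sequences must be at least 100 bp (offending id: ",
         records$id[nchar(records$sequence) < 100][1], ")", call. = FALSE)
  validate_taxon_table(records)
  rownames(records) <- NULL
  by_marker <- split(records$id, factor(records$marker, levels = KNOWN_MARKERS))
  by_marker <- by_marker[vapply(by_marker, length, 1L) > 0L]
  structure(list(records = records, by_marker = by_marker),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference barcode database:", nrow(x$records), "records\n")
  for (m in names(x$by_marker))
    cat(sprintf("  %-18s %d\n", m, length(x$by_marker[[m]])))
  invisible(x)
}

#' Load a reference database from FASTA + taxonomy TSV
#'
#' @param fasta_path FASTA of uppercase DNA reference sequences.
#' @param taxonomy_path TSV with columns `id`, `marker`, `species`, `genus`,
#'   `family`, `kingdom`; every FASTA id must appear and vice versa.
#' @return a `reference_db`; record order follows the FASTA.
#' @export
load_reference_db <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxonomy_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("id", "marker", "species", "genus", "family", "kingdom")
  if (!all(need %in% names(tax)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  orphan_tsv <- setdiff(tax$id, ids)
  if (length(orphan_tsv))
    stop("taxonomy rows without a FASTA sequence: ",
         paste(orphan_tsv, collapse = ", "), call. = FALSE)
  missing_tax <- setdiff(ids, tax$id)
  if (length(missing_tax))
    stop("FASTA ids missing from the taxonomy table: ",
         paste(missing_tax, collapse = ", "), call. = FALSE)
  tax <- tax[match(ids, tax$id), ]
  reference_db(data.frame(
    id = ids, marker = tax$marker, species = tax$species, genus = tax$genus,
    family = tax$family, kingdom = tax$kingdom,
    sequence = as.character(seqs), stringsAsFactors = FALSE))
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' Inverse of [load_reference_db()]; `load(write(db))` is the identity.
#'
#' @param db a `reference_db`.
#' @param fasta_path,taxonomy_path output paths.
#' @export
write_reference_db <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "reference_db"))
  s <- Biostrings::DNAStringSet(db$records$sequence)
  names(s) <- db$records$id
  Biostrings::writeXStringSet(s, fasta_path, width = 80L)
  write.table(db$records[, c("id", "marker", "species", "genus", "family",
                             "kingdom")],
              taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, taxonomy = taxonomy_path))
}

#' Subset a reference database by marker
#'
#' @param db a `reference_db`.
#' @param markers marker names to keep.
#' @return a `reference_db` restricted to those markers.
#' @export
subset_markers <- function(db, markers = BARCODE_MARKERS) {
  stopifnot(inherits(db, "reference_db"))
  reference_db(db$records[db$records$marker %in% markers, , drop = FALSE])
}

## ---------------------------------------------------------------------------
## k-mer index
## ---------------------------------------------------------------------------

#' Build a canonical k-mer index over a reference database
#'
#' Maps each canonical k-mer (lexicographic minimum of a k-mer and its reverse
#' complement, so lookups are strand-agnostic) to the records and markers it
#' occurs in. k-mers containing `N` are skipped. This is the index the
#' enrichment stage matches read k-mers against.
#'
#' @param db a `reference_db`.
#' @param k k-mer length, between 8 and 31.
#' @return object of class `kmer_index`: list with `k`, `keys` (canonical
#'   k-mers), `records` and `markers` (parallel lists of character vectors).
#' @export
build_kmer_index <- function(db, k = 21L) {
  stopifnot(inherits(db, "reference_db"))
  k <- as.integer(k)
  if (is.na(k) || k < 8L || k > 31L)
    stop("k must be between 8 and 31", call. = FALSE)
  per_rec <- lapply(db$records$sequence, canonical_kmers_cpp, k = k,
                    unique_only = TRUE)
  keys <- unlist(per_rec, use.names = FALSE)
  rec_ids <- rep(db$records$id, lengths(per_rec))
  markers <- rep(db$records$marker, lengths(per_rec))
  f <- factor(keys)
  structure(list(
    k = k,
    keys = levels(f),
    records = split(rec_ids, f),
    markers = lapply(split(markers, f), unique)
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("Canonical %d-mer index: %d keys over %d markers\n", x$k,
              length(x$keys), length(unique(unlist(x$markers)))))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Prescription / formulation configuration
## ---------------------------------------------------------------------------

#' Construct a prescription configuration
#'
#' The labelled formulation of the product: ingredients with their official
#' source species and recipe proportions (percent), sanctioned substitutions,
#' known adulterants, and an optional positive-control species. Proportions
#' are normalized to fractions by their sum (a recipe need not total exactly
#' 100%); the raw total is retained as `total_percent`.
#'
#' @param ingredients data.frame with columns `pinyin`, `species` (list column
#'   of official species) and `proportion` (percent).
#' @param substitutions named character: species -> ingredient pinyin.
#' @param adulterants named character: species -> ingredient pinyin.
#' @param positive_control species name or `NULL`.
#' @return object of class `prescription`.
#' @export
prescription <- function(ingredients, substitutions = character(0),
                         adulterants = character(0), positive_control = NULL) {
  ingredients <- as.data.frame(ingredients)
  stopifnot(all(c("pinyin", "species", "proportion") %in% names(ingredients)))
  if (!is.list(ingredients$species))
    ingredients$species <- as.list(ingredients$species)
  if (any(lengths(ingredients$species) == 0L) ||
      any(!vapply(ingredients$species, function(s) all(nzchar(s)), TRUE)))
    stop("every ingredient needs a non-empty official species list",
         call. = FALSE)
  prop <- as.numeric(ingredients$proportion)
  if (any(is.na(prop)) || any(prop <= 0))
    stop("ingredient proportions must be positive", call. = FALSE)
  total <- sum(prop)
  ingredients$fraction <- prop / total
  structure(list(ingredients = ingredients,
                 substitutions = substitutions,
                 adulterants = adulterants,
                 positive_control = positive_control,
                 total_percent = total),
            class = "prescription")
}

#' Load a prescription configuration from YAML
#'
#' @param config_path YAML file with fields `ingredients` (list of `pinyin`,
#'   `species`, `proportion` in percent), optional `substitutions`,
#'   `adulterants` (species -> ingredient maps) and `positive_control`.
#' @return a `prescription` with proportions normalized to fractions.
#' @export
load_prescription <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$ingredients) || !length(cfg$ingredients))
    stop("prescription config has no ingredients", call. = FALSE)
  ing <- data.frame(
    pinyin = vapply(cfg$ingredients, function(i) i$pinyin %||% "", ""),
    proportion = vapply(cfg$ingredients,
                        function(i) as.numeric(i$proportion %||% NA_real_), 0)
  )
  ing$species <- lapply(cfg$ingredients, function(i) unlist(i$species))
  prescription(ing,
               substitutions = unlist(cfg$substitutions) %||% character(0),
               adulterants = unlist(cfg$adulterants) %||% character(0),
               positive_control = cfg$positive_control)
}

#' @export
print.prescription <- function(x, ...) {
  cat("Prescription:", nrow(x$ingredients), "ingredients (recipe total",
      sprintf("%.1f%%)\n", x$total_percent))
  for (i in seq_len(nrow(x$ingredients)))
    cat(sprintf("  %-16s %5.1f%% -> %.4f  [%s]\n", x$ingredients$pinyin[i],
                x$ingredients$proportion[i], x$ingredients$fraction[i],
                paste(x$ingredients$species[[i]], collapse = "; ")))
  if (!is.null(x$positive_control))
    cat("  positive control:", x$positive_control, "\n")
  invisible(x)
}

#' All official species of a prescription
#' @param x a `prescription`.
#' @return character vector of species names.
#' @export
official_species <- function(x) {
  stopifnot(inherits(x, "prescription"))
  unique(unlist(x$ingredients$species))
}
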