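## ---------------------------------------------------------------------------
## Taxonomic assignment, multi-marker consolidation, ingredient classification
## ---------------------------------------------------------------------------

#' Pairwise identity and base differences between two barcode sequences
#'
#' End-gap-free (overlap) global alignment with match +1 / mismatch -1 /
#' gap open 2 / gap extend 0.5. Differences are the differing columns of
#' the mutually covered region, each gap column counting 1; identity is
#' `1 - differences / aligned_length`. Substitution-only counts are reported
#' alongside, since published base-difference tallies depend on the gap
#' convention.
#'
#' @param a,b DNA sequences, each at least 50 bp.
#' @return list: `identity`, `differences`, `aligned_length`,
#'   `substitutions`, `gap_columns`.
#' @export
pairwise_identity_and_differences <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence", call. = FALSE)
  if (nchar(a) < 50 || nchar(b) < 50)
    stop("sequences must be at least 50 bp", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  subs <- sum(!gap & p != s)
  diffs <- subs + sum(gap)
  len <- length(p)
  list(identity = 1 - diffs / len, differences = as.integer(diffs),
       aligned_length = as.integer(len), substitutions = as.integer(subs),
       gap_columns = as.integer(sum(gap)))
}

#' Assign a taxon to an OTU against the reference database
#'
#' Overlap-alignment identity is computed against every same-marker
#' reference; references within `tie_margin` of the best identity are
#' collected and the assignment rank is the lowest rank at which their
#' taxon labels agree (species, else genus, else family, else unassigned).
#' A best identity below `min_identity` leaves the OTU unassigned.
#'
#' @param otu one-row `otu_set` data.frame (uses `representative`,
#'   `marker`, `otu_id`).
#' @param db a `reference_db`.
#' @param tie_margin identity margin within which references count as tied.
#' @param min_identity minimum best identity for any assignment.
#' @param min_query_coverage minimum fraction of the query covered by the
#'   overlap alignment for a reference to count (partial or chimeric
#'   representatives whose alignment covers only a segment are not
#'   assignable, mirroring query-coverage thresholds in BLAST-based
#'   assignment).
#' @return one-row data.frame (`assignment_hit`): `otu_id`, `marker`,
#'   `best_identity`, `rank`, `species`, `genus`, `family`, `kingdom`,
#'   `tied_ids`.
#' @export
assign_taxon <- function(otu, db, tie_margin = 0.002, min_identity = 0.97,
                         min_query_coverage = 0.8) {
  stopifnot(inherits(db, "reference_db"))
  marker <- otu$marker[[1]]
  refs <- db$records[db$records$marker == marker, , drop = FALSE]
  if (!nrow(refs))
    stop("no reference records for marker ", marker, call. = FALSE)
  query <- otu$representative[[1]] %||% otu$sequence[[1]]
  ident <- vapply(refs$sequence, function(r) {
    p <- pairwise_identity_and_differences(query, r)
    qcov <- (p$aligned_length - p$gap_columns) / nchar(query)
    if (qcov < min_query_coverage) -1 else p$identity
  }, numeric(1), USE.NAMES = FALSE)
  best <- max(ident)
  hit <- data.frame(otu_id = otu$otu_id[[1]] %||% NA_character_,
                    marker = marker,
                    best_identity = if (best >= 0) best else NA_real_,
                    rank = "unassigned", species = "", genus = "",
                    family = "", kingdom = "", tied_ids = "",
                    stringsAsFactors = FALSE)
  if (best < min_identity) return(hit)
  tied <- refs[ident >= best - tie_margin, , drop = FALSE]
  hit$tied_ids <- paste(tied$id, collapse = ";")
  agree <- function(x) length(unique(x)) == 1L && all(nzchar(x))
  if (agree(tied$species)) {
    hit$rank <- "species"
    hit$species <- tied$species[1]; hit$genus <- tied$genus[1]
    hit$family <- tied$family[1]; hit$kingdom <- tied$kingdom[1]
  } else if (agree(tied$genus)) {
    hit$rank <- "genus"
    hit$genus <- tied$genus[1]; hit$family <- tied$family[1]
    hit$kingdom <- if (agree(tied$kingdom)) tied$kingdom[1] else ""
  } else if (agree(tied$family)) {
    hit$rank <- "family"
    hit$family <- tied$family[1]
    hit$kingdom <- if (agree(tied$kingdom)) tied$kingdom[1] else ""
  }
  hit
}

#' Assign all OTUs of an `otu_set`
#'
#' @param otus an `otu_set`.
#' @inheritParams assign_taxon
#' @return data.frame of assignment hits, one row per OTU.
#' @export
assign_otus <- function(otus, db, tie_margin = 0.002, min_identity = 0.97) {
  rows <- lapply(seq_len(nrow(otus)), function(i)
    assign_taxon(otus[i, , drop = FALSE], db, tie_margin, min_identity))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

classify_one <- function(rank, species, genus, family, kingdom,
                         prescription) {
  off <- official_species(prescription)
  off_tab <- data.frame(species = off,
                        genus = vapply(strsplit(off, " "), `[`, "", 1L))
  if (rank == "species") {
    if (!is.null(prescription$positive_control) &&
        species == prescription$positive_control) return("positive-control")
    if (species %in% off) return("authentic")
    if (species %in% names(prescription$substitutions)) return("substitution")
    if (species %in% names(prescription$adulterants)) return("adulterant")
  } else if (rank == "genus") {
    ## a genus-level call matching an official species' genus supports that
    ## ingredient without resolving the species
    if (genus %in% off_tab$genus && kingdom != "Fungi") return("authentic")
  }
  if (kingdom == "Fungi") return("contaminant-fungal")
  "contaminant-impurity"
}

#' Consolidate assignment hits across markers and classify them
#'
#' Hits are grouped by assigned taxon (rank-aware: genus- and family-level
#' hits group separately from species hits), per-marker read counts are
#' summed and every group receives exactly one category with precedence
#' positive-control > authentic > substitution > adulterant >
#' contaminant-fungal > contaminant-impurity. Official species with no
#' species-level call are listed as absent.
#'
#' @param hits assignment-hit data.frame; an `n_reads` column (mapped read
#'   pairs per OTU) is used for the per-marker counts when present.
#' @param prescription a [prescription()].
#' @return list with `calls` (data.frame: `taxon`, `rank`, `kingdom`,
#'   `genus`, `family`, `category`, `markers`, `n_reads`, plus a
#'   `marker_reads` list-column) and `absent` (official species with no
#'   species-rank call).
#' @export
consolidate_and_classify <- function(hits, prescription) {
  stopifnot(inherits(prescription, "prescription"))
  hits <- hits[hits$rank != "unassigned", , drop = FALSE]
  if (!"n_reads" %in% names(hits)) hits$n_reads <- 1L
  if (nrow(hits)) {
    taxon <- ifelse(hits$rank == "species", hits$species,
                    ifelse(hits$rank == "genus", hits$genus, hits$family))
    grp <- paste(hits$rank, taxon, sep = "\r")
    groups <- split(seq_len(nrow(hits)), grp)
    rows <- lapply(groups, function(ix) {
      h <- hits[ix, , drop = FALSE]
      mk <- sort(unique(h$marker))
      mr <- vapply(mk, function(m) sum(h$n_reads[h$marker == m]), numeric(1))
      data.frame(taxon = taxon[ix[1]], rank = h$rank[1],
                 kingdom = h$kingdom[1], genus = h$genus[1],
                 family = h$family[1],
                 category = classify_one(h$rank[1], h$species[1], h$genus[1],
                                         h$family[1], h$kingdom[1],
                                         prescription),
                 markers = paste(mk, collapse = ";"),
                 n_reads = sum(mr), stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    calls$marker_reads <- lapply(groups, function(ix) {
      h <- hits[ix, , drop = FALSE]
      mk <- sort(unique(h$marker))
      setNames(vapply(mk, function(m) sum(h$n_reads[h$marker == m]),
                      numeric(1)), mk)
    })
    calls <- calls[order(-calls$n_reads, calls$taxon), , drop = FALSE]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(taxon = character(0), rank = character(0),
                        kingdom = character(0), genus = character(0),
                        family = character(0), category = character(0),
                        markers = character(0), n_reads = numeric(0))
    calls$marker_reads <- list()
  }
  absent <- setdiff(official_species(prescription),
                    calls$taxon[calls$rank == "species"])
  list(calls = calls, absent = absent)
}
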