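## ---------------------------------------------------------------------------
## Detection matrix, fungal table, truth-based evaluation
## ---------------------------------------------------------------------------

#' Species x marker detection matrix
#'
#' Rows are the prescription's official species, the positive control and
#' any additional species called; columns are the four barcode markers. A
#' cell is `TRUE` when a QC-passing OTU of that marker was assigned (at
#' species rank) to that species.
#'
#' @param calls consolidated species calls ([consolidate_and_classify()]).
#' @param prescription a [prescription()].
#' @return logical matrix species x markers.
#' @export
detection_matrix <- function(calls, prescription) {
  rows <- official_species(prescription)
  if (!is.null(prescription$positive_control))
    rows <- c(rows, prescription$positive_control)
  sp_calls <- calls[calls$rank == "species", , drop = FALSE]
  rows <- unique(c(rows, sp_calls$taxon))
  M <- matrix(FALSE, length(rows), length(BARCODE_MARKERS),
              dimnames = list(rows, BARCODE_MARKERS))
  for (i in seq_len(nrow(sp_calls))) {
    mk <- intersect(names(sp_calls$marker_reads[[i]]), BARCODE_MARKERS)
    M[sp_calls$taxon[i], mk] <- TRUE
  }
  M
}

#' Fungal contamination table at genus level
#'
#' Aggregates contaminant-fungal calls to genus, with read counts and
#' fractions of all fungal reads, sorted by decreasing abundance.
#'
#' @param calls consolidated species calls.
#' @return data.frame: `genus`, `n_reads`, `fraction`.
#' @export
fungal_genus_table <- function(calls) {
  f <- calls[calls$category == "contaminant-fungal", , drop = FALSE]
  if (!nrow(f))
    return(data.frame(genus = character(0), n_reads = numeric(0),
                      fraction = numeric(0)))
  genus <- ifelse(nzchar(f$genus), f$genus,
                  vapply(strsplit(f$taxon, " "), `[`, "", 1L))
  agg <- tapply(f$n_reads, genus, sum)
  out <- data.frame(genus = names(agg), n_reads = as.numeric(agg),
                    row.names = NULL)
  out$fraction <- out$n_reads / sum(out$n_reads)
  out[order(-out$n_reads, out$genus), , drop = FALSE]
}

#' Evaluate a pipeline report against the simulator's truth table
#'
#' Computes, per marker, species-detection precision and recall (detected
#' species-rank calls vs species with truth reads for that marker),
#' chimera-screening sensitivity/specificity at the assembled-barcode level
#' (a barcode counts as truth-chimeric when at least half of its supporting
#' reads are chimeric), and per-species absolute errors between truth read
#' fractions and the report's mapped-read fractions.
#'
#' @param report a `sample_report` from [run_pipeline()].
#' @param truth the truth table of the same simulation.
#' @param min_truth_pairs species need at least this many truth pairs at a
#'   marker to count as expected there.
#' @return list: `per_marker` (data.frame marker/precision/recall),
#'   `chimera` (sensitivity, specificity, n), `fraction_errors`
#'   (data.frame species/truth_fraction/observed_fraction/abs_error).
#' @export
evaluate_against_truth <- function(report, truth, min_truth_pairs = 1L) {
  stopifnot(inherits(report, "sample_report"))
  if (!is.null(report$sample_id) && !is.null(attr(truth, "sample_id")) &&
      !identical(report$sample_id, attr(truth, "sample_id")))
    stop("truth table and report come from different samples", call. = FALSE)
  M <- report$detection
  per_marker <- do.call(rbind, lapply(BARCODE_MARKERS, function(m) {
    expect <- truth[truth$marker == m & !truth$is_chimera, "taxon"]
    expect <- names(which(table(expect) >= min_truth_pairs))
    got <- rownames(M)[M[, m]]
    tp <- length(intersect(got, expect))
    data.frame(marker = m,
               n_expected = length(expect), n_detected = length(got),
               precision = if (length(got)) tp / length(got) else NA_real_,
               recall = if (length(expect)) tp / length(expect) else NA_real_)
  }))

  chim <- list(sensitivity = NA_real_, specificity = NA_real_, n = 0L)
  cs <- report$chimera_screen
  if (!is.null(cs) && nrow(cs) && !is.null(report$barcode_members)) {
    truth_chim <- setNames(truth$is_chimera, truth$read_id)
    lab <- vapply(cs$contig_id, function(id) {
      mem <- report$barcode_members[[id]]
      if (is.null(mem) || !length(mem)) return(NA)
      mean(truth_chim[sub("/[12]$", "", mem)], na.rm = TRUE) >= 0.5
    }, logical(1))
    ok <- !is.na(lab)
    if (any(ok)) {
      pos <- lab[ok]; called <- cs$is_chimera[ok]
      chim$n <- sum(ok)
      chim$sensitivity <- if (any(pos)) mean(called[pos]) else NA_real_
      chim$specificity <- if (any(!pos)) mean(!called[!pos]) else NA_real_
    }
  }

  tf <- table(truth$taxon[truth$marker != "genomic-background"])
  tf <- tf / sum(tf)
  calls <- report$calls
  sp <- calls[calls$rank == "species", , drop = FALSE]
  obs <- setNames(sp$n_reads, sp$taxon)
  obs <- obs / max(1, sum(obs))
  species <- sort(unique(c(names(tf), names(obs))))
  fe <- data.frame(
    species = species,
    truth_fraction = as.numeric(tf[species]),
    observed_fraction = as.numeric(obs[species]),
    stringsAsFactors = FALSE)
  fe$truth_fraction[is.na(fe$truth_fraction)] <- 0
  fe$observed_fraction[is.na(fe$observed_fraction)] <- 0
  fe$abs_error <- abs(fe$truth_fraction - fe$observed_fraction)

  list(per_marker = per_marker, chimera = chim, fraction_errors = fe)
}
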