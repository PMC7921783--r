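## ---------------------------------------------------------------------------
## Greedy overlap-layout-consensus assembly of enriched reads, per marker
## ---------------------------------------------------------------------------

#' Assemble one marker's enriched reads into contigs
#'
#' Desk-scale greedy overlap-layout-consensus: both mates (reverse
#' complements considered) are merged by the longest prefix overlap of at
#' least `min_overlap` bp with mismatch rate at most `max_mismatch_rate`;
#' the consensus is the per-column majority with ties resolved by the
#' earliest supporting read. Seeding order is deterministic (reads sorted
#' lexicographically by id). Reads containing an AT-dinucleotide tandem run
#' of `at_repeat_abort` bp or more are withheld, so extension aborts at such
#' repeats (the known psbA-trnH failure mode of AT-rich Araceae loci).
#' Contigs whose read pileup disagrees at two or more columns (depth >= 4,
#' minority >= 30%) carry a collapse warning: near-identical haplotypes
#' merged into one consensus.
#'
#' @param pairs read-pair data.frame for one marker (see [marker_pool()]).
#' @param marker marker name recorded on the contigs.
#' @param min_overlap minimum merge overlap (bp), >= 20.
#' @param max_mismatch_rate maximum mismatch rate in an accepted overlap,
#'   <= 0.02.
#' @param min_length minimum contig length retained.
#' @param min_support minimum supporting reads per contig.
#' @param at_repeat_abort AT-repeat abort length (bp); 0 disables.
#' @param anchor_w exact-match anchor width used to find overlap candidates.
#' @return data.frame of class `contig_set`: `id`, `marker`, `sequence`,
#'   `n_reads`, `param_tag`, `collapse_warning`, `n_variant_cols`, plus a
#'   `members` list-column of supporting read ids.
#' @export
assemble_reads <- function(pairs, marker, min_overlap = 30L,
                           max_mismatch_rate = 0.02, min_length = 150L,
                           min_support = 2L, at_repeat_abort = 20L,
                           anchor_w = 15L) {
  if (min_overlap < 20) stop("min_overlap must be >= 20", call. = FALSE)
  if (max_mismatch_rate > 0.02)
    stop("max_mismatch_rate must be <= 0.02", call. = FALSE)
  reads <- character(0)
  if (nrow(pairs)) {
    reads <- c(setNames(pairs$seq1, paste0(pairs$id, "/1")),
               setNames(pairs$seq2, paste0(pairs$id, "/2")))
    reads <- reads[order(names(reads), method = "radix")]
  }
  empty <- data.frame(id = character(0), marker = character(0),
                      sequence = character(0), n_reads = integer(0),
                      param_tag = character(0), collapse_warning = logical(0),
                      n_variant_cols = integer(0))
  empty$members <- list()
  if (!length(reads)) return(structure(empty, class = c("contig_set", "data.frame")))
  res <- assemble_greedy_cpp(unname(reads), as.integer(min_overlap),
                             max_mismatch_rate, as.integer(anchor_w),
                             as.integer(min_length), as.integer(min_support),
                             as.integer(at_repeat_abort), 50000L)
  nc <- length(res$sequence)
  if (!nc) return(structure(empty, class = c("contig_set", "data.frame")))
  out <- data.frame(
    id = sprintf("%s_ov%d_c%04d", marker, min_overlap, seq_len(nc)),
    marker = marker,
    sequence = unlist(res$sequence),
    n_reads = res$n_reads,
    param_tag = sprintf("ov%d", min_overlap),
    collapse_warning = res$collapse_warning,
    n_variant_cols = res$n_variant_cols,
    stringsAsFactors = FALSE)
  out$members <- lapply(res$members, function(m) names(reads)[m])
  if (at_repeat_abort > 0)
    out <- split_at_repeats(out, at_repeat_abort, min_length)
  if (any(out$collapse_warning))
    message(sum(out$collapse_warning), " ", marker,
            " contig(s) show clustered within-contig read mismatches: ",
            "possible collapse of near-identical haplotypes")
  structure(out, class = c("contig_set", "data.frame"))
}

## Enforce the AT-repeat abort on the consensus: a contig whose consensus
## contains an alternating-AT tandem run of >= at_abort bp is split at the
## run(s) and the run itself discarded -- no contig may span such a repeat.
## Pieces inherit the parent's members; support is length-prorated.
split_at_repeats <- function(contigs, at_abort, min_length) {
  if (!nrow(contigs)) return(contigs)
  pat <- sprintf("(AT|TA){%d,}", ceiling(at_abort / 2))
  hit <- grepl(pat, contigs$sequence)
  if (!any(hit)) return(contigs)
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    if (!hit[i]) { rows[[length(rows) + 1L]] <- contigs[i, ]; next }
    pieces <- strsplit(contigs$sequence[i], pat)[[1]]
    keep <- which(nchar(pieces) >= min_length)
    total <- nchar(contigs$sequence[i])
    for (k in seq_along(keep)) {
      row <- contigs[i, ]
      row$sequence <- pieces[keep[k]]
      row$id <- paste0(row$id, letters[k])
      row$n_reads <- max(2L, as.integer(round(
        row$n_reads * nchar(row$sequence) / total)))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("contig_set", "data.frame"))
}

#' Remove exactly redundant contigs (100% identity, either strand)
#'
#' Merges contig sets (typically from two assembly parameter settings) and
#' removes exact duplicates and exact substrings on either strand, keeping
#' the longest representative. Output is sorted by (marker, descending
#' length, id). Idempotent.
#'
#' @param ... one or more `contig_set` data.frames.
#' @return de-duplicated `contig_set`.
#' @export
dedup_identical <- function(...) {
  contigs <- do.call(rbind, list(...))
  if (!nrow(contigs))
    return(structure(contigs, class = c("contig_set", "data.frame")))
  contigs <- contigs[order(contigs$marker, -nchar(contigs$sequence),
                           contigs$id, method = "radix"), , drop = FALSE]
  keep <- logical(nrow(contigs))
  for (m in unique(contigs$marker)) {
    idx <- which(contigs$marker == m)
    keep[idx] <- !contained_in_earlier_cpp(contigs$sequence[idx])
  }
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contig_set", "data.frame"))
}

#' Write contigs as FASTA with support and parameter tag in the header
#' @param contigs a `contig_set`.
#' @param path output FASTA path.
#' @export
write_contigs <- function(contigs, path) {
  s <- Biostrings::DNAStringSet(contigs$sequence)
  names(s) <- sprintf("%s n_reads=%d param=%s%s", contigs$id, contigs$n_reads,
                      contigs$param_tag,
                      ifelse(contigs$collapse_warning, " collapse_warning", ""))
  Biostrings::writeXStringSet(s, path, width = 80L)
  invisible(path)
}
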