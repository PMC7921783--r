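## ---------------------------------------------------------------------------
## Quality trimming and k-mer enrichment of barcode-bearing read pairs
## ---------------------------------------------------------------------------

#' Quality-trim read pairs
#'
#' Trims 3' bases while their Phred+33 quality is below `min_quality` and
#' drops a pair when either trimmed mate is shorter than `min_length`.
#' Input order is preserved.
#'
#' @param pairs data.frame with columns `id`, `seq1`, `seq2`, `qual1`,
#'   `qual2` (see [read_fastq_pairs()]).
#' @param min_quality Phred threshold, between 2 and 40.
#' @param min_length minimum surviving mate length (bp).
#' @return the trimmed pairs data.frame.
#' @export
quality_trim_reads <- function(pairs, min_quality = 20L, min_length = 50L) {
  if (min_quality < 2 || min_quality > 40)
    stop("min_quality must lie in [2, 40]", call. = FALSE)
  if (!nrow(pairs)) return(pairs)
  bad <- which(nchar(pairs$seq1) != nchar(pairs$qual1) |
               nchar(pairs$seq2) != nchar(pairs$qual2))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1],
         ": sequence/quality length mismatch", call. = FALSE)
  k1 <- quality_keep_length_cpp(pairs$qual1, as.integer(min_quality))
  k2 <- quality_keep_length_cpp(pairs$qual2, as.integer(min_quality))
  out <- data.frame(id = pairs$id,
                    seq1 = substr(pairs$seq1, 1L, k1),
                    seq2 = substr(pairs$seq2, 1L, k2),
                    qual1 = substr(pairs$qual1, 1L, k1),
                    qual2 = substr(pairs$qual2, 1L, k2),
                    stringsAsFactors = FALSE)
  out[k1 >= min_length & k2 >= min_length, , drop = FALSE]
}

#' Enrich read pairs by shared canonical k-mers per marker
#'
#' A pair is retained for marker `m` when the union of canonical k-mers of
#' both mates shares at least `min_shared_kmers` keys with `m`'s bucket of
#' the reference index. A pair may be retained for several markers; the
#' retained set shrinks (weakly) as `min_shared_kmers` grows.
#'
#' @param pairs read-pair data.frame (post-trimming).
#' @param index a [build_kmer_index()] over the barcode reference database.
#' @param min_shared_kmers minimum number of distinct shared canonical
#'   k-mers, >= 1.
#' @return object of class `enriched_pairs`: list with `pairs` (retained
#'   rows), `counts` (integer matrix pairs x markers of shared k-mers) and
#'   the thresholds used.
#' @export
enrich_read_pairs <- function(pairs, index, min_shared_kmers = 3L) {
  stopifnot(inherits(index, "kmer_index"), min_shared_kmers >= 1)
  marker_levels <- intersect(KNOWN_MARKERS, unique(unlist(index$markers)))
  if (!nrow(pairs)) {
    counts <- matrix(0L, 0, length(marker_levels),
                     dimnames = list(NULL, marker_levels))
    return(structure(list(pairs = pairs, counts = counts,
                          min_shared_kmers = as.integer(min_shared_kmers),
                          k = index$k),
                     class = "enriched_pairs"))
  }
  key_markers <- lapply(index$markers,
                        function(m) match(m, marker_levels))
  counts <- enrich_counts_cpp(pairs$seq1, pairs$seq2, index$keys, key_markers,
                              length(marker_levels), index$k)
  colnames(counts) <- marker_levels
  keep <- rowSums(counts >= min_shared_kmers) > 0L
  structure(list(pairs = pairs[keep, , drop = FALSE],
                 counts = counts[keep, , drop = FALSE],
                 min_shared_kmers = as.integer(min_shared_kmers),
                 k = index$k),
            class = "enriched_pairs")
}

#' @export
print.enriched_pairs <- function(x, ...) {
  cat("Enriched read pairs:", nrow(x$pairs),
      sprintf("(k = %d, min shared k-mers = %d)\n", x$k, x$min_shared_kmers))
  print(enrichment_summary(x))
  invisible(x)
}

#' Markers attached to each enriched pair
#' @param x an `enriched_pairs`.
#' @return list (one element per retained pair) of marker name vectors.
#' @export
pair_markers <- function(x) {
  stopifnot(inherits(x, "enriched_pairs"))
  apply(x$counts >= x$min_shared_kmers, 1L,
        function(r) colnames(x$counts)[r], simplify = FALSE)
}

#' Subset the enriched pairs belonging to one marker's pool
#' @param x an `enriched_pairs`.
#' @param marker marker name.
#' @return read-pair data.frame for that marker (pairs matching several
#'   markers appear in every matching pool).
#' @export
marker_pool <- function(x, marker) {
  stopifnot(inherits(x, "enriched_pairs"))
  if (!marker %in% colnames(x$counts))
    return(x$pairs[0, , drop = FALSE])
  x$pairs[x$counts[, marker] >= x$min_shared_kmers, , drop = FALSE]
}

#' Per-marker enrichment summary
#' @param x an `enriched_pairs`.
#' @return data.frame with columns `marker`, `pairs_retained`.
#' @export
enrichment_summary <- function(x) {
  stopifnot(inherits(x, "enriched_pairs"))
  data.frame(marker = colnames(x$counts),
             pairs_retained = as.integer(
               colSums(x$counts >= x$min_shared_kmers)),
             row.names = NULL)
}
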