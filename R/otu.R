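## ---------------------------------------------------------------------------
## OTU clustering, read-back mapping, depth/coverage QC, evenness diagnostic
## ---------------------------------------------------------------------------

#' Global-alignment identity between two sequences
#'
#' Identity = matching columns / alignment columns, end gaps penalized
#' (Needleman-Wunsch, match +1 / mismatch -1 / gap open 2 / extend 0.5).
#' This is the identity used for OTU clustering, where the definition
#' decides membership at the 99-100% boundary.
#'
#' @param a,b DNA sequences (character).
#' @return identity fraction in `[0, 1]`.
#' @export
identity_global <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  mean(p == s)
}

#' Greedy centroid OTU clustering at a fixed identity
#'
#' Candidates are sorted by (descending read support, descending length,
#' id) and each joins the first existing centroid whose global-alignment
#' identity reaches the threshold, otherwise founds a new centroid. The
#' representative is the founding centroid, so clustering is deterministic.
#' At identity 1.0 this is exactly grouping of identical strings.
#'
#' @param barcodes barcode data.frame for one marker (columns `contig_id`,
#'   `marker`, `sequence`, `n_reads`).
#' @param identity clustering identity threshold in `[0.9, 1.0]`.
#' @return data.frame of class `otu_set`: `otu_id`, `marker`,
#'   `representative`, `support` (total reads), `n_members`, plus a
#'   `members` list-column.
#' @export
cluster_otus <- function(barcodes, identity = 1.0) {
  if (identity < 0.9 || identity > 1.0)
    stop("clustering identity must lie in [0.9, 1.0]", call. = FALSE)
  if (length(unique(barcodes$marker)) > 1L)
    stop("cluster_otus requires a single marker; got: ",
         paste(unique(barcodes$marker), collapse = ", "), call. = FALSE)
  empty <- data.frame(otu_id = character(0), marker = character(0),
                      representative = character(0), support = integer(0),
                      n_members = integer(0))
  empty$members <- list()
  if (!nrow(barcodes))
    return(structure(empty, class = c("otu_set", "data.frame")))
  sup <- barcodes$n_reads
  sup[is.na(sup)] <- 0L
  ord <- order(-sup, -nchar(barcodes$sequence), barcodes$contig_id,
               method = "radix")
  barcodes <- barcodes[ord, , drop = FALSE]
  sup <- sup[ord]
  centroid <- integer(0)                # row index of each centroid
  assign_to <- integer(nrow(barcodes))
  for (i in seq_len(nrow(barcodes))) {
    hit <- 0L
    for (ci in seq_along(centroid)) {
      ident <- if (identity >= 1.0) {
        as.numeric(barcodes$sequence[i] == barcodes$sequence[centroid[ci]])
      } else {
        identity_global(barcodes$sequence[i], barcodes$sequence[centroid[ci]])
      }
      if (ident >= identity) { hit <- ci; break }
    }
    if (hit == 0L) { centroid <- c(centroid, i); hit <- length(centroid) }
    assign_to[i] <- hit
  }
  marker <- barcodes$marker[1]
  out <- data.frame(
    otu_id = sprintf("%s_OTU%03d", marker, seq_along(centroid)),
    marker = marker,
    representative = barcodes$sequence[centroid],
    support = as.integer(vapply(seq_along(centroid), function(ci)
      sum(sup[assign_to == ci]), numeric(1))),
    n_members = as.integer(tabulate(assign_to, length(centroid))),
    stringsAsFactors = FALSE)
  out$members <- lapply(seq_along(centroid), function(ci)
    barcodes$contig_id[assign_to == ci])
  structure(out, class = c("otu_set", "data.frame"))
}

#' Map read pairs back to OTU representatives
#'
#' Each mate is placed by exact seed-and-extend ungapped alignment (seeds of
#' `seed_k` bp at the read ends and middle, best placement with at most
#' `max_mismatch` mismatches). Ties across OTUs are resolved per
#' `multimap_mode`: `"random"` draws one target with the seeded generator
#' (the mechanism behind conserved-region false positives), `"all"` counts
#' the mate in every tied target. Depth is incremented over aligned
#' positions.
#'
#' @param pairs read-pair data.frame.
#' @param otus an `otu_set`.
#' @param seed_k seed length; must not exceed the read length.
#' @param multimap_mode `"random"` or `"all"`.
#' @param rng_seed integer seed for the random mode (`NULL` uses the current
#'   RNG state).
#' @param max_mismatch maximum mismatches per placed mate.
#' @param min_aligned minimum aligned length per placement (bp).
#' @return data.frame of class `mapping_profile_set`: `otu_id`, `length`,
#'   `n_pairs_mapped`, `mean_depth`, `coverage`, plus a `depth` list-column
#'   of per-position integer vectors.
#' @export
map_read_pairs <- function(pairs, otus, seed_k = 21L,
                           multimap_mode = c("random", "all"),
                           rng_seed = NULL, max_mismatch = 3L,
                           min_aligned = 30L) {
  multimap_mode <- match.arg(multimap_mode)
  if (nrow(pairs) && seed_k > min(nchar(c(pairs$seq1, pairs$seq2))))
    stop("seed_k exceeds the shortest read length", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  reads <- c(rbind(pairs$seq1, pairs$seq2))   # interleaved, pair-major
  pair_of <- rep(seq_len(nrow(pairs)), each = 2L)
  res <- map_reads_cpp(reads, otus$representative, as.integer(seed_k),
                       as.integer(max_mismatch), multimap_mode == "all",
                       as.integer(min_aligned))
  n_otus <- nrow(otus)
  npairs_mapped <- integer(n_otus)
  if (length(reads)) {
    hit_ref <- unlist(res$assigned)
    hit_pair <- rep(pair_of, lengths(res$assigned))
    if (length(hit_ref)) {
      u <- unique(data.frame(ref = hit_ref, pair = hit_pair))
      tab <- tabulate(u$ref, n_otus)
      npairs_mapped <- as.integer(tab)
    }
  }
  depth <- lapply(res$depth, as.integer)
  out <- data.frame(
    otu_id = otus$otu_id,
    length = nchar(otus$representative),
    n_pairs_mapped = npairs_mapped,
    mean_depth = vapply(depth, function(d) sum(d) / length(d), numeric(1)),
    coverage = vapply(depth, function(d) mean(d >= 1L), numeric(1)),
    stringsAsFactors = FALSE)
  out$depth <- depth
  structure(out, class = c("mapping_profile_set", "data.frame"))
}

#' QC thresholds for OTU filtering and the evenness diagnostic
#'
#' @param max_removed_depth OTUs with mean per-base depth at or below this
#'   are removed.
#' @param max_removed_coverage OTUs with coverage at or below this fraction
#'   are removed.
#' @param evenness_window window width (bp) for the coverage-evenness
#'   diagnostic.
#' @param evenness_ratio max-window / median-window depth ratio at or above
#'   which a profile is flagged.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_removed_depth = 3, max_removed_coverage = 0.95,
                          evenness_window = 30L, evenness_ratio = 50) {
  stopifnot(max_removed_depth > 0, max_removed_coverage > 0,
            evenness_window > 0, evenness_ratio > 0)
  structure(list(max_removed_depth = max_removed_depth,
                 max_removed_coverage = max_removed_coverage,
                 evenness_window = as.integer(evenness_window),
                 evenness_ratio = evenness_ratio),
            class = "qc_thresholds")
}

#' Remove poor-quality OTUs by depth and coverage
#'
#' An OTU is removed when its representative's mean sequencing depth is
#' `<= max_removed_depth` or its coverage is `<= max_removed_coverage`
#' (inclusive bounds). Kept and removed sets partition the input; removal
#' reasons are recorded.
#'
#' @param otus an `otu_set`.
#' @param profiles a `mapping_profile_set`, one profile per OTU.
#' @param thresholds a [qc_thresholds()].
#' @return list with `kept` (an `otu_set`) and `removed` (data.frame with
#'   `otu_id`, `mean_depth`, `coverage`, `reason`).
#' @export
qc_filter <- function(otus, profiles, thresholds = qc_thresholds()) {
  miss <- setdiff(otus$otu_id, profiles$otu_id)
  if (length(miss))
    stop("no mapping profile for OTU: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pr <- profiles[match(otus$otu_id, profiles$otu_id), ]
  low_depth <- pr$mean_depth <= thresholds$max_removed_depth
  low_cov <- pr$coverage <= thresholds$max_removed_coverage
  removed <- low_depth | low_cov
  reason <- ifelse(low_depth & low_cov, "depth;coverage",
                   ifelse(low_depth, "depth", "coverage"))
  kept <- otus[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = structure(kept, class = c("otu_set", "data.frame")),
       removed = data.frame(otu_id = otus$otu_id[removed],
                            mean_depth = pr$mean_depth[removed],
                            coverage = pr$coverage[removed],
                            reason = reason[removed],
                            stringsAsFactors = FALSE))
}

#' Coverage-evenness false-positive diagnostic
#'
#' Computes windowed mean depths over a representative and flags the profile
#' as suspicious when the maximum window exceeds the median window (floored
#' at 1) by at least `evenness_ratio`. A high-depth window abutting a
#' sequence end is the signature of multi-mapping reads piling onto a
#' retained conserved flank (e.g. 28S) rather than the diagnostic interior.
#'
#' @param profile one-row `mapping_profile_set` (uses the `depth` vector).
#' @param thresholds a [qc_thresholds()].
#' @param flags annotation flags of the OTU's representative (character),
#'   reported alongside.
#' @return list: `flagged`, `ratio`, `max_window`, `n_windows`,
#'   `tail_end_signature`, `flags`, `window_means`.
#' @export
evenness_diagnostic <- function(profile, thresholds = qc_thresholds(),
                                flags = character(0)) {
  d <- profile$depth[[1]]
  w <- thresholds$evenness_window
  if (length(d) < 2L * w)
    stop("profile must span at least two evenness windows", call. = FALSE)
  idx <- ceiling(seq_along(d) / w)
  means <- as.numeric(tapply(d, idx, mean))
  ratio <- max(means) / max(1, median(means))
  mx <- which(means == max(means))
  list(flagged = ratio >= thresholds$evenness_ratio,
       ratio = ratio,
       max_window = mx[1],
       n_windows = length(means),
       tail_end_signature = 1L %in% mx || length(means) %in% mx,
       flags = flags,
       window_means = means)
}

#' Write OTU representatives as FASTA
#' @param otus an `otu_set`.
#' @param path output path.
#' @export
write_otus <- function(otus, path) {
  s <- Biostrings::DNAStringSet(otus$representative)
  names(s) <- sprintf("%s support=%d members=%d", otus$otu_id, otus$support,
                      otus$n_members)
  Biostrings::writeXStringSet(s, path, width = 80L)
  invisible(path)
}

#' Write mapping profiles as TSV
#' @param profiles a `mapping_profile_set`.
#' @param path output path.
#' @export
write_profiles <- function(profiles, path) {
  write.table(profiles[, c("otu_id", "length", "n_pairs_mapped",
                           "mean_depth", "coverage")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
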