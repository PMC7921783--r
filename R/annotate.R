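## ---------------------------------------------------------------------------
## Barcode annotation: motif-anchored ITS2, primer-anchored plastid markers,
## conserved-tail trimming and de novo chimera screening
## ---------------------------------------------------------------------------

#' Construct a position weight matrix motif model
#'
#' Anchored flank motifs stand in for a full profile HMM: deterministic,
#' trainable from known flanks, and sufficient to locate the conserved
#' 5.8S-end / 28S-start boundaries of ITS2.
#'
#' @param name motif name (`"5.8S-end"` or `"28S-start"`).
#' @param pwm 4 x L probability matrix, rows `A`,`C`,`G`,`T`, columns
#'   summing to 1; L between 12 and 25.
#' @param threshold log-odds score (base 2, uniform background) above which
#'   a hit is accepted.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(name, pwm, threshold) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
  if (ncol(pwm) < 12 || ncol(pwm) > 25)
    stop("motif length must be between 12 and 25", call. = FALSE)
  if (max(abs(colSums(pwm) - 1)) > 1e-6)
    stop("PWM columns must sum to 1", call. = FALSE)
  stopifnot(is.finite(threshold))
  rownames(pwm) <- DNA_BASES
  structure(list(name = name, pwm = pwm, threshold = threshold,
                 width = ncol(pwm)),
            class = "motif_model")
}

#' Build a motif model from a consensus sequence
#'
#' @param name motif name.
#' @param consensus flank consensus sequence.
#' @param match_prob probability mass on the consensus base per column.
#' @param threshold_frac acceptance threshold as a fraction of the maximum
#'   attainable score.
#' @return a `motif_model`.
#' @export
motif_from_consensus <- function(name, consensus, match_prob = 0.85,
                                 threshold_frac = 0.8) {
  ch <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(ch %in% DNA_BASES))
  pwm <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(ch),
                dimnames = list(DNA_BASES, NULL))
  pwm[cbind(match(ch, DNA_BASES), seq_along(ch))] <- match_prob
  max_score <- length(ch) * log2(match_prob / 0.25)
  motif_model(name, pwm, threshold = threshold_frac * max_score)
}

#' Default ITS2 flank motifs (5.8S end, 28S start)
#' @return list with elements `five` and `three`.
#' @export
default_flank_motifs <- function() {
  list(five = motif_from_consensus("5.8S-end", MOTIF_5_8S_END),
       three = motif_from_consensus("28S-start", MOTIF_28S_START))
}

## best-scoring motif hit on a single strand; log2 odds vs uniform background
scan_motif <- function(seq, motif) {
  lo <- log2(pmax(motif$pwm, 1e-9) / 0.25)
  hit <- pwm_best_hit_cpp(seq, lo)
  list(score = hit[1], start = as.integer(hit[2]))
}

barcode_row <- function(contig_id, marker, sequence, start, end, strand,
                        flags, n_reads = NA_integer_) {
  data.frame(contig_id = contig_id, marker = marker, sequence = sequence,
             start = start, end = end, strand = strand,
             flags = paste(flags, collapse = ";"),
             n_reads = n_reads, stringsAsFactors = FALSE)
}

#' Extract the ITS2 interior of a contig via its conserved flank motifs
#'
#' Locates the best 5.8S-end and 28S-start motif hits on either strand and
#' returns the interior between them when both pass their thresholds and the
#' interior length lies in `[100, 600]` bp. Anything 3' of the 28S-start hit
#' is removed; when removed sequence extends beyond the motif itself the
#' `conserved_tail_trimmed` flag is set (the retained-28S false-positive
#' fix). A sub-threshold but recognizable 28S hit (at least
#' `tail_threshold_frac` of the threshold) is still used as a trimming
#' anchor; with no usable 28S hit the interior runs to the contig end,
#' flagged `partial`. Coordinates are 0-based half-open on the input contig.
#'
#' @param contig one-row `contig_set` data.frame (or list with `id`,
#'   `sequence`, `n_reads`).
#' @param motifs list with `five` and `three` motif models,
#'   [default_flank_motifs()].
#' @param tail_threshold_frac fraction of the 28S threshold accepted for
#'   tail-trimming anchors; 0 disables weak-anchor trimming.
#' @param interior_range admissible interior length range (bp).
#' @return one-row barcode data.frame, or `NULL` when no 5.8S motif passes.
#' @export
extract_its2 <- function(contig, motifs = default_flank_motifs(),
                         tail_threshold_frac = 0.5,
                         interior_range = c(100L, 600L)) {
  seq <- toupper(contig$sequence[[1]])
  id <- contig$id[[1]]
  n_reads <- if (!is.null(contig$n_reads)) contig$n_reads[[1]] else NA_integer_
  L <- nchar(seq)

  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    h5 <- scan_motif(s, motifs$five)
    if (h5$score < motifs$five$threshold) next
    int_start <- h5$start + motifs$five$width    # 1-based first interior base
    tail_part <- if (int_start <= L) substr(s, int_start, L) else ""
    h3 <- if (nchar(tail_part) >= motifs$three$width)
      scan_motif(tail_part, motifs$three) else list(score = -Inf, start = NA)
    flags <- character(0)
    if (is.finite(h3$score) && h3$score >= motifs$three$threshold) {
      int_end <- int_start + h3$start - 2L       # last interior base
      removed <- L - (int_end + motifs$three$width)
      if (removed > 0) flags <- c(flags, "conserved_tail_trimmed")
    } else if (tail_threshold_frac > 0 && is.finite(h3$score) &&
               h3$score >= tail_threshold_frac * motifs$three$threshold) {
      int_end <- int_start + h3$start - 2L
      flags <- c(flags, "conserved_tail_trimmed")
    } else {
      int_end <- L
      flags <- c(flags, "partial")
    }
    ilen <- int_end - int_start + 1L
    if (!("partial" %in% flags) &&
        (ilen < interior_range[1] || ilen > interior_range[2])) next
    if (ilen < 1L) next
    cand <- list(strand = strand, int_start = int_start, int_end = int_end,
                 flags = flags, score = h5$score + max(h3$score, 0),
                 oriented = s)
    if (is.null(best) || cand$score > best$score ||
        (length(best$flags) > 0 && !length(cand$flags))) best <- cand
  }
  if (is.null(best)) return(NULL)
  interior <- substr(best$oriented, best$int_start, best$int_end)
  ## coordinates on the original contig (0-based half-open)
  if (best$strand == "+") {
    start0 <- best$int_start - 1L; end0 <- best$int_end
  } else {
    start0 <- L - best$int_end; end0 <- L - best$int_start + 1L
  }
  barcode_row(id, "ITS2", interior, start0, end0, best$strand, best$flags,
              n_reads)
}

## all primer hit positions with <= max.mismatch substitutions (no indels)
primer_hits <- function(primer, subject, max_mismatch) {
  m <- Biostrings::matchPattern(primer, Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = "subject")
  data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
}

#' Trim a plastid contig to the interior between its primer binding sites
#'
#' The forward and reverse primers are located on either strand allowing up
#' to `primers$max_mismatch` substitutions (no indels; IUPAC codes in the
#' primer match their base class). Both primers found: the interior between
#' them is returned. One primer: interior to the contig end, flagged
#' `partial` and `untrimmed_primer`. None: `NULL`.
#'
#' @param contig one-row `contig_set` data.frame.
#' @param primers a [primer_set()].
#' @return one-row barcode data.frame or `NULL`.
#' @export
trim_plastid_primers <- function(contig, primers) {
  stopifnot(inherits(primers, "primer_set"))
  seq <- toupper(contig$sequence[[1]])
  id <- contig$id[[1]]
  marker <- if (!is.null(contig$marker)) contig$marker[[1]] else NA_character_
  n_reads <- if (!is.null(contig$n_reads)) contig$n_reads[[1]] else NA_integer_
  L <- nchar(seq)
  mm <- primers$max_mismatch
  rev_rc <- revcomp(primers$reverse)

  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    fh <- primer_hits(primers$forward, s, mm)
    rh <- primer_hits(rev_rc, s, mm)
    cand <- NULL
    if (nrow(fh) && nrow(rh)) {
      f <- fh[which.min(fh$start), ]
      r <- rh[rh$start > f$end, , drop = FALSE]
      if (nrow(r)) {
        r <- r[which.max(r$start), ]
        cand <- list(int_start = f$end + 1L, int_end = r$start - 1L,
                     flags = character(0), score = 2)
      }
    }
    if (is.null(cand) && nrow(fh)) {
      f <- fh[which.min(fh$start), ]
      cand <- list(int_start = f$end + 1L, int_end = L,
                   flags = c("partial", "untrimmed_primer"), score = 1)
    }
    if (is.null(cand) && nrow(rh)) {
      r <- rh[which.max(rh$start), ]
      cand <- list(int_start = 1L, int_end = r$start - 1L,
                   flags = c("partial", "untrimmed_primer"), score = 1)
    }
    if (is.null(cand)) next
    if (cand$int_end < cand$int_start) next
    cand$strand <- strand
    cand$oriented <- s
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (is.null(best)) return(NULL)
  interior <- substr(best$oriented, best$int_start, best$int_end)
  if (best$strand == "+") {
    start0 <- best$int_start - 1L; end0 <- best$int_end
  } else {
    start0 <- L - best$int_end; end0 <- L - best$int_start + 1L
  }
  barcode_row(id, marker, interior, start0, end0, best$strand, best$flags,
              n_reads)
}

#' Annotate a contig set: ITS2 by motifs, plastid markers by primers
#'
#' @param contigs a `contig_set`.
#' @param markers marker registry ([default_markers()]).
#' @param keep_partial keep single-anchor (`partial`) barcodes? The default
#'   drops them: an unanchored end means the diagnostic interior is not
#'   delimited (and is how AT-repeat assembly failures are excluded).
#' @param ... passed to [extract_its2()].
#' @return barcode data.frame (possibly 0 rows).
#' @export
annotate_contigs <- function(contigs, markers = default_markers(),
                             keep_partial = FALSE, ...) {
  rows <- list()
  for (i in seq_len(nrow(contigs))) {
    ctg <- contigs[i, , drop = FALSE]
    m <- ctg$marker[[1]]
    b <- if (m == "ITS2") {
      extract_its2(ctg, markers[["ITS2"]]$flank_motifs, ...)
    } else if (m %in% names(markers)) {
      trim_plastid_primers(ctg, markers[[m]]$primer_set)
    } else NULL
    if (!is.null(b)) rows[[length(rows) + 1L]] <- b
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    barcode_row(character(0), character(0), character(0), integer(0),
                integer(0), character(0), character(0))[0, ]
  if (!keep_partial && nrow(out))
    out <- out[!grepl("partial", out$flags), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## per-candidate-position match indicators against each parent (banded
## global alignment in C++; candidate gap columns ignored)
match_profiles <- function(candidate, parents) {
  chimera_match_profiles_cpp(candidate, parents)
}

#' De novo two-parent chimera detection
#'
#' Single-breakpoint model: a candidate is chimeric when some ordered parent
#' pair (A, B) and breakpoint `p` give segment identities
#' `identity(cand[0:p], A) >= min_parent_identity` and
#' `identity(cand[p:], B) >= min_parent_identity`, the two-segment model
#' explains at least `min_gain` more matching columns than the best single
#' parent, and each parent has read support at least the candidate's
#' (abundance rule: chimeras cannot out-number their parents).
#'
#' @param candidate one-row barcode data.frame (uses `sequence`, `n_reads`).
#' @param pool barcode data.frame of potential parents (candidate excluded).
#' @param min_parent_identity per-segment identity threshold.
#' @param min_gain minimum extra matching columns over the best single
#'   parent.
#' @param max_parents parent search is limited to this many most-abundant
#'   eligible pool members (chimeras arise between abundant templates).
#' @return list (`chimera_verdict`): `candidate`, `is_chimera`, `parents`,
#'   `breakpoint`, `score`.
#' @export
detect_chimera <- function(candidate, pool, min_parent_identity = 0.99,
                           min_gain = 4L, max_parents = 20L) {
  cand_id <- candidate$contig_id[[1]] %||% NA_character_
  verdict <- function(is_chim, parents = NULL, breakpoint = NULL, score = 0)
    structure(list(candidate = cand_id, is_chimera = is_chim,
                   parents = parents, breakpoint = breakpoint, score = score),
              class = "chimera_verdict")
  if (is.null(pool) || !nrow(pool)) return(verdict(FALSE))
  cand_seq <- candidate$sequence[[1]]
  cand_sup <- candidate$n_reads[[1]]
  if (is.na(cand_sup)) cand_sup <- 0L
  L <- nchar(cand_seq)

  eligible <- which(is.na(pool$n_reads) | pool$n_reads >= cand_sup)
  if (!length(eligible)) return(verdict(FALSE))
  if (length(eligible) > max_parents) {
    sup <- pool$n_reads[eligible]
    sup[is.na(sup)] <- 0L
    eligible <- eligible[order(-sup, pool$contig_id[eligible],
                               method = "radix")[seq_len(max_parents)]]
  }
  profs <- match_profiles(cand_seq, pool$sequence[eligible])
  lens <- lengths(profs)
  if (any(lens != L)) profs <- lapply(profs, function(p) {
    length(p) <- L; p[is.na(p)] <- FALSE; p
  })
  cums <- lapply(profs, cumsum)
  tots <- vapply(cums, function(x) x[L], numeric(1))
  best_single <- max(tots)

  best <- list(score = -Inf)
  for (a in seq_along(eligible)) for (b in seq_along(eligible)) {
    if (a == b) next
    ## matches of the A|B model as a function of breakpoint p (1..L-1)
    p <- seq_len(L - 1L)
    total <- cums[[a]][p] + (tots[b] - cums[[b]][p])
    ok <- (cums[[a]][p] / p >= min_parent_identity) &
      ((tots[b] - cums[[b]][p]) / (L - p) >= min_parent_identity)
    if (!any(ok)) next
    mx <- max(total[ok])
    if (mx > best$score) {
      at <- p[ok & total == mx]
      best <- list(score = mx, a = a, b = b, bp = at[ceiling(length(at) / 2)])
    }
  }
  gain <- best$score - best_single
  if (is.finite(best$score) && gain >= min_gain) {
    ids <- pool$contig_id[eligible[c(best$a, best$b)]]
    return(verdict(TRUE, parents = ids, breakpoint = best$bp, score = gain))
  }
  verdict(FALSE, score = max(0, gain))
}

#' Screen a barcode set for chimeras
#'
#' Runs [detect_chimera()] for every barcode against the rest of its
#' marker's pool.
#'
#' @param barcodes barcode data.frame.
#' @inheritParams detect_chimera
#' @return data.frame with columns `contig_id`, `marker`, `is_chimera`,
#'   `parents`, `breakpoint`, `score`.
#' @export
screen_chimeras <- function(barcodes, min_parent_identity = 0.99,
                            min_gain = 4L, max_parents = 20L) {
  n <- nrow(barcodes)
  out <- data.frame(contig_id = barcodes$contig_id,
                    marker = barcodes$marker,
                    is_chimera = logical(n), parents = NA_character_,
                    breakpoint = NA_integer_, score = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pool <- barcodes[barcodes$marker == barcodes$marker[i] &
                       seq_len(n) != i, , drop = FALSE]
    v <- detect_chimera(barcodes[i, , drop = FALSE], pool,
                        min_parent_identity, min_gain, max_parents)
    out$is_chimera[i] <- v$is_chimera
    out$score[i] <- v$score
    if (v$is_chimera) {
      out$parents[i] <- paste(v$parents, collapse = ";")
      out$breakpoint[i] <- v$breakpoint
    }
  }
  out
}
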