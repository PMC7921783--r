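## ---------------------------------------------------------------------------
## Synthetic shotgun library generator: species panel + paired reads + truth
## ---------------------------------------------------------------------------

#' Default marker interior lengths and GC content
#'
#' Interior (primer/flank-free) lengths and base composition used when a
#' divergence specification does not override them. Values are typical for
#' plant barcodes recovered from herbal products: a short GC-rich ITS2, an
#' AT-rich psbA-trnH spacer, and long matK/rbcL coding regions.
#' @export
default_marker_lengths <- function() {
  c("ITS2" = 208L, "psbA-trnH" = 321L, "matK" = 836L, "rbcL" = 703L)
}

default_marker_gc <- function() {
  c("ITS2" = 0.544, "psbA-trnH" = 0.322, "matK" = 0.347, "rbcL" = 0.441)
}

#' Construct a divergence specification for a synthetic species panel
#'
#' Describes the taxa to simulate and, per marker, the target pairwise
#' sequence identities between them. Identities must be realizable on a star
#' topology (per-taxon branch lengths `b` with `b_i + b_j ~= 1 - identity_ij`);
#' incompatible matrices are rejected. Taxa of kingdom `Fungi` carry only
#' ITS2 (plus genomic background).
#'
#' @param taxa data.frame with columns `species`, `genus`, `family`,
#'   `kingdom`.
#' @param identity named list, marker -> symmetric identity matrix with unit
#'   diagonal and dimnames = species (taxa missing from a matrix default to
#'   the `baseline_identity` against everything).
#' @param baseline_identity identity assumed between taxa not covered by an
#'   explicit matrix entry (unrelated families).
#' @param at_rich_loci data.frame with columns `species`, `marker`,
#'   `at_fraction` (>= 0.70): loci rebuilt AT-rich with a >= 20 bp
#'   AT-dinucleotide tandem repeat.
#' @param marker_lengths named integer vector of interior lengths.
#' @return object of class `divergence_spec`.
#' @export
divergence_spec <- function(taxa, identity = list(), baseline_identity = 0.70,
                            at_rich_loci = NULL,
                            marker_lengths = default_marker_lengths()) {
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "genus", "family", "kingdom") %in% names(taxa)))
  if (anyDuplicated(taxa$species)) stop("duplicate species in panel", call. = FALSE)
  for (m in names(identity)) {
    M <- identity[[m]]
    if (!isTRUE(all.equal(M, t(M))) || any(diag(M) != 1))
      stop("identity matrix for ", m, " must be symmetric with unit diagonal",
           call. = FALSE)
    off <- M[upper.tri(M)]
    if (length(off) && (any(off < 0.5) || any(off > 1)))
      stop("target identities must lie in [0.5, 1]", call. = FALSE)
  }
  stopifnot(baseline_identity >= 0.5, baseline_identity <= 1)
  if (!is.null(at_rich_loci)) {
    at_rich_loci <- as.data.frame(at_rich_loci)
    stopifnot(all(c("species", "marker", "at_fraction") %in% names(at_rich_loci)))
  }
  structure(list(taxa = taxa, identity = identity,
                 baseline_identity = baseline_identity,
                 at_rich_loci = at_rich_loci,
                 marker_lengths = marker_lengths),
            class = "divergence_spec")
}

## Solve star-tree branch lengths b (>= 0) for a pairwise distance matrix:
## d_ij ~ b_i + b_j (least squares). Residuals beyond `tol` mean the identity
## matrix is not realizable on a star topology.
solve_star_branches <- function(D, tol = 0.005) {
  n <- nrow(D)
  if (n == 1L) return(0)
  if (n == 2L) return(rep(D[1, 2] / 2, 2))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), n)
  A[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  A[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 1
  b <- as.numeric(stats::coef(stats::lm.fit(A, D[upper.tri(D)])))
  b[b < 0] <- 0
  resid <- abs(A %*% b - D[upper.tri(D)])
  if (max(resid) > tol)
    stop("infeasible identity matrix: pairwise targets violate additivity ",
         sprintf("(max residual %.4f > %.4f)", max(resid), tol), call. = FALSE)
  b
}

## mutate `seq` at `m` positions drawn from `avail` (removed from the pool)
mutate_at <- function(seq, positions) {
  if (!length(positions)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

make_at_rich_interior <- function(length, at_target, repeat_len = 30L) {
  core <- random_dna(1, length - repeat_len, gc = 1 - at_target)
  rep_seq <- paste(rep(c("A", "T"), length.out = repeat_len), collapse = "")
  at <- floor((length - repeat_len) / 2)
  s <- paste0(substr(core, 1, at), rep_seq, substr(core, at + 1, nchar(core)))
  ## guarantee the target composition: promote G/C to A/T where needed
  ch <- strsplit(s, "")[[1]]
  need <- ceiling(at_target * length) - sum(ch %in% c("A", "T"))
  if (need > 0) {
    gc_pos <- which(ch %in% c("G", "C"))
    flip <- sample(gc_pos, min(need, length(gc_pos)))
    ch[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
    s <- paste(ch, collapse = "")
  }
  s
}

## concrete-base version of an IUPAC primer (first base of each ambiguity set)
concretize_iupac <- function(x) {
  map <- c(R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
           B = "C", D = "A", H = "A", V = "A", N = "A")
  ch <- strsplit(x, "")[[1]]
  amb <- ch %in% names(map)
  ch[amb] <- map[ch[amb]]
  paste(ch, collapse = "")
}

#' Generate a synthetic species panel
#'
#' Builds, per marker, a set of taxon sequences realizing the target pairwise
#' identities of the divergence specification. Taxa explicitly related in an
#' identity matrix (target above the baseline) form groups; within a group a
#' star topology is used, mutating a group ancestor at disjoint position
#' sets per taxon so realized within-group identities match their targets up
#' to rounding (infeasible matrices are rejected). Groups descend from a
#' common root so that cross-group identities land near the baseline
#' (approximately: overlapping mutations are not corrected at that depth).
#' ITS2 interiors are embedded
#' between the conserved 5.8S-end / 28S-start flank motifs (plus conserved
#' lead/tail context); plastid interiors between their primer binding sites.
#' AT-rich loci are rebuilt to their target composition with a >= 20 bp
#' AT-dinucleotide tandem repeat. Every taxon also receives a random
#' `genomic-background` pseudo-locus.
#'
#' @param spec a [divergence_spec()].
#' @param seed integer RNG seed; generation is seed-deterministic.
#' @param markers marker registry, see [default_markers()].
#' @param background_length length of the genomic-background pseudo-locus.
#' @param context genomic context (bp) flanking each plastid locus beyond
#'   its primer sites.
#' @return list with elements `db` (a `reference_db` of full loci) and
#'   `report` (per-marker realized identity matrices, AT statistics and
#'   interior coordinates).
#' @export
generate_species_panel <- function(spec, seed, markers = default_markers(),
                                   background_length = 2000L,
                                   context = 50L) {
  stopifnot(inherits(spec, "divergence_spec"))
  set.seed(as.integer(seed))
  taxa <- spec$taxa
  gc <- default_marker_gc()
  lens <- spec$marker_lengths
  records <- list()
  report <- list(realized_identity = list(), at_rich = NULL, interior = list())

  taxon_code <- sprintf("T%03d", seq_len(nrow(taxa)))
  names(taxon_code) <- taxa$species

  for (m in BARCODE_MARKERS) {
    has_marker <- if (m == "ITS2") rep(TRUE, nrow(taxa)) else
      taxa$kingdom == "Viridiplantae"
    sp <- taxa$species[has_marker]
    if (!length(sp)) next
    L <- as.integer(lens[[m]])

    ## target identity matrix over the taxa carrying this marker
    M <- matrix(spec$baseline_identity, length(sp), length(sp),
                dimnames = list(sp, sp))
    diag(M) <- 1
    if (!is.null(spec$identity[[m]])) {
      G <- spec$identity[[m]]
      common <- intersect(rownames(G), sp)
      M[common, common] <- G[common, common]
    }
    ## groups: connected components of "related above baseline"
    related <- M > spec$baseline_identity + 0.02
    diag(related) <- TRUE
    grp <- seq_along(sp)
    repeat {
      changed <- FALSE
      for (i in seq_along(sp)) for (j in seq_along(sp)) {
        if (related[i, j] && grp[j] != grp[i]) {
          grp[grp == grp[j]] <- grp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    root <- random_dna(1, L, gc = gc[[m]])
    d_group <- (1 - spec$baseline_identity) / 2
    interiors <- setNames(character(length(sp)), sp)
    for (g in unique(grp)) {
      gi <- which(grp == g)
      b <- solve_star_branches(1 - M[gi, gi, drop = FALSE])
      m_counts <- round(b * L)
      if (sum(m_counts) > L)
        stop("infeasible identity matrix: required divergence exceeds ",
             "locus length for ", m, call. = FALSE)
      m_g <- max(0L, round(L * d_group) - round(mean(m_counts)))
      anc_g <- mutate_at(root, sample.int(L, min(m_g, L)))
      pool <- sample.int(L)                 # disjoint within-group positions
      offset <- 0L
      for (w in seq_along(gi)) {
        take <- if (m_counts[w] > 0)
          pool[(offset + 1):(offset + m_counts[w])] else integer(0)
        offset <- offset + m_counts[w]
        interiors[gi[w]] <- mutate_at(anc_g, take)
      }
    }

    ## AT-rich overrides
    if (!is.null(spec$at_rich_loci)) {
      ar <- spec$at_rich_loci[spec$at_rich_loci$marker == m, , drop = FALSE]
      for (j in seq_len(nrow(ar))) {
        s <- ar$species[j]
        if (!s %in% sp) next
        interiors[[s]] <- make_at_rich_interior(L, ar$at_fraction[j])
      }
    }

    ## realized identities measured on the interiors themselves
    R <- diag(1, length(sp)); dimnames(R) <- list(sp, sp)
    for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
      a <- strsplit(interiors[i], "")[[1]]; bb <- strsplit(interiors[j], "")[[1]]
      R[i, j] <- R[j, i] <- mean(a == bb)
    }
    report$realized_identity[[m]] <- R

    ## wrap interiors in their genomic context; plastid loci carry random
    ## per-taxon context beyond the primer sites (the genome continues), so
    ## locus ends do not sit at a coverage cliff
    if (m == "ITS2") {
      full <- paste0(CONSERVED_5_8S_LEAD, MOTIF_5_8S_END, interiors,
                     MOTIF_28S_START, CONSERVED_28S_TAIL)
      int_start <- nchar(CONSERVED_5_8S_LEAD) + nchar(MOTIF_5_8S_END)
    } else {
      ps <- markers[[m]]$primer_set
      ctx5 <- random_dna(length(sp), context, gc = gc[[m]])
      ctx3 <- random_dna(length(sp), context, gc = gc[[m]])
      full <- paste0(ctx5, concretize_iupac(ps$forward), interiors,
                     revcomp(concretize_iupac(ps$reverse)), ctx3)
      int_start <- context + nchar(ps$forward)
    }
    report$interior[[m]] <- data.frame(
      species = sp, start = int_start, end = int_start + L)
    records[[m]] <- data.frame(
      id = paste0(taxon_code[sp], "_", m), marker = m, species = sp,
      genus = taxa$genus[match(sp, taxa$species)],
      family = taxa$family[match(sp, taxa$species)],
      kingdom = taxa$kingdom[match(sp, taxa$species)],
      sequence = unname(full), stringsAsFactors = FALSE)
  }

  ## genomic background, one pseudo-locus per taxon
  records[["genomic-background"]] <- data.frame(
    id = paste0(taxon_code, "_bg"), marker = "genomic-background",
    species = taxa$species, genus = taxa$genus, family = taxa$family,
    kingdom = taxa$kingdom,
    sequence = random_dna(nrow(taxa), background_length, gc = 0.38),
    stringsAsFactors = FALSE)

  db <- reference_db(do.call(rbind, records))
  if (!is.null(spec$at_rich_loci)) {
    ar <- spec$at_rich_loci
    key <- paste0(taxon_code[ar$species], "_", ar$marker)
    seqs <- db$records$sequence[match(key, db$records$id)]
    report$at_rich <- data.frame(
      ar, realized_at = at_fraction(seqs),
      longest_at_run = longest_at_dinucleotide_run(seqs))
  }
  list(db = db, report = report)
}

## ---------------------------------------------------------------------------
## formulation + read simulation
## ---------------------------------------------------------------------------

#' Construct a formulation specification
#'
#' The composition of the simulated powdered sample: ingredient species with
#' mass-like fractions, fungal contaminants, an optional positive-control
#' spike, a DNA-degradation fragment-length model and per-locus copy weights.
#' All fractions together must sum to 1.
#'
#' @param ingredients named numeric: species -> fraction.
#' @param contaminants named numeric: fungal species -> fraction.
#' @param spike_species positive-control species or `NULL`.
#' @param spike_fraction fraction for the spike.
#' @param fragment_mean,fragment_sd fragment-length model (bp); normal,
#'   truncated below at `fragment_min`. `fragment_mean` may carry named
#'   per-taxon entries under `degraded` to model severely processed
#'   ingredients.
#' @param fragment_min minimum fragment length; `NA` means "read length",
#'   resolved at simulation time.
#' @param degraded optional named numeric: species -> fragment mean (bp) for
#'   taxa whose DNA is too degraded for the global model. Degraded taxa
#'   draw fragments from a tight distribution (sd = mean / 4, floored at
#'   30 bp) and are subject to library size selection: their fragments
#'   below `min_library_fragment` are lost, so severe degradation depletes
#'   the taxon from the library, as extensive processing does in practice.
#' @param min_library_fragment size-selection cutoff (bp) applied to
#'   degraded taxa's fragments.
#' @param copy_weights named numeric of per-marker copy weights; defaults:
#'   ITS2 10 (multi-copy rDNA), plastid loci 10 each, genomic background 1.
#' @param chimera_rate fraction of fragments built as two-parent chimeras.
#' @return object of class `formulation_spec`.
#' @export
formulation_spec <- function(ingredients, contaminants = numeric(0),
                             spike_species = NULL, spike_fraction = 0,
                             fragment_mean = 180, fragment_sd = 60,
                             fragment_min = NA, degraded = NULL,
                             min_library_fragment = 100L,
                             copy_weights = NULL, chimera_rate = 0.01) {
  stopifnot(is.numeric(ingredients), !is.null(names(ingredients)))
  fr <- c(ingredients, contaminants,
          if (!is.null(spike_species)) setNames(spike_fraction, spike_species))
  if (any(fr < 0)) stop("fractions must be >= 0", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("ingredient + contaminant + spike fractions must sum to 1 (got ",
         format(sum(fr)), ")", call. = FALSE)
  if (is.null(copy_weights))
    copy_weights <- c("ITS2" = 10, "psbA-trnH" = 10, "matK" = 10,
                      "rbcL" = 10, "genomic-background" = 1)
  stopifnot(all(copy_weights > 0), chimera_rate >= 0, chimera_rate <= 1)
  structure(list(ingredients = ingredients, contaminants = contaminants,
                 spike_species = spike_species, spike_fraction = spike_fraction,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 fragment_min = fragment_min, degraded = degraded,
                 min_library_fragment = as.integer(min_library_fragment),
                 copy_weights = copy_weights, chimera_rate = chimera_rate),
            class = "formulation_spec")
}

#' Read-simulation parameters
#'
#' @param n_pairs number of read pairs to emit.
#' @param read_length read length (bp); must not exceed the minimum fragment
#'   length of the global degradation model.
#' @param error_rate per-base substitution error rate, in `[0, 0.05]`.
#' @param quality_model `"constant"` (Q37) or `"decay"` (Q38 falling to Q20
#'   along the read).
#' @return object of class `read_sim_params`.
#' @export
read_sim_params <- function(n_pairs, read_length = 150L, error_rate = 0.01,
                            quality_model = c("constant", "decay")) {
  stopifnot(n_pairs >= 1, read_length >= 30)
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 quality_model = match.arg(quality_model)),
            class = "read_sim_params")
}

quality_string <- function(len, model) {
  q <- if (model == "constant") rep(37L, max(len)) else
    pmax(20L, 38L - floor(seq_len(max(len)) / 10))
  full <- intToUtf8(q + 33L, multiple = FALSE)
  substring(full, 1L, len)
}

#' Simulate a paired-end shotgun library with a per-read truth table
#'
#' Read pairs are drawn taxon-first by formulation fraction, then locus by
#' copy weight; fragment lengths follow the (truncated normal) degradation
#' model; substitution errors are applied per base; a `chimera_rate` fraction
#' of fragments is formed by joining two random same-marker parent windows at
#' a uniform breakpoint. Output is byte-identical for identical seeds.
#'
#' @param panel a `reference_db` from [generate_species_panel()] (or any DB
#'   whose species cover the formulation).
#' @param formulation a [formulation_spec()].
#' @param params a [read_sim_params()].
#' @param seed integer RNG seed.
#' @return object of class `shotgun_sim`: list with `pairs` (data.frame
#'   `id`, `seq1`, `seq2`, `qual1`, `qual2`), `truth` (data.frame `read_id`,
#'   `taxon`, `marker`, `is_chimera`, `parents`), and the inputs.
#' @export
simulate_shotgun_reads <- function(panel, formulation, params, seed) {
  stopifnot(inherits(panel, "reference_db"),
            inherits(formulation, "formulation_spec"),
            inherits(params, "read_sim_params"))
  set.seed(as.integer(seed))
  fr <- c(formulation$ingredients, formulation$contaminants,
          if (!is.null(formulation$spike_species))
            setNames(formulation$spike_fraction, formulation$spike_species))
  fr <- fr[fr > 0]
  taxa <- names(fr)
  missing <- setdiff(taxa, panel$records$species)
  if (length(missing))
    stop("formulation taxa absent from panel: ",
         paste(missing, collapse = ", "), call. = FALSE)

  fmin <- formulation$fragment_min
  if (is.na(fmin)) fmin <- params$read_length
  if (params$read_length > fmin)
    stop("read length exceeds the minimum fragment length", call. = FALSE)

  n <- params$n_pairs
  rl <- params$read_length

  ## locus table: species x marker -> sequence
  rec <- panel$records[panel$records$species %in% taxa, ]
  locus_key <- paste(rec$species, rec$marker, sep = "\r")
  locus_seq <- setNames(rec$sequence, locus_key)
  locus_len <- setNames(nchar(rec$sequence), locus_key)

  ## 1) taxon, then marker by copy weight
  taxon <- sample(taxa, n, replace = TRUE, prob = fr)
  marker <- character(n)
  for (t in taxa) {
    idx <- which(taxon == t)
    if (!length(idx)) next
    mk <- rec$marker[rec$species == t]
    w <- formulation$copy_weights[mk]
    w[is.na(w)] <- 1
    marker[idx] <- if (length(mk) == 1L) mk else
      sample(mk, length(idx), replace = TRUE, prob = w)
  }
  key <- paste(taxon, marker, sep = "\r")
  llen <- locus_len[key]

  ## 2) fragment lengths (per-taxon degraded overrides + size selection)
  fmean <- rep(formulation$fragment_mean, n)
  fsd <- rep(formulation$fragment_sd, n)
  floor_len <- rep(fmin, n)
  deg_hit <- rep(FALSE, n)
  if (!is.null(formulation$degraded)) {
    deg <- formulation$degraded
    deg_hit <- taxon %in% names(deg)
    fmean[deg_hit] <- deg[taxon[deg_hit]]
    fsd[deg_hit] <- fmean[deg_hit] / 4
    floor_len[deg_hit] <- 30L
  }
  flen <- round(rnorm(n, mean = fmean, sd = fsd))
  flen <- pmax(flen, floor_len)
  flen <- pmin(flen, llen)
  ## library size selection: degraded taxa's short fragments are lost
  keep <- !deg_hit | flen >= formulation$min_library_fragment
  if (!all(keep)) {
    taxon <- taxon[keep]; marker <- marker[keep]
    key <- key[keep]; llen <- llen[keep]; flen <- flen[keep]
    n <- sum(keep)
  }

  ## 3) fragment windows; chimeric fragments join two same-marker parents
  start <- floor(runif(n, min = 0, max = llen - flen + 1)) + 1L
  frag <- substring(locus_seq[key], start, start + flen - 1L)
  is_chim <- runif(n) < formulation$chimera_rate &
    marker != "genomic-background"
  parents <- rep(NA_character_, n)
  if (any(is_chim)) {
    for (i in which(is_chim)) {
      mk <- marker[i]
      cand <- unique(rec$species[rec$marker == mk])
      cand2 <- setdiff(cand, taxon[i])   # parents are distinct templates
      if (!length(cand2)) { is_chim[i] <- FALSE; next }
      p2 <- if (length(cand2) == 1L) cand2 else
        sample(cand2, 1L, prob = fr[cand2] / sum(fr[cand2]))
      k2 <- paste(p2, mk, sep = "\r")
      l2 <- locus_len[[k2]]
      fl <- min(flen[i], l2)
      s2 <- sample.int(l2 - fl + 1L, 1L)
      w2 <- substr(locus_seq[[k2]], s2, s2 + fl - 1L)
      bp <- sample.int(fl - 1L, 1L)
      frag[i] <- paste0(substr(frag[i], 1, bp),
                        substr(w2, bp + 1, fl))
      flen[i] <- fl
      parents[i] <- paste(taxon[i], p2, sep = ";")
    }
  }

  ## 4) mates + errors + qualities
  r1 <- substr(frag, 1L, pmin(rl, flen))
  r2 <- revcomp(substr(frag, pmax(1L, flen - rl + 1L), flen))
  r1 <- as.character(mutate_seqs_cpp(r1, params$error_rate))
  r2 <- as.character(mutate_seqs_cpp(r2, params$error_rate))
  ids <- sprintf("read%07d", seq_len(n))
  pairs <- data.frame(id = ids, seq1 = r1, seq2 = r2,
                      qual1 = quality_string(nchar(r1), params$quality_model),
                      qual2 = quality_string(nchar(r2), params$quality_model),
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, taxon = taxon, marker = marker,
                      is_chimera = is_chim, parents = parents,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, truth = truth, params = params,
                 formulation = formulation, seed = as.integer(seed)),
            class = "shotgun_sim")
}

#' @export
print.shotgun_sim <- function(x, ...) {
  cat("Simulated shotgun library:", nrow(x$pairs), "read pairs,",
      sum(x$truth$is_chimera), "chimeric\n")
  tab <- sort(table(x$truth$taxon), decreasing = TRUE)
  for (t in names(tab))
    cat(sprintf("  %-28s %6d (%.3f)\n", t, tab[[t]], tab[[t]] / nrow(x$pairs)))
  invisible(x)
}

#' Write a simulated library as paired FASTQ (+ truth TSV)
#'
#' @param sim a `shotgun_sim` (or a bare pairs data.frame).
#' @param prefix output path prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq` and, for a full `shotgun_sim`, `<prefix>_truth.tsv`.
#' @return invisibly, the paths written.
#' @export
write_fastq_pair <- function(sim, prefix) {
  pairs <- if (inherits(sim, "shotgun_sim")) sim$pairs else sim
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/1"), pairs$seq1,
                             "+", pairs$qual1)), f1)
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/2"), pairs$seq2,
                             "+", pairs$qual2)), f2)
  paths <- c(f1, f2)
  if (inherits(sim, "shotgun_sim")) {
    ft <- paste0(prefix, "_truth.tsv")
    write.table(sim$truth, ft, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ft)
  }
  invisible(paths)
}

#' Read paired FASTQ files into a pairs data.frame
#'
#' Minimal Phred+33 FASTQ reader for mate pairs with `/1` `/2` id suffixes.
#' Malformed records are reported with their record index.
#'
#' @param fastq1,fastq2 paths to the two mate files.
#' @return data.frame with columns `id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  rd <- function(path) {
    x <- readLines(path)
    if (length(x) %% 4L != 0L)
      stop("malformed FASTQ (truncated record ", length(x) %/% 4L + 1L,
           ") in ", path, call. = FALSE)
    hdr <- x[seq(1, length(x), 4)]
    plus <- x[seq(3, length(x), 4)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad))
      stop("malformed FASTQ record ", bad[1], " in ", path, call. = FALSE)
    seq <- x[seq(2, length(x), 4)]
    qual <- x[seq(4, length(x), 4)]
    badlen <- which(nchar(seq) != nchar(qual))
    if (length(badlen))
      stop("malformed FASTQ record ", badlen[1],
           " (sequence/quality length mismatch) in ", path, call. = FALSE)
    data.frame(id = sub("/[12]$", "", sub("\\s.*$", "", sub("^@", "", hdr))),
               seq = toupper(seq), qual = qual, stringsAsFactors = FALSE)
  }
  a <- rd(fastq1); b <- rd(fastq2)
  if (nrow(a) != nrow(b) || !all(a$id == b$id))
    stop("mate files disagree on read ids", call. = FALSE)
  data.frame(id = a$id, seq1 = a$seq, seq2 = b$seq,
             qual1 = a$qual, qual2 = b$qual, stringsAsFactors = FALSE)
}
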