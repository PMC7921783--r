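## Shared fixtures and independent oracles. Oracles are written in plain R,
## separate from the package's compiled paths, so they can arbitrate.

## independent canonical k-mer oracle (pure R string handling)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1L), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (!length(km)) return(character(0))
  rc <- oracle_revcomp(km)
  unique(ifelse(km < rc, km, rc))
}

## brute-force enrichment oracle: shared canonical k-mers per marker
oracle_enrich_counts <- function(pairs, db, k) {
  buckets <- lapply(split(db$records$sequence, db$records$marker),
                    function(seqs) unique(unlist(lapply(seqs,
                      oracle_canonical_kmers, k = k))))
  t(vapply(seq_len(nrow(pairs)), function(i) {
    km <- union(oracle_canonical_kmers(pairs$seq1[i], k),
                oracle_canonical_kmers(pairs$seq2[i], k))
    vapply(buckets, function(b) length(intersect(km, b)), integer(1))
  }, setNames(integer(length(buckets)), names(buckets))))
}

## a small valid reference database (sequences must be >= 100 bp)
tiny_db <- function(n_per_marker = 1L, markers = c("ITS2", "matK"),
                    len = 150L, seed = 100L) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(markers, function(m) {
    data.frame(id = sprintf("%s_%02d", gsub("[^A-Za-z]", "", m),
                            seq_len(n_per_marker)),
               marker = m,
               species = sprintf("Species %s%d", substr(m, 1, 2),
                                 seq_len(n_per_marker)),
               genus = "Genus", family = "Testaceae",
               kingdom = "Viridiplantae",
               sequence = random_dna(n_per_marker, len),
               stringsAsFactors = FALSE)
  }))
  reference_db(rows)
}

## substitute-only mutant at exactly `n_diff` random positions
mutate_n <- function(seq, n_diff, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_diff)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

## deterministic tiling read pairs over a locus (optionally with errors)
tiling_pairs <- function(locus, read_len = 150L, frag_len = 180L, by = 8L,
                         error_rate = 0, prefix = "t") {
  L <- nchar(locus)
  starts <- unique(c(seq(1L, L - frag_len + 1L, by = by), L - frag_len + 1L))
  frag <- substring(locus, starts, starts + frag_len - 1L)
  s1 <- substr(frag, 1L, read_len)
  s2 <- revcomp(substr(frag, frag_len - read_len + 1L, frag_len))
  if (error_rate > 0) {
    s1 <- as.character(herbshotgun:::mutate_seqs_cpp(s1, error_rate))
    s2 <- as.character(herbshotgun:::mutate_seqs_cpp(s2, error_rate))
  }
  data.frame(id = sprintf("%s%05d", prefix, seq_along(starts)),
             seq1 = s1, seq2 = s2,
             qual1 = strrep("F", read_len), qual2 = strrep("F", read_len),
             stringsAsFactors = FALSE)
}

## one-row contig data.frame for annotate-level functions
as_contig <- function(sequence, id = "ctg1", marker = "ITS2",
                      n_reads = 10L) {
  data.frame(id = id, marker = marker, sequence = sequence,
             n_reads = n_reads, stringsAsFactors = FALSE)
}

## one-row barcode data.frame
as_barcode <- function(sequence, contig_id = "b1", marker = "ITS2",
                       n_reads = 10L) {
  data.frame(contig_id = contig_id, marker = marker, sequence = sequence,
             start = 0L, end = nchar(sequence), strand = "+", flags = "",
             n_reads = n_reads, stringsAsFactors = FALSE)
}

## synthetic mapping-profile row with a given depth vector
as_profile <- function(otu_id, depth) {
  out <- data.frame(otu_id = otu_id, length = length(depth),
                    n_pairs_mapped = NA_integer_,
                    mean_depth = sum(depth) / length(depth),
                    coverage = mean(depth >= 1),
                    stringsAsFactors = FALSE)
  out$depth <- list(as.integer(depth))
  structure(out, class = c("mapping_profile_set", "data.frame"))
}

write_tiny_refdb_files <- function(db, dir = tempfile("db")) {
  dir.create(dir)
  fa <- file.path(dir, "ref.fasta")
  tx <- file.path(dir, "ref.tsv")
  write_reference_db(db, fa, tx)
  list(fasta = fa, taxonomy = tx, dir = dir)
}

## fixture shared by the enrichment unit tests and acceptance oracle check
make_enrich_fixture <- function(seed = 500L, n_bg = 30L) {
  set.seed(seed)
  db <- tiny_db(n_per_marker = 2L, markers = c("ITS2", "matK", "rbcL"),
                len = 200L, seed = seed)
  reads <- lapply(seq_len(nrow(db$records)), function(i) {
    s <- db$records$sequence[i]
    data.frame(id = sprintf("%s_p%d", db$records$id[i], 1:4),
               seq1 = substring(s, c(1, 21, 41, 61), c(100, 120, 140, 160)),
               seq2 = revcomp(substring(s, c(61, 81, 101, 101),
                                        c(160, 180, 200, 200))),
               stringsAsFactors = FALSE)
  })
  bg <- data.frame(id = sprintf("bg_p%d", seq_len(n_bg)),
                   seq1 = random_dna(n_bg, 100),
                   seq2 = random_dna(n_bg, 100), stringsAsFactors = FALSE)
  pairs <- rbind(do.call(rbind, reads), bg)
  pairs$qual1 <- strrep("I", 100); pairs$qual2 <- strrep("I", 100)
  list(db = db, pairs = pairs)
}
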