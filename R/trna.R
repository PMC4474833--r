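# tRNA-seq: modification-aware read alignment, spike-in normalization,
# fold changes and 3'-truncation profiling.

#' Construct a tRNA reference with a modified-position mask
#'
#' @param species_id Species label, e.g. `"1-Ala(TGC)"`.
#' @param sequence DNA sequence of the mature tRNA including the 3' CCA
#'   (tandem CCACCA ends are detected automatically).
#' @param modified_positions Integer vector of 0-based positions carrying
#'   post-transcriptionally modified nucleotides (Modomics-style); these
#'   match any read base during alignment.
#' @return Object of class `"trna_reference"`.
#' @export
trna_reference <- function(species_id, sequence, modified_positions = integer(0)) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]+$", sequence)) stop("sequence must be over A,C,G,T,N")
  if (!endsWith(sequence, "CCA"))
    stop(sprintf("%s: mature tRNA sequence must end in CCA", species_id))
  modified_positions <- as.integer(modified_positions)
  if (any(modified_positions < 0L | modified_positions >= nchar(sequence)))
    stop("modified position outside the sequence")
  structure(list(species_id = species_id, sequence = sequence,
                 modified_mask = sort(unique(modified_positions)),
                 tandem_cca = endsWith(sequence, "CCACCA")),
            class = "trna_reference")
}

#' @export
print.trna_reference <- function(x, ...) {
  cat(sprintf("tRNA %s: %d nt, %d modified positions%s\n", x$species_id,
              nchar(x$sequence), length(x$modified_mask),
              if (x$tandem_cca) ", tandem CCACCA 3' end" else ""))
  invisible(x)
}

#' Load tRNA references from FASTA plus a modification table
#'
#' @param fasta Path to the reference FASTA.
#' @param mods_tsv Optional TSV with columns `species_id` and `position`
#'   (0-based modified positions).
#' @return Named list of `"trna_reference"` objects, sorted by species id.
#' @export
read_trna_refs <- function(fasta, mods_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  mods <- if (!is.null(mods_tsv)) {
    m <- read.delim(mods_tsv, stringsAsFactors = FALSE)
    stopifnot(all(c("species_id", "position") %in% names(m)))
    split(m$position, m$species_id)
  } else list()
  refs <- lapply(seq_along(seqs), function(i) {
    trna_reference(ids[i], as.character(seqs[[i]]),
                   if (ids[i] %in% names(mods)) mods[[ids[i]]] else integer(0))
  })
  names(refs) <- ids
  refs[order(ids)]
}

#' Trim a 3' adapter from reads
#'
#' Removes the adapter starting at the leftmost position where either the
#' full adapter occurs or a suffix of the read matches a prefix of the
#' adapter of at least `min_overlap` bases.
#'
#' @param reads Character vector of read sequences.
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum terminal match length (default 5).
#' @param min_length Reads shorter than this after trimming are flagged in
#'   the `"too_short"` attribute (default 25).
#' @return Trimmed reads (names preserved) with attribute `"too_short"`.
#' @export
trim_adapters <- function(reads, adapter, min_overlap = 5, min_length = 25) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  adapter <- toupper(adapter)
  la <- nchar(adapter)
  out <- vapply(reads, function(rd) {
    rd <- toupper(rd)
    lr <- nchar(rd)
    for (i in seq_len(lr)) {
      k <- min(la, lr - i + 1L)  # k < la only at the read's 3' end
      if ((k == la || k >= min_overlap) &&
          substr(rd, i, i + k - 1L) == substr(adapter, 1L, k))
        return(substr(rd, 1L, i - 1L))
    }
    rd
  }, character(1), USE.NAMES = TRUE)
  attr(out, "too_short") <- nchar(out) < min_length
  out
}

#' Align one read to one tRNA reference
#'
#' Semi-global dynamic programming: the read must align end to end, both
#' reference ends are free, and reference positions in the modified mask
#' match any base at zero cost.  Errors are unit-cost mismatches,
#' insertions and deletions.  `three_prime_offset` counts reference bases
#' missing from the read's 3' end.
#'
#' @param read Read sequence (A,C,G,T,N).
#' @param ref A `"trna_reference"`, or a character sequence (then
#'   `modified_positions` supplies the mask).
#' @param max_errors Maximum errors for acceptance (default 3).
#' @param min_length Minimum read/alignment length (default 25); shorter
#'   reads are rejected with a reason.
#' @param mode `"semiglobal"` (default) or `"local"` (strict
#'   Smith-Waterman scoring; provided for comparison).
#' @param modified_positions 0-based mask when `ref` is a plain sequence.
#' @return Object of class `"read_alignment"`: list with `species_id`,
#'   `errors`, `aligned_length`, `ref_start`, `ref_end` (0-based),
#'   `three_prime_offset`, `accepted` and `reason`.
#' @export
align_read <- function(read, ref, max_errors = 3, min_length = 25,
                       mode = c("semiglobal", "local"),
                       modified_positions = integer(0)) {
  mode <- match.arg(mode)
  if (inherits(ref, "trna_reference")) {
    species <- ref$species_id
    mask <- ref$modified_mask
    refseq <- ref$sequence
  } else {
    species <- NA_character_
    mask <- as.integer(modified_positions)
    refseq <- toupper(ref)
  }
  read <- toupper(read)
  if (!grepl("^[ACGTN]+$", read)) stop("read must be over A,C,G,T,N")
  if (nchar(read) < min_length) {
    return(structure(list(species_id = species, errors = NA_integer_,
                          aligned_length = NA_integer_, ref_start = NA_integer_,
                          ref_end = NA_integer_, three_prime_offset = NA_integer_,
                          accepted = FALSE,
                          reason = "read shorter than min_length"),
                     class = "read_alignment"))
  }
  al <- if (mode == "semiglobal") .align_read_cpp(read, refseq, mask)
        else .align_local_cpp(read, refseq, mask)
  accepted <- al$errors <= max_errors && al$aligned_length >= min_length
  structure(list(species_id = species, errors = al$errors,
                 aligned_length = al$aligned_length,
                 ref_start = al$ref_start, ref_end = al$ref_end,
                 three_prime_offset = nchar(refseq) - 1L - al$ref_end,
                 accepted = accepted,
                 reason = if (accepted) NA_character_ else "too many errors or too short"),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("read alignment to %s: %s errors, length %s, 3' offset %s, %s\n",
              x$species_id, x$errors, x$aligned_length, x$three_prime_offset,
              if (isTRUE(x$accepted)) "accepted" else paste0("rejected (", x$reason, ")")))
  invisible(x)
}

.refs_sorted <- function(refs) {
  ids <- vapply(refs, `[[`, "", "species_id")
  refs[order(ids)]
}

#' Assign a read to its best tRNA species
#'
#' Aligns against every reference and keeps the best accepted alignment by
#' fewest errors, then longest alignment, then lexicographically smallest
#' species id (a deterministic tie-break for reads shared between
#' isoacceptors).
#'
#' @param read Read sequence.
#' @param refs List of `"trna_reference"` objects.
#' @inheritParams align_read
#' @return A `"read_alignment"`; `species_id` is `NA` when no reference
#'   accepts the read.
#' @export
assign_read <- function(read, refs, max_errors = 3, min_length = 25) {
  if (!length(refs)) stop("empty reference set")
  refs <- .refs_sorted(refs)
  res <- align_reads(setNames(read, "r1"), refs, max_errors, min_length)
  al <- res[1L, ]
  structure(list(species_id = al$species_id, errors = al$errors,
                 aligned_length = al$aligned_length, ref_start = al$ref_start,
                 ref_end = al$ref_end,
                 three_prime_offset = al$three_prime_offset,
                 accepted = al$accepted,
                 reason = if (al$accepted) NA_character_ else "no accepted alignment"),
            class = "read_alignment")
}

#' Align a read set against tRNA references
#'
#' Vectorized driver around the semi-global aligner: each read is assigned
#' to the species of its best accepted alignment (see [assign_read()] for
#' the tie-break).
#'
#' @param reads Named character vector of read sequences.
#' @param refs List of `"trna_reference"` objects (spike-in included as an
#'   ordinary reference).
#' @inheritParams align_read
#' @return data.frame with one row per read: `read_id`, `species_id` (`NA`
#'   if unassigned), `errors`, `aligned_length`, `ref_start`, `ref_end`,
#'   `three_prime_offset`, `accepted`.
#' @export
align_reads <- function(reads, refs, max_errors = 3, min_length = 25) {
  if (!length(refs)) stop("empty reference set")
  refs <- .refs_sorted(refs)
  ids <- vapply(refs, `[[`, "", "species_id")
  seqs <- vapply(refs, `[[`, "", "sequence")
  masks <- lapply(refs, `[[`, "modified_mask")
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  res <- .align_batch_cpp(toupper(unname(reads)), unname(seqs),
                          unname(masks), as.integer(max_errors),
                          as.integer(min_length))
  k <- res$best_ref
  reflen <- nchar(seqs)[k]
  data.frame(
    read_id = names(reads),
    species_id = ifelse(is.na(k), NA_character_, ids[k]),
    errors = res$errors,
    aligned_length = res$aligned_length,
    ref_start = res$ref_start,
    ref_end = res$ref_end,
    three_prime_offset = ifelse(is.na(k), NA_integer_, reflen - 1L - res$ref_end),
    accepted = !is.na(k),
    too_short = res$too_short,
    stringsAsFactors = FALSE)
}

#' Per-species read counts with spike-in normalization
#'
#' @param alignments data.frame from [align_reads()].
#' @param spike_in_id Species id of the spike-in reference.
#' @param condition Condition label carried with the counts.
#' @param species_ids Optional full species universe (species with zero
#'   accepted reads are reported as 0).
#' @return Object of class `"species_counts"`: `condition`, `counts`
#'   (named vector, spike-in excluded), `spike_in_count`, `normalized`
#'   (counts / spike-in count; only defined for positive spike-in counts)
#'   and `unassigned`.
#' @export
species_counts <- function(alignments, spike_in_id = "spike-in",
                           condition = "normal", species_ids = NULL) {
  acc <- alignments[alignments$accepted, , drop = FALSE]
  tab <- table(acc$species_id)
  spike <- if (spike_in_id %in% names(tab)) as.integer(tab[[spike_in_id]]) else 0L
  tab <- tab[setdiff(names(tab), spike_in_id)]
  if (is.null(species_ids)) species_ids <- names(tab)
  species_ids <- sort(setdiff(species_ids, spike_in_id))
  counts <- setNames(integer(length(species_ids)), species_ids)
  counts[names(tab)[names(tab) %in% species_ids]] <-
    as.integer(tab[names(tab) %in% species_ids])
  structure(list(condition = condition, counts = counts,
                 spike_in_count = spike,
                 normalized = if (spike > 0) counts / spike else
                   setNames(rep(NA_real_, length(counts)), species_ids),
                 unassigned = sum(!alignments$accepted)),
            class = "species_counts")
}

#' @export
print.species_counts <- function(x, ...) {
  cat(sprintf("tRNA counts [%s]: %d species, %d aligned reads, spike-in %d, %d unassigned\n",
              x$condition, length(x$counts), sum(x$counts),
              x$spike_in_count, x$unassigned))
  invisible(x)
}

#' Spike-in-normalized per-species fold changes
#'
#' For every species, the fold decrease under stress is
#' `normalized_normal / normalized_stress` where each side is the accepted
#' read count divided by that library's spike-in count.  The mean fold
#' decrease is reported both as the arithmetic mean of per-species ratios
#' (species with zero stress counts flagged and excluded) and as the ratio
#' of normalized totals.
#'
#' @param counts_normal,counts_stress `"species_counts"` objects.
#' @return List with `per_species` (data.frame), `mean_fold_change`,
#'   `total_fold_change` and `excluded` (species with zero stress counts).
#' @export
normalize_and_fold_change <- function(counts_normal, counts_stress) {
  stopifnot(inherits(counts_normal, "species_counts"),
            inherits(counts_stress, "species_counts"))
  if (counts_normal$spike_in_count <= 0 || counts_stress$spike_in_count <= 0)
    stop("spike-in count must be positive in both conditions")
  sp <- sort(union(names(counts_normal$counts), names(counts_stress$counts)))
  cn <- setNames(numeric(length(sp)), sp); cs <- cn
  cn[names(counts_normal$counts)] <- counts_normal$counts
  cs[names(counts_stress$counts)] <- counts_stress$counts
  nn <- cn / counts_normal$spike_in_count
  ns <- cs / counts_stress$spike_in_count
  fold <- ifelse(cs > 0, nn / ns, NA_real_)
  per <- data.frame(species_id = sp, count_normal = cn, count_stress = cs,
                    normalized_normal = nn, normalized_stress = ns,
                    fold_decrease = fold, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_species = per,
       mean_fold_change = mean(fold, na.rm = TRUE),
       total_fold_change = sum(nn) / sum(ns),
       excluded = sp[cs == 0])
}

#' 3'-truncation profile of one tRNA species
#'
#' Fraction of a species' accepted reads missing exactly k bases from the
#' reference 3' end, for k = 0..`max_offset`.  For species with a tandem
#' CCACCA end, the fraction at offset 3 corresponds to loss of the outer
#' CCA unit (reads ending at the inner CCA).
#'
#' @param alignments data.frame from [align_reads()].
#' @param species Species id to profile.
#' @param max_offset Largest truncation length reported (default 10).
#' @param tandem_cca Set `TRUE` for CCACCA-ended species to report the
#'   inner-CCA fraction explicitly.
#' @return List with `species_id`, `fractions` (named vector over offsets
#'   0..max_offset), `n_reads` and, when `tandem_cca`, `inner_cca_fraction`.
#' @export
truncation_profile <- function(alignments, species, max_offset = 10,
                               tandem_cca = FALSE) {
  acc <- alignments[alignments$accepted &
                      alignments$species_id == species, , drop = FALSE]
  if (!nrow(acc)) stop(sprintf("no accepted reads for species %s", species))
  off <- pmin(acc$three_prime_offset, max_offset + 1L)
  frac <- vapply(0:max_offset, function(k) mean(off == k), 0)
  names(frac) <- as.character(0:max_offset)
  out <- list(species_id = species, fractions = frac, n_reads = nrow(acc))
  if (tandem_cca) out$inner_cca_fraction <- frac[["3"]]
  out
}

#' Replicate concordance of normalized counts
#'
#' @param counts_rep1,counts_rep2 `"species_counts"` objects for two
#'   replicates (spike-in normalized).
#' @return List with `pearson` and `spearman` correlations over the shared
#'   species and `n_shared`.
#' @export
replicate_concordance <- function(counts_rep1, counts_rep2) {
  shared <- intersect(names(counts_rep1$normalized),
                      names(counts_rep2$normalized))
  if (length(shared) < 3L) stop("need at least 3 shared species")
  a <- counts_rep1$normalized[shared]
  b <- counts_rep2$normalized[shared]
  list(pearson = cor(a, b, method = "pearson"),
       spearman = cor(a, b, method = "spearman"),
       n_shared = length(shared))
}

#' Read FASTQ sequences
#'
#' @param path FASTQ file (Phred+33).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ
#'
#' @param reads Named character vector.
#' @param path Output path; constant high base quality is written.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- names(reads)
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write tRNA references to FASTA plus a modification TSV
#'
#' @param refs List of `"trna_reference"`.
#' @param fasta,mods_tsv Output paths.
#' @export
write_trna_refs <- function(refs, fasta, mods_tsv) {
  seqs <- Biostrings::DNAStringSet(vapply(refs, `[[`, "", "sequence"))
  names(seqs) <- vapply(refs, `[[`, "", "species_id")
  Biostrings::writeXStringSet(seqs, fasta)
  mods <- do.call(rbind, lapply(refs, function(r) {
    if (!length(r$modified_mask)) return(NULL)
    data.frame(species_id = r$species_id, position = r$modified_mask,
               stringsAsFactors = FALSE)
  }))
  if (is.null(mods))
    mods <- data.frame(species_id = character(0), position = integer(0))
  write.table(mods, mods_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}
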