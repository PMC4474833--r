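# Independent oracles used across the suite.  These deliberately avoid the
# package's own algorithms: alignment errors come from an exhaustive
# branch-and-bound enumeration of edit scripts, digestion from a brute-force
# substring filter, and mass lookups from a linear scan.

# Minimum error count of a semi-global alignment (read consumed end to end,
# free reference ends), found by enumerating edit scripts up to `max_err`
# errors from every reference start.  Dominated states are pruned, which
# bounds the search without changing the result.
oracle_min_errors <- function(read, ref, modified_positions = integer(0),
                              max_err = 3L) {
  rd <- strsplit(read, "", fixed = TRUE)[[1L]]
  rf <- strsplit(ref, "", fixed = TRUE)[[1L]]
  m <- length(rd); n <- length(rf)
  wild <- logical(n)
  wild[modified_positions + 1L] <- TRUE
  best <- max_err + 1L
  seen <- matrix(max_err + 2L, m + 1L, n + 1L)
  explore <- function(i, j, e) {
    if (e >= best) return(invisible(NULL))
    if (e >= seen[i + 1L, j + 1L]) return(invisible(NULL))
    seen[i + 1L, j + 1L] <<- e
    if (i == m) { best <<- e; return(invisible(NULL)) }
    if (j < n) {
      ok <- wild[j + 1L] || rd[i + 1L] == rf[j + 1L] ||
        rd[i + 1L] == "N" || rf[j + 1L] == "N"
      explore(i + 1L, j + 1L, e + !ok)   # (mis)match
      explore(i, j + 1L, e + 1L)         # delete reference base
    }
    explore(i + 1L, j, e + 1L)           # insert read base
    invisible(NULL)
  }
  for (s in 0:n) explore(0L, s, 0L)
  best  # max_err + 1 means "more than max_err errors"
}

# Brute-force tryptic digestion: every substring whose boundaries are valid
# cleavage points and whose internal missed-cleavage count is within bounds.
oracle_digest <- function(sequence, max_missed, proline_rule = TRUE) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  len <- length(res)
  is_site <- function(i) {          # cleavage after position i?
    if (i == 0L || i == len) return(TRUE)
    res[i] %in% c("K", "R") && !(proline_rule && res[i + 1L] == "P")
  }
  out <- list()
  for (a in 1:len) for (b in a:len) {
    if (!is_site(a - 1L) || !is_site(b)) next
    internal <- if (b > a) sum(vapply((a):(b - 1L), is_site, TRUE)) else 0L
    if (internal > max_missed) next
    out[[length(out) + 1L]] <- data.frame(
      sequence = paste(res[a:b], collapse = ""),
      missed_cleavages = internal, stringsAsFactors = FALSE)
  }
  unique(do.call(rbind, out))
}

# Linear-scan candidate lookup over the peptide table.
oracle_lookup <- function(peptides, precursor_mz, charge, tol_ppm) {
  proton <- 1.007276466621
  obs <- precursor_mz * charge - charge * proton
  keep <- abs(obs - peptides$monoisotopic_mass) <=
    tol_ppm * peptides$monoisotopic_mass * 1e-6
  peptides[keep, , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n) paste(sample(rownames(isoturn:::.RESIDUE_COMP),
                                           n, TRUE), collapse = "")

# apply k substitutions at random distinct positions
substitute_bases <- function(seqn, k) {
  s <- strsplit(seqn, "", fixed = TRUE)[[1L]]
  pos <- sample(seq_along(s), k)
  for (i in pos) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  paste(s, collapse = "")
}
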