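# Dual-isotope (14N/15N) peptide chemistry: digestion, elemental composition,
# isotope envelopes, mass-indexed peptide databases and MS1 area-ratio
# quantification.

# Monoisotopic masses of the principal (lightest) isotopes, CODATA/AME values.
.ELEMENT_MONO <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.00307400443,
  O = 15.99491461957,
  S = 31.9720711744
)

.N15_MASS  <- 15.00010889888
#' Monoisotopic mass difference between 15N and 14N
#'
#' Every nitrogen replaced by the heavy isotope adds this many Daltons, so a
#' fully labeled peptide is shifted by `n_N * n15_mass_shift()` relative to
#' its light form.
#'
#' @return Mass difference in Da (scalar).
#' @export
n15_mass_shift <- function() .N15_MASS - .ELEMENT_MONO[["N"]]

.PROTON_MASS <- 1.007276466621

# Natural isotope patterns: mass offset from the principal isotope and
# abundance.  Nominal offset (integer Da) indexes the aggregated envelope.
.ISOTOPE_TABLE <- list(
  C = list(dm = c(0, 1.00335483507),                     ab = c(0.9893, 0.0107),         k = c(0L, 1L)),
  H = list(dm = c(0, 1.00627674578),                     ab = c(0.999885, 0.000115),     k = c(0L, 1L)),
  O = list(dm = c(0, 1.00421713693, 2.00424499329),      ab = c(0.99757, 0.00038, 0.00205), k = c(0L, 1L, 2L)),
  S = list(dm = c(0, 0.9993877354, 1.9957958296, 3.9950095356),
           ab = c(0.9499, 0.0075, 0.0425, 0.0001),       k = c(0L, 1L, 2L, 4L))
)
.N_NATURAL_AB15 <- 0.00364   # natural abundance of 15N

# Residue elemental compositions (C, H, N, O, S), peptide-bond residues.
.RESIDUE_COMP <- matrix(c(
  # C   H   N  O  S
    3,  5,  1, 1, 0,  # A
    6, 12,  4, 1, 0,  # R
    4,  6,  2, 2, 0,  # N
    4,  5,  1, 3, 0,  # D
    3,  5,  1, 1, 1,  # C
    5,  7,  1, 3, 0,  # E
    5,  8,  2, 2, 0,  # Q
    2,  3,  1, 1, 0,  # G
    6,  7,  3, 1, 0,  # H
    6, 11,  1, 1, 0,  # I
    6, 11,  1, 1, 0,  # L
    6, 12,  2, 1, 0,  # K
    5,  9,  1, 1, 1,  # M
    9,  9,  1, 1, 0,  # F
    5,  7,  1, 1, 0,  # P
    3,  5,  1, 2, 0,  # S
    4,  7,  1, 2, 0,  # T
   11, 10,  2, 1, 0,  # W
    9,  9,  1, 2, 0,  # Y
    5,  9,  1, 1, 0   # V
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A","R","N","D","C","E","Q","G","H","I",
                    "L","K","M","F","P","S","T","W","Y","V"),
                  c("C","H","N","O","S")))

.WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
# carbamidomethylation of cysteine adds C2H3NO; methionine oxidation adds O
.MOD_CAM <- c(C = 2, H = 3, N = 1, O = 1, S = 0)
.MOD_OX  <- c(C = 0, H = 0, N = 0, O = 1, S = 0)

.check_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("peptide/protein sequence must be a single non-empty string")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% rownames(.RESIDUE_COMP))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1L]], bad[1L]))
  res
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) and arginine (R), by default suppressing
#' cleavage before proline, and enumerates all peptides carrying up to
#' `max_missed` missed cleavage sites.
#'
#' @param sequence Protein sequence (20-letter amino-acid alphabet).
#' @param max_missed Maximum number of internal missed cleavage sites
#'   (default 2).
#' @param proline_rule Suppress cleavage when the following residue is
#'   proline (default `TRUE`).
#' @return A data.frame with columns `sequence` and `missed_cleavages`,
#'   deduplicated on both.
#' @examples
#' digest("MKAAR", max_missed = 0)
#' @export
digest <- function(sequence, max_missed = 2, proline_rule = TRUE) {
  res <- .check_residues(sequence)
  if (max_missed < 0) stop("max_missed must be >= 0")
  len <- length(res)
  site <- which(res %in% c("K", "R"))
  if (proline_rule && length(site))
    site <- site[!(site < len & res[pmin(site + 1L, len)] == "P")]
  bounds <- unique(c(0L, site[site < len], len))
  nseg <- length(bounds) - 1L
  out_seq <- character(0); out_miss <- integer(0)
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      out_seq <- c(out_seq, paste(res[(bounds[i] + 1L):bounds[j + 1L]],
                                  collapse = ""))
      out_miss <- c(out_miss, m)
    }
  }
  out <- data.frame(sequence = out_seq, missed_cleavages = out_miss,
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Elemental composition and monoisotopic mass of a peptide
#'
#' Sums residue compositions plus one water, applies fixed
#' carbamidomethylation of cysteines and any variable methionine oxidations,
#' and computes the monoisotopic mass.  Under the `"N15"` label every
#' nitrogen atom is counted at the heavy-isotope monoisotopic mass, so
#' `mass(N15) - mass(N14) = n_N * n15_mass_shift()` for any sequence.
#'
#' @param sequence Peptide sequence.
#' @param carbamidomethyl Apply fixed carbamidomethyl-C (default `TRUE`).
#' @param oxidized_m Integer positions (1-based) of oxidized methionines.
#' @param label `"N14"` (natural) or `"N15"` (metabolically labeled).
#' @param free_amino_acid If `TRUE` treat a single residue as the free amino
#'   acid (identical arithmetic: residue plus water).
#' @return A list with `composition` (named counts of C,H,N,O,S),
#'   `monoisotopic_mass` (Da), `label` and `n_N`.
#' @examples
#' composition_and_mass("G", carbamidomethyl = FALSE)$monoisotopic_mass # 75.03203
#' @export
composition_and_mass <- function(sequence, carbamidomethyl = TRUE,
                                 oxidized_m = integer(0),
                                 label = c("N14", "N15"),
                                 free_amino_acid = FALSE) {
  label <- match.arg(label)
  res <- .check_residues(sequence)
  oxidized_m <- as.integer(oxidized_m)
  if (length(oxidized_m)) {
    if (any(oxidized_m < 1L | oxidized_m > length(res)))
      stop("oxidized_m position outside the peptide")
    if (any(res[oxidized_m] != "M"))
      stop(sprintf("oxidation requested at position %d which is not methionine",
                   oxidized_m[which(res[oxidized_m] != "M")[1L]]))
  }
  comp <- colSums(.RESIDUE_COMP[res, , drop = FALSE]) + .WATER
  if (carbamidomethyl) comp <- comp + .MOD_CAM * sum(res == "C")
  comp <- comp + .MOD_OX * length(oxidized_m)
  nmass <- if (label == "N15") .N15_MASS else .ELEMENT_MONO[["N"]]
  mono <- comp[["C"]] * .ELEMENT_MONO[["C"]] +
    comp[["H"]] * .ELEMENT_MONO[["H"]] +
    comp[["N"]] * nmass +
    comp[["O"]] * .ELEMENT_MONO[["O"]] +
    comp[["S"]] * .ELEMENT_MONO[["S"]]
  list(composition = comp, monoisotopic_mass = mono, label = label,
       n_N = comp[["N"]])
}

# Aggregated (nominal-bin) isotope distribution of n atoms of one element:
# probability and intensity-weighted mean exact-mass offset per bin.
.element_bins <- function(element, n, kmax) {
  p <- numeric(kmax + 1L); wm <- numeric(kmax + 1L)
  if (n == 0L) { p[1L] <- 1; return(list(p = p, m = wm)) }
  it <- .ISOTOPE_TABLE[[element]]
  ni <- length(it$ab)
  if (ni == 2L) {
    k <- 0:min(n, kmax)
    pr <- dbinom(k, n, it$ab[2L])
    p[k + 1L] <- pr
    wm[k + 1L] <- k * it$dm[2L]
    return(list(p = p, m = wm))
  }
  # multinomial enumeration over heavier isotopes (O: 17O/18O; S: 33/34/36)
  heavy_k <- it$k[-1L]; heavy_dm <- it$dm[-1L]; heavy_ab <- it$ab[-1L]
  nh <- length(heavy_k)
  counts_max <- pmin(n, kmax %/% heavy_k)
  grid <- do.call(expand.grid, lapply(counts_max, function(mx) 0:mx))
  for (r in seq_len(nrow(grid))) {
    cnt <- as.integer(grid[r, ])
    tot <- sum(cnt)
    if (tot > n) next
    k <- sum(cnt * heavy_k)
    if (k > kmax) next
    pr <- dmultinom(c(n - tot, cnt), prob = c(it$ab[1L], heavy_ab))
    dm <- sum(cnt * heavy_dm)
    p[k + 1L] <- p[k + 1L] + pr
    wm[k + 1L] <- wm[k + 1L] + pr * dm
  }
  nz <- p > 0
  wm[nz] <- wm[nz] / p[nz]
  list(p = p, m = wm)
}

.convolve_bins <- function(a, b, kmax) {
  p <- numeric(kmax + 1L); wm <- numeric(kmax + 1L)
  for (i in which(a$p > 0)) {
    jmax <- kmax + 2L - i
    j <- which(b$p[seq_len(jmax)] > 0)
    if (!length(j)) next
    idx <- i + j - 1L
    contrib <- a$p[i] * b$p[j]
    p[idx] <- p[idx] + contrib
    wm[idx] <- wm[idx] + contrib * (a$m[i] + b$m[j])
  }
  nz <- p > 0
  wm[nz] <- wm[nz] / p[nz]
  list(p = p, m = wm)
}

#' Predict the isotope envelope of a peptide ion
#'
#' Convolves per-element isotope distributions (natural abundances for C, H,
#' O and S).  Nitrogen is treated separately: natural under the `"N14"`
#' label, and as independent heavy incorporation at probability
#' `n15_incorporation` under `"N15"`, which reproduces the binomial
#' fine structure of a metabolically labeled peptide.  Peak m/z values are
#' `(mass + z * proton) / z`.
#'
#' @param composition Named element counts (C,H,N,O,S), e.g. from
#'   [composition_and_mass()]. The monoisotopic mass is recomputed from the
#'   composition with light nitrogen; heavy shifts enter through the
#'   envelope itself.
#' @param label `"N14"` or `"N15"`.
#' @param charge Positive integer charge state.
#' @param n15_incorporation Fraction of nitrogen atoms labeled under
#'   `"N15"` (default 0.99, effectively complete labeling).
#' @param intensity_floor Peaks with relative intensity below this fraction
#'   of the total are truncated from the returned list (default 1e-3); the
#'   remaining intensities are not renormalized, so the retained area shows
#'   how much of the envelope survives truncation.
#' @return An object of class `"isotope_envelope"`: list with `charge`,
#'   `label`, `monoisotopic_mz` (all-light CHOS; all-heavy N under N15) and
#'   `peaks` (data.frame of strictly increasing `mz` and `intensity`).
#'   The attribute `"total_intensity"` holds the pre-truncation sum.
#' @export
isotope_envelope <- function(composition, label = c("N14", "N15"), charge = 1L,
                             n15_incorporation = 0.99, intensity_floor = 1e-3) {
  label <- match.arg(label)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  if (n15_incorporation <= 0 || n15_incorporation > 1)
    stop("n15_incorporation must be in (0, 1]")
  comp <- setNames(numeric(5), c("C", "H", "N", "O", "S"))
  comp[names(composition)] <- composition
  if (any(comp < 0) || sum(comp) == 0) stop("empty or invalid composition")
  kmax <- 60L

  mono_light <- sum(comp * .ELEMENT_MONO[names(comp)])
  chos <- list(p = c(1, numeric(kmax)), m = numeric(kmax + 1L))
  for (el in c("C", "H", "O", "S"))
    chos <- .convolve_bins(chos, .element_bins(el, as.integer(comp[[el]]), kmax), kmax)

  nN <- as.integer(comp[["N"]])
  p_heavy <- if (label == "N15") n15_incorporation else .N_NATURAL_AB15
  h <- 0:nN
  np <- dbinom(h, nN, p_heavy)
  ndm <- h * n15_mass_shift()

  ci <- which(chos$p > 0)
  mass <- rep(mono_light + chos$m[ci], times = length(h)) +
    rep(ndm, each = length(ci))
  prob <- rep(chos$p[ci], times = length(h)) * rep(np, each = length(ci))
  keep <- prob > 0
  mass <- mass[keep]; prob <- prob[keep]
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  # merge numerically coincident species
  grp <- cumsum(c(TRUE, diff(mass) > 1e-9))
  mass <- vapply(split(mass * prob, grp), sum, 0) /
    vapply(split(prob, grp), sum, 0)
  prob <- vapply(split(prob, grp), sum, 0)

  total <- sum(prob)
  sel <- prob >= intensity_floor * total
  mz <- (mass[sel] + charge * .PROTON_MASS) / charge
  mono_mass <- if (label == "N15") mono_light + nN * n15_mass_shift() else mono_light
  structure(
    list(charge = charge, label = label,
         monoisotopic_mz = (mono_mass + charge * .PROTON_MASS) / charge,
         peaks = data.frame(mz = mz, intensity = prob[sel])),
    total_intensity = total,
    class = "isotope_envelope")
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat(sprintf("Isotope envelope (%s, z=%d): %d peaks, monoisotopic m/z %.4f\n",
              x$label, x$charge, nrow(x$peaks), x$monoisotopic_mz))
  invisible(x)
}

.expand_var_mods <- function(sequence, max_var_mods = 2L) {
  mpos <- which(strsplit(sequence, "", fixed = TRUE)[[1L]] == "M")
  out <- list(integer(0))
  if (length(mpos)) {
    for (k in seq_len(min(max_var_mods, length(mpos)))) {
      cmb <- if (length(mpos) == 1L) list(mpos)  # combn would expand 1:mpos
             else combn(mpos, k, simplify = FALSE)
      out <- c(out, cmb)
    }
  }
  out
}

#' Build a mass-indexed dual-label peptide database
#'
#' Digests every protein in a proteome, expands variable methionine
#' oxidations, and records each peptide under both the light (14N) and
#' heavy (15N) label, sorted by monoisotopic mass for range queries.
#'
#' @param proteome Either a path to a FASTA file or a named character
#'   vector of protein sequences.
#' @param max_missed Missed cleavages allowed (default 2).
#' @param carbamidomethyl Fixed carbamidomethyl-C (default `TRUE`).
#' @param max_var_mods Maximum simultaneous oxidized methionines per
#'   peptide (default 2).
#' @param proline_rule Passed to [digest()].
#' @param min_length Minimum peptide length retained (default 1).
#' @return Object of class `"peptide_index"`: list with `peptides`
#'   (mass-sorted data.frame) and the build parameters.
#' @export
build_dual_db <- function(proteome, max_missed = 2, carbamidomethyl = TRUE,
                          max_var_mods = 2, proline_rule = TRUE,
                          min_length = 1) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome)) {
    aa <- Biostrings::readAAStringSet(proteome)
    proteome <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  if (!length(proteome)) stop("empty proteome")
  if (is.null(names(proteome)))
    names(proteome) <- sprintf("protein%03d", seq_along(proteome))
  rows <- vector("list", 0L)
  for (pid in names(proteome)) {
    pep <- digest(proteome[[pid]], max_missed = max_missed,
                  proline_rule = proline_rule)
    pep <- pep[nchar(pep$sequence) >= min_length, , drop = FALSE]
    for (i in seq_len(nrow(pep))) {
      mods <- .expand_var_mods(pep$sequence[i], max_var_mods)
      for (ox in mods) {
        for (lab in c("N14", "N15")) {
          cm <- composition_and_mass(pep$sequence[i],
                                     carbamidomethyl = carbamidomethyl,
                                     oxidized_m = ox, label = lab)
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, sequence = pep$sequence[i],
            missed_cleavages = pep$missed_cleavages[i],
            oxidized_m = paste(ox, collapse = ","),
            label = lab, n_N = cm$n_N,
            monoisotopic_mass = cm$monoisotopic_mass,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  peptides <- do.call(rbind, rows)
  peptides <- peptides[order(peptides$monoisotopic_mass), , drop = FALSE]
  rownames(peptides) <- NULL
  structure(list(peptides = peptides,
                 params = list(max_missed = max_missed,
                               carbamidomethyl = carbamidomethyl,
                               max_var_mods = max_var_mods,
                               proline_rule = proline_rule)),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("Dual-label peptide index: %d records (%d distinct sequences), mass %.2f-%.2f Da\n",
              nrow(x$peptides), length(unique(x$peptides$sequence)),
              min(x$peptides$monoisotopic_mass),
              max(x$peptides$monoisotopic_mass)))
  invisible(x)
}

#' Precursor-mass candidate lookup
#'
#' Returns all database peptides (either label) whose neutral monoisotopic
#' mass lies within a ppm tolerance of the observed precursor, the
#' dual-isotope analogue of a search engine's candidate selection.
#'
#' @param index A `"peptide_index"` from [build_dual_db()].
#' @param precursor_mz Observed precursor m/z.
#' @param charge Precursor charge (positive integer).
#' @param tol_ppm Mass tolerance in parts per million (default 10).
#' @return Subset of `index$peptides` matching the window (possibly empty).
#' @export
candidate_lookup <- function(index, precursor_mz, charge, tol_ppm = 10) {
  stopifnot(inherits(index, "peptide_index"))
  if (length(charge) != 1L || is.na(charge) || charge <= 0)
    stop("charge must be positive")
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  obs <- precursor_mz * charge - charge * .PROTON_MASS
  masses <- index$peptides$monoisotopic_mass
  lo <- obs / (1 + tol_ppm * 1e-6)
  hi <- obs / (1 - tol_ppm * 1e-6)
  i <- findInterval(c(lo, hi), masses)
  if (i[2L] <= i[1L] && (i[1L] == 0L || masses[i[1L]] < lo))
    return(index$peptides[0L, , drop = FALSE])
  sel <- seq.int(i[1L] + 1L, i[2L])
  # guard boundaries explicitly (findInterval is half-open)
  if (i[1L] >= 1L && masses[i[1L]] >= lo) sel <- c(i[1L], sel)
  out <- index$peptides[sel, , drop = FALSE]
  out[abs(obs - out$monoisotopic_mass) <=
        tol_ppm * out$monoisotopic_mass * 1e-6, , drop = FALSE]
}

.envelope_pair <- function(peptide, charge, oxidized_m = integer(0),
                           carbamidomethyl = TRUE, n15_incorporation = 0.99) {
  c14 <- composition_and_mass(peptide, carbamidomethyl = carbamidomethyl,
                              oxidized_m = oxidized_m, label = "N14")
  list(
    n14 = isotope_envelope(c14$composition, "N14", charge,
                           n15_incorporation = n15_incorporation),
    n15 = isotope_envelope(c14$composition, "N15", charge,
                           n15_incorporation = n15_incorporation))
}

.integrate_envelope <- function(scans, envelope, mz_tol_ppm, granularity) {
  if (!nrow(scans)) return(0)
  # union of scan peaks matched by any envelope peak: fine-structure
  # species closer than the tolerance must not be double counted
  hit <- logical(nrow(scans))
  for (mz in envelope$peaks$mz) {
    tol <- mz * mz_tol_ppm * 1e-6
    hit <- hit | abs(scans$mz - mz) <= tol
  }
  if (!any(hit)) return(0)
  matched <- scans[hit, , drop = FALSE]
  per_scan <- vapply(split(matched$intensity, matched$scan_index), sum, 0)
  if (granularity == "apex") max(per_scan) else sum(per_scan)
}

#' Quantify the 14N/15N MS1 area ratio of a peptide pair
#'
#' Integrates the matched envelope peaks of the light and heavy form across
#' MS1 scans and reports R = area(14N) / area(15N), the quantity the kinetic
#' model consumes.  When the heavy area falls below `area_floor` the ratio is
#' returned as missing with a reason rather than an error.
#'
#' @param scans An MS1 scan set: data.frame with columns `scan_index`, `mz`,
#'   `intensity` (centroided peaks), e.g. from [simulate_ms1()] or
#'   [read_ms1_tsv()].
#' @param peptide_pair Either a peptide sequence (envelopes are computed for
#'   both labels at `charge`) or a list with elements `n14` and `n15` of
#'   class `"isotope_envelope"`.
#' @param charge Charge state used when `peptide_pair` is a sequence.
#' @param mz_tol_ppm Peak-matching tolerance in ppm (default 10, mirroring
#'   the precursor tolerance).
#' @param rt_window Optional `c(first, last)` scan indices to integrate.
#' @param area_floor Minimum heavy-label area for a defined ratio.
#' @param granularity `"sum"` integrates areas over all scans in the window;
#'   `"apex"` uses the single most intense scan per label.
#' @param ... Passed to the envelope construction (e.g. `n15_incorporation`).
#' @return List with `ratio` (NA when missing), `area_n14`, `area_n15`,
#'   `missing` flag and `reason`.
#' @export
quantify_ratio <- function(scans, peptide_pair, charge = 2L, mz_tol_ppm = 10,
                           rt_window = NULL, area_floor = 1e-9,
                           granularity = c("sum", "apex"), ...) {
  granularity <- match.arg(granularity)
  stopifnot(is.data.frame(scans),
            all(c("scan_index", "mz", "intensity") %in% names(scans)))
  if (is.character(peptide_pair))
    peptide_pair <- .envelope_pair(peptide_pair, charge, ...)
  if (!is.null(rt_window)) {
    if (length(rt_window) != 2L || rt_window[2L] < rt_window[1L])
      stop("rt_window must be c(first, last) scan indices")
    scans <- scans[scans$scan_index >= rt_window[1L] &
                     scans$scan_index <= rt_window[2L], , drop = FALSE]
  }
  a14 <- .integrate_envelope(scans, peptide_pair$n14, mz_tol_ppm, granularity)
  a15 <- .integrate_envelope(scans, peptide_pair$n15, mz_tol_ppm, granularity)
  if (a15 < area_floor) {
    return(list(ratio = NA_real_, area_n14 = a14, area_n15 = a15,
                missing = TRUE, reason = "denominator below floor"))
  }
  list(ratio = a14 / a15, area_n14 = a14, area_n15 = a15,
       missing = FALSE, reason = NA_character_)
}

#' Read MS1 centroid peaks from the internal TSV format
#'
#' @param path TSV with columns `scan_index`, `mz`, `intensity`.
#' @return data.frame usable with [quantify_ratio()].
#' @export
read_ms1_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("scan_index", "mz", "intensity") %in% names(x)))
  x
}
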