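# Seeded synthetic-data generators.  Every input the pipeline consumes can
# be produced here with known ground truth, so each analysis module is
# testable end to end without external data.

# Spike-in RNA used for tRNA library normalization: an in-vitro transcript
# ending in a CCA tail and at least 3 nt away from every cellular tRNA
# (DNA transcript form of the published oligo).
.SPIKE_IN_DNA <- paste0(
  "CGAAATTAATACGACTCACTATAGGGGAATTGTGAGCGGATAACTGACTGACTGACTAAA",
  "TAATTTTGTTTAACTTTAAGAAGGAGATATACCA")

#' The default spike-in sequence
#'
#' @return DNA form of the spike-in RNA (ends in CCA).
#' @export
spike_in_sequence <- function() .SPIKE_IN_DNA

#' Specification for a turnover-labeling simulation
#'
#' Describes a pulse-labeling experiment: per-protein synthesis rate
#' constants drawn log-normally, sampling timepoints after the medium
#' switch, multiplicative measurement noise on the light/heavy ratio, and
#' an optional oxidative-stress condition in which synthesis is attenuated.
#'
#' @param n_proteins Number of proteins (default 500).
#' @param k_meanlog,k_sdlog Log-normal parameters of k_syn in per-minute
#'   units (defaults `log(0.007)` and `0.3`, i.e. a median half-life of
#'   about 99 minutes, the scale observed for an exponentially growing
#'   bacterial proteome).
#' @param timepoints Minutes since the medium switch (strictly increasing,
#'   default `c(15, 30, 60, 90)`).
#' @param noise_cv Multiplicative coefficient of variation on R
#'   (default 0.1).
#' @param condition `"normal"` or `"oxidative"`.
#' @param oxidative_attenuation Factor multiplying every k_syn under the
#'   oxidative condition (default 0.05: synthesis nearly abolished, so
#'   most half-lives exceed the 500-minute censoring cap).
#' @param seed Integer seed.
#' @return Object of class `"turnover_sim_spec"`.
#' @export
turnover_sim_spec <- function(n_proteins = 500, k_meanlog = log(0.007),
                              k_sdlog = 0.3, timepoints = c(15, 30, 60, 90),
                              noise_cv = 0.1,
                              condition = c("normal", "oxidative"),
                              oxidative_attenuation = 0.05, seed = 1) {
  condition <- match.arg(condition)
  if (any(diff(timepoints) <= 0) || any(timepoints <= 0))
    stop("timepoints must be positive and strictly increasing")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (oxidative_attenuation <= 0) stop("oxidative_attenuation must be > 0")
  structure(list(n_proteins = n_proteins, k_meanlog = k_meanlog,
                 k_sdlog = k_sdlog, timepoints = timepoints,
                 noise_cv = noise_cv, condition = condition,
                 oxidative_attenuation = oxidative_attenuation, seed = seed),
            class = "turnover_sim_spec")
}

#' Simulate light/heavy ratio series with known synthesis rates
#'
#' Inverts the kinetic model: at labeling time t the noiseless ratio is
#' R = 1 / (exp(k_syn t) - 1), then multiplicative log-normal noise with
#' the requested coefficient of variation (mean 1) is applied.  Ratios
#' exceeding `cap` (vanishing synthesis) are reported at the cap.
#'
#' @param spec A [turnover_sim_spec()].
#' @param cap Finite ceiling for near-infinite ratios (default 1e12).
#' @return List with `data` (long data.frame: `protein_id`, `time_min`,
#'   `ratio`) and `truth` (data.frame of `protein_id` and the true
#'   `k_syn`).
#' @export
simulate_turnover <- function(spec, cap = 1e12) {
  stopifnot(inherits(spec, "turnover_sim_spec"))
  set.seed(spec$seed)
  k <- rlnorm(spec$n_proteins, spec$k_meanlog, spec$k_sdlog)
  if (spec$condition == "oxidative") k <- k * spec$oxidative_attenuation
  ids <- sprintf("P%04d", seq_len(spec$n_proteins))
  tt <- spec$timepoints
  grid <- expand.grid(i = seq_len(spec$n_proteins), t = tt)
  r_true <- 1 / expm1(k[grid$i] * grid$t)
  if (spec$noise_cv > 0) {
    sdl <- sqrt(log(1 + spec$noise_cv^2))
    r_obs <- r_true * rlnorm(nrow(grid), -sdl^2 / 2, sdl)
  } else r_obs <- r_true
  data <- data.frame(protein_id = ids[grid$i], time_min = grid$t,
                     ratio = pmin(r_obs, cap), stringsAsFactors = FALSE)
  data <- data[order(data$protein_id, data$time_min), , drop = FALSE]
  rownames(data) <- NULL
  list(data = data,
       truth = data.frame(protein_id = ids, k_syn = k,
                          stringsAsFactors = FALSE))
}

#' Simulate centroided MS1 scans for light/heavy peptide pairs
#'
#' Emits a scan set containing the 14N and 15N isotope envelopes of each
#' peptide eluting with a Gaussian profile, with the light area equal to
#' `ratio` times the heavy area, optional additive intensity noise and
#' random noise peaks.
#'
#' @param peptides Character vector of peptide sequences, or data.frame
#'   with columns `sequence` and `charge`.
#' @param ratio Target 14N/15N area ratio (positive).
#' @param noise Additive intensity standard deviation (same units as
#'   `base_intensity`; 0 for noiseless scans).
#' @param n_scans Number of MS1 scans (default 21).
#' @param base_intensity Heavy-envelope base-peak scale (default 1e6).
#' @param charge Charge used for plain-character input (default 2).
#' @param n15_incorporation Heavy-label incorporation for the 15N
#'   envelopes.
#' @param seed Optional integer seed.
#' @return data.frame of centroided peaks (`scan_index`, `mz`,
#'   `intensity`), usable with [quantify_ratio()].
#' @export
simulate_ms1 <- function(peptides, ratio, noise = 0, n_scans = 21,
                         base_intensity = 1e6, charge = 2L,
                         n15_incorporation = 0.99, seed = NULL) {
  if (length(ratio) != 1L || !is.finite(ratio) || ratio < 0)
    stop("ratio must be a non-negative number")
  if (!is.null(seed)) set.seed(seed)
  if (is.character(peptides))
    peptides <- data.frame(sequence = peptides, charge = charge,
                           stringsAsFactors = FALSE)
  prof <- dnorm(seq_len(n_scans), mean = (n_scans + 1) / 2, sd = n_scans / 6)
  prof <- prof / max(prof)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(peptides))) {
    env <- .envelope_pair(peptides$sequence[i], peptides$charge[i],
                          n15_incorporation = n15_incorporation)
    for (s in seq_len(n_scans)) {
      for (lab in c("n14", "n15")) {
        scale <- base_intensity * prof[s] * if (lab == "n14") ratio else 1
        if (scale <= 0) next
        # normalize over the retained (floor-truncated) peaks so the summed
        # label areas realize the requested ratio exactly at zero noise
        rel <- env[[lab]]$peaks$intensity / sum(env[[lab]]$peaks$intensity)
        ints <- rel * scale
        # baseline-subtracted signal: additive noise is left unclipped so
        # integrated areas stay unbiased (small negatives are legitimate)
        if (noise > 0) ints <- ints + rnorm(length(ints), 0, noise)
        rows[[length(rows) + 1L]] <- data.frame(
          scan_index = s, mz = env[[lab]]$peaks$mz, intensity = ints)
      }
      if (noise > 0) {
        nn <- 3L
        rows[[length(rows) + 1L]] <- data.frame(
          scan_index = s, mz = runif(nn, 300, 1500),
          intensity = abs(rnorm(nn, 0, noise)))
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$scan_index, out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# deterministic species labels in the "<index>-<aa>(<anticodon>)" style
.TRNA_LABELS <- c(
  "Ala(GGC)", "Ala(TGC)", "Arg(ACG)", "Arg(CCG)", "Arg(CCT)", "Arg(TCT)",
  "Asn(GTT)", "Asp(GTC)", "Cys(GCA)", "Gln(CTG)", "Gln(TTG)", "Glu(TTC)",
  "Gly(CCC)", "Gly(GCC)", "Gly(TCC)", "His(GTG)", "Ile(GAT)", "Ile2(CAT)",
  "Leu(CAA)", "Leu(CAG)", "Leu(GAG)", "Leu(TAA)", "Leu(TAG)", "Lys(TTT)",
  "Met(CAT)", "fMet(CAT)", "Phe(GAA)", "Pro(CGG)", "Pro(GGG)", "Pro(TGG)",
  "SeC(TCA)", "Ser(CGA)", "Ser(GCT)", "Ser(GGA)", "Ser(TGA)", "Thr(CGT)",
  "Thr(GGT)", "Thr(TGT)", "Trp(CCA)", "Tyr(GTA)", "Val(GAC)", "Val(TAC)",
  "Val(GTA)", "Gly(ACC)", "Arg(GCG)", "Leu(GAA)", "Ile(TAT)")

#' Generate a synthetic tRNA reference set
#'
#' Builds `n` random tRNA-like references (default 47, the size of the
#' E. coli mature tRNA complement): 74-93 nt, ending in CCA, a small
#' number of them carrying tandem CCACCA 3' ends, each with a set of
#' modified positions away from the 3' tail.
#'
#' @param n Number of species (default 47).
#' @param n_tandem How many species get CCACCA ends (default 3).
#' @param n_modified Modified positions per species (default 9).
#' @param seed Integer seed.
#' @return Named list of `"trna_reference"` objects.
#' @export
simulate_trna_refs <- function(n = 47, n_tandem = 3, n_modified = 9, seed = 1) {
  set.seed(seed)
  labels <- sprintf("%d-%s", seq_len(n),
                    rep_len(.TRNA_LABELS, n))
  tandem <- seq_len(n) %in% sample.int(n, min(n_tandem, n))
  refs <- lapply(seq_len(n), function(i) {
    len <- sample(74:93, 1L)
    body <- paste(sample(c("A", "C", "G", "T"), len - 3L, replace = TRUE),
                  collapse = "")
    seqn <- paste0(body, if (tandem[i]) "CCACCA" else "CCA")
    mods <- sort(sample.int(nchar(seqn) - 6L, n_modified)) - 1L
    trna_reference(labels[i], seqn, mods)
  })
  names(refs) <- labels
  refs[order(labels)]
}

.seq_edit_distance <- function(a, b) {
  # semi-global errors of the shorter against the longer, both orientations
  min(.align_read_cpp(a, b, integer(0))$errors,
      .align_read_cpp(b, a, integer(0))$errors)
}

#' Specification for a tRNA sequencing simulation
#'
#' @param refs List of `"trna_reference"` (e.g. [simulate_trna_refs()]).
#' @param spike_in_seq Spike-in sequence, CCA-ended and at least 3 nt from
#'   every reference (default: the bundled spike-in).
#' @param species_abundance Named expected read counts per species under
#'   the normal condition; default: log-normal weights scaled to
#'   `read_count * (1 - spike_in_fraction)`.
#' @param fold_change Per-species (or scalar) factor by which expected
#'   counts decrease under stress (default 1).
#' @param truncation_pmf Named probability vector over 3'-truncation
#'   lengths `0..10` (names are the lengths; default: no truncation).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param modified_error_rate Substitution probability at modified
#'   positions, modeling reverse-transcription misreads (default 0.15).
#' @param read_count Total expected reads in the normal library
#'   (default 1e5).
#' @param spike_in_fraction Fraction of the library taken by the spike-in
#'   (default 0.05).  The spike-in input amount is a free experimental
#'   choice; it is emitted at its expected depth, equal across conditions,
#'   because the input amount is known by construction (see
#'   [simulate_trna_reads()]).
#' @param seed Integer seed.
#' @return Object of class `"trna_sim_spec"`.
#' @export
trna_sim_spec <- function(refs, spike_in_seq = spike_in_sequence(),
                          species_abundance = NULL, fold_change = 1,
                          truncation_pmf = c(`0` = 1), error_rate = 0.005,
                          modified_error_rate = 0.15, read_count = 1e5,
                          spike_in_fraction = 0.05, seed = 1) {
  if (!length(refs)) stop("empty reference set")
  if (!endsWith(spike_in_seq, "CCA")) stop("spike-in must end in CCA")
  if (abs(sum(truncation_pmf) - 1) > 1e-8)
    stop("truncation_pmf must sum to 1")
  if (is.null(names(truncation_pmf)))
    names(truncation_pmf) <- seq_along(truncation_pmf) - 1L
  if (any(fold_change <= 0)) stop("fold_change must be > 0")
  ids <- vapply(refs, `[[`, "", "species_id")
  for (r in refs)
    if (.seq_edit_distance(spike_in_seq, r$sequence) < 3L)
      stop(sprintf("spike-in deviates by fewer than 3 nt from %s",
                   r$species_id))
  if (is.null(species_abundance)) {
    set.seed(seed)
    w <- rlnorm(length(refs), 0, 0.5)
    species_abundance <- setNames(
      w / sum(w) * read_count * (1 - spike_in_fraction), ids)
  }
  fold_change <- if (length(fold_change) == 1L)
    setNames(rep(fold_change, length(refs)), ids) else fold_change
  structure(list(refs = refs, spike_in_seq = spike_in_seq,
                 species_abundance = species_abundance,
                 fold_change = fold_change,
                 truncation_pmf = truncation_pmf,
                 error_rate = error_rate,
                 modified_error_rate = modified_error_rate,
                 read_count = read_count,
                 spike_in_fraction = spike_in_fraction, seed = seed),
            class = "trna_sim_spec")
}

# substitute bases of n copies of one template, position-specific error
# probabilities; returns sequences and per-read error counts
.mutate_reads <- function(template, n, prob) {
  L <- nchar(template)
  chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  M <- matrix(chars, nrow = n, ncol = L, byrow = TRUE)
  hits <- matrix(runif(n * L) < rep(prob, each = n), nrow = n)
  nh <- sum(hits)
  if (nh) {
    bases <- c("A", "C", "G", "T")
    others <- matrix(c("C", "G", "T", "A", "G", "T",
                       "A", "C", "T", "A", "C", "G"),
                     nrow = 4, byrow = TRUE)
    cur <- match(M[hits], bases)
    repl <- others[cbind(cur, sample.int(3L, nh, replace = TRUE))]
    repl[is.na(cur)] <- "N"
    M[hits] <- repl
  }
  list(seqs = apply(M, 1L, paste, collapse = ""), n_errors = rowSums(hits))
}

#' Simulate a tRNA sequencing library with ground truth
#'
#' Reads are 3'-anchored copies of the reference (reverse transcription
#' primes from the 3'-CCA), truncated at the 3' end according to
#' `truncation_pmf`, with per-base substitution errors and an elevated
#' substitution rate at modified positions.  Spike-in reads are full-length
#' (in-vitro transcript, unmodified) with ordinary errors.  Per-species
#' counts are Poisson around the expected abundances, divided by the
#' species fold change under the `"oxidative"` condition.
#'
#' @param spec A [trna_sim_spec()].
#' @param condition `"normal"` or `"oxidative"`.
#' @return List with `reads` (named character vector), `truth` (data.frame
#'   `read_id`, `species_id`, `truncation`, `n_errors`), `counts` (named
#'   sampled per-species counts), `spike_in_count` and `condition`.
#' @export
simulate_trna_reads <- function(spec, condition = c("normal", "oxidative")) {
  stopifnot(inherits(spec, "trna_sim_spec"))
  condition <- match.arg(condition)
  set.seed(spec$seed + (condition == "oxidative"))
  ids <- vapply(spec$refs, `[[`, "", "species_id")
  lambda <- spec$species_abundance[ids]
  if (condition == "oxidative") lambda <- lambda / spec$fold_change[ids]
  counts <- setNames(rpois(length(lambda), lambda), ids)
  # the spike-in is added at a known amount, equal across conditions; it is
  # emitted at its expected depth so that normalization reflects the known
  # input rather than an extra draw of sampling noise (at real library
  # depths the spike Poisson CV is negligible anyway)
  spike_n <- as.integer(round(spec$spike_in_fraction * spec$read_count))
  trunc_lens <- as.integer(names(spec$truncation_pmf))
  chunks <- vector("list", 0L)
  for (i in seq_along(spec$refs)) {
    r <- spec$refs[[i]]
    nct <- counts[[i]]
    if (nct == 0L) next
    tr <- if (length(trunc_lens) == 1L) rep(trunc_lens, nct) else
      sample(trunc_lens, nct, replace = TRUE, prob = spec$truncation_pmf)
    for (tl in sort(unique(tr))) {
      g <- sum(tr == tl)
      keep <- nchar(r$sequence) - tl
      tmpl <- substr(r$sequence, 1L, keep)
      prob <- rep(spec$error_rate, keep)
      mp <- r$modified_mask[r$modified_mask < keep] + 1L
      prob[mp] <- spec$modified_error_rate
      mut <- .mutate_reads(tmpl, g, prob)
      chunks[[length(chunks) + 1L]] <- data.frame(
        seq = mut$seqs, species_id = r$species_id, truncation = tl,
        n_errors = mut$n_errors, stringsAsFactors = FALSE)
    }
  }
  if (spike_n > 0L) {
    mut <- .mutate_reads(spec$spike_in_seq, spike_n,
                         rep(spec$error_rate, nchar(spec$spike_in_seq)))
    chunks[[length(chunks) + 1L]] <- data.frame(
      seq = mut$seqs, species_id = "spike-in", truncation = 0L,
      n_errors = mut$n_errors, stringsAsFactors = FALSE)
  }
  pool <- do.call(rbind, chunks)
  out_seq <- pool$seq; out_sp <- pool$species_id
  out_tr <- pool$truncation; out_err <- pool$n_errors
  perm <- sample.int(length(out_seq))
  read_ids <- sprintf("read%07d", seq_along(out_seq))
  reads <- setNames(out_seq[perm], read_ids)
  list(reads = reads,
       truth = data.frame(read_id = read_ids, species_id = out_sp[perm],
                          truncation = out_tr[perm], n_errors = out_err[perm],
                          stringsAsFactors = FALSE),
       counts = counts, spike_in_count = spike_n, condition = condition)
}

#' Simulate an exponential growth curve
#'
#' OD(t) = od0 * exp(k t), with an optional transient arrest window during
#' which the rate is multiplied by `arrest$factor`, plus additive Gaussian
#' noise.
#'
#' @param k Growth rate constant per minute (negative = death).
#' @param od0 Initial OD (> 0, default 0.005).
#' @param duration Total minutes (default 300).
#' @param interval Sampling interval in minutes (default 1).
#' @param noise_sd Additive OD noise standard deviation (default 0).
#' @param arrest Optional `list(start =, end =, factor =)` arrest window.
#' @param seed Optional integer seed.
#' @return data.frame with `time_min` and `od`.
#' @export
simulate_growth <- function(k, od0 = 0.005, duration = 300, interval = 1,
                            noise_sd = 0, arrest = NULL, seed = NULL) {
  if (od0 <= 0) stop("od0 must be positive")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = interval)
  rate <- rep(k, length(tt))
  if (!is.null(arrest))
    rate[tt >= arrest$start & tt < arrest$end] <- k * arrest$factor
  # integrate the piecewise-constant rate over each interval
  logod <- log(od0) + c(0, cumsum(rate[-length(rate)] * diff(tt)))
  od <- exp(logod)
  if (noise_sd > 0) od <- od + rnorm(length(od), 0, noise_sd)
  data.frame(time_min = tt, od = od)
}

#' Simulate a qPCR CT table from known abundance changes
#'
#' CT values are generated as `ct0 - log2(quantity)` plus Gaussian noise,
#' so a q-fold decrease of a target raises its CT by log2(q) cycles.
#'
#' @param targets Named vector of target fold decreases under stress
#'   (e.g. `c(tRNA1 = 2.47)`).
#' @param reference_id Name of the normalizer (constant abundance).
#' @param ct0 Baseline CT for unit quantity (default 20).
#' @param noise_sd CT noise in cycles (default 0).
#' @param seed Optional integer seed.
#' @return data.frame with columns `target_id`, `condition`, `ct` covering
#'   both conditions for all targets plus the reference.
#' @export
simulate_ct_table <- function(targets, reference_id = "spike-in", ct0 = 20,
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- c(names(targets), reference_id)
  qty_normal <- setNames(rep(1, length(ids)), ids)
  qty_stress <- qty_normal
  qty_stress[names(targets)] <- 1 / targets
  mk <- function(qty, cond) data.frame(
    target_id = ids, condition = cond,
    ct = ct0 - log2(qty[ids]) + rnorm(length(ids), 0, noise_sd),
    stringsAsFactors = FALSE)
  out <- rbind(mk(qty_normal, "normal"), mk(qty_stress, "oxidative"))
  rownames(out) <- NULL
  out
}
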