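# Kyte-Doolittle hydropathy values
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2, X = 0)

#' Heuristic signal-peptide call
#'
#' A lightweight stand-in used only when no external signal-peptide call
#' table is supplied: windows of length 8 within the first 45 residues are
#' scanned; the protein is called secreted iff some window has mean
#' Kyte-Doolittle hydropathy >= 1.6 (a hydrophobic core) and the first five
#' residues contain a K/R or the sequence starts with M (a positively
#' charged or initiator N-region). The predicted cleavage position (last
#' residue of the signal peptide) is the end of the best window plus 3.
#' Sequences shorter than 30 residues are never called secreted. Whenever a
#' call table is provided it takes precedence over this heuristic.
#'
#' @param seq amino-acid sequence (single string).
#' @param min_core_hydropathy mean-hydropathy threshold (default 1.6).
#' @param window hydrophobic-core window length (default 8).
#' @return List (`SignalCall`): `is_secreted` (logical), `cleavage_pos`
#'   (integer or `NA`).
#' @export
call_signal_peptide <- function(seq, min_core_hydropathy = 1.6, window = 8) {
  L <- nchar(seq)
  if (L < 30) return(list(is_secreted = FALSE, cleavage_pos = NA_integer_))
  aa <- strsplit(seq, "")[[1]]
  h <- KD_HYDROPATHY[aa]
  h[is.na(h)] <- 0
  last_start <- min(45, L) - window + 1
  if (last_start < 1) return(list(is_secreted = FALSE,
                                  cleavage_pos = NA_integer_))
  means <- vapply(seq_len(last_start), function(s)
    mean(h[s:(s + window - 1)]), numeric(1))
  n_ok <- aa[1] == "M" || any(aa[1:5] %in% c("K", "R"))
  if (max(means) < min_core_hydropathy || !n_ok)
    return(list(is_secreted = FALSE, cleavage_pos = NA_integer_))
  best <- which.max(means)                     # earliest on ties
  cleavage <- min(best + window - 1 + 3, 45, L - 1)
  list(is_secreted = TRUE, cleavage_pos = as.integer(cleavage))
}

#' Find basic-residue cleavage sites downstream of a signal peptide
#'
#' Dibasic sites are left-to-right non-overlapping matches of
#' `KR|RR|KK|RK` (position = first residue of the pair). Monobasic sites
#' are single K/R residues not used by a dibasic site and preceded by
#' another K/R exactly 2, 4 or 6 residues upstream; the context residue
#' must itself be free-standing (not part of a dibasic site, which would
#' otherwise cleave inside canonical `KR`-flanked repeats) and lie
#' downstream of the signal peptide.
#'
#' @param seq amino-acid sequence.
#' @param signal_end 1-based position of the last signal-peptide residue
#'   (0 for none); must be < `nchar(seq)`.
#' @return data.frame with columns `position` (1-based, in the full
#'   sequence) and `motif_class` (`"dibasic"` or `"monobasic"`), sorted.
#' @export
find_cleavage_sites <- function(seq, signal_end) {
  L <- nchar(seq)
  if (signal_end >= L) stop("signal_end must be < sequence length")
  region <- substr(seq, signal_end + 1, L)
  aa <- strsplit(seq, "")[[1]]
  m <- gregexpr("KR|RR|KK|RK", region)[[1]]
  di_pos <- if (m[1] == -1) integer(0) else as.integer(m) + signal_end
  di_used <- c(di_pos, di_pos + 1L)
  is_basic <- aa %in% c("K", "R")
  is_context <- is_basic
  is_context[di_used] <- FALSE
  mono_pos <- integer(0)
  for (i in setdiff(which(is_basic), di_used)) {
    if (i <= signal_end) next
    up <- i - c(2L, 4L, 6L)
    up <- up[up > signal_end]
    if (any(is_context[up])) mono_pos <- c(mono_pos, i)
  }
  out <- data.frame(position = c(di_pos, mono_pos),
                    motif_class = c(rep("dibasic", length(di_pos)),
                                    rep("monobasic", length(mono_pos))),
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Enumerate candidate peptides between cleavage sites
#'
#' Peptides are the segments strictly between the signal peptide, the
#' cleavage-site residues, and the sequence end. A segment whose last
#' residue before a downstream cleavage site is G is flagged amidated and
#' the G is trimmed (C-terminal amidation donor); flanking K/R residues are
#' then trimmed from both ends. Segments with trimmed length in
#' `[min_len, max_len]` become peptides; others are discarded but
#' accounted for. Every post-signal residue is assigned to exactly one
#' category (site, trimmed basic, trimmed G, peptide, discarded), which
#' [audit_conservation()] verifies reconstitutes the sequence.
#'
#' @param seq amino-acid sequence.
#' @param signal_end last signal-peptide residue (0 for none).
#' @param sites data.frame from [find_cleavage_sites()].
#' @param min_len,max_len peptide length bounds (defaults 3 and 40).
#' @return List (`PrecursorCandidate`): `signal_end`, `sites`, `peptides`
#'   (data.frame `start`, `end`, `sequence`, `amidated`), `n_peptides`,
#'   `segments` (full per-interval accounting for the conservation audit).
#' @export
extract_peptides <- function(seq, signal_end, sites, min_len = 3,
                             max_len = 40) {
  L <- nchar(seq)
  blocks <- if (nrow(sites)) data.frame(
    start = sites$position,
    end = sites$position + ifelse(sites$motif_class == "dibasic", 1L, 0L)
  ) else data.frame(start = integer(0), end = integer(0))
  segs <- list()
  add_seg <- function(start, end, category) {
    if (end >= start)
      segs[[length(segs) + 1L]] <<- data.frame(
        start = start, end = end, category = category,
        stringsAsFactors = FALSE)
  }
  peptides <- list()
  bounds_start <- c(signal_end + 1L, blocks$end + 1L)
  bounds_end <- c(blocks$start - 1L, L)
  followed_by_site <- c(rep(TRUE, nrow(blocks)), FALSE)
  for (b in seq_len(nrow(blocks)))
    add_seg(blocks$start[b], blocks$end[b], "site")
  for (s in seq_along(bounds_start)) {
    a <- bounds_start[s]; z <- bounds_end[s]
    if (z < a) next
    amid <- FALSE
    if (followed_by_site[s] && substr(seq, z, z) == "G") {
      add_seg(z, z, "trimmed_G")
      z <- z - 1L
      amid <- TRUE
    }
    while (z >= a && substr(seq, a, a) %in% c("K", "R")) {
      add_seg(a, a, "trimmed_basic"); a <- a + 1L
    }
    while (z >= a && substr(seq, z, z) %in% c("K", "R")) {
      add_seg(z, z, "trimmed_basic"); z <- z - 1L
    }
    len <- z - a + 1L
    if (len >= min_len && len <= max_len) {
      add_seg(a, z, "peptide")
      peptides[[length(peptides) + 1L]] <- data.frame(
        start = a, end = z, sequence = substr(seq, a, z), amidated = amid,
        stringsAsFactors = FALSE)
    } else if (len > 0) {
      add_seg(a, z, if (len > max_len) "discarded_oversize"
                    else "discarded_undersize")
    }
  }
  pep <- if (length(peptides)) do.call(rbind, peptides) else
    data.frame(start = integer(0), end = integer(0),
               sequence = character(0), amidated = logical(0),
               stringsAsFactors = FALSE)
  seg_tab <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start = integer(0), end = integer(0),
               category = character(0), stringsAsFactors = FALSE)
  seg_tab <- seg_tab[order(seg_tab$start), , drop = FALSE]
  list(signal_end = signal_end, sites = sites, peptides = pep,
       n_peptides = nrow(pep), segments = seg_tab)
}

#' Verify that peptide extraction conserved the post-signal sequence
#'
#' Checks that the candidate's segment accounting partitions positions
#' `signal_end + 1 .. nchar(seq)` exactly once each, i.e. concatenating
#' cleaved residues, peptides, trimmed residues and discarded segments
#' reconstitutes the post-signal sequence.
#'
#' @param cand a [extract_peptides()] result.
#' @param seq the sequence it was derived from.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
audit_conservation <- function(cand, seq) {
  L <- nchar(seq)
  covered <- integer(0)
  for (r in seq_len(nrow(cand$segments))) {
    covered <- c(covered, cand$segments$start[r]:cand$segments$end[r])
  }
  expected <- if (cand$signal_end < L) (cand$signal_end + 1L):L else integer(0)
  if (length(covered) != length(expected) ||
      !identical(sort(covered), expected))
    stop("segment accounting does not partition the post-signal sequence")
  for (r in which(cand$segments$category == "peptide")) {
    s <- cand$segments[r, ]
    if (!substr(seq, s$start, s$end) %in% cand$peptides$sequence)
      stop("peptide segment text mismatch")
  }
  invisible(TRUE)
}

#' Scan a proteome for neuropeptide-precursor candidates
#'
#' For every protein: determine secretion (external call table if provided,
#' else the [call_signal_peptide()] heuristic); for secreted proteins, find
#' cleavage sites and extract candidate peptides. An external table is a
#' data.frame with columns `protein_id`, `is_secreted`, `cleavage_pos` and
#' optionally `d_score` (rows with `d_score` below `d_cutoff` are treated
#' as non-secreted, mirroring a sensitive secretome cutoff).
#'
#' @param seqs named character vector of protein sequences
#'   ([read_fasta()] output).
#' @param signal_calls optional external call table (takes precedence).
#' @param d_cutoff D-score cutoff applied to external tables that carry a
#'   `d_score` column (default 0.34).
#' @param min_len,max_len peptide length bounds.
#' @return Named list of `PrecursorCandidate`s (one per protein), each with
#'   `protein_id` and `is_secreted` filled in.
#' @export
np_scan <- function(seqs, signal_calls = NULL, d_cutoff = 0.34,
                    min_len = 3, max_len = 40) {
  out <- vector("list", length(seqs))
  names(out) <- names(seqs)
  for (id in names(seqs)) {
    seq <- seqs[[id]]
    call <- NULL
    if (!is.null(signal_calls) && id %in% signal_calls$protein_id) {
      row <- signal_calls[signal_calls$protein_id == id, , drop = FALSE][1, ]
      secreted <- isTRUE(as.logical(row$is_secreted))
      if (secreted && "d_score" %in% names(row) && !is.na(row$d_score) &&
          row$d_score < d_cutoff)
        secreted <- FALSE
      call <- list(is_secreted = secreted,
                   cleavage_pos = if (secreted) as.integer(row$cleavage_pos)
                                  else NA_integer_)
    } else {
      call <- call_signal_peptide(seq)
    }
    if (call$is_secreted && !is.na(call$cleavage_pos) &&
        call$cleavage_pos < nchar(seq)) {
      sites <- find_cleavage_sites(seq, call$cleavage_pos)
      cand <- extract_peptides(seq, call$cleavage_pos, sites,
                               min_len = min_len, max_len = max_len)
    } else {
      cand <- extract_peptides(seq, 0L,
                               data.frame(position = integer(0),
                                          motif_class = character(0)),
                               min_len = min_len, max_len = max_len)
      cand$peptides <- cand$peptides[0, , drop = FALSE]
      cand$n_peptides <- 0L
    }
    cand$protein_id <- id
    cand$is_secreted <- call$is_secreted
    cand$cleavage_pos <- call$cleavage_pos
    out[[id]] <- cand
  }
  out
}

#' Rank precursor candidates
#'
#' Retains secreted candidates with at least `min_peptides` peptides and
#' orders them lexicographically by (number of peptides, number of
#' amidated peptides, maximum pairwise peptide similarity) descending —
#' repeated similar (often amidated) peptide copies are the hallmark of
#' neuropeptide precursors. Similarity is the identity fraction of the
#' best gap-free overlap alignment of two peptides.
#'
#' @param candidates list from [np_scan()].
#' @param min_peptides minimum peptide count (default 2).
#' @return data.frame with columns `protein_id`, `n_peptides`,
#'   `n_amidated`, `max_similarity`, ranked.
#' @export
rank_candidates <- function(candidates, min_peptides = 2) {
  rows <- lapply(candidates, function(cand) {
    if (!isTRUE(cand$is_secreted) || cand$n_peptides < min_peptides)
      return(NULL)
    sim <- max_pairwise_similarity(cand$peptides$sequence)
    data.frame(protein_id = cand$protein_id, n_peptides = cand$n_peptides,
               n_amidated = sum(cand$peptides$amidated),
               max_similarity = sim, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(protein_id = character(0), n_peptides = integer(0),
                      n_amidated = integer(0), max_similarity = numeric(0),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab[order(-tab$n_peptides, -tab$n_amidated, -tab$max_similarity,
            tab$protein_id), , drop = FALSE]
}

max_pairwise_similarity <- function(peps) {
  if (length(peps) < 2) return(0)
  best <- 0
  for (i in seq_len(length(peps) - 1)) {
    for (j in (i + 1):length(peps)) {
      best <- max(best, gapfree_identity(peps[i], peps[j]))
    }
  }
  best
}

# identity fraction of the best gap-free overlap alignment (overlap >= 3
# or the shorter peptide's length, whichever is smaller)
gapfree_identity <- function(p1, p2) {
  a <- strsplit(p1, "")[[1]]; b <- strsplit(p2, "")[[1]]
  la <- length(a); lb <- length(b)
  min_ov <- min(3, la, lb)
  best <- 0
  for (off in (-lb + min_ov):(la - min_ov)) {
    ia <- max(1, 1 + off):min(la, lb + off)
    ib <- ia - off
    ov <- length(ia)
    if (ov < min_ov) next
    best <- max(best, sum(a[ia] == b[ib]) / ov)
  }
  best
}
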