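#' Default 23-nt universal sequencing anchor
#'
#' The anchor is the rolling-circle priming / sequencing-anchor segment
#' placed in the middle of the barcoded linker. It is a configuration
#' value: any 23-nt ACGT sequence may be supplied to the assembly and
#' design functions instead of this default.
#'
#' @return a 23-nt character scalar.
#' @export
default_anchor <- function() "CATCGTCCGATCAGTCAGGTACT"

#' Enumerate candidate 25-nt target windows
#'
#' Breaks a transcript into all k-mers (default 25) and removes windows
#' containing a guanine or cytosine homotetramer (GGGG/CCCC). The legacy
#' behaviour of filtering only GGGG is available via
#' \code{legacy_g_filter = TRUE}.
#'
#' Coordinates are 0-based half-open on the transcript.
#'
#' @param transcript one-row data.frame (columns \code{transcript_id},
#'   \code{sequence}) or a character scalar sequence.
#' @param k window length (default 25).
#' @param legacy_g_filter filter only GGGG homotetramers.
#' @return data.frame with columns \code{transcript_id}, \code{start},
#'   \code{target} (the window sequence).
#' @export
enumerate_candidates <- function(transcript, k = 25, legacy_g_filter = FALSE) {
  if (is.character(transcript))
    transcript <- data.frame(transcript_id = "t", sequence = transcript,
                             stringsAsFactors = FALSE)
  seq <- transcript$sequence[1]
  id <- transcript$transcript_id[1]
  .check_dna(seq, id)
  n <- nchar(seq)
  if (n < k) {
    warning("transcript ", id, " shorter than ", k, " nt; no candidates")
    return(data.frame(transcript_id = character(0), start = integer(0),
                      target = character(0), stringsAsFactors = FALSE))
  }
  nw <- n - k + 1L
  keep <- rep(TRUE, nw)
  pat <- if (legacy_g_filter) "(?=GGGG)" else "(?=GGGG|CCCC)"
  hits <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (hits[1] != -1L) {
    for (m in as.integer(hits)) {     # run occupies m..m+3 (1-based)
      lo <- max(1L, m - (k - 4L))     # windows fully containing the run
      hi <- min(nw, m)
      if (lo <= hi) keep[lo:hi] <- FALSE
    }
  }
  starts <- which(keep)               # 1-based window starts
  data.frame(transcript_id = rep(id, length(starts)),
             start = starts - 1L,
             target = if (length(starts)) substring(seq, starts,
                                                    starts + k - 1L)
                      else character(0),
             stringsAsFactors = FALSE)
}

#' Split a target window into probe hybridization arms
#'
#' The probe is antiparallel to the target, so its 5' arm is the reverse
#' complement of the target's 5'-side sub-window and its 3' arm the
#' reverse complement of the 3'-side sub-window; the ligation nick falls
#' between target positions \code{arm5_len} and \code{arm5_len + 1}.
#' The junction is reported as the ordered pair (probe 3'-terminal base,
#' probe 5'-terminal base) meeting at the nick.
#'
#' @param target target window sequence (transcript sense).
#' @param arm5_len length of the probe's 5' hybridization arm
#'   (default 18, giving the 18/7 split on a 25-nt window).
#' @return list with \code{arm5}, \code{arm3}, \code{junction}.
#' @examples
#' split_arms(strrep("A", 25))  # arms of 18 and 7 T's
#' @export
split_arms <- function(target, arm5_len = 18) {
  n <- nchar(target)
  if (arm5_len <= 0 || arm5_len >= n)
    stop("arm5_len must be strictly between 0 and ", n)
  arm5 <- revcomp(substr(target, 1L, arm5_len))
  arm3 <- revcomp(substr(target, arm5_len + 1L, n))
  junction <- paste0(substr(arm3, nchar(arm3), nchar(arm3)),
                     substr(arm5, 1L, 1L))
  list(arm5 = arm5, arm3 = arm3, junction = junction)
}

#' Default ligation-junction quality table
#'
#' Ordered junction pairs are classed by their expected RNA-splinted
#' ligation efficiency. Junctions containing G are disfavored (ligation
#' on G-containing nicks is poor), with TG, CG and GA the worst
#' performers; TC, CC and AC are favored; the remaining pairs are
#' neutral. Supply your own named vector to override.
#'
#' @return named character vector over all 16 ordered base pairs with
#'   values in \code{favored}, \code{neutral}, \code{disfavored}.
#' @export
default_junction_table <- function() {
  bases <- c("A", "C", "G", "T")
  pairs <- as.vector(outer(bases, bases, paste0))
  cls <- rep("neutral", 16)
  names(cls) <- pairs
  cls[grepl("G", pairs)] <- "disfavored"
  cls[c("TC", "CC", "AC")] <- "favored"
  cls
}

#' Ligation-junction quality class
#'
#' @param junction ordered two-base junction string.
#' @param table named classification vector; defaults to
#'   [default_junction_table()].
#' @return \code{"favored"}, \code{"neutral"} or \code{"disfavored"}.
#' @export
junction_quality <- function(junction, table = default_junction_table()) {
  if (!junction %in% names(table))
    stop("junction must be an ordered pair of ACGT bases")
  unname(table[junction])
}

#' Minimum-mismatch off-target screen
#'
#' Computes the minimum Hamming distance from a candidate target window
#' to every same-length window of every non-target transcript in the
#' reference, and passes the candidate when that minimum is at least
#' \code{min_mismatches}. The scan is ungapped and by default runs on
#' the sense strand only (mRNA targets); \code{scan_reverse = TRUE}
#' additionally scans the reverse complement of each reference.
#'
#' @param target candidate window sequence.
#' @param gene_id gene of the candidate (its own transcripts are
#'   excluded from the comparison).
#' @param reference data.frame of reference transcripts (from
#'   [filter_reference()]), columns \code{gene_id}, \code{sequence}.
#' @param min_mismatches pass threshold (default 6).
#' @param scan_reverse also scan reverse-complement windows.
#' @return list with \code{pass} (logical) and \code{min_mm} (integer;
#'   \code{Inf} when the non-target reference is empty).
#' @export
offtarget_screen <- function(target, gene_id, reference, min_mismatches = 6,
                             scan_reverse = FALSE) {
  k <- nchar(target)
  others <- reference[reference$gene_id != gene_id, , drop = FALSE]
  seqs <- others$sequence[nchar(others$sequence) >= k]
  if (scan_reverse) seqs <- c(seqs, revcomp(seqs))
  if (length(seqs) == 0L)
    return(list(pass = TRUE, min_mm = Inf))
  tg <- utf8ToInt(target)
  min_mm <- k
  for (s in seqs) {
    sv <- utf8ToInt(s)
    nw <- length(sv) - k + 1L
    mm <- integer(nw)
    for (j in seq_len(k)) mm <- mm + (sv[j:(j + nw - 1L)] != tg[j])
    m <- min(mm)
    if (m < min_mm) min_mm <- m
    if (min_mm == 0L) break
  }
  list(pass = min_mm >= min_mismatches, min_mm = as.integer(min_mm))
}

#' Secondary-structure score of an assembled probe
#'
#' Scores intramolecular structure of a single-stranded DNA oligo.
#' Lower (more negative) scores mean more predicted structure. The
#' default \code{"pairing"} backend is a deterministic maximum
#' base-pairing dynamic program over Watson-Crick pairs (G:C -3, A:T -2
#' per pair, an extra -1 per stacked pair, minimum hairpin loop of 3
#' unpaired bases). Scores are comparable only within one backend. The
#' optional \code{"rnafold"} backend shells out to an external
#' thermodynamic folding binary when available.
#'
#' @param probe_seq DNA sequence to fold.
#' @param backend \code{"pairing"} (default) or \code{"rnafold"}.
#' @return numeric score, \code{<= 0} for the pairing backend.
#' @examples
#' structure_score(strrep("A", 60))  # 0: a homopolymer cannot pair
#' @export
structure_score <- function(probe_seq, backend = c("pairing", "rnafold")) {
  backend <- match.arg(backend)
  .check_dna(probe_seq, "probe_seq")
  if (backend == "rnafold") return(.rnafold_score(probe_seq))
  .pairing_dp(probe_seq)
}

## Watson-Crick maximum-pairing DP with stacking bonus.
## P[i,j]: best (lowest) energy with i,j paired; M[i,j]: best over [i,j].
#' @keywords internal
.pairing_dp <- function(seq, e_gc = -3, e_at = -2, e_stack = -1,
                        min_loop = 3L) {
  b <- .dna_to_int(seq)
  n <- length(b)
  if (n < min_loop + 2L) return(0)
  pair_e <- matrix(Inf, 4, 4)
  pair_e[1 + 0, 1 + 3] <- e_at; pair_e[1 + 3, 1 + 0] <- e_at  # A:T
  pair_e[1 + 1, 1 + 2] <- e_gc; pair_e[1 + 2, 1 + 1] <- e_gc  # C:G
  P <- matrix(Inf, n, n)
  M <- matrix(0, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      e <- pair_e[b[i] + 1L, b[j] + 1L]
      if (is.finite(e)) {
        inner <- if (i + 1L <= j - 1L) M[i + 1L, j - 1L] else 0
        stacked <- if (i + 1L < j - 1L && is.finite(P[i + 1L, j - 1L]))
          P[i + 1L, j - 1L] + e_stack else Inf
        P[i, j] <- e + min(inner, stacked)
      }
      best <- min(M[i + 1L, j], M[i, j - 1L], P[i, j])
      if (span >= 2L) {
        ks <- i:(j - 1L)
        split <- min(M[i, ks] + M[cbind(ks + 1L, j)])
        best <- min(best, split)
      }
      M[i, j] <- best
    }
  }
  M[1L, n]
}

#' @keywords internal
.rnafold_score <- function(seq) {
  bin <- Sys.which("RNAfold")
  if (bin == "") stop("RNAfold binary not found on PATH")
  out <- system2(bin, args = c("--noPS"), input = seq, stdout = TRUE)
  last <- out[length(out)]
  mfe <- regmatches(last, regexpr("-?[0-9]+\\.?[0-9]*(?=\\s*\\)\\s*$)",
                                  last, perl = TRUE))
  if (length(mfe) == 0L) stop("could not parse RNAfold output")
  as.numeric(mfe)
}

#' Rank candidates by structure and keep the least-structured
#'
#' Candidates (already past the junction and off-target filters) are
#' ordered by structure score descending, so the least-structured probe
#' ranks first; ties are broken by ascending transcript coordinate. The
#' first \code{min(n, available)} candidates are returned with ranks
#' 1..n.
#'
#' @param candidates data.frame with columns \code{structure_dG} and
#'   \code{start}.
#' @param n number of probes to keep per target (default 10).
#' @return the selected rows with a \code{rank} column.
#' @export
rank_and_select <- function(candidates, n = 10) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  ord <- order(-candidates$structure_dG, candidates$start)
  sel <- candidates[ord, , drop = FALSE][seq_len(min(n, nrow(candidates))), ,
                                         drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Assemble a barcoded padlock probe
#'
#' Multiplexed layout (5' to 3'): 5' arm, 4-base barcode copy, 23-nt
#' anchor, 8-base barcode, 3' arm. The 4-base element is copied from
#' positions 5-8 of the 8-base barcode so that short sequencing reads
#' from either direction cover it. With the standard 18/7 arms the
#' total length is 18 + 4 + 23 + 8 + 7 = 60 nt. In singleplex mode
#' (\code{barcode8 = NULL}, two 6-base fillers supplied) the linker is
#' filler1 + anchor + filler2 (35 nt) and the probe is again 60 nt.
#'
#' @param arm5,arm3 probe hybridization arms.
#' @param anchor 23-nt universal anchor (default [default_anchor()]).
#' @param barcode8 8-base gene barcode, or NULL for singleplex mode.
#' @param fillers character vector of two 6-base fillers (singleplex).
#' @return assembled probe sequence.
#' @export
assemble_probe <- function(arm5, arm3, anchor = default_anchor(),
                           barcode8 = NULL, fillers = NULL) {
  if (nchar(anchor) != 23L) stop("anchor must be 23 nt")
  if (!is.null(barcode8)) {
    if (nchar(barcode8) != 8L) stop("barcode8 must be 8 nt")
    linker <- paste0(substr(barcode8, 5L, 8L), anchor, barcode8)
  } else {
    if (is.null(fillers) || length(fillers) != 2L ||
        any(nchar(fillers) != 6L))
      stop("singleplex mode requires two 6-base fillers")
    linker <- paste0(fillers[1], anchor, fillers[2])
  }
  paste0(arm5, linker, arm3)
}

#' Design padlock probes for a set of target transcripts
#'
#' Full design pipeline: enumerate 25-nt windows, drop homotetramer
#' windows, split arms at the 18/7 position, drop disfavored ligation
#' junctions, screen off-targets against the expressed reference at a
#' minimum Hamming distance, assemble the 60-nt barcoded oligo, score
#' its secondary structure and keep the least-structured \code{n_per_gene}
#' probes per target.
#'
#' Targets shorter than the footprint (mature miRNAs, 18-23 nt) are
#' designed in short-target mode: the whole target is used, the 3' arm
#' is kept at least 7 nt, and the split with the best junction class is
#' chosen in preference to the 18/7 proportion.
#'
#' @param targets data.frame of target transcripts (\code{transcript_id},
#'   \code{gene_id}, \code{sequence}).
#' @param reference data.frame of reference transcripts for the
#'   off-target screen (typically [filter_reference()] output). The
#'   targets' own genes are excluded per candidate.
#' @param assignment named character vector mapping gene_id to 8-base
#'   barcode (see [assign_barcodes()]); NULL designs unbarcoded probes
#'   scored on arms + linker with fillers.
#' @param anchor 23-nt anchor sequence.
#' @param n_per_gene probes kept per target (default 10).
#' @param arm5_len 5' arm length (default 18).
#' @param min_offtarget_mm minimum mismatches to any non-target window
#'   (default 6).
#' @param min_base_mean unused here; filter the reference beforehand.
#' @param junction_table junction classification, default
#'   [default_junction_table()].
#' @param scan_reverse also scan reverse-complement reference windows.
#' @param legacy_g_filter filter only GGGG homotetramers.
#' @param backend structure backend passed to [structure_score()].
#' @return data.frame of selected probes: transcript_id, gene_id, start,
#'   target, arm5, arm3, junction, offtarget_min_mm, structure_dG,
#'   probe_seq, rank.
#' @export
design_probes <- function(targets, reference, assignment = NULL,
                          anchor = default_anchor(), n_per_gene = 10,
                          arm5_len = 18, min_offtarget_mm = 6,
                          min_base_mean = 10,
                          junction_table = default_junction_table(),
                          scan_reverse = FALSE, legacy_g_filter = FALSE,
                          backend = "pairing") {
  out <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    tr <- targets[t, , drop = FALSE]
    short <- nchar(tr$sequence) < 25L
    cand <- if (short) {
      data.frame(transcript_id = tr$transcript_id, start = 0L,
                 target = tr$sequence, stringsAsFactors = FALSE)
    } else {
      enumerate_candidates(tr, k = 25, legacy_g_filter = legacy_g_filter)
    }
    if (nrow(cand) == 0L) next
    rows <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      arms <- if (short)
        .best_short_split(cand$target[i], junction_table)
      else split_arms(cand$target[i], arm5_len)
      if (is.null(arms)) next
      if (junction_quality(arms$junction, junction_table) == "disfavored")
        next
      ot <- offtarget_screen(cand$target[i], tr$gene_id, reference,
                             min_mismatches = min_offtarget_mm,
                             scan_reverse = scan_reverse)
      if (!ot$pass) next
      bc <- if (!is.null(assignment)) unname(assignment[tr$gene_id]) else NA
      probe <- if (!is.null(assignment) && !is.na(bc))
        assemble_probe(arms$arm5, arms$arm3, anchor, barcode8 = bc)
      else
        assemble_probe(arms$arm5, arms$arm3, anchor,
                       fillers = c("TATTAT", "ATTATA"))
      rows[[i]] <- data.frame(
        transcript_id = tr$transcript_id, gene_id = tr$gene_id,
        start = cand$start[i], target = cand$target[i],
        arm5 = arms$arm5, arm3 = arms$arm3, junction = arms$junction,
        offtarget_min_mm = ot$min_mm,
        structure_dG = structure_score(probe, backend = backend),
        probe_seq = probe, stringsAsFactors = FALSE)
    }
    kept <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(kept) || nrow(kept) == 0L) next
    out[[t]] <- rank_and_select(kept, n = n_per_gene)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame()
  rownames(res) <- NULL
  res
}

## Short-target (miRNA) arm split: whole target, 3' arm >= 7 nt, best
## junction class preferred over proportion; NULL if no split avoids a
## disfavored junction.
#' @keywords internal
.best_short_split <- function(target, junction_table) {
  n <- nchar(target)
  if (n - 7L < 2L) return(NULL)
  splits <- lapply(2:(n - 7L), function(a5) split_arms(target, a5))
  cls <- vapply(splits, function(s)
    junction_quality(s$junction, junction_table), character(1))
  rank <- match(cls, c("favored", "neutral", "disfavored"))
  ok <- rank < 3L
  if (!any(ok)) return(NULL)
  pref <- abs(vapply(splits, function(s) nchar(s$arm5), integer(1)) - (n - 7L))
  best <- order(rank, pref)[1]
  splits[[best]]
}

#' Write a probe order sheet
#'
#' Writes a TSV ready for plate-format oligo ordering (probe name,
#' sequence, 5'-phosphate flag, 96-well plate and well in row-major
#' A1..H12 order) and, optionally, a parallel FASTA.
#'
#' @param probes data.frame from [design_probes()] (needs
#'   \code{transcript_id}, \code{rank}, \code{probe_seq}).
#' @param path output TSV path.
#' @param fasta_path optional FASTA path.
#' @return invisibly, the written data.frame.
#' @export
write_order_sheet <- function(probes, path, fasta_path = NULL) {
  if (nrow(probes) == 0L) stop("no probes to write")
  n <- nrow(probes)
  idx <- seq_len(n) - 1L
  plate <- idx %/% 96L + 1L
  within <- idx %% 96L
  well <- paste0(LETTERS[within %/% 12L + 1L], within %% 12L + 1L)
  sheet <- data.frame(
    name = paste0(probes$transcript_id, "_p", probes$rank),
    sequence = probes$probe_seq,
    phosphate_5p = "yes",
    plate = plate, well = well, stringsAsFactors = FALSE)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    set <- Biostrings::DNAStringSet(sheet$sequence)
    names(set) <- sheet$name
    Biostrings::writeXStringSet(set, fasta_path)
  }
  invisible(sheet)
}

#' Read a probe order sheet
#'
#' @param path TSV written by [write_order_sheet()].
#' @return data.frame of the sheet.
#' @export
read_order_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
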