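## ORF extraction, annotation quality metrics, reciprocal-best-hit
## orthology, and the iterative homology-discovery loop over a pluggable
## search backend.

#' Find open reading frames in a transcript (6 frames)
#'
#' ATG-to-stop ORFs of at least `min_len_nt` (stop codon included) on both
#' strands; candidates containing N are excluded. With
#' `stop_to_stop = TRUE` the permissive variant reports maximal
#' stop-to-stop stretches instead.
#'
#' @param transcript DNA string over A, C, G, T, N.
#' @param min_len_nt minimum ORF length in nucleotides (multiple of 3).
#' @param id_prefix prefix for generated ORF ids.
#' @param parent id of the parent transcript.
#' @param stop_to_stop report maximal stop-to-stop ORFs instead of
#'   ATG-to-stop.
#' @return data.frame `id, parent_transcript, strand, frame, start, end,
#'   nt_sequence, aa_sequence` sorted by length descending. Coordinates are
#'   1-based on the forward strand of the input.
#' @export
find_orfs <- function(transcript, min_len_nt = 300L, id_prefix = "orf",
                      parent = "transcript", stop_to_stop = FALSE) {
  transcript <- toupper(as.character(transcript))
  if (nchar(transcript) == 0L) return(.empty_orfs())
  if (min_len_nt %% 3L != 0L) stop("min_len_nt must be a multiple of 3")
  n <- nchar(transcript)
  scan_strand <- function(seq, strand) {
    res <- list()
    for (frame in 0:2) {
      usable <- nchar(seq) - frame
      n_cod <- usable %/% 3L
      if (n_cod < 2L) next
      starts <- frame + seq(1L, by = 3L, length.out = n_cod)
      cods <- substring(seq, starts, starts + 2L)
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      is_start <- cods == "ATG"
      stop_idx <- which(is_stop)
      if (stop_to_stop) {
        bounds <- c(0L, stop_idx)
        for (b in seq_len(length(bounds) - 1L)) {
          from <- bounds[b] + 1L; to <- bounds[b + 1L]
          if (to < from) next
          res[[length(res) + 1L]] <- c(from, to, frame)
        }
      } else {
        start_idx <- which(is_start)
        for (s in start_idx) {
          nxt <- stop_idx[stop_idx > s]
          if (length(nxt) == 0L) next
          res[[length(res) + 1L]] <- c(s, nxt[1L], frame)
        }
      }
    }
    if (length(res) == 0L) return(NULL)
    do.call(rbind, lapply(res, function(x) {
      from_cod <- x[1]; to_cod <- x[2]; frame <- x[3]
      nt_start <- frame + (from_cod - 1L) * 3L + 1L
      nt_end <- frame + to_cod * 3L
      nt <- substr(seq, nt_start, nt_end)
      data.frame(strand = strand, frame = frame, s = nt_start, e = nt_end,
                 nt_sequence = nt, stringsAsFactors = FALSE)
    }))
  }
  fwd <- scan_strand(transcript, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(transcript)))
  rev <- scan_strand(rc, "-")
  orfs <- rbind(fwd, rev)
  if (is.null(orfs) || nrow(orfs) == 0L) return(.empty_orfs())
  orfs <- orfs[nchar(orfs$nt_sequence) >= min_len_nt, , drop = FALSE]
  orfs <- orfs[!grepl("N", orfs$nt_sequence, fixed = TRUE), , drop = FALSE]
  if (nrow(orfs) == 0L) return(.empty_orfs())
  ## convert minus-strand coordinates back to forward-strand positions
  minus <- orfs$strand == "-"
  start_fwd <- ifelse(minus, n - orfs$e + 1L, orfs$s)
  end_fwd <- ifelse(minus, n - orfs$s + 1L, orfs$e)
  aa <- vapply(orfs$nt_sequence, function(x) {
    a <- translate_dna(x)
    sub("\\*$", "", a)
  }, character(1L), USE.NAMES = FALSE)
  out <- data.frame(
    id = character(nrow(orfs)), parent_transcript = parent,
    strand = orfs$strand, frame = orfs$frame,
    start = as.integer(start_fwd), end = as.integer(end_fwd),
    nt_sequence = orfs$nt_sequence, aa_sequence = aa,
    stringsAsFactors = FALSE)
  out <- out[order(-nchar(out$nt_sequence), out$start), , drop = FALSE]
  out$id <- sprintf("%s_%02d", id_prefix, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

.empty_orfs <- function() {
  data.frame(id = character(0), parent_transcript = character(0),
             strand = character(0), frame = integer(0), start = integer(0),
             end = integer(0), nt_sequence = character(0),
             aa_sequence = character(0), stringsAsFactors = FALSE)
}

#' Completeness and contiguity of a segmented reconstruction
#'
#' Completeness: percent of reference residues covered by the union of
#' segments. Contiguity: percent covered by the single longest segment.
#'
#' @param segments data.frame or matrix with `start`, `end` columns
#'   (1-based, closed, reference coordinates).
#' @param reference_length length of the reference protein (> 0).
#' @return c(completeness = %, contiguity = %).
#' @export
completeness_contiguity <- function(segments, reference_length) {
  if (reference_length <= 0) stop("empty reference")
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0L)
    return(c(completeness = 0, contiguity = 0))
  covered <- logical(reference_length)
  seg_len <- numeric(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- max(1L, segments$start[i]); e <- min(reference_length, segments$end[i])
    if (e >= s) {
      covered[s:e] <- TRUE
      seg_len[i] <- e - s + 1L
    }
  }
  c(completeness = 100 * sum(covered) / reference_length,
    contiguity = 100 * max(seg_len) / reference_length)
}

#' Column identity of two equal-length sequences
#' @param a,b character sequences.
#' @return fraction of matching positions.
#' @export
sequence_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Reciprocal best-hit orthologs between two sequence sets
#'
#' Candidate pairs have identical length; identity is column-wise
#' (matches / length). A pair is orthologous when each member is the other's
#' unique best-identity match and identity >= `min_identity`. Best-hit ties
#' are broken by lexicographically smallest id and flagged.
#'
#' @param set_A,set_B named character vectors of sequences.
#' @param min_identity minimum identity (default 0.95).
#' @return list with `pairs` (data.frame `id_A, id_B, length_nt, identity,
#'   tie_flag`) and `unpaired_A`, `unpaired_B` id vectors.
#' @export
reciprocal_orthologs <- function(set_A, set_B, min_identity = 0.95) {
  stopifnot(length(set_A) > 0, length(set_B) > 0)
  len_A <- nchar(set_A); len_B <- nchar(set_B)
  best_hit <- function(seqs_from, seqs_to, len_from, len_to) {
    ## returns for each 'from' record its best match id in 'to' (or NA)
    out_id <- rep(NA_character_, length(seqs_from))
    out_idy <- rep(NA_real_, length(seqs_from))
    out_tie <- rep(FALSE, length(seqs_from))
    for (i in seq_along(seqs_from)) {
      cand <- which(len_to == len_from[i])
      if (length(cand) == 0L) next
      idy <- vapply(cand, function(j)
        sequence_identity(seqs_from[[i]], seqs_to[[j]]), numeric(1L))
      mx <- max(idy)
      winners <- cand[idy >= mx - 1e-12]
      wid <- names(seqs_to)[winners]
      pick <- sort(wid)[1L]
      out_id[i] <- pick
      out_idy[i] <- mx
      out_tie[i] <- length(winners) > 1L
    }
    list(id = out_id, identity = out_idy, tie = out_tie)
  }
  ab <- best_hit(set_A, set_B, len_A, len_B)
  ba <- best_hit(set_B, set_A, len_B, len_A)
  pairs <- list()
  for (i in seq_along(set_A)) {
    j_id <- ab$id[i]
    if (is.na(j_id)) next
    j <- match(j_id, names(set_B))
    if (is.na(ba$id[j]) || ba$id[j] != names(set_A)[i]) next
    if (ab$identity[i] < min_identity) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      id_A = names(set_A)[i], id_B = j_id,
      length_nt = nchar(set_A[[i]]), identity = ab$identity[i],
      tie_flag = ab$tie[i] || ba$tie[j], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(id_A = character(0), id_B = character(0),
               length_nt = integer(0), identity = numeric(0),
               tie_flag = logical(0), stringsAsFactors = FALSE)
  list(pairs = pairs,
       unpaired_A = setdiff(names(set_A), pairs$id_A),
       unpaired_B = setdiff(names(set_B), pairs$id_B))
}

#' Default protein-vs-transcript search backend
#'
#' Local alignment (Smith-Waterman, BLOSUM62, affine gaps) of each query
#' protein against the six-frame translations of each transcript. Returns a
#' raw alignment score per (query, transcript) pair — a self-contained,
#' offline stand-in for an e-value-based search tool.
#'
#' @param queries named character vector of protein sequences.
#' @param transcripts named character vector of DNA sequences.
#' @return data.frame `query, transcript, score`.
#' @export
alignment_search <- function(queries, transcripts) {
  six_frames <- function(dna) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dna)))
    frames <- character(0)
    for (s in c(dna, rc)) {
      for (f in 0:2) {
        usable <- (nchar(s) - f) %/% 3L * 3L
        if (usable < 3L) next
        aa <- translate_dna(substr(s, f + 1L, f + usable))
        frames <- c(frames, strsplit(aa, "\\*")[[1]])
      }
    }
    frames[nchar(frames) > 0]
  }
  rows <- list()
  for (tn in names(transcripts)) {
    frames <- six_frames(transcripts[[tn]])
    if (length(frames) == 0L) next
    subj <- Biostrings::AAStringSet(frames)
    for (qn in names(queries)) {
      sc <- max(Biostrings::pairwiseAlignment(
        subj, Biostrings::AAString(queries[[qn]]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
        type = "local", scoreOnly = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        query = qn, transcript = tn, score = sc, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(0), transcript = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Iterative homology discovery over a pluggable search backend
#'
#' Repeats search -> ORF extraction -> validation -> query augmentation
#' until no new ORFs are found (a fixed point; the query set grows
#' monotonically and is bounded, so the loop terminates).
#'
#' @param transcripts named character vector of DNA transcripts.
#' @param seed_queries named character vector of seed protein queries.
#' @param search_fn function(queries, transcripts) -> data.frame
#'   `query, transcript, score` (default [alignment_search()]).
#' @param score_threshold minimum score to accept a hit.
#' @param min_orf_len minimum ORF length (nt) for the family.
#' @param max_iterations safety cap (default 20); exceeding it is an error.
#' @return data.frame of candidate ORFs (as [find_orfs()]), deduplicated by
#'   nucleotide sequence.
#' @export
iterative_discovery <- function(transcripts, seed_queries,
                                search_fn = alignment_search,
                                score_threshold = 50,
                                min_orf_len = 300L,
                                max_iterations = 20L) {
  stopifnot(score_threshold > 0, min_orf_len > 0)
  queries <- seed_queries
  found <- .empty_orfs()
  seen_nt <- character(0)
  for (iter in seq_len(max_iterations)) {
    hits <- search_fn(queries, transcripts)
    hits <- hits[hits$score >= score_threshold, , drop = FALSE]
    new_orfs <- .empty_orfs()
    for (tn in unique(hits$transcript)) {
      orfs <- find_orfs(transcripts[[tn]], min_len_nt = min_orf_len,
                        id_prefix = tn, parent = tn)
      if (nrow(orfs) == 0L) next
      ## validate each ORF against the current query library
      keep <- logical(nrow(orfs))
      for (k in seq_len(nrow(orfs))) {
        if (orfs$nt_sequence[k] %in% seen_nt) next
        vh <- search_fn(queries,
                        stats::setNames(orfs$nt_sequence[k], orfs$id[k]))
        keep[k] <- nrow(vh) > 0 && max(vh$score) >= score_threshold
      }
      new_orfs <- rbind(new_orfs, orfs[keep, , drop = FALSE])
    }
    if (nrow(new_orfs) == 0L) return(found)
    found <- rbind(found, new_orfs)
    seen_nt <- c(seen_nt, new_orfs$nt_sequence)
    add <- stats::setNames(new_orfs$aa_sequence, new_orfs$id)
    queries <- c(queries, add[!add %in% queries])
  }
  stop("iterative_discovery did not reach a fixed point within ",
       max_iterations, " iterations")
}
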