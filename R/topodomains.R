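## Consensus membrane topology, ligand-binding-domain transfer, and
## substitution-to-domain mapping for 7-TM receptor proteins.

.protein_length_of <- function(annotation) max(annotation$end)

## Per-residue TM membership vector from an interval annotation.
.tm_mask <- function(annotation, len) {
  mask <- logical(len)
  tm <- annotation[grepl("^TM", annotation$label), , drop = FALSE]
  for (i in seq_len(nrow(tm)))
    mask[tm$start[i]:tm$end[i]] <- TRUE
  mask
}

#' Consensus topology from several predictor annotations
#'
#' A residue is consensus-TM when at least `min_support` predictors place it
#' inside a TM interval; maximal runs become consensus TM intervals numbered
#' from the N-terminus. Non-TM stretches are labelled by position: IN before
#' TM1 (intracellular N-terminus), then alternating EL/IL loops, EC after
#' the last TM.
#'
#' @param annotations list of >= `min_support` interval data.frames
#'   (`protein_id, start, end, label, predictor`) for one protein.
#' @param protein_length residues (default: max end over annotations).
#' @param min_support predictor votes required (default 2).
#' @return consensus annotation data.frame (predictor = "consensus").
#' @export
consensus_topology <- function(annotations, protein_length = NULL,
                               min_support = 2L) {
  if (length(annotations) < min_support)
    stop("need at least ", min_support, " predictor annotations")
  pid <- annotations[[1]]$protein_id[1]
  if (is.null(protein_length))
    protein_length <- max(vapply(annotations, .protein_length_of, numeric(1)))
  votes <- Reduce(`+`, lapply(annotations, function(a)
    as.integer(.tm_mask(a, protein_length))))
  tm <- votes >= min_support
  r <- rle(tm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- list()
  tm_count <- 0L
  n_tm_total <- sum(r$values)
  loop_i <- 0L
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      tm_count <- tm_count + 1L
      lab <- paste0("TM", tm_count)
    } else {
      lab <- if (tm_count == 0L) "IN"
        else if (tm_count == n_tm_total) "EC"
        else if (tm_count %% 2L == 1L) "EL" else "IL"
    }
    iv[[k]] <- data.frame(protein_id = pid, start = starts[k], end = ends[k],
                          label = lab, predictor = "consensus",
                          stringsAsFactors = FALSE)
  }
  do.call(rbind, iv)
}

#' Transfer interval annotations through a global protein alignment
#'
#' Aligns query and reference (Needleman-Wunsch, BLOSUM62, affine gaps) and
#' projects the reference intervals onto query coordinates. Reference
#' positions aligned to gaps contract the interval to the aligned residues
#' it still covers.
#'
#' @param query,reference protein sequences (character).
#' @param intervals data.frame `start, end, label` in reference coordinates.
#' @return data.frame of projected intervals in query coordinates, with a
#'   `low_identity` attribute flag when alignment identity < 15%.
#' @export
transfer_lbd <- function(query, reference, intervals) {
  stopifnot(nchar(query) > 0, nchar(reference) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  ## map: reference position -> query position (NA when aligned to a gap)
  map <- rep(NA_integer_, nchar(reference))
  aligned <- which(qa != "-" & ra != "-")
  map[rpos[aligned]] <- qpos[aligned]
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    hit <- map[intervals$start[i]:intervals$end[i]]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) return(NULL)
    data.frame(start = min(hit), end = max(hit),
               label = intervals$label[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  ident <- sum(qa == ra & qa != "-") / sum(qa != "-" & ra != "-")
  attr(out, "low_identity") <- ident < 0.15
  attr(out, "identity") <- ident
  out
}

#' Fraction of a protein covered by intervals with given labels
#'
#' @param topology annotation data.frame.
#' @param labels labels to count (regular prefixes allowed via `tm = TRUE`).
#' @param tm if TRUE, any label starting with "TM" matches.
#' @param protein_length residues (default max end).
#' @return fraction in [0, 1].
#' @export
domain_fraction <- function(topology, labels = NULL, tm = FALSE,
                            protein_length = NULL) {
  if (is.null(protein_length)) protein_length <- .protein_length_of(topology)
  sel <- if (tm) grepl("^TM", topology$label) else topology$label %in% labels
  sum(topology$end[sel] - topology$start[sel] + 1) / protein_length
}

#' Map substitution sites onto a topology
#'
#' Each site is assigned the unique interval containing it; sites falling in
#' an annotation gap are assigned the nearest flanking non-TM label and
#' flagged. The in-LBD flag is TRUE when the assigned label is a TM domain
#' (odorant receptors) or S1/S2 (ionotropic receptors).
#'
#' @param positions 1-based residue positions of (non-synonymous)
#'   substitutions.
#' @param topology annotation data.frame.
#' @param lbd_labels labels counted as ligand-binding ("TM" prefix plus
#'   S1/S2 by default).
#' @return list with `sites` (position, label, in_lbd, gap_flag) and
#'   `counts` (named per-label tally).
#' @export
map_substitutions <- function(positions, topology,
                              lbd_labels = c("S1", "S2")) {
  len <- .protein_length_of(topology)
  lab <- character(length(positions))
  gap <- logical(length(positions))
  for (k in seq_along(positions)) {
    p <- positions[k]
    if (p < 1 || p > len) stop("site position ", p, " outside protein")
    hit <- which(topology$start <= p & topology$end >= p)
    if (length(hit) >= 1L) {
      lab[k] <- topology$label[hit[1]]
    } else {
      ## annotation gap: nearest flanking non-TM interval
      gap[k] <- TRUE
      non_tm <- topology[!grepl("^TM", topology$label), , drop = FALSE]
      d <- pmin(abs(non_tm$start - p), abs(non_tm$end - p))
      lab[k] <- non_tm$label[which.min(d)]
    }
  }
  in_lbd <- grepl("^TM", lab) | lab %in% lbd_labels
  counts <- table(factor(lab, levels = unique(topology$label)))
  sites <- data.frame(position = positions, label = lab, in_lbd = in_lbd,
                      gap_flag = gap, stringsAsFactors = FALSE)
  list(sites = sites, counts = c(counts))
}

#' Pooled ligand-binding-domain enrichment test
#'
#' Pools substitutions across genes; the expected in-LBD fraction is the
#' unweighted mean of the per-protein LBD coverage fractions; delegates to
#' [chisq_gof()].
#'
#' @param n_sites,n_in_lbd,lbd_fraction equal-length per-gene vectors.
#' @return [chisq_gof()] result with `observed_in`, `total`,
#'   `expected_fraction` attached.
#' @export
lbd_enrichment <- function(n_sites, n_in_lbd, lbd_fraction) {
  stopifnot(length(n_sites) == length(n_in_lbd),
            length(n_sites) == length(lbd_fraction))
  total <- sum(n_sites)
  if (total == 0) stop("no substitutions to test")
  f <- mean(lbd_fraction)
  res <- chisq_gof(sum(n_in_lbd), total, f)
  res$observed_in <- sum(n_in_lbd)
  res$total <- total
  res$expected_fraction <- f
  res
}

## Canonical 15-slot domain order for a 7-TM receptor with intracellular
## N-terminus.
CANONICAL_7TM_ORDER <- c("IN", "TM1", "EL1", "TM2", "IL1", "TM3", "EL2",
                         "TM4", "IL2", "TM5", "EL3", "TM6", "IL3", "TM7",
                         "EC")

#' Spatial profile of substitutions over the canonical 7-TM domain order
#'
#' @param positions substitution residue positions.
#' @param topology consensus annotation (intervals in N-to-C order).
#' @return list with `histogram` (named counts over the canonical order),
#'   `n_half`, `c_half` (counts split at the protein midpoint).
#' @export
spatial_profile <- function(positions, topology) {
  len <- .protein_length_of(topology)
  ## name loop intervals positionally to match the canonical order
  labs <- topology$label
  el <- which(labs == "EL"); il <- which(labs == "IL")
  labs[el] <- paste0("EL", seq_along(el))
  labs[il] <- paste0("IL", seq_along(il))
  hist <- stats::setNames(rep(0L, length(CANONICAL_7TM_ORDER)),
                          CANONICAL_7TM_ORDER)
  for (p in positions) {
    hit <- which(topology$start <= p & topology$end >= p)
    if (length(hit) == 0L) next
    lab <- labs[hit[1]]
    if (lab %in% names(hist)) hist[lab] <- hist[lab] + 1L
  }
  mid <- len / 2
  list(histogram = hist,
       n_half = sum(positions <= mid),
       c_half = sum(positions > mid))
}
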