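## Shared codon machinery: standard-code tables, single-step codon pair
## structure used by both the NG86 counter and the GY94 rate matrix.

.poolsel_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' Standard genetic code lookup for a vector of codons
#'
#' @param codons character vector of 3-letter codons (uppercase DNA).
#' @return amino-acid characters, `"*"` for stop codons.
#' @keywords internal
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("invalid codon(s): ", paste(codons[is.na(aa)], collapse = ", "))
  aa
}

#' Codon model structure (cached)
#'
#' Enumerates the 61 sense codons of the standard code and every ordered
#' single-nucleotide neighbour pair, annotated as transition/transversion and
#' synonymous/non-synonymous. This is the backbone of both the GY94 generator
#' and the NG86 site counter.
#'
#' @return list with `codons`, `aa`, `index` (named codon->1..61), and pair
#'   vectors `pi_` (from), `pj_` (to, pj > pi), `ts` (logical transition),
#'   `syn` (logical synonymous), `pos` (codon position 1..3 that differs).
#' @keywords internal
codon_structure <- function() {
  if (!is.null(.poolsel_cache$codon)) return(.poolsel_cache$codon)
  grid <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                      stringsAsFactors = FALSE)
  codons64 <- paste0(grid$p1, grid$p2, grid$p3)
  aa64 <- translate_codons(codons64)
  sense <- aa64 != "*"
  codons <- codons64[sense]
  aa <- aa64[sense]
  n <- length(codons)           # 61
  mat <- do.call(rbind, strsplit(codons, ""))
  is_transition <- function(x, y) {
    (x %in% c("A", "G") & y %in% c("A", "G")) |
      (x %in% c("C", "T") & y %in% c("C", "T"))
  }
  pi_ <- integer(0); pj_ <- integer(0); ts <- logical(0)
  syn <- logical(0); pos <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      diffs <- which(mat[i, ] != mat[j, ])
      if (length(diffs) != 1L) next
      d <- diffs[1L]
      pi_ <- c(pi_, i); pj_ <- c(pj_, j)
      ts <- c(ts, is_transition(mat[i, d], mat[j, d]))
      syn <- c(syn, aa[i] == aa[j])
      pos <- c(pos, d)
    }
  }
  out <- list(codons = codons, aa = aa,
              index = stats::setNames(seq_len(n), codons),
              mat = mat, pi_ = pi_, pj_ = pj_, ts = ts, syn = syn, pos = pos,
              ## precomputed helpers for the hot GY94 path
              ts_num = as.numeric(ts), nonsyn_num = as.numeric(!syn),
              idx_up = (pj_ - 1L) * n + pi_, idx_lo = (pi_ - 1L) * n + pj_)
  .poolsel_cache$codon <- out
  out
}

#' Split an in-frame DNA string into codons
#' @keywords internal
split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate an in-frame DNA string (character in, character out)
#' @keywords internal
translate_dna <- function(seq) {
  paste(translate_codons(split_codons(seq)), collapse = "")
}

## Sense (non-stop) codons, optionally excluding those one step from a stop.
sense_codons <- function() codon_structure()$codons

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")
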