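## Fixed/polymorphic site classification from two species' pooled pileups.
##
## Implements the read-count calling rules: a nucleotide is *present* when
## supported by at least max(floor, frac x depth) reads; a site is *fixed*
## when one species shows a >= 95% majority base that is absent from the
## other species' pool; a site with two or more present alleles in either
## species (and no fixed call) is *polymorphic*; sites below the per-site
## depth floor are *unclassifiable*; everything else is *invariant*.

#' Present alleles at one pileup column
#'
#' A base is deemed present when supported by at least `floor_reads` reads,
#' or `frac` of all reads when that is higher (strict "max of the two" rule).
#'
#' @param counts named numeric vector (A, C, G, T).
#' @param depth total reads at the site (defaults to sum of counts).
#' @param floor_reads minimum absolute read support (default 5).
#' @param frac minimum fractional support (default 0.05).
#' @return character vector of present bases (possibly empty).
#' @export
allele_presence <- function(counts, depth = sum(counts),
                            floor_reads = 5, frac = 0.05) {
  if (depth < 1) return(character(0))
  thr <- max(floor_reads, frac * depth)
  BASES[counts[BASES] >= thr]
}

## Vectorized internals: count matrices are n_sites x 4 (A,C,G,T).
.presence_matrix <- function(counts, floor_reads, frac) {
  depth <- rowSums(counts)
  thr <- pmax(floor_reads, frac * depth)
  counts >= thr & depth >= 1
}

.major_allele <- function(counts) {
  ## ties broken by base order A < C < G < T (max.col "first")
  idx <- max.col(counts, ties.method = "first")
  list(base = BASES[idx],
       freq = counts[cbind(seq_len(nrow(counts)), idx)] /
         pmax(rowSums(counts), 1),
       tie = rowSums(counts == counts[cbind(seq_len(nrow(counts)), idx)]) > 1)
}

#' Classify one site from paired pileup columns
#'
#' @param col_A,col_B named count vectors (A,C,G,T) for the two species.
#' @param min_site_depth per-site depth floor in both species (default 10).
#' @param fixed_major_freq majority frequency required for a fixed call.
#' @param floor_reads,frac presence-rule parameters (see [allele_presence()]).
#' @param require_bidirectional if TRUE both directions must satisfy the
#'   fixed rule (stricter reading); default FALSE (either direction).
#' @return one-row data.frame with class, direction, alleles.
#' @export
classify_site <- function(col_A, col_B, min_site_depth = 10,
                          fixed_major_freq = 0.95,
                          floor_reads = 5, frac = 0.05,
                          require_bidirectional = FALSE) {
  m <- classify_sites(matrix(col_A[BASES], 1, dimnames = list(NULL, BASES)),
                      matrix(col_B[BASES], 1, dimnames = list(NULL, BASES)),
                      min_site_depth = min_site_depth,
                      fixed_major_freq = fixed_major_freq,
                      floor_reads = floor_reads, frac = frac,
                      require_bidirectional = require_bidirectional)
  m
}

#' Classify many sites at once (vectorized)
#'
#' @param counts_A,counts_B n x 4 count matrices (columns A,C,G,T), rows are
#'   homologous sites in the two species.
#' @inheritParams classify_site
#' @return data.frame with columns `class` (fixed/polymorphic/invariant/
#'   unclassifiable), `direction` (A/B/both/none), `major_A`, `major_B`,
#'   `present_A`, `present_B` (comma-joined base sets), `polymorphic_in`.
#' @export
classify_sites <- function(counts_A, counts_B, min_site_depth = 10,
                           fixed_major_freq = 0.95,
                           floor_reads = 5, frac = 0.05,
                           require_bidirectional = FALSE) {
  stopifnot(nrow(counts_A) == nrow(counts_B))
  n <- nrow(counts_A)
  depth_A <- rowSums(counts_A); depth_B <- rowSums(counts_B)
  pres_A <- .presence_matrix(counts_A, floor_reads, frac)
  pres_B <- .presence_matrix(counts_B, floor_reads, frac)
  maj_A <- .major_allele(counts_A); maj_B <- .major_allele(counts_B)
  ## direction A: species A has a >=95% base that is not present in B
  majA_idx <- match(maj_A$base, BASES)
  majB_idx <- match(maj_B$base, BASES)
  dir_A <- maj_A$freq >= fixed_major_freq &
    !pres_B[cbind(seq_len(n), majA_idx)]
  dir_B <- maj_B$freq >= fixed_major_freq &
    !pres_A[cbind(seq_len(n), majB_idx)]
  fixed <- if (require_bidirectional) dir_A & dir_B else dir_A | dir_B
  poly_A <- rowSums(pres_A) >= 2L
  poly_B <- rowSums(pres_B) >= 2L
  cls <- rep("invariant", n)
  cls[poly_A | poly_B] <- "polymorphic"
  cls[fixed] <- "fixed"
  cls[depth_A < min_site_depth | depth_B < min_site_depth] <- "unclassifiable"
  direction <- rep("none", n)
  direction[cls == "fixed" & dir_A & !dir_B] <- "A"
  direction[cls == "fixed" & dir_B & !dir_A] <- "B"
  direction[cls == "fixed" & dir_A & dir_B] <- "both"
  polymorphic_in <- rep("none", n)
  polymorphic_in[cls == "polymorphic" & poly_A & !poly_B] <- "A"
  polymorphic_in[cls == "polymorphic" & poly_B & !poly_A] <- "B"
  polymorphic_in[cls == "polymorphic" & poly_A & poly_B] <- "both"
  join <- function(m) apply(m, 1L, function(r) paste(BASES[r], collapse = ","))
  data.frame(class = cls, direction = direction,
             major_A = maj_A$base, major_B = maj_B$base,
             major_tie_A = maj_A$tie, major_tie_B = maj_B$tie,
             present_A = join(pres_A), present_B = join(pres_B),
             polymorphic_in = polymorphic_in, stringsAsFactors = FALSE)
}

#' Annotate the coding effect of a classified site
#'
#' For a fixed site the codon containing the site is compared between the
#' species-A consensus codon and the same codon with the site base replaced
#' by the species-B major allele (all other positions held at consensus).
#' For a polymorphic site the minor allele is compared to the major within
#' the polymorphic species' consensus codon.
#'
#' @param pos 1-based ORF coordinate of the site.
#' @param base_ref,base_alt the two bases to compare at `pos`.
#' @param consensus in-frame consensus sequence providing codon context.
#' @return "syn" or "nonsyn".
#' @export
annotate_effect <- function(pos, base_ref, base_alt, consensus) {
  L <- nchar(consensus)
  if (pos < 1 || pos > L) stop("pos outside ORF")
  ci <- (pos - 1L) %/% 3L
  cod <- substr(consensus, ci * 3L + 1L, ci * 3L + 3L)
  off <- pos - ci * 3L
  cod_ref <- cod; substr(cod_ref, off, off) <- base_ref
  cod_alt <- cod; substr(cod_alt, off, off) <- base_alt
  if (translate_codons(cod_ref) == translate_codons(cod_alt)) "syn" else "nonsyn"
}

#' Classify a whole gene from its two pileup tables
#'
#' Applies the gene-level mean-coverage filter (both species must reach
#' `min_mean_cov` mean per-base coverage over the ORF), classifies every
#' site, annotates effects of fixed and polymorphic sites, and aggregates
#' the per-gene variation counts. Positions absent from a pileup are
#' treated as depth 0.
#'
#' @param pileups_A,pileups_B data.frames `gene_id, pos, species, A, C, G, T`
#'   for one gene (one species each).
#' @param orf the reference ORF sequence (character); defines ORF length and
#'   the codon context fallback where pileup depth is 0.
#' @param gene_id gene identifier.
#' @param family_tag gene-family label carried into the summary.
#' @param min_mean_cov gene-level mean coverage threshold (default 10).
#' @param ... passed to [classify_sites()].
#' @return list with `gene` (one-row data.frame: mean coverages, counts,
#'   passes_coverage) and `sites` (site-call data.frame; empty if filtered),
#'   plus `consensus_A`/`consensus_B` strings.
#' @export
classify_gene <- function(pileups_A, pileups_B, orf, gene_id,
                          family_tag = "NC", min_mean_cov = 10,
                          min_site_depth = 10, ...) {
  L <- nchar(orf)
  expand <- function(p) {
    m <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
    if (nrow(p)) {
      keep <- p$pos >= 1 & p$pos <= L
      p <- p[keep, , drop = FALSE]
      m[p$pos, ] <- as.matrix(p[, BASES])
    }
    m
  }
  cA <- expand(pileups_A); cB <- expand(pileups_B)
  mean_cov_A <- mean(rowSums(cA)); mean_cov_B <- mean(rowSums(cB))
  passes <- mean_cov_A >= min_mean_cov && mean_cov_B >= min_mean_cov
  ref_chars <- strsplit(toupper(orf), "")[[1]]
  gene_row <- function(nfs = 0L, nfn = 0L, nps = 0L, npn = 0L) {
    data.frame(gene_id = gene_id, family_tag = family_tag,
               mean_cov_A = mean_cov_A, mean_cov_B = mean_cov_B,
               n_fixed_syn = nfs, n_fixed_nonsyn = nfn,
               n_poly_syn = nps, n_poly_nonsyn = npn,
               passes_coverage = passes, stringsAsFactors = FALSE)
  }
  if (!passes) {
    return(list(gene = gene_row(), sites = NULL,
                consensus_A = NA_character_, consensus_B = NA_character_))
  }
  calls <- classify_sites(cA, cB, min_site_depth = min_site_depth, ...)
  calls$gene_id <- gene_id
  calls$pos <- seq_len(L)
  ## consensus: major allele where adequately covered; reference base at
  ## low-depth sites (a couple of error reads must not fake a consensus
  ## change, which could even introduce a spurious stop codon)
  consA <- ifelse(rowSums(cA) >= min_site_depth, calls$major_A, ref_chars)
  consB <- ifelse(rowSums(cB) >= min_site_depth, calls$major_B, ref_chars)
  consensus_A <- paste(consA, collapse = "")
  consensus_B <- paste(consB, collapse = "")
  calls$effect <- "none"
  fx <- which(calls$class == "fixed")
  for (i in fx) {
    calls$effect[i] <- annotate_effect(calls$pos[i], calls$major_A[i],
                                       calls$major_B[i], consensus_A)
  }
  pl <- which(calls$class == "polymorphic")
  for (i in pl) {
    sp <- calls$polymorphic_in[i]
    cm <- if (sp == "B") cB else cA
    cons <- if (sp == "B") consensus_B else consensus_A
    pres <- allele_presence(cm[calls$pos[i], ])
    major <- if (sp == "B") calls$major_B[i] else calls$major_A[i]
    minor <- setdiff(pres, major)
    if (length(minor) == 0L) {  # presence in the other species only
      cm <- cB; cons <- consensus_B; major <- calls$major_B[i]
      minor <- setdiff(allele_presence(cm[calls$pos[i], ]), major)
    }
    if (length(minor))
      calls$effect[i] <- annotate_effect(calls$pos[i], major, minor[1L], cons)
  }
  g <- gene_row(sum(calls$class == "fixed" & calls$effect == "syn"),
                sum(calls$class == "fixed" & calls$effect == "nonsyn"),
                sum(calls$class == "polymorphic" & calls$effect == "syn"),
                sum(calls$class == "polymorphic" & calls$effect == "nonsyn"))
  cols <- c("gene_id", "pos", "class", "direction", "effect",
            "polymorphic_in", "major_A", "major_B", "present_A", "present_B",
            "major_tie_A", "major_tie_B")
  list(gene = g, sites = calls[, cols], consensus_A = consensus_A,
       consensus_B = consensus_B)
}

#' Build a fixed-difference-only codon alignment for one gene
#'
#' The output pair differs exactly at fixed-classified sites; polymorphic and
#' unclassifiable sites carry the species-A major allele in both sequences
#' (polymorphisms are discarded before dN/dS estimation).
#'
#' @param consensus_A,consensus_B equal-length consensus sequences.
#' @param site_calls site-call data.frame from [classify_gene()].
#' @return character vector c(A = seqA, B = seqB).
#' @export
build_fixed_alignment <- function(consensus_A, consensus_B, site_calls) {
  stopifnot(nchar(consensus_A) == nchar(consensus_B))
  a <- strsplit(consensus_A, "")[[1]]
  b <- a
  fx <- site_calls[site_calls$class == "fixed", , drop = FALSE]
  if (nrow(fx)) b[fx$pos] <- fx$major_B
  c(A = paste(a, collapse = ""), B = paste(b, collapse = ""))
}

.has_internal_stop <- function(seq) {
  cods <- split_codons(seq)
  any(is_stop_codon(cods[-length(cods)]))
}

#' Classify every gene of a study
#'
#' @param pileups combined pileup data.frame (both species).
#' @param orfs named character vector of reference ORFs.
#' @param family_tags named character vector of family labels (optional).
#' @param min_mean_cov gene-level coverage filter.
#' @param ... passed to [classify_sites()].
#' @return list with `genes` (one row per gene), `sites` (row-bound calls),
#'   `alignments` (named list of fixed-difference pairs for genes with >= 1
#'   fixed site), `consensus` (list with A and B named vectors).
#' @export
classify_all_genes <- function(pileups, orfs, family_tags = NULL,
                               min_mean_cov = 10, min_site_depth = 10, ...) {
  genes <- list(); sites <- list(); alignments <- list()
  cons_A <- character(0); cons_B <- character(0)
  by_gene_sp <- split(pileups, list(pileups$gene_id, pileups$species),
                      drop = FALSE)
  for (g in names(orfs)) {
    pA <- by_gene_sp[[paste(g, "A", sep = ".")]]
    pB <- by_gene_sp[[paste(g, "B", sep = ".")]]
    if (is.null(pA)) pA <- pileups[0, ]
    if (is.null(pB)) pB <- pileups[0, ]
    tag <- if (!is.null(family_tags) && g %in% names(family_tags))
      family_tags[[g]] else "NC"
    r <- classify_gene(pA, pB, orfs[[g]], g, family_tag = tag,
                       min_mean_cov = min_mean_cov,
                       min_site_depth = min_site_depth, ...)
    genes[[g]] <- r$gene
    if (!is.null(r$sites)) {
      sites[[g]] <- r$sites
      cons_A[g] <- r$consensus_A; cons_B[g] <- r$consensus_B
      if (any(r$sites$class == "fixed")) {
        aln <- build_fixed_alignment(r$consensus_A, r$consensus_B, r$sites)
        ## orthologs whose consensus pair carries a premature stop codon
        ## (e.g. a fixed difference plus a neighbouring polymorphism
        ## combining into a stop) are discarded from the dN/dS stage,
        ## mirroring the upstream ortholog filter
        last_stop <- vapply(aln, function(s)
          is_stop_codon(substr(s, nchar(s) - 2L, nchar(s))), logical(1))
        if (!any(vapply(aln, .has_internal_stop, logical(1))) &&
            length(unique(last_stop)) == 1L)
          alignments[[g]] <- aln
      }
    }
  }
  list(genes = do.call(rbind, genes),
       sites = if (length(sites)) do.call(rbind, sites) else NULL,
       alignments = alignments,
       consensus = list(A = cons_A, B = cons_B))
}
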