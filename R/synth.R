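## Synthetic pooled-transcriptome generator.
##
## Emulates the study design the pipeline targets: two sibling-species pools
## of 40 haploid males each, orthologous equal-length ORFs, a handful of
## fixed interspecific differences and within-species polymorphisms, and
## per-site read pileups with overdispersed depth and sequencing error.
## Every introduced change is recorded as ground truth so downstream stages
## can be tested for parameter recovery.

#' Simulation configuration
#'
#' Defaults state the emulated world: pools of 40 haploid males per species,
#' 50x mean coverage with moderate overdispersion, 0.3% per-base sequencing
#' error, and fixed-substitution rates matching the chemosensory-gene means
#' of the study system (mean dN 0.0035, mean dS 0.0039 per site).
#'
#' @param n_genes number of orthologous genes to simulate.
#' @param length_range integer (min, max) gene length in codons, incl. start
#'   and stop; minimum 100.
#' @param n_haploids_per_pool haploid individuals per species pool.
#' @param mean_depth mean sequencing depth per site (reads).
#' @param depth_dispersion negative-binomial size parameter; smaller = more
#'   overdispersed. Variance = mu + mu^2/size.
#' @param error_rate per-base sequencing error probability.
#' @param fixed_syn_rate,fixed_nonsyn_rate expected fixed synonymous /
#'   non-synonymous substitutions per nucleotide site.
#' @param poly_rate expected polymorphic sites per nucleotide site per species.
#' @param minor_allele_freq_range uniform range for the minor allele
#'   frequency of a polymorphic site (fraction of the pool).
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 50L,
                              length_range = c(100L, 300L),
                              n_haploids_per_pool = 40L,
                              mean_depth = 50,
                              depth_dispersion = 10,
                              error_rate = 0.003,
                              fixed_syn_rate = 0.0039,
                              fixed_nonsyn_rate = 0.0035,
                              poly_rate = 0.004,
                              minor_allele_freq_range = c(0.1, 0.5),
                              seed = 1L) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  if (length_range[1] < 100L)
    stop("length_range minimum is 100 codons")
  if (n_haploids_per_pool < 2L)
    stop("n_haploids_per_pool must be >= 2")
  rates <- c(error_rate, fixed_syn_rate, fixed_nonsyn_rate, poly_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]")
  stopifnot(minor_allele_freq_range[1] > 0, minor_allele_freq_range[2] <= 0.5)
  structure(list(
    n_genes = as.integer(n_genes),
    length_range = as.integer(length_range),
    n_haploids_per_pool = as.integer(n_haploids_per_pool),
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    error_rate = error_rate,
    fixed_syn_rate = fixed_syn_rate,
    fixed_nonsyn_rate = fixed_nonsyn_rate,
    poly_rate = poly_rate,
    minor_allele_freq_range = minor_allele_freq_range,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate ancestral in-frame coding sequences
#'
#' Each gene starts with ATG, ends with a stop codon, and contains uniformly
#' drawn sense codons in between (no internal stop).
#'
#' @param config a [simulation_config()].
#' @return named character vector of CDS (names `gene001`, ...).
#' @export
generate_ancestral_cds <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  internal <- sense_codons()   # any sense codon, ATG included, may be internal
  stops <- c("TAA", "TAG", "TGA")
  out <- character(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    len <- if (config$length_range[1] == config$length_range[2]) {
      config$length_range[1]
    } else sample(config$length_range[1]:config$length_range[2], 1L)
    body <- sample(internal, len - 2L, replace = TRUE)
    out[g] <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
  }
  names(out) <- sprintf("gene%03d", seq_len(config$n_genes))
  out
}

## Pick a substitution at a random eligible site with the requested coding
## effect (syn/nonsyn), avoiding stop creation and already-used sites.
## Returns list(pos, from, to) or NULL after bounded retries.
.draw_substitution <- function(cds_chars, effect, used, max_retries = 100L) {
  L <- length(cds_chars)
  for (r in seq_len(max_retries)) {
    pos <- sample.int(L - 6L, 1L) + 3L          # skip start and stop codons
    if (pos %in% used) next
    ci <- (pos - 1L) %/% 3L                     # 0-based codon index
    cod <- paste(cds_chars[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    off <- pos - ci * 3L                        # position in codon 1..3
    from <- cds_chars[pos]
    for (to in sample(setdiff(BASES, from))) {
      new <- cod
      substr(new, off, off) <- to
      if (is_stop_codon(new)) next
      syn <- translate_codons(cod) == translate_codons(new)
      if ((effect == "syn") == syn)
        return(list(pos = pos, from = from, to = to))
    }
  }
  NULL
}

#' Evolve a species pair from an ancestral CDS set
#'
#' Introduces fixed interspecific differences (carried by every haplotype of
#' exactly one species) and within-species polymorphisms (segregating at a
#' drawn minor frequency in one species), recording every change as ground
#' truth. Substitution counts per gene are Poisson with mean rate x length.
#'
#' @param ancestral_cds named character vector from [generate_ancestral_cds()].
#' @param config a [simulation_config()].
#' @return list with `pool_A`, `pool_B` (each a named list of character
#'   matrices, haplotypes x sites), `truth_fixed`, `truth_poly`
#'   (data.frames), and `consensus_A`/`consensus_B` named character vectors.
#' @export
evolve_species_pair <- function(ancestral_cds, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nh <- config$n_haploids_per_pool
  pool_A <- list(); pool_B <- list()
  cons_A <- character(0); cons_B <- character(0)
  tf <- list(); tp <- list()
  for (g in names(ancestral_cds)) {
    anc <- strsplit(ancestral_cds[[g]], "")[[1]]
    L <- length(anc)
    seq_A <- anc; seq_B <- anc
    used <- integer(0)
    n_syn <- stats::rpois(1L, config$fixed_syn_rate * L)
    n_non <- stats::rpois(1L, config$fixed_nonsyn_rate * L)
    effects <- c(rep("syn", n_syn), rep("nonsyn", n_non))
    for (eff in effects) {
      ## fixed difference: derived allele on every haplotype of one species
      target <- sample(c("A", "B"), 1L)
      base_seq <- if (target == "A") seq_A else seq_B
      sub <- .draw_substitution(base_seq, eff, used)
      if (is.null(sub))
        stop("gene ", g, ": could not place requested substitution without ",
             "creating a stop after bounded retries")
      used <- c(used, sub$pos)
      if (target == "A") seq_A[sub$pos] <- sub$to else seq_B[sub$pos] <- sub$to
      tf[[length(tf) + 1L]] <- data.frame(
        gene_id = g, pos = sub$pos,
        allele_A = if (target == "A") sub$to else sub$from,
        allele_B = if (target == "B") sub$to else sub$from,
        effect = eff, stringsAsFactors = FALSE)
    }
    hap_A <- matrix(rep(seq_A, each = nh), nrow = nh)
    hap_B <- matrix(rep(seq_B, each = nh), nrow = nh)
    ## polymorphisms: per species, at most one segregating allele per site
    for (sp in c("A", "B")) {
      n_poly <- stats::rpois(1L, config$poly_rate * L)
      base_seq <- if (sp == "A") seq_A else seq_B
      for (k in seq_len(n_poly)) {
        eff <- sample(c("syn", "nonsyn"), 1L)
        sub <- .draw_substitution(base_seq, eff, used)
        if (is.null(sub)) next
        used <- c(used, sub$pos)
        f <- stats::runif(1L, config$minor_allele_freq_range[1],
                          config$minor_allele_freq_range[2])
        n_minor <- max(1L, round(f * nh))
        if (n_minor > nh %/% 2L) n_minor <- nh %/% 2L
        carriers <- sample.int(nh, n_minor)
        if (sp == "A") hap_A[carriers, sub$pos] <- sub$to
        else hap_B[carriers, sub$pos] <- sub$to
        tp[[length(tp) + 1L]] <- data.frame(
          gene_id = g, species = sp, pos = sub$pos,
          major = sub$from, minor = sub$to,
          minor_freq = n_minor / nh, effect = eff, stringsAsFactors = FALSE)
      }
    }
    pool_A[[g]] <- hap_A; pool_B[[g]] <- hap_B
    cons_A[g] <- paste(seq_A, collapse = "")
    cons_B[g] <- paste(seq_B, collapse = "")
  }
  empty_fixed <- data.frame(gene_id = character(0), pos = integer(0),
                            allele_A = character(0), allele_B = character(0),
                            effect = character(0), stringsAsFactors = FALSE)
  empty_poly <- data.frame(gene_id = character(0), species = character(0),
                           pos = integer(0), major = character(0),
                           minor = character(0), minor_freq = numeric(0),
                           effect = character(0), stringsAsFactors = FALSE)
  list(pool_A = pool_A, pool_B = pool_B,
       truth_fixed = if (length(tf)) do.call(rbind, tf) else empty_fixed,
       truth_poly = if (length(tp)) do.call(rbind, tp) else empty_poly,
       consensus_A = cons_A, consensus_B = cons_B)
}

#' Simulate per-site pooled read pileups for one species pool
#'
#' Depth per site is negative binomial (mu = mean_depth, size =
#' depth_dispersion); each read samples a random haplotype's base and is
#' flipped to a uniformly chosen other base with probability `error_rate`.
#'
#' @param pool named list of haplotype matrices (from [evolve_species_pair()]).
#' @param config a [simulation_config()].
#' @param species label written into the `species` column.
#' @param seed_offset internal offset so A and B pileups differ.
#' @return data.frame `gene_id, pos, species, A, C, G, T`.
#' @export
simulate_pileups <- function(pool, config, species = "A", seed_offset = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1000L + seed_offset)
  res <- vector("list", length(pool))
  for (gi in seq_along(pool)) {
    hap <- pool[[gi]]
    nh <- nrow(hap); L <- ncol(hap)
    depth <- stats::rnbinom(L, size = config$depth_dispersion,
                            mu = config$mean_depth)
    counts <- matrix(0L, nrow = L, ncol = 4L,
                     dimnames = list(NULL, BASES))
    for (p in seq_len(L)) {
      d <- depth[p]
      if (d == 0L) next
      alleles <- hap[, p]
      if (length(unique(alleles)) == 1L) {
        reads <- rep(alleles[1L], d)
      } else {
        reads <- alleles[sample.int(nh, d, replace = TRUE)]
      }
      if (config$error_rate > 0) {
        err <- stats::runif(d) < config$error_rate
        if (any(err)) {
          reads[err] <- vapply(reads[err], function(b)
            sample(setdiff(BASES, b), 1L), character(1L))
        }
      }
      tab <- tabulate(match(reads, BASES), 4L)
      counts[p, ] <- tab
    }
    res[[gi]] <- data.frame(gene_id = names(pool)[gi], pos = seq_len(L),
                            species = species, counts,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate noisy membrane-topology predictions around a 7-TM truth
#'
#' Builds a ground-truth alternating architecture (intracellular N-terminus,
#' n_tm transmembrane helices of ~21 residues separated by loops,
#' extracellular C-terminus) and three predictor variants whose TM
#' boundaries are jittered by integer Gaussian noise.
#'
#' @param protein_length residues.
#' @param n_tm number of TM helices (default 7).
#' @param jitter_sd standard deviation of the integer boundary jitter.
#' @param seed integer seed.
#' @param protein_id id written into the interval tables.
#' @return list with `truth` and `predictors` (list of 3), each a data.frame
#'   `protein_id, start, end, label, predictor` of 1-based closed intervals.
#' @export
synth_topologies <- function(protein_length, n_tm = 7L, jitter_sd = 1,
                             seed = 1L, protein_id = "prot1") {
  tm_len <- 21L
  min_len <- n_tm * tm_len + (n_tm + 1L) * 5L
  if (protein_length < min_len)
    stop("protein too short for ", n_tm, " TM domains (need >= ", min_len, ")")
  set.seed(seed)
  slack <- protein_length - n_tm * tm_len
  gaps <- floor(slack * rep(1 / (n_tm + 1), n_tm + 1))
  gaps[n_tm + 1L] <- slack - sum(gaps[seq_len(n_tm)])
  tm_start <- integer(n_tm); tm_end <- integer(n_tm)
  cur <- 0L
  for (k in seq_len(n_tm)) {
    cur <- cur + gaps[k]
    tm_start[k] <- cur + 1L
    tm_end[k] <- cur + tm_len
    cur <- cur + tm_len
  }
  build <- function(starts, ends, predictor) {
    iv <- list()
    prev_end <- 0L
    for (k in seq_along(starts)) {
      if (starts[k] > prev_end + 1L)
        iv[[length(iv) + 1L]] <- c(prev_end + 1L, starts[k] - 1L, "LOOP")
      iv[[length(iv) + 1L]] <- c(starts[k], ends[k], paste0("TM", k))
      prev_end <- ends[k]
    }
    if (prev_end < protein_length)
      iv[[length(iv) + 1L]] <- c(prev_end + 1L, protein_length, "LOOP")
    df <- do.call(rbind, lapply(iv, function(x)
      data.frame(protein_id = protein_id, start = as.integer(x[1]),
                 end = as.integer(x[2]), label = x[3],
                 predictor = predictor, stringsAsFactors = FALSE)))
    ## name the loops positionally: IN, EL/IL alternating, EC
    loops <- which(df$label == "LOOP")
    tm_before <- vapply(loops, function(i)
      sum(grepl("^TM", df$label[seq_len(i)])), integer(1L))
    for (m in seq_along(loops)) {
      i <- loops[m]
      k <- tm_before[m]
      df$label[i] <- if (k == 0L) "IN"
        else if (k == length(starts)) "EC"
        else if (k %% 2L == 1L) "EL" else "IL"
    }
    df
  }
  truth <- build(tm_start, tm_end, "truth")
  predictors <- lapply(1:3, function(v) {
    s <- tm_start; e <- tm_end
    if (jitter_sd > 0) {
      s <- s + round(stats::rnorm(n_tm, 0, jitter_sd))
      e <- e + round(stats::rnorm(n_tm, 0, jitter_sd))
      ## clamp to keep intervals ordered, non-overlapping, in range
      for (k in seq_len(n_tm)) {
        lo <- if (k == 1L) 1L else e[k - 1L] + 2L
        s[k] <- max(s[k], lo)
        e[k] <- max(e[k], s[k])
        hi <- if (k == n_tm) protein_length else tm_start[k + 1L] - 2L
        e[k] <- min(e[k], hi)
        s[k] <- min(s[k], e[k])
      }
    }
    build(s, e, paste0("pred", v))
  })
  list(truth = truth, predictors = predictors)
}

#' Run the full generator and return a synthetic study
#'
#' Convenience wrapper: ancestral CDS, evolved pools, pileups for both
#' species, and the ground truth, all from one config.
#'
#' @param config a [simulation_config()].
#' @return list with `ancestral`, `pools` (evolve_species_pair output),
#'   `pileups` (row-bound A and B data.frame).
#' @export
simulate_study <- function(config) {
  anc <- generate_ancestral_cds(config)
  ev <- evolve_species_pair(anc, config)
  pu_A <- simulate_pileups(ev$pool_A, config, species = "A", seed_offset = 0L)
  pu_B <- simulate_pileups(ev$pool_B, config, species = "B", seed_offset = 1L)
  list(ancestral = anc, pools = ev, pileups = rbind(pu_A, pu_B))
}
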