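# ORF extraction, completeness/contiguity, reciprocal orthology, and the
# iterative discovery loop.

test_that("find_orfs locates a constructed ORF on both strands", {
  tx <- paste0("ATG", strrep("GCT", 99), "TAA")   # 303 nt total
  got <- find_orfs(tx, min_len_nt = 300)
  expect_equal(nrow(got), 1)
  expect_equal(nchar(got$nt_sequence), 303)
  expect_equal(got$strand, "+")
  expect_equal(got$aa_sequence, paste0("M", strrep("A", 99)))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  grc <- find_orfs(rc, min_len_nt = 300)
  expect_equal(grc$strand, "-")
  expect_equal(grc$nt_sequence, got$nt_sequence)

  expect_equal(nrow(find_orfs("", 300)), 0)
  # N-containing ORFs are excluded
  txn <- paste0("ATG", strrep("GCT", 50), "NAT", strrep("GCT", 48), "TAA")
  expect_equal(nrow(find_orfs(txn, min_len_nt = 300)), 0)
})

test_that("find_orfs equals a brute-force 6-frame scan on random input", {
  set.seed(71)
  for (k in 1:25) {
    tx <- random_dna(2000)
    got <- sort(find_orfs(tx, min_len_nt = 90)$nt_sequence)
    expect_equal(got, oracle_orfs(tx, 90))
  }
})

test_that("completeness and contiguity follow the coverage definitions", {
  expect_equal(completeness_contiguity(data.frame(start = 1, end = 100), 100),
               c(completeness = 100, contiguity = 100))
  expect_equal(completeness_contiguity(
    data.frame(start = c(1, 51), end = c(50, 100)), 100),
    c(completeness = 100, contiguity = 50))
  expect_error(completeness_contiguity(data.frame(start = 1, end = 5), 0),
               "empty")
  # random segment sets vs an interval-union oracle
  set.seed(72)
  for (k in 1:30) {
    L <- sample(50:200, 1)
    n <- sample(1:6, 1)
    s <- sample(L, n, replace = TRUE)
    e <- pmin(L, s + sample(0:40, n, replace = TRUE))
    segs <- data.frame(start = s, end = e)
    cov <- rep(FALSE, L)
    for (i in 1:n) cov[s[i]:e[i]] <- TRUE
    got <- completeness_contiguity(segs, L)
    expect_equal(unname(got["completeness"]), 100 * sum(cov) / L)
    expect_equal(unname(got["contiguity"]), 100 * max(e - s + 1) / L)
  }
})

test_that("reciprocal orthology enforces identity and uniqueness", {
  set.seed(73)
  genes <- setNames(vapply(1:10, function(i) random_dna(120), ""),
                    paste0("g", 1:10))
  self <- reciprocal_orthologs(genes, genes)
  expect_equal(nrow(self$pairs), 10)
  expect_true(all(self$pairs$identity == 1))

  # pair at 94% identity excluded at the 0.95 threshold
  a <- setNames(random_dna(100, seed = 74), "x")
  bchars <- strsplit(a[[1]], "")[[1]]
  flip <- sample(100, 6)
  for (i in flip) bchars[i] <- setdiff(c("A", "C", "G", "T"), bchars[i])[1]
  b <- setNames(paste(bchars, collapse = ""), "y")
  res94 <- reciprocal_orthologs(a, b, min_identity = 0.95)
  expect_equal(nrow(res94$pairs), 0)
  expect_equal(nrow(reciprocal_orthologs(a, b, min_identity = 0.90)$pairs), 1)

  # simulated orthologs plus unrelated decoys
  cfg <- simulation_config(n_genes = 15, length_range = c(100, 140),
                           fixed_syn_rate = 0.005, fixed_nonsyn_rate = 0.005,
                           seed = 75)
  ev <- evolve_species_pair(generate_ancestral_cds(cfg), cfg)
  set_A <- ev$consensus_A
  set_B <- ev$consensus_B
  decoys <- setNames(vapply(1:5, function(i) random_dna(333), ""),
                     paste0("decoy", 1:5))
  res <- reciprocal_orthologs(c(set_A, decoys), set_B)
  expect_setequal(res$pairs$id_A, names(set_A))
  expect_equal(res$pairs$id_B[match(names(set_A), res$pairs$id_A)],
               names(set_B))
  expect_true(all(paste0("decoy", 1:5) %in% res$unpaired_A))

  # symmetry: swapping the sets yields the same pair set
  swapped <- reciprocal_orthologs(set_B, c(set_A, decoys))
  expect_setequal(paste(res$pairs$id_A, res$pairs$id_B),
                  paste(swapped$pairs$id_B, swapped$pairs$id_A))
})

test_that("iterative discovery reaches a fixed point and finds chains", {
  # search backend: score 100 when query and a frame-0 translation share a
  # 30-residue window
  share30 <- function(p, q) {
    if (nchar(p) < 30 || nchar(q) < 30) return(FALSE)
    wins <- substring(p, 1:(nchar(p) - 29), 30:nchar(p))
    any(vapply(wins, function(w) grepl(w, q, fixed = TRUE), logical(1)))
  }
  search_fn <- function(queries, transcripts) {
    rows <- list()
    for (tn in names(transcripts)) {
      dna <- transcripts[[tn]]
      usable <- nchar(dna) %/% 3 * 3
      aa <- sub("\\*.*$", "", as.character(Biostrings::translate(
        Biostrings::DNAString(substr(dna, 1, usable)))))
      for (qn in names(queries)) {
        sc <- if (share30(queries[[qn]], aa)) 100 else 0
        rows[[length(rows) + 1]] <- data.frame(query = qn, transcript = tn,
                                               score = sc)
      }
    }
    do.call(rbind, rows)
  }
  # reverse-translate with a fixed codon per amino acid
  aa2codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  encode <- function(aa) paste0("ATG", paste(aa2codon[strsplit(aa, "")[[1]]],
                                             collapse = ""), "TAA")
  # chain of 5 homologs: consecutive members share a 60-residue block
  set.seed(76)
  blocks <- vapply(1:6, function(i) random_protein(60), "")
  prots <- vapply(1:5, function(i) paste0(blocks[i], blocks[i + 1]), "")
  transcripts <- setNames(vapply(prots, encode, ""), paste0("t", 1:5))
  seed_q <- setNames(paste0("M", prots[1]), "seed1")

  got <- iterative_discovery(transcripts, seed_q, search_fn = search_fn,
                             score_threshold = 50, min_orf_len = 300)
  expect_setequal(unique(got$parent_transcript), paste0("t", 1:5))

  # zero hits -> empty result
  none <- iterative_discovery(
    setNames(random_dna(900, seed = 77), "t0"), seed_q,
    search_fn = search_fn, score_threshold = 50, min_orf_len = 300)
  expect_equal(nrow(none), 0)

  # idempotence: rerunning on recovered ORFs adds nothing new
  again <- iterative_discovery(
    setNames(got$nt_sequence, got$id),
    setNames(got$aa_sequence, paste0("q_", got$id)),
    search_fn = search_fn, score_threshold = 50, min_orf_len = 300)
  expect_true(all(again$nt_sequence %in% got$nt_sequence))
})

test_that("the default alignment backend scores planted homology", {
  set.seed(78)
  prot <- random_protein(150)
  aa2codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  dna <- paste0("ATG", paste(aa2codon[strsplit(prot, "")[[1]]],
                             collapse = ""), "TAA")
  hits <- alignment_search(setNames(prot, "q"),
                           setNames(c(dna, random_dna(450)), c("hom", "bg")))
  sc <- setNames(hits$score, hits$transcript)
  expect_gt(sc[["hom"]], 4 * sc[["bg"]])
})
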