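# Site classification: presence rule, fixed/polymorphic calling, effect
# annotation, gene-level filtering, and the class-partition invariants.

test_that("allele presence applies the max(5, 5% depth) rule", {
  expect_equal(allele_presence(cnts(A = 95, C = 4)), "A")
  expect_setequal(allele_presence(cnts(A = 940, C = 60)), c("A", "C"))
  expect_equal(allele_presence(cnts(A = 940, C = 49, G = 11)), "A")
  expect_equal(allele_presence(cnts()), character(0))
})

test_that("single-site classification matches the stated rules", {
  r <- classify_site(cnts(T = 100), cnts(C = 98, T = 1))
  expect_equal(r$class, "fixed")
  expect_equal(r$direction, "both")

  r2 <- classify_site(cnts(T = 60, C = 40), cnts(T = 100))
  expect_equal(r2$class, "polymorphic")
  expect_equal(r2$polymorphic_in, "A")

  r3 <- classify_site(cnts(A = 8), cnts(A = 100))
  expect_equal(r3$class, "unclassifiable")

  r4 <- classify_site(cnts(G = 50), cnts(G = 52))
  expect_equal(r4$class, "invariant")
})

test_that("vectorized classification equals a straight-line oracle", {
  set.seed(101)
  n <- 5000
  counts_A <- matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts_B <- counts_A
  for (i in seq_len(n)) {
    scenario <- sample(c("inv", "poly", "fixed", "low"), 1)
    maj <- sample(4, 1)
    dA <- rnbinom(1, size = 10, mu = 50); dB <- rnbinom(1, size = 10, mu = 50)
    if (scenario == "low") { dA <- sample(0:9, 1) }
    mk <- function(d, maj, minor_frac = 0, minor = NULL) {
      x <- rep(0, 4)
      nm <- rbinom(1, d, minor_frac)
      x[maj] <- d - nm
      if (!is.null(minor)) x[minor] <- nm
      # sprinkle sequencing error
      ne <- rbinom(1, d, 0.003)
      if (ne > 0) { tgt <- sample(4, 1); x[tgt] <- x[tgt] + ne; x[maj] <- max(0, x[maj] - ne) }
      x
    }
    minor <- sample(setdiff(1:4, maj), 1)
    if (scenario == "poly") {
      counts_A[i, ] <- mk(dA, maj, runif(1, 0.05, 0.5), minor)
      counts_B[i, ] <- mk(dB, maj)
    } else if (scenario == "fixed") {
      counts_A[i, ] <- mk(dA, maj)
      counts_B[i, ] <- mk(dB, minor)
    } else {
      counts_A[i, ] <- mk(dA, maj)
      counts_B[i, ] <- mk(dB, maj)
    }
  }
  got <- classify_sites(counts_A, counts_B)
  want <- vapply(seq_len(n), function(i)
    oracle_classify_site(setNames(counts_A[i, ], colnames(counts_A)),
                         setNames(counts_B[i, ], colnames(counts_B))),
    character(1))
  expect_equal(got$class, want)
})

test_that("class partition, symmetry and monotonicity hold", {
  set.seed(77)
  n <- 800
  counts_A <- matrix(rnbinom(n * 4, size = 3, mu = 12), n, 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  counts_B <- matrix(rnbinom(n * 4, size = 3, mu = 12), n, 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
  ab <- classify_sites(counts_A, counts_B)
  ba <- classify_sites(counts_B, counts_A)
  expect_true(all(ab$class %in% c("fixed", "polymorphic", "invariant",
                                  "unclassifiable")))
  expect_equal(ab$class, ba$class)

  # monotonicity: adding reads for a non-major base never turns a
  # polymorphic site into a fixed one
  poly <- which(ab$class == "polymorphic")[1:50]
  poly <- poly[!is.na(poly)]
  for (i in poly) {
    bumped <- counts_A
    nonmaj <- setdiff(1:4, which.max(counts_A[i, ]))[1]
    bumped[i, nonmaj] <- bumped[i, nonmaj] + 5
    r <- classify_sites(bumped[i, , drop = FALSE],
                        counts_B[i, , drop = FALSE])
    expect_false(r$class == "fixed")
  }
})

test_that("effect annotation distinguishes syn and nonsyn changes", {
  # Lys AAA -> Lys AAG at codon position 3
  expect_equal(annotate_effect(3, "A", "G", "AAACCC"), "syn")
  # Met ATG -> Thr ACG at codon position 2
  expect_equal(annotate_effect(2, "T", "C", "ATGCCC"), "nonsyn")
  expect_error(annotate_effect(9, "A", "G", "AAACCC"), "outside")
})

test_that("gene-level coverage filter and zero-rate null behave", {
  orf <- "ATGAAACCCGGGTTTTAA"
  L <- nchar(orf)
  mk_pileup <- function(depth, species) {
    base <- strsplit(orf, "")[[1]]
    df <- data.frame(gene_id = "g", pos = 1:L, species = species,
                     A = 0L, C = 0L, G = 0L, T = 0L)
    for (i in 1:L) df[i, base[i]] <- depth
    df
  }
  # mean coverage below 10 in species A -> excluded
  low <- classify_gene(mk_pileup(9, "A"), mk_pileup(50, "B"), orf, "g")
  expect_false(low$gene$passes_coverage)
  expect_null(low$sites)

  ok <- classify_gene(mk_pileup(50, "A"), mk_pileup(50, "B"), orf, "g")
  expect_true(ok$gene$passes_coverage)
  expect_true(all(ok$sites$class == "invariant"))
  expect_equal(ok$gene$n_fixed_syn + ok$gene$n_fixed_nonsyn +
                 ok$gene$n_poly_syn + ok$gene$n_poly_nonsyn, 0)
  expect_equal(ok$consensus_A, orf)
})

test_that("small-scale pipeline recovers simulated truth per gene", {
  cfg <- simulation_config(n_genes = 10, length_range = c(100, 130),
                           fixed_syn_rate = 0.008, fixed_nonsyn_rate = 0.008,
                           poly_rate = 0.004, seed = 6)
  st <- simulate_study(cfg)
  cls <- classify_all_genes(st$pileups, st$ancestral)
  truth <- st$pools$truth_fixed
  for (g in names(st$ancestral)) {
    tg <- truth[truth$gene_id == g, ]
    got <- cls$genes[cls$genes$gene_id == g, ]
    expect_equal(got$n_fixed_syn + got$n_fixed_nonsyn, nrow(tg))
    expect_equal(got$n_fixed_nonsyn, sum(tg$effect == "nonsyn"))
  }
})

test_that("fixed-difference alignments differ exactly at fixed sites", {
  cfg <- simulation_config(n_genes = 6, length_range = c(100, 120),
                           fixed_syn_rate = 0.006, fixed_nonsyn_rate = 0.006,
                           poly_rate = 0.008, seed = 13)
  st <- simulate_study(cfg)
  cls <- classify_all_genes(st$pileups, st$ancestral)
  for (g in names(cls$alignments)) {
    aln <- cls$alignments[[g]]
    a <- strsplit(aln[1], "")[[1]]; b <- strsplit(aln[2], "")[[1]]
    diffs <- which(a != b)
    called_fixed <- cls$sites$pos[cls$sites$gene_id == g &
                                    cls$sites$class == "fixed"]
    expect_setequal(diffs, called_fixed)
    # and called fixed sites should equal the simulated truth here
    tg <- st$pools$truth_fixed[st$pools$truth_fixed$gene_id == g, ]
    expect_setequal(diffs, tg$pos)
  }
  # no fixed sites -> identical pair
  calls <- data.frame(gene_id = "x", pos = 1:6, class = "invariant",
                      major_B = strsplit("ATGTAA", "")[[1]])
  aln <- build_fixed_alignment("ATGTAA", "ATGTAA", calls)
  expect_equal(aln[["A"]], aln[["B"]])
})
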