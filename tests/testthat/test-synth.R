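# Synthetic-data generator: structural postconditions, determinism,
# ground-truth consistency, and sampling-distribution checks.

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(length_range = c(50, 100)), "100 codons")
  expect_error(simulation_config(n_haploids_per_pool = 1), ">= 2")
  expect_error(simulation_config(error_rate = 1.5), "rates")
})

test_that("ancestral CDS are in-frame, stop-free, and deterministic", {
  cfg <- simulation_config(n_genes = 1, length_range = c(100, 100), seed = 1)
  cds <- generate_ancestral_cds(cfg)
  expect_length(cds, 1)
  expect_equal(nchar(cds[[1]]), 300)
  expect_equal(substr(cds[[1]], 1, 3), "ATG")

  cfg7 <- simulation_config(n_genes = 5, seed = 7)
  expect_identical(generate_ancestral_cds(cfg7), generate_ancestral_cds(cfg7))

  # brute-force translation of every frame-0 codon over many genes
  cfg100 <- simulation_config(n_genes = 100, length_range = c(100, 120),
                              seed = 3)
  for (s in generate_ancestral_cds(cfg100)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aas <- unname(GC_TABLE[cods])
    expect_false(any(aas[-length(aas)] == "*"))
    expect_equal(aas[length(aas)], "*")
  }
})

test_that("zero rates leave pools identical to the ancestor, empty truth", {
  cfg <- simulation_config(n_genes = 3, length_range = c(100, 110),
                           fixed_syn_rate = 0, fixed_nonsyn_rate = 0,
                           poly_rate = 0, seed = 2)
  anc <- generate_ancestral_cds(cfg)
  ev <- evolve_species_pair(anc, cfg)
  expect_equal(nrow(ev$truth_fixed), 0)
  expect_equal(nrow(ev$truth_poly), 0)
  for (g in names(anc)) {
    expect_true(all(apply(ev$pool_A[[g]], 1, paste, collapse = "") == anc[[g]]))
    expect_true(all(apply(ev$pool_B[[g]], 1, paste, collapse = "") == anc[[g]]))
  }
})

test_that("truth labels and consensus are internally consistent", {
  cfg <- simulation_config(n_genes = 20, length_range = c(100, 150),
                           fixed_syn_rate = 0.01, fixed_nonsyn_rate = 0.01,
                           poly_rate = 0.01, seed = 5)
  anc <- generate_ancestral_cds(cfg)
  ev <- evolve_species_pair(anc, cfg)
  tf <- ev$truth_fixed
  expect_gt(nrow(tf), 0)
  # effect labels: re-translate every truth codon independently
  for (k in seq_len(nrow(tf))) {
    g <- tf$gene_id[k]; pos <- tf$pos[k]
    ci <- (pos - 1) %/% 3
    cod_anc <- substr(anc[[g]], ci * 3 + 1, ci * 3 + 3)
    off <- pos - ci * 3
    ca <- cod_anc; substr(ca, off, off) <- tf$allele_A[k]
    cb <- cod_anc; substr(cb, off, off) <- tf$allele_B[k]
    want <- if (GC_TABLE[ca] == GC_TABLE[cb]) "syn" else "nonsyn"
    expect_equal(tf$effect[k], want)
    expect_true(pos >= 1 && pos <= nchar(anc[[g]]))
    expect_true(tf$allele_A[k] != tf$allele_B[k])
  }
  # applying truth to the ancestor reproduces the pool consensus
  for (g in names(anc)) {
    a <- strsplit(anc[[g]], "")[[1]]; b <- a
    rows <- tf[tf$gene_id == g, , drop = FALSE]
    if (nrow(rows)) {
      a[rows$pos] <- rows$allele_A
      b[rows$pos] <- rows$allele_B
    }
    expect_equal(paste(a, collapse = ""), unname(ev$consensus_A[g]))
    expect_equal(paste(b, collapse = ""), unname(ev$consensus_B[g]))
  }
  # polymorphic truth: minor allele realized at the recorded frequency
  tp <- ev$truth_poly
  for (k in seq_len(nrow(tp))) {
    hap <- if (tp$species[k] == "A") ev$pool_A[[tp$gene_id[k]]] else
      ev$pool_B[[tp$gene_id[k]]]
    col <- hap[, tp$pos[k]]
    expect_equal(mean(col == tp$minor[k]), tp$minor_freq[k])
  }
})

test_that("fixed substitution counts are Poisson around the expected mean", {
  # expected fixed nonsyn per gene = 3 over 200 genes (rate x length = 3)
  n_genes <- 200
  len_cod <- 100
  rate <- 3 / (len_cod * 3)
  cfg <- simulation_config(n_genes = n_genes,
                           length_range = c(len_cod, len_cod),
                           fixed_syn_rate = 0, fixed_nonsyn_rate = rate,
                           poly_rate = 0, seed = 11)
  ev <- evolve_species_pair(generate_ancestral_cds(cfg), cfg)
  per_gene <- table(factor(ev$truth_fixed$gene_id,
                           levels = sprintf("gene%03d", 1:n_genes)))
  m <- mean(per_gene)
  se <- sqrt(3 / n_genes)
  expect_lt(abs(m - 3), 3 * se)
})

test_that("pileups conserve depth and match allele frequencies", {
  cfg <- simulation_config(n_genes = 1, length_range = c(100, 100),
                           error_rate = 0, seed = 4)
  hap <- matrix("A", nrow = 40, ncol = 50)
  pu <- simulate_pileups(list(g1 = hap), cfg, species = "A")
  expect_true(all(rowSums(pu[, c("A", "C", "G", "T")]) == pu$A))

  # mean depth within 2% at 10^4 sites
  cfg2 <- simulation_config(n_genes = 1, length_range = c(100, 100),
                            mean_depth = 50, seed = 8)
  hap2 <- matrix("C", nrow = 40, ncol = 10000)
  pu2 <- simulate_pileups(list(g1 = hap2), cfg2, species = "A")
  d <- rowSums(pu2[, c("A", "C", "G", "T")])
  expect_lt(abs(mean(d) - 50) / 50, 0.02)
  # depth is overdispersed relative to Poisson
  expect_gt(stats::var(d), 1.5 * mean(d))

  # minor allele at 0.25: pooled frequency recovered at high depth
  cfg3 <- simulation_config(n_genes = 1, length_range = c(100, 100),
                            mean_depth = 10000, error_rate = 0, seed = 9)
  hap3 <- matrix("G", nrow = 40, ncol = 3)
  hap3[1:10, 2] <- "T"
  pu3 <- simulate_pileups(list(g1 = hap3), cfg3, species = "A")
  f <- pu3$T[2] / sum(pu3[2, c("A", "C", "G", "T")])
  expect_gt(f, 0.22); expect_lt(f, 0.28)
})

test_that("whole-study generation is byte-deterministic at fixed seed", {
  cfg <- simulation_config(n_genes = 4, length_range = c(100, 110), seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)
})

test_that("synthetic topologies honour geometry and zero-noise identity", {
  tp <- synth_topologies(400, n_tm = 7, jitter_sd = 0, seed = 1)
  for (pred in tp$predictors) {
    expect_identical(pred[, c("start", "end", "label")],
                     tp$truth[, c("start", "end", "label")])
  }
  tpj <- synth_topologies(400, n_tm = 7, jitter_sd = 2, seed = 5)
  for (ann in c(list(tpj$truth), tpj$predictors)) {
    expect_true(all(ann$start <= ann$end))
    expect_true(all(diff(ann$start) > 0))
    expect_true(all(ann$start[-1] > ann$end[-nrow(ann)]))
    expect_true(all(ann$start >= 1 & ann$end <= 400))
  }
  expect_error(synth_topologies(100, n_tm = 7), "too short")
})
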