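## End-to-end orchestration: simulate -> classify -> dnds -> stats ->
## domains, with tabular reports and a machine-readable summary.

#' Default run configuration
#'
#' Every published threshold is surfaced as a named key with its study
#' value as default: gene-level mean coverage >= 10x, presence rule
#' max(5 reads, 5% of depth), fixed-site majority 0.95, ortholog identity
#' 0.95, topology consensus support 2 of 3.
#'
#' @param seed integer master seed.
#' @param out_dir run directory (created if missing).
#' @return nested list (RunConfig).
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("poolsel_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    codon_freq_mode = "F3x4",
    thresholds = list(min_mean_cov = 10, presence_floor = 5,
                      presence_frac = 0.05, fixed_major_freq = 0.95,
                      min_site_depth = 10, min_identity = 0.95,
                      min_support = 2L),
    simulate = list(
      n_chemo_genes = 12L, n_nc_genes = 36L,
      ## receptor-like gene lengths: the study's receptor ORF floor is
      ## 900 nt (300 codons), and a 7-TM topology needs ~190+ residues
      length_range = c(300L, 400L),
      n_haploids_per_pool = 40L, mean_depth = 50, depth_dispersion = 10,
      error_rate = 0.003,
      chemo = list(fixed_syn_rate = 0.0039, fixed_nonsyn_rate = 0.0035,
                   poly_rate = 0.004),
      nc = list(fixed_syn_rate = 0.0043, fixed_nonsyn_rate = 0.0005,
                poly_rate = 0.004)),
    topology = list(n_tm = 7L, jitter_sd = 1)
  )
}

#' Read a run configuration from YAML
#' @param path YAML file; missing keys fall back to [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  modifyList(base, cfg)
}

## Simulate the two gene sets of a synthetic study with family tags.
.simulate_tagged_study <- function(config) {
  sim <- config$simulate
  mk <- function(n, rates, seed_shift, prefix, tag) {
    if (n == 0L) return(NULL)
    sc <- simulation_config(
      n_genes = n, length_range = sim$length_range,
      n_haploids_per_pool = sim$n_haploids_per_pool,
      mean_depth = sim$mean_depth, depth_dispersion = sim$depth_dispersion,
      error_rate = sim$error_rate,
      fixed_syn_rate = rates$fixed_syn_rate,
      fixed_nonsyn_rate = rates$fixed_nonsyn_rate,
      poly_rate = rates$poly_rate,
      seed = config$seed + seed_shift)
    st <- simulate_study(sc)
    rename <- function(x) {
      names(x) <- sub("^gene", prefix, names(x))
      x
    }
    st$ancestral <- rename(st$ancestral)
    st$pools$consensus_A <- rename(st$pools$consensus_A)
    st$pools$consensus_B <- rename(st$pools$consensus_B)
    st$pools$pool_A <- rename(st$pools$pool_A)
    st$pools$pool_B <- rename(st$pools$pool_B)
    st$pileups$gene_id <- sub("^gene", prefix, st$pileups$gene_id)
    for (tt in c("truth_fixed", "truth_poly"))
      st$pools[[tt]]$gene_id <- sub("^gene", prefix, st$pools[[tt]]$gene_id)
    st$tags <- stats::setNames(rep(tag, n), names(st$ancestral))
    st
  }
  chemo <- mk(sim$n_chemo_genes, sim$chemo, 101L, "OR", "OR")
  nc <- mk(sim$n_nc_genes, sim$nc, 202L, "NC", "NC")
  list(
    orfs = c(chemo$ancestral, nc$ancestral),
    pileups = rbind(chemo$pileups, nc$pileups),
    tags = c(chemo$tags, nc$tags),
    truth_fixed = rbind(chemo$pools$truth_fixed, nc$pools$truth_fixed),
    truth_poly = rbind(chemo$pools$truth_poly, nc$pools$truth_poly))
}

#' Run the full pipeline on a synthetic study
#'
#' Simulates chemosensory and non-chemosensory gene sets, classifies all
#' sites, estimates omega on fixed-difference alignments, runs the gene-set
#' statistics, maps non-synonymous substitutions of omega > 1 receptor
#' genes onto consensus topologies, and writes all stage outputs plus a
#' summary JSON to the run directory.
#'
#' @param config a RunConfig (see [default_run_config()]).
#' @return invisibly, a list with all stage outputs and the summary.
#' @export
run_all <- function(config = default_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  study <- .simulate_tagged_study(config)
  cls <- classify_all_genes(
    study$pileups, study$orfs, family_tags = study$tags,
    min_mean_cov = th$min_mean_cov,
    min_site_depth = th$min_site_depth,
    fixed_major_freq = th$fixed_major_freq,
    floor_reads = th$presence_floor, frac = th$presence_frac)
  om <- if (length(cls$alignments))
    omega_all(cls$alignments, codon_freq_mode = config$codon_freq_mode)
  else NULL
  stats_res <- tryCatch(geneset_contingencies(cls$genes, om),
                        error = function(e) list(error = conditionMessage(e)))
  ## domain mapping for receptor genes with omega > 1
  domain_rows <- list()
  if (!is.null(om)) {
    sel <- merge(om, cls$genes[, c("gene_id", "family_tag")], by = "gene_id")
    sel <- sel[sel$family_tag %in% c("OR", "GR", "IR") &
                 (sel$omega_infinite | (!is.na(sel$omega) & sel$omega > 1)), ,
               drop = FALSE]
    min_plen <- config$topology$n_tm * 21L + (config$topology$n_tm + 1L) * 5L
    for (g in sel$gene_id) {
      plen <- (nchar(study$orfs[[g]]) %/% 3L) - 1L
      if (plen < min_plen) next   # too short for the configured TM geometry
      topo <- synth_topologies(plen, n_tm = config$topology$n_tm,
                               jitter_sd = config$topology$jitter_sd,
                               seed = config$seed + match(g, names(study$orfs)),
                               protein_id = g)
      cons <- consensus_topology(topo$predictors, protein_length = plen,
                                 min_support = th$min_support)
      s <- cls$sites[cls$sites$gene_id == g &
                       cls$sites$class == "fixed" &
                       cls$sites$effect == "nonsyn", , drop = FALSE]
      respos <- unique(pmin((s$pos + 2L) %/% 3L, plen))
      mp <- map_substitutions(respos, cons)
      domain_rows[[g]] <- data.frame(
        gene_id = g, n_sites = length(respos),
        n_in_lbd = sum(mp$sites$in_lbd),
        lbd_fraction = domain_fraction(cons, tm = TRUE,
                                       protein_length = plen),
        stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(domain_rows)) do.call(rbind, domain_rows) else NULL
  domain_test <- if (!is.null(domains) && sum(domains$n_sites) > 0)
    lbd_enrichment(domains$n_sites, domains$n_in_lbd, domains$lbd_fraction)
  else NULL
  ## persist stage outputs
  od <- config$out_dir
  write_tsv(cls$genes, file.path(od, "gene_variation.tsv"))
  if (!is.null(cls$sites))
    write_tsv(cls$sites, file.path(od, "site_calls.tsv"))
  if (!is.null(om)) write_tsv(om, file.path(od, "omega.tsv"))
  if (!is.null(domains)) write_tsv(domains, file.path(od, "domains.tsv"))
  for (g in names(cls$alignments))
    write_fasta(stats::setNames(cls$alignments[[g]],
                                paste0(g, "|", c("A", "B"))),
                file.path(od, paste0("aln_", g, ".fasta")))
  summary <- list(
    seed = config$seed,
    n_genes = nrow(cls$genes),
    n_genes_pass_coverage = sum(cls$genes$passes_coverage),
    n_fixed_sites = if (is.null(cls$sites)) 0L else
      sum(cls$sites$class == "fixed"),
    n_polymorphic_sites = if (is.null(cls$sites)) 0L else
      sum(cls$sites$class == "polymorphic"),
    n_alignments = length(cls$alignments),
    tests = lapply(stats_res, function(r)
      if (is.list(r)) r[intersect(names(r), c("p", "statistic", "U", "chisq",
                                              "odds_ratio", "method"))] else r),
    domain_test = if (!is.null(domain_test))
      domain_test[c("chisq", "p", "observed_in", "total",
                    "expected_fraction")] else NULL)
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(study = study, classification = cls, omega = om,
                 stats = stats_res, domains = domains,
                 domain_test = domain_test, summary = summary,
                 out_dir = od))
}

#' Per-family variation summary (published table-2 layout)
#'
#' @param genes_df per-gene counts with family tags.
#' @param omega_df per-gene omega results (optional).
#' @return data.frame, one row per family plus chemosensory total and NC.
#' @export
family_summary_table <- function(genes_df, omega_df = NULL) {
  chemo_families <- c("OR", "GR", "IR", "OBP", "CSP")
  g <- genes_df[genes_df$passes_coverage, , drop = FALSE]
  if (!is.null(omega_df) && nrow(omega_df)) {
    g <- merge(g, omega_df[, c("gene_id", "dn", "ds", "omega",
                               "omega_infinite")],
               by = "gene_id", all.x = TRUE)
  } else {
    g$dn <- NA_real_; g$ds <- NA_real_; g$omega <- NA_real_
    g$omega_infinite <- FALSE
  }
  sets <- c(intersect(chemo_families, unique(g$family_tag)),
            "chemosensory_total", "NC")
  rows <- lapply(sets, function(fam) {
    sub <- if (fam == "chemosensory_total")
      g[g$family_tag %in% chemo_families, , drop = FALSE]
    else g[g$family_tag == fam, , drop = FALSE]
    n_var <- sum(sub$n_fixed_syn + sub$n_fixed_nonsyn +
                   sub$n_poly_syn + sub$n_poly_nonsyn > 0)
    n_fixed_genes <- sum(sub$n_fixed_syn + sub$n_fixed_nonsyn > 0)
    has_fix <- sub$n_fixed_syn + sub$n_fixed_nonsyn > 0
    gt1 <- sum(has_fix & (sub$omega_infinite |
                            (!is.na(sub$omega) & sub$omega > 1)), na.rm = TRUE)
    data.frame(
      family = fam,
      unique_genes = nrow(sub),
      variable_genes = n_var,
      poly_syn = sum(sub$n_poly_syn), poly_nonsyn = sum(sub$n_poly_nonsyn),
      fixed_syn = sum(sub$n_fixed_syn), fixed_nonsyn = sum(sub$n_fixed_nonsyn),
      genes_fixed = n_fixed_genes,
      mean_dn = if (any(has_fix)) mean(sub$dn[has_fix], na.rm = TRUE) else 0,
      mean_ds = if (any(has_fix)) mean(sub$ds[has_fix], na.rm = TRUE) else 0,
      n_omega_gt1 = gt1,
      s_ratio_pct = if (nrow(sub)) round(100 * gt1 / nrow(sub), 1) else 0,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render the report tables of a completed run
#'
#' @param run_dir run directory written by [run_all()].
#' @return list with `table2` (family summary) and `table3`
#'   ([omega_table()] layout); both also written as TSV into the directory.
#' @export
report_tables <- function(run_dir) {
  gv <- file.path(run_dir, "gene_variation.tsv")
  if (!file.exists(gv))
    stop("incomplete run: missing ", gv)
  genes <- read_tsv(gv)
  omf <- file.path(run_dir, "omega.tsv")
  om <- if (file.exists(omf)) read_tsv(omf) else NULL
  t2 <- family_summary_table(genes, om)
  t3 <- if (!is.null(om)) omega_table(om, genes) else NULL
  write_tsv(t2, file.path(run_dir, "table2_family_summary.tsv"))
  if (!is.null(t3)) write_tsv(t3, file.path(run_dir, "table3_omega.tsv"))
  list(table2 = t2, table3 = t3)
}
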