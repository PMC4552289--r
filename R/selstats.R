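## Gene-set test statistics: Fisher's exact test (minimum-likelihood
## two-sided p), Mann-Whitney U with midranks and tie/continuity
## corrections, two-bin goodness-of-fit chi-square, Pearson correlation,
## and assembly of the study's standard contingency tables.

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the minimum-likelihood convention: the sum of
#' hypergeometric point probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table (the
#' convention of the standard statistics environments).
#'
#' @param tab 2x2 matrix or c(a, b, c, d) counts (row-wise).
#' @return list with `p`, `odds_ratio` (sample estimate (a/b)/(c/d)),
#'   `method`.
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- as.vector(t(as.matrix(tab)))
  stopifnot(length(x) == 4L, all(x >= 0))
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    p <- 1
  } else {
    lo <- max(0, k - n); hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, n, k)
    obs <- stats::dhyper(a, m, n, k)
    ## relative tolerance guards against ties broken by float noise
    p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  or <- if (b > 0 && d > 0 && c_ > 0) (a / b) / (c_ / d) else NA_real_
  list(p = p, odds_ratio = or, statistic = or, method = "fisher_exact_2x2",
       n = sum(x))
}

#' Mann-Whitney U test (two-sided, normal approximation)
#'
#' U is computed with midranks for ties; the two-sided p uses the normal
#' approximation with tie correction and continuity correction. `U` is
#' the statistic for sample `x` (number of (x, y) pairs with x > y, ties
#' counted half).
#'
#' @param x,y numeric samples.
#' @return list with `U`, `p`, `method`, `n`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- nx * ny / 12 * ((nx + ny + 1) - tie_term /
                              ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "mann_whitney_u",
                               n = c(nx, ny)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(U = U, p = p, statistic = U, method = "mann_whitney_u", n = c(nx, ny))
}

#' Two-bin goodness-of-fit chi-square
#'
#' Tests an observed in/out split against an expected fraction, without
#' continuity correction; df = 1, upper-tail p.
#'
#' @param observed_in count inside the category of interest.
#' @param total total count.
#' @param expected_fraction expected fraction in the category (0 < f < 1).
#' @return list with `chisq`, `p`, `method`.
#' @export
chisq_gof <- function(observed_in, total, expected_fraction) {
  stopifnot(total > 0, observed_in >= 0, observed_in <= total,
            expected_fraction > 0, expected_fraction < 1)
  e_in <- total * expected_fraction
  e_out <- total * (1 - expected_fraction)
  chisq <- (observed_in - e_in)^2 / e_in +
    ((total - observed_in) - e_out)^2 / e_out
  list(chisq = chisq, statistic = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       method = "chisq_gof", n = total)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-zero variance).
#' @return list with `r`, `p`, `method`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, statistic = r, p = min(1, p), t = tstat,
       method = "pearson_r", n = n)
}

#' Build the standard gene-set contingency tables and run the tests
#'
#' From per-gene variation counts and omega estimates, emits four 2x2
#' Fisher tests: (1) fixed vs polymorphic sites by gene set, (2)
#' non-synonymous vs synonymous fixed sites by gene set, (3) genes with
#' omega > 1 vs omega <= 1 by gene set, (4) receptor vs non-receptor genes
#' among omega > 1 genes; plus Mann-Whitney tests on per-gene dn and ds
#' between the sets.
#'
#' @param genes_df per-gene counts with `family_tag` (chemosensory families:
#'   OR, GR, IR, OBP, CSP; everything else NC).
#' @param omega_df per-gene omega results (may be NULL for site-only tests).
#' @param receptor_families family tags counted as receptors (OR, GR, IR).
#' @return list of test results; each element carries its `table`.
#' @export
geneset_contingencies <- function(genes_df, omega_df = NULL,
                                receptor_families = c("OR", "GR", "IR")) {
  chemo_families <- c("OR", "GR", "IR", "OBP", "CSP")
  g <- genes_df[genes_df$passes_coverage, , drop = FALSE]
  is_chemo <- g$family_tag %in% chemo_families
  if (!any(is_chemo)) stop("no chemosensory genes in input")
  if (all(is_chemo)) stop("no NC genes in input")
  out <- list()
  sum2 <- function(v) sum(v, na.rm = TRUE)
  fixed_c <- sum2(g$n_fixed_syn[is_chemo] + g$n_fixed_nonsyn[is_chemo])
  poly_c <- sum2(g$n_poly_syn[is_chemo] + g$n_poly_nonsyn[is_chemo])
  fixed_n <- sum2(g$n_fixed_syn[!is_chemo] + g$n_fixed_nonsyn[!is_chemo])
  poly_n <- sum2(g$n_poly_syn[!is_chemo] + g$n_poly_nonsyn[!is_chemo])
  t1 <- matrix(c(fixed_c, poly_c, fixed_n, poly_n), 2, byrow = TRUE,
               dimnames = list(c("chemosensory", "NC"),
                               c("fixed", "polymorphic")))
  out$fixed_vs_polymorphic <- c(fisher_exact_2x2(t1), list(table = t1))
  t2 <- matrix(c(sum2(g$n_fixed_nonsyn[is_chemo]),
                 sum2(g$n_fixed_syn[is_chemo]),
                 sum2(g$n_fixed_nonsyn[!is_chemo]),
                 sum2(g$n_fixed_syn[!is_chemo])), 2, byrow = TRUE,
               dimnames = list(c("chemosensory", "NC"),
                               c("nonsyn_fixed", "syn_fixed")))
  out$nonsyn_vs_syn_fixed <- c(fisher_exact_2x2(t2), list(table = t2))
  if (!is.null(omega_df) && nrow(omega_df) > 0) {
    m <- merge(g[, c("gene_id", "family_tag")], omega_df, by = "gene_id")
    gt1 <- m$omega_infinite | (!is.na(m$omega) & m$omega > 1)
    mc <- m$family_tag %in% chemo_families
    ## omega > 1 enrichment is assessed over all coverage-passing genes,
    ## with invariant genes counted in the omega <= 1 column
    n_chemo_total <- sum(is_chemo); n_nc_total <- sum(!is_chemo)
    t3 <- matrix(c(sum(gt1 & mc), n_chemo_total - sum(gt1 & mc),
                   sum(gt1 & !mc), n_nc_total - sum(gt1 & !mc)),
                 2, byrow = TRUE,
                 dimnames = list(c("chemosensory", "NC"),
                                 c("omega_gt1", "omega_le1")))
    out$omega_gt1_by_set <- c(fisher_exact_2x2(t3), list(table = t3))
    is_rec <- m$family_tag %in% receptor_families
    all_rec <- g$family_tag %in% receptor_families
    t4 <- matrix(c(sum(gt1 & is_rec), sum(gt1 & !is_rec),
                   sum(all_rec) - sum(gt1 & is_rec),
                   sum(!all_rec) - sum(gt1 & !is_rec)), 2, byrow = TRUE,
                 dimnames = list(c("omega_gt1", "omega_le1"),
                                 c("receptor", "non_receptor")))
    out$receptor_among_gt1 <- c(fisher_exact_2x2(t4), list(table = t4))
    dn_c <- m$dn[mc]; dn_n <- m$dn[!mc]
    ds_c <- m$ds[mc]; ds_n <- m$ds[!mc]
    if (length(dn_c) && length(dn_n)) {
      out$dn_mann_whitney <- mann_whitney_u(dn_c, dn_n)
      out$ds_mann_whitney <- mann_whitney_u(ds_c, ds_n)
    }
  }
  out
}
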