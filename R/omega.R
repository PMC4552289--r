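## Pairwise dN/dS on fixed-difference codon alignments.
##
## Two routes to the same quantity: (1) NG86 counting (synonymous /
## non-synonymous site fractions with pathway averaging and Jukes-Cantor
## correction) used as a fast independent check, and (2) maximum likelihood
## under the GY94 codon substitution model with parameters t (divergence in
## expected substitutions per codon), kappa (transition/transversion rate
## ratio) and omega (dN/dS), followed by a likelihood-ratio test of the
## neutral null omega = 1 (chi-square, 1 df).

## ---------------------------------------------------------------- NG86 ---

## Per-codon synonymous site fraction table (cached). Convention: mutations
## creating a stop codon count as non-synonymous opportunities (denominator
## stays 3 per position).
.ng86_sites <- function() {
  if (!is.null(.poolsel_cache$ng86_sites)) return(.poolsel_cache$ng86_sites)
  cs <- codon_structure()
  s <- numeric(length(cs$codons))
  names(s) <- cs$codons
  for (i in seq_along(cs$codons)) {
    cod <- cs$codons[i]
    syn <- 0
    for (p in 1:3) {
      for (b in setdiff(BASES, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        if (!is_stop_codon(alt) && translate_codons(alt) == cs$aa[i])
          syn <- syn + 1 / 3
      }
    }
    s[i] <- syn
  }
  .poolsel_cache$ng86_sites <- s
  s
}

## Pathway-averaged (sd, nd) difference counts between two codons.
## Pathways passing through a stop codon are excluded; if every pathway is
## blocked, all pathways are used.
.ng86_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 1L) list(pos) else
    lapply(seq_len(factorial(length(pos))), function(k) pos)  # placeholder
  if (length(pos) > 1L) {
    perm <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    paths <- perm(pos)
  }
  step_counts <- function(order) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop_codon(nxt)) return(NULL)
      if (translate_codons(cur) == translate_codons(nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(paths, step_counts)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (length(ok) == 0L) {  # all pathways pass through a stop: count anyway
    step_all <- function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (is_stop_codon(nxt) || is_stop_codon(cur)) nd <- nd + 1
        else if (translate_codons(cur) == translate_codons(nxt)) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    ok <- lapply(paths, step_all)
  }
  colMeans(do.call(rbind, ok))
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous and non-synonymous sites (averaged over both
#' sequences) and pathway-averaged differences, then applies the
#' Jukes-Cantor correction to both proportions.
#'
#' @param seq_a,seq_b equal-length in-frame gap-free DNA strings.
#' @return list with `dn`, `ds`, `omega`, raw counts `S`, `N`, `Sd`, `Nd`
#'   and proportions `pS`, `pN`; `omega` is `Inf` when `ds == 0 < dn` and
#'   `NaN` when both are 0.
#' @export
ng86 <- function(seq_a, seq_b) {
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  if (any(is_stop_codon(ca[-length(ca)])) || any(is_stop_codon(cb[-length(cb)])))
    stop("internal stop codon in alignment")
  ## terminal stop codons (if present in both) are dropped from counting
  if (is_stop_codon(ca[length(ca)]) && is_stop_codon(cb[length(cb)])) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  stab <- .ng86_sites()
  S <- (sum(stab[ca]) + sum(stab[cb])) / 2
  N <- 3 * length(ca) - S
  d <- mapply(function(x, y) .ng86_diffs(x, y), ca, cb)
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (pS >= 3 / 4 || pN >= 3 / 4)
    stop("proportion of differences >= 3/4: Jukes-Cantor correction undefined")
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  dn <- jc(pN); ds <- jc(pS)
  omega <- if (ds > 0) dn / ds else if (dn > 0) Inf else NaN
  list(dn = dn, ds = ds, omega = omega, S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN)
}

## ---------------------------------------------------------------- GY94 ---

#' F3x4 codon equilibrium frequencies from an alignment pair
#'
#' Nucleotide frequencies are tallied at each codon position over both
#' sequences; codon frequencies are position products, zeroed at stop
#' codons and renormalized. A small floor keeps observed codons off zero.
#'
#' @param seq_a,seq_b in-frame DNA strings.
#' @return numeric vector of 61 frequencies (order of [codon_structure()]).
#' @export
f3x4_frequencies <- function(seq_a, seq_b) {
  cs <- codon_structure()
  ch <- c(strsplit(toupper(seq_a), "")[[1]], strsplit(toupper(seq_b), "")[[1]])
  n <- length(ch)
  posidx <- rep_len(1:3, n)
  freq <- sapply(1:3, function(p) {
    tab <- tabulate(match(ch[posidx == p], BASES), 4L)
    tab / sum(tab)
  })  # 4 x 3
  pi <- freq[match(cs$mat[, 1], BASES), 1] *
    freq[match(cs$mat[, 2], BASES), 2] *
    freq[match(cs$mat[, 3], BASES), 3]
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}

## Eigendecomposition of the scaled, symmetrized GY94 generator.
## The generator Q (q_ij = r_ij pi_j, r symmetric) is similar to the
## symmetric S_ij = r_ij sqrt(pi_i pi_j), which is built directly here;
## reversibility guarantees the real spectrum.
.gy94_eigen <- function(kappa, omega, pi) {
  cs <- codon_structure()
  n <- length(pi)
  r <- exp(cs$ts_num * log(kappa) + cs$nonsyn_num * log(omega))
  pipj <- pi[cs$pi_] * pi[cs$pj_]
  w <- r * sqrt(pipj)
  S <- matrix(0, n, n)
  S[cs$idx_up] <- w
  S[cs$idx_lo] <- w
  rowQ <- rowsum(c(r * pi[cs$pj_], r * pi[cs$pi_]), c(cs$pi_, cs$pj_))[, 1]
  diag(S) <- -rowQ
  scale <- sum(pi * rowQ)          # mean substitution rate before scaling
  e <- eigen(S, symmetric = TRUE)
  flux_nonsyn <- 2 * sum(pipj * r * cs$nonsyn_num) / scale
  list(U = e$vectors, lam = e$values / scale, sq = sqrt(pi), scale = scale,
       flux_nonsyn = flux_nonsyn)
}

#' GY94 rate matrix (scaled to one expected substitution per unit time)
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega dN/dS ratio.
#' @param pi 61 codon equilibrium frequencies.
#' @return 61 x 61 generator matrix.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi) {
  cs <- codon_structure()
  n <- length(pi)
  r <- exp(cs$ts_num * log(kappa) + cs$nonsyn_num * log(omega))
  Q <- matrix(0, n, n, dimnames = list(cs$codons, cs$codons))
  Q[cbind(cs$pi_, cs$pj_)] <- r * pi[cs$pj_]
  Q[cbind(cs$pj_, cs$pi_)] <- r * pi[cs$pi_]
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

#' Transition probability matrix exp(Qt) for the GY94 model
#' @inheritParams gy94_rate_matrix
#' @param t divergence time (expected substitutions per codon).
#' @export
gy94_probability_matrix <- function(t, kappa, omega, pi) {
  e <- .gy94_eigen(kappa, omega, pi)
  P <- (e$U %*% (t(e$U) * exp(e$lam * t))) * ((1 / e$sq) %o% e$sq)
  dimnames(P) <- list(codon_structure()$codons, codon_structure()$codons)
  P
}

## Observed codon-pair data: distinct (i, j) index pairs with counts.
.codon_pair_data <- function(seq_a, seq_b, drop_terminal_stop = TRUE) {
  cs <- codon_structure()
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  if (drop_terminal_stop &&
      is_stop_codon(ca[length(ca)]) && is_stop_codon(cb[length(cb)])) {
    ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
  }
  ia <- cs$index[ca]; ib <- cs$index[cb]
  if (anyNA(ia) || anyNA(ib))
    stop("alignment contains stop or ambiguous codons")
  key <- (ia - 1L) * 61L + ib
  tab <- table(key)
  k <- as.integer(names(tab))
  list(i = (k - 1L) %/% 61L + 1L, j = (k - 1L) %% 61L + 1L,
       n = as.numeric(tab), n_codons = length(ca),
       n_diff = sum(ia != ib))
}

.gy94_lnL_from_eigen <- function(e, t, pd) {
  m <- e$U[pd$i, , drop = FALSE] * e$U[pd$j, , drop = FALSE]
  joint <- as.vector(m %*% exp(e$lam * t)) * e$sq[pd$i] * e$sq[pd$j]
  sum(pd$n * log(pmax(joint, 1e-300)))
}

#' GY94 pairwise log-likelihood
#'
#' `lnL = sum over sites of log(pi_i P_ij(t))` — the standard pairwise
#' likelihood with the ancestor integrated out under reversibility.
#'
#' @param t,kappa,omega model parameters.
#' @param seq_a,seq_b in-frame DNA strings.
#' @param codon_freq_mode "F3x4" (from the pair) or "equal".
#' @param pi optional explicit 61-vector of codon frequencies.
#' @return log-likelihood (numeric scalar).
#' @export
gy94_loglik <- function(t, kappa, omega, seq_a, seq_b,
                        codon_freq_mode = c("F3x4", "equal"), pi = NULL) {
  codon_freq_mode <- match.arg(codon_freq_mode)
  if (is.null(pi)) {
    pi <- if (codon_freq_mode == "F3x4") f3x4_frequencies(seq_a, seq_b)
      else rep(1 / 61, 61)
  }
  pd <- .codon_pair_data(seq_a, seq_b)
  .gy94_lnL_from_eigen(.gy94_eigen(kappa, omega, pi), t, pd)
}

.GY94_BOUNDS <- list(t = c(1e-6, 50), kappa = c(0.01, 100),
                     omega = c(1e-4, 99))
.GY94_STARTS <- list(c(t = 0.05, kappa = 2, omega = 0.5),
                     c(t = 0.20, kappa = 1, omega = 2.0),
                     c(t = 0.01, kappa = 4, omega = 0.1))

#' Maximum-likelihood pairwise GY94 fit
#'
#' Jointly maximizes (t, kappa, omega) — or (t, kappa) with omega fixed —
#' by bounded quasi-Newton on log-transformed parameters, multi-started
#' from three fixed initial points. dN and dS are derived from the fitted
#' matrix: the non-synonymous flux fraction rho_N times t, per
#' non-synonymous site (sites measured by the neutral omega = 1 flux at the
#' fitted kappa), and likewise for dS.
#'
#' @param seq_a,seq_b equal-length in-frame DNA strings.
#' @param codon_freq_mode "F3x4" or "equal".
#' @param fix_omega fix omega at this value (NULL = free).
#' @param pi optional explicit codon frequencies.
#' @return list with t, kappa, omega, lnL, dn, ds, converged, degenerate
#'   (TRUE when the pair has no differences).
#' @export
gy94_pairwise_ml <- function(seq_a, seq_b, codon_freq_mode = c("F3x4", "equal"),
                             fix_omega = NULL, pi = NULL) {
  codon_freq_mode <- match.arg(codon_freq_mode)
  if (is.null(pi)) {
    pi <- if (codon_freq_mode == "F3x4") f3x4_frequencies(seq_a, seq_b)
      else rep(1 / 61, 61)
  }
  pd <- .codon_pair_data(seq_a, seq_b)
  b <- .GY94_BOUNDS
  free_omega <- is.null(fix_omega)
  if (pd$n_diff == 0L) {
    ## no information: lnL is maximized at the t lower bound
    kappa <- 2; omega <- if (free_omega) NA_real_ else fix_omega
    e <- .gy94_eigen(kappa, if (free_omega) 1 else fix_omega, pi)
    lnL <- .gy94_lnL_from_eigen(e, b$t[1], pd)
    return(list(t = b$t[1], kappa = kappa, omega = omega, lnL = lnL,
                dn = 0, ds = 0, converged = TRUE, degenerate = TRUE))
  }
  ## (kappa, omega) are optimized by bounded quasi-Newton with t profiled
  ## out: one eigendecomposition per (kappa, omega), then a cheap 1-D search
  ## over t reusing the cached spectrum.
  profile_t <- function(e) {
    m <- e$U[pd$i, , drop = FALSE] * e$U[pd$j, , drop = FALSE]
    base <- log(e$sq[pd$i] * e$sq[pd$j])
    f <- function(logt) {
      joint <- as.vector(m %*% exp(e$lam * exp(logt)))
      sum(pd$n * (log(pmax(joint, 1e-300)) + base))
    }
    op <- stats::optimize(f, lower = log(b$t[1]), upper = log(b$t[2]),
                          maximum = TRUE, tol = 1e-9)
    list(t = exp(op$maximum), lnL = op$objective)
  }
  obj <- function(par) {
    kappa <- exp(par[1])
    omega <- if (free_omega) exp(par[2]) else fix_omega
    profile_t(.gy94_eigen(kappa, omega, pi))$lnL
  }
  lower <- log(c(b$kappa[1], if (free_omega) b$omega[1]))
  upper <- log(c(b$kappa[2], if (free_omega) b$omega[2]))
  best <- NULL
  for (s in .GY94_STARTS) {
    par0 <- log(if (free_omega) s[2:3] else s[2])
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(fnscale = -1, factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best))
    stop("GY94 optimization failed for all starting points")
  kappa_hat <- exp(best$par[1])
  omega_hat <- if (free_omega) exp(best$par[2]) else fix_omega
  t_hat <- profile_t(.gy94_eigen(kappa_hat, omega_hat, pi))$t
  rhoN <- .gy94_eigen(kappa_hat, omega_hat, pi)$flux_nonsyn
  rhoN1 <- .gy94_eigen(kappa_hat, 1, pi)$flux_nonsyn
  dn <- t_hat * rhoN / (3 * rhoN1)
  ds <- t_hat * (1 - rhoN) / (3 * (1 - rhoN1))
  list(t = t_hat, kappa = kappa_hat, omega = omega_hat, lnL = best$value,
       dn = dn, ds = ds, converged = best$convergence == 0,
       degenerate = FALSE)
}

#' Likelihood-ratio test of neutrality (omega = 1)
#'
#' Fits the free-omega model (M1) and the omega = 1 null (M0); the
#' statistic Delta = 2(lnL_M1 - lnL_M0) is referred to chi-square with one
#' degree of freedom.
#'
#' @inheritParams gy94_pairwise_ml
#' @return list with `delta`, `p`, and the two fits (`fit_free`, `fit_null`).
#' @export
lrt_neutral <- function(seq_a, seq_b, codon_freq_mode = c("F3x4", "equal"),
                        pi = NULL) {
  codon_freq_mode <- match.arg(codon_freq_mode)
  free <- gy94_pairwise_ml(seq_a, seq_b, codon_freq_mode, pi = pi)
  null <- gy94_pairwise_ml(seq_a, seq_b, codon_freq_mode, fix_omega = 1,
                           pi = pi)
  delta <- max(0, 2 * (free$lnL - null$lnL))
  list(delta = delta, p = stats::pchisq(delta, df = 1, lower.tail = FALSE),
       fit_free = free, fit_null = null)
}

#' Full omega analysis of one fixed-difference alignment
#'
#' @param seq_a,seq_b the alignment pair.
#' @param gene_id identifier carried into the result row.
#' @inheritParams gy94_pairwise_ml
#' @return one-row data.frame (OmegaResult): t, kappa, omega, lnL_free,
#'   lnL_null, delta, p, dn, ds, ng86_dn, ng86_ds, ng86_omega,
#'   omega_infinite (no synonymous differences observed, >= 1
#'   non-synonymous), converged.
#' @export
omega_result <- function(seq_a, seq_b, gene_id = NA_character_,
                         codon_freq_mode = c("F3x4", "equal"), pi = NULL) {
  codon_freq_mode <- match.arg(codon_freq_mode)
  lrt <- lrt_neutral(seq_a, seq_b, codon_freq_mode, pi = pi)
  ng <- tryCatch(ng86(seq_a, seq_b), error = function(e)
    list(dn = NA_real_, ds = NA_real_, omega = NA_real_,
         Sd = NA_real_, Nd = NA_real_))
  inf_flag <- isTRUE(ng$Sd == 0 && ng$Nd > 0)
  data.frame(gene_id = gene_id,
             t = lrt$fit_free$t, kappa = lrt$fit_free$kappa,
             omega = lrt$fit_free$omega,
             lnL_free = lrt$fit_free$lnL, lnL_null = lrt$fit_null$lnL,
             delta = lrt$delta, p = lrt$p,
             dn = lrt$fit_free$dn, ds = lrt$fit_free$ds,
             ng86_dn = ng$dn, ng86_ds = ng$ds, ng86_omega = ng$omega,
             omega_infinite = inf_flag,
             converged = lrt$fit_free$converged && lrt$fit_null$converged,
             stringsAsFactors = FALSE)
}

#' Omega results for a set of alignments
#'
#' @param alignments named list of c(A=..., B=...) pairs
#'   (from [classify_all_genes()]).
#' @inheritParams gy94_pairwise_ml
#' @return data.frame of [omega_result()] rows.
#' @export
omega_all <- function(alignments, codon_freq_mode = c("F3x4", "equal")) {
  codon_freq_mode <- match.arg(codon_freq_mode)
  rows <- lapply(names(alignments), function(g)
    omega_result(alignments[[g]][1], alignments[[g]][2], gene_id = g,
                 codon_freq_mode = codon_freq_mode))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report table of genes ranked by fixed non-synonymous substitutions
#'
#' Mirrors the published layout: rows sorted by fixed non-synonymous count
#' descending, omega printed as the infinity symbol when no synonymous
#' difference was observed, and genes with fewer than 3 fixed substitutions
#' flagged as low support.
#'
#' @param omega_df data.frame from [omega_all()].
#' @param genes_df per-gene variation counts (from [classify_all_genes()]).
#' @return data.frame with merged counts, `omega_print`, `low_support`.
#' @export
omega_table <- function(omega_df, genes_df) {
  cols <- c("gene_id", "family_tag", "n_fixed_syn", "n_fixed_nonsyn",
            "n_poly_syn", "n_poly_nonsyn")
  if (is.null(omega_df) || nrow(omega_df) == 0L) {
    out <- cbind(genes_df[0, cols],
                 data.frame(dn = numeric(0), ds = numeric(0),
                            omega = numeric(0), omega_print = character(0),
                            delta = numeric(0), p = numeric(0),
                            low_support = logical(0)))
    return(out)
  }
  m <- merge(genes_df[, cols], omega_df, by = "gene_id")
  m$n_fixed <- m$n_fixed_syn + m$n_fixed_nonsyn
  m <- m[order(-m$n_fixed_nonsyn, m$gene_id), ]
  m$omega_print <- ifelse(m$omega_infinite, "∞",
                          formatC(m$omega, digits = 4, format = "f"))
  m$low_support <- m$n_fixed < 3L
  rownames(m) <- NULL
  m
}

#' Simulate a codon sequence pair under the GY94 model
#'
#' Draws an ancestor from the equilibrium distribution and a descendant from
#' the transition matrix at divergence t (all divergence on one branch,
#' which is equivalent under reversibility).
#'
#' @param n_codons number of codons.
#' @param t,kappa,omega model parameters.
#' @param pi codon frequencies (default equal over the 61 sense codons).
#' @param seed integer seed.
#' @return character vector c(A = ..., B = ...).
#' @export
simulate_gy94_pair <- function(n_codons, t, kappa, omega,
                               pi = rep(1 / 61, 61), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- codon_structure()
  P <- gy94_probability_matrix(t, kappa, omega, pi)
  anc <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  des <- vapply(anc, function(i)
    sample.int(61L, 1L, prob = pmax(P[i, ], 0)), integer(1L))
  c(A = paste(cs$codons[anc], collapse = ""),
    B = paste(cs$codons[des], collapse = ""))
}
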