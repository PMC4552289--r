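# Independent oracle implementations used across the suite. Deliberately
# naive and written without the package's internal helpers so the two
# routes to each quantity stay independent.

GC_TABLE <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(GC_TABLE[codon])

# --- naive NG86 ------------------------------------------------------------

oracle_ng86 <- function(a, b) {
  to_codons <- function(s) {
    s <- toupper(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- to_codons(a); cb <- to_codons(b)
  stops <- c("TAA", "TAG", "TGA")
  nlast <- length(ca)
  if (ca[nlast] %in% stops && cb[nlast] %in% stops) {
    ca <- ca[-nlast]; cb <- cb[-nlast]
  }
  syn_sites <- function(codon) {
    aa0 <- oracle_translate(codon)
    s <- 0
    for (p in 1:3) {
      orig <- substr(codon, p, p)
      for (nt in c("A", "C", "G", "T")) {
        if (nt == orig) next
        mut <- codon
        substr(mut, p, p) <- nt
        if (!(mut %in% stops) && oracle_translate(mut) == aa0) s <- s + 1 / 3
      }
    }
    s
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v))
      for (r in all_orders(v[-i])) res[[length(res) + 1]] <- c(v[i], r)
    res
  }
  pair_diffs <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    counts <- list()
    for (ord in all_orders(pos)) {
      cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% stops) { blocked <- TRUE; break }
        if (oracle_translate(cur) == oracle_translate(nxt)) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked) counts[[length(counts) + 1]] <- c(sd, nd)
    }
    if (length(counts) == 0) {
      for (ord in all_orders(pos)) {
        cur <- c1; sd <- 0; nd <- 0
        for (p in ord) {
          nxt <- cur
          substr(nxt, p, p) <- substr(c2, p, p)
          if (nxt %in% stops || cur %in% stops) nd <- nd + 1
          else if (oracle_translate(cur) == oracle_translate(nxt)) sd <- sd + 1
          else nd <- nd + 1
          cur <- nxt
        }
        counts[[length(counts) + 1]] <- c(sd, nd)
      }
    }
    colMeans(do.call(rbind, counts))
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    S <- S + (syn_sites(ca[k]) + syn_sites(cb[k])) / 2
    d <- pair_diffs(ca[k], cb[k])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * length(ca) - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(dn = jc(pN), ds = jc(pS), S = S, N = N, Sd = Sd, Nd = Nd)
}

# --- straight-line site classifier -----------------------------------------

oracle_classify_site <- function(cnt_a, cnt_b, min_depth = 10, maj = 0.95,
                                 floor_reads = 5, frac = 0.05) {
  bases <- c("A", "C", "G", "T")
  da <- sum(cnt_a); db <- sum(cnt_b)
  if (da < min_depth || db < min_depth) return("unclassifiable")
  present <- function(cnt, d) {
    thr <- max(floor_reads, frac * d)
    bases[cnt[bases] >= thr]
  }
  pa <- present(cnt_a, da); pb <- present(cnt_b, db)
  fixed <- FALSE
  for (bb in bases) {
    if (cnt_a[bb] / da >= maj && !(bb %in% pb)) fixed <- TRUE
    if (cnt_b[bb] / db >= maj && !(bb %in% pa)) fixed <- TRUE
  }
  if (fixed) return("fixed")
  if (length(pa) >= 2 || length(pb) >= 2) return("polymorphic")
  "invariant"
}

# --- brute-force 6-frame ORF scan ------------------------------------------

oracle_orfs <- function(transcript, min_len) {
  stops <- c("TAA", "TAG", "TGA")
  orfs <- character(0)
  scan <- function(s) {
    found <- character(0)
    n <- nchar(s)
    for (i in seq_len(max(0, n - 5))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        cod <- substr(s, j, j + 2)
        if (cod %in% stops) {
          orf <- substr(s, i, j + 2)
          if (nchar(orf) >= min_len && !grepl("N", orf)) found <- c(found, orf)
          break
        }
        j <- j + 3
      }
    }
    found
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(transcript)))
  sort(c(scan(toupper(transcript)), scan(toupper(rc))))
}

# --- tiny random-sequence helpers ------------------------------------------

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# small pileup count matrix constructor
cnts <- function(A = 0, C = 0, G = 0, T = 0) {
  c(A = A, C = C, G = G, T = T)
}
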