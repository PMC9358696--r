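# Independent oracles, implemented by simple enumeration / brute force so
# they stay structurally unrelated to the package's optimized paths.

# --- Nei-Gojobori by direct recursive pathway enumeration -------------------
oracle_translate <- function(codon) Biostrings::GENETIC_CODE[[codon]]

oracle_syn_sites_codon <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    orig <- substr(codon, p, p)
    for (b in nts[nts != orig]) {
      mut <- codon
      substr(mut, p, p) <- b
      if (oracle_translate(mut) == aa && oracle_translate(mut) != "*") {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# recursively walk every ordering of the differing positions, counting
# synonymous / non-synonymous single-nucleotide steps
oracle_codon_paths <- function(from, to) {
  dpos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L) return(list(s = 0, n = 0, paths = 1))
    tot <- list(s = 0, n = 0, paths = 0)
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      syn_step <- oracle_translate(cur) == oracle_translate(nxt) &&
        oracle_translate(cur) != "*"
      sub <- walk(nxt, setdiff(remaining, p))
      tot$s <- tot$s + sub$paths * syn_step + sub$s
      tot$n <- tot$n + sub$paths * (!syn_step) + sub$n
      tot$paths <- tot$paths + sub$paths
    }
    tot
  }
  res <- walk(from, dpos)
  list(Sd = res$s / max(res$paths, 1), Nd = res$n / max(res$paths, 1))
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- 0
  Sd <- 0
  Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (oracle_syn_sites_codon(ca[i]) + oracle_syn_sites_codon(cb[i])) / 2
    pd <- oracle_codon_paths(ca[i], cb[i])
    Sd <- Sd + pd$Sd
    Nd <- Nd + pd$Nd
  }
  N <- 3 * length(ca) - S
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (1 - 4 * p / 3 > 0) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       Ks = jc(ps), Ka = jc(pn))
}

random_cds_pair <- function(n_codons, n_changes, rng_seed) {
  set.seed(rng_seed)
  nts <- c("A", "C", "G", "T")
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
  repeat {
    a <- paste(sample(non_stop, n_codons, replace = TRUE), collapse = "")
    b <- a
    idx <- sample(nchar(a), n_changes)
    for (i in idx) {
      substr(b, i, i) <- sample(setdiff(nts, substr(a, i, i)), 1)
    }
    cods_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    if (!any(cods_b %in% c("TAA", "TAG", "TGA"))) return(list(a = a, b = b))
  }
}

# --- quadratic interval-overlap oracle --------------------------------------
brute_force_overlaps <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] < subject$end[j] && query$end[i] > subject$start[j]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(query = m[, 1], subject = m[, 2])
}
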