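# Nei-Gojobori (1986) counting method with Jukes-Cantor correction.
#
# Site counting: for each codon, the synonymous-site fraction at a position
# is the share of the 3 possible single-nucleotide changes that preserve the
# amino acid (changes to or from a stop count as non-synonymous). Sites are
# averaged over the two sequences. Differences: codon pairs differing at k
# positions are resolved by averaging the synonymous/non-synonymous step
# counts over all k! orderings of single-nucleotide steps, all orderings
# weighted equally.

ng86_tables <- local({
  tables <- NULL
  function() {
    if (!is.null(tables)) return(tables)
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    code <- Biostrings::GENETIC_CODE[codons]
    aa <- unname(code)

    syn_sites <- vapply(seq_along(codons), function(i) {
      cod <- strsplit(codons[i], "")[[1]]
      s <- 0
      for (p in 1:3) {
        for (b in setdiff(bases, cod[p])) {
          mut <- cod
          mut[p] <- b
          maa <- Biostrings::GENETIC_CODE[[paste(mut, collapse = "")]]
          if (maa == aa[i] && maa != "*") s <- s + 1 / 3
        }
      }
      s
    }, numeric(1))
    names(syn_sites) <- codons

    step_syn <- function(c1, c2) {
      a1 <- Biostrings::GENETIC_CODE[[c1]]
      a2 <- Biostrings::GENETIC_CODE[[c2]]
      a1 == a2 && a1 != "*"
    }
    # pairwise Sd/Nd over all 64x64 codon pairs, path-averaged
    n_cod <- length(codons)
    Sd <- matrix(0, n_cod, n_cod, dimnames = list(codons, codons))
    Nd <- Sd
    for (i in seq_len(n_cod)) {
      ci <- strsplit(codons[i], "")[[1]]
      for (j in seq_len(n_cod)) {
        if (i == j) next
        cj <- strsplit(codons[j], "")[[1]]
        diffpos <- which(ci != cj)
        k <- length(diffpos)
        perms <- switch(k,
          list(diffpos),
          list(diffpos, rev(diffpos)),
          {
            p <- diffpos
            list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                 p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
          }
        )
        tot_s <- 0
        tot_n <- 0
        for (ord in perms) {
          cur <- ci
          for (p in ord) {
            nxt <- cur
            nxt[p] <- cj[p]
            if (step_syn(paste(cur, collapse = ""), paste(nxt, collapse = ""))) {
              tot_s <- tot_s + 1
            } else {
              tot_n <- tot_n + 1
            }
            cur <- nxt
          }
        }
        Sd[i, j] <- tot_s / length(perms)
        Nd[i, j] <- tot_n / length(perms)
      }
    }
    tables <<- list(codons = codons, aa = aa, syn_sites = syn_sites,
                    Sd = Sd, Nd = Nd)
    tables
  }
})

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("coding sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

jc_correct <- function(p) {
  ifelse(1 - 4 * p / 3 > 0, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori Ka/Ks for an aligned codon pair
#'
#' Computes synonymous (S) and non-synonymous (N) site counts, path-averaged
#' synonymous/non-synonymous differences (Sd, Nd), the proportions
#' `ps = Sd/S` and `pn = Nd/N`, and the Jukes-Cantor-corrected rates
#' `Ks = -3/4 log(1 - 4 ps / 3)` and `Ka` analogously. Codons containing
#' non-ACGT letters (gaps, ambiguity codes) in either sequence are excluded
#' pairwise and counted; a terminal stop codon shared by both sequences is
#' trimmed; an internal stop is an error.
#'
#' @param cds_a,cds_b Aligned coding sequences of equal length, divisible
#'   by 3.
#' @return A one-row tibble: `n_codons`, `n_skipped`, `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `ka_ks` and flags `ks_undefined`,
#'   `ka_undefined`, `ratio_undefined`.
#' @examples
#' ng86_kaks("TTTGCT", "TTCGCT")
#' @export
ng86_kaks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences must be aligned to equal length")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  tb <- ng86_tables()

  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  n_skipped <- sum(!clean)
  ca <- ca[clean]
  cb <- cb[clean]
  if (length(ca) == 0L) stop("no analyzable codons after exclusions")

  aa_a <- tb$aa[match(ca, tb$codons)]
  aa_b <- tb$aa[match(cb, tb$codons)]
  last <- length(ca)
  if (aa_a[last] == "*" && aa_b[last] == "*") {
    ca <- ca[-last]
    cb <- cb[-last]
    aa_a <- aa_a[-last]
    aa_b <- aa_b[-last]
  }
  if (any(aa_a == "*") || any(aa_b == "*")) {
    stop("internal stop codon in input sequence")
  }
  n_codons <- length(ca)

  S <- (sum(tb$syn_sites[ca]) + sum(tb$syn_sites[cb])) / 2
  N <- 3 * n_codons - S
  ia <- match(ca, tb$codons)
  ib <- match(cb, tb$codons)
  Sd <- sum(tb$Sd[cbind(ia, ib)])
  Nd <- sum(tb$Nd[cbind(ia, ib)])

  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  ks_undef <- is.na(Ks)
  ka_undef <- is.na(Ka)
  ratio_undef <- ks_undef || ka_undef || Ks == 0
  tibble::tibble(
    n_codons = n_codons, n_skipped = n_skipped,
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn, Ks = Ks, Ka = Ka,
    ka_ks = if (ratio_undef) NA_real_ else Ka / Ks,
    ks_undefined = ks_undef, ka_undefined = ka_undef,
    ratio_undefined = ratio_undef
  )
}

#' Ka/Ks over many aligned pairs
#'
#' @param pairs Tibble with columns `id_a`, `id_b`.
#' @param sequences Named character vector of aligned coding sequences.
#' @return One [ng86_kaks()] row per pair, with `id_a`, `id_b` prepended.
#' @export
ng86_kaks_pairs <- function(pairs, sequences) {
  purrr::pmap(pairs[c("id_a", "id_b")], function(id_a, id_b) {
    res <- ng86_kaks(sequences[[id_a]], sequences[[id_b]])
    dplyr::bind_cols(tibble::tibble(id_a = id_a, id_b = id_b), res)
  }) |> dplyr::bind_rows()
}

#' Contrast Ka/Ks between balanced and unbalanced triad groups
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that the unbalanced
#' group's Ka/Ks ratios are stochastically larger than the balanced group's.
#' Undefined ratios are dropped; each group must retain at least 3 values.
#' A rank test is used because Ka/Ks is bounded below and right-skewed.
#'
#' @param kaks_balanced,kaks_unbalanced Numeric vectors of Ka/Ks ratios
#'   (NAs allowed, dropped).
#' @return An object of class `kaks_contrast` with
#'   [tidy()][generics::tidy] / [glance()][generics::glance] methods; fields
#'   `statistic`, `p_value`, `median_balanced`, `median_unbalanced`,
#'   `n_balanced`, `n_unbalanced`.
#' @export
compare_kaks_groups <- function(kaks_balanced, kaks_unbalanced) {
  b <- kaks_balanced[is.finite(kaks_balanced)]
  u <- kaks_unbalanced[is.finite(kaks_unbalanced)]
  if (length(b) < 3L || length(u) < 3L) {
    stop("fewer than 3 defined ratios in a group after filtering")
  }
  ht <- stats::wilcox.test(u, b, alternative = "greater", exact = FALSE)
  structure(
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         median_balanced = stats::median(b), median_unbalanced = stats::median(u),
         n_balanced = length(b), n_unbalanced = length(u), test = ht),
    class = "kaks_contrast"
  )
}

#' @export
print.kaks_contrast <- function(x, ...) {
  cat("<kaks_contrast> Wilcoxon rank-sum, one-sided (unbalanced > balanced)\n")
  cat(sprintf("  W = %.1f, p = %.3g\n", x$statistic, x$p_value))
  cat(sprintf("  median Ka/Ks: balanced %.3f (n=%d), unbalanced %.3f (n=%d)\n",
              x$median_balanced, x$n_balanced, x$median_unbalanced,
              x$n_unbalanced))
  invisible(x)
}

#' @rdname compare_kaks_groups
#' @param x A `kaks_contrast` object.
#' @param ... Unused.
#' @export
tidy.kaks_contrast <- function(x, ...) {
  tibble::tibble(
    group = c("balanced", "unbalanced"),
    n = c(x$n_balanced, x$n_unbalanced),
    median_ka_ks = c(x$median_balanced, x$median_unbalanced)
  )
}

#' @rdname compare_kaks_groups
#' @export
glance.kaks_contrast <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = "Wilcoxon rank-sum (one-sided)",
                 alternative = "unbalanced > balanced")
}
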