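#' Attach mean FPKMs to a triad table
#'
#' Joins an expression matrix onto a triad table (columns `LF`, `MF1`,
#' `MF2`), averaging expression across the selected sample columns for each
#' homoeolog. Genes absent from the matrix get FPKM 0.
#'
#' @param triads Tibble with columns `LF`, `MF1`, `MF2` (gene IDs).
#' @param expression Expression tibble (`feature_id` + sample columns), as
#'   read by [read_expression_tsv()].
#' @param samples Sample columns to average over; default all.
#' @return `triads` with numeric columns `fpkm_lf`, `fpkm_mf1`, `fpkm_mf2`
#'   and a `triad_id`.
#' @export
triad_expression <- function(triads, expression, samples = NULL) {
  if (is.null(samples)) samples <- setdiff(names(expression), "feature_id")
  mean_expr <- rowMeans(as.matrix(expression[samples]))
  lookup <- stats::setNames(mean_expr, expression$feature_id)
  get0 <- function(ids) {
    v <- lookup[ids]
    v[is.na(v)] <- 0
    unname(v)
  }
  out <- dplyr::mutate(triads,
    triad_id = sprintf("triad%04d", dplyr::row_number()),
    fpkm_lf = get0(.data$LF), fpkm_mf1 = get0(.data$MF1),
    fpkm_mf2 = get0(.data$MF2),
    .before = 1
  )
  out
}

#' Filter triads by summed expression
#'
#' Keeps triads whose summed FPKM across the three homoeologs is strictly
#' greater than `min_sum` (default 0.5), the usual guard against classifying
#' noise-level triads on the simplex.
#'
#' @param triads Tibble with `fpkm_lf`, `fpkm_mf1`, `fpkm_mf2` (see
#'   [triad_expression()]).
#' @param min_sum Strict lower bound on the summed FPKM.
#' @return The filtered tibble.
#' @export
filter_expressed_triads <- function(triads, min_sum = 0.5) {
  dplyr::filter(triads, .data$fpkm_lf + .data$fpkm_mf1 + .data$fpkm_mf2 > min_sum)
}

#' Ternary (relative-expression) coordinates of a triad
#'
#' @param fpkm Numeric matrix or data frame with three columns (LF, MF1,
#'   MF2) or a length-3 vector; all row sums must be > 0.
#' @return A matrix of row-normalised relative contributions summing to 1.
#' @examples
#' ternary_coordinates(c(2, 1, 1))
#' @export
ternary_coordinates <- function(fpkm) {
  m <- matrix(as.numeric(as.matrix(fpkm)), ncol = 3)
  s <- rowSums(m)
  if (any(s <= 0)) stop("triad with non-positive total expression; filter first")
  out <- m / s
  colnames(out) <- c("LF", "MF1", "MF2")
  out
}

#' Classify triads into seven expression-bias categories
#'
#' Each triad's relative-expression triple is compared by Euclidean distance
#' against seven archetype centroids on the ternary simplex: Balanced
#' (1/3, 1/3, 1/3); X-dominant = the unit vector on X; X-suppressed = 0 on X
#' and 1/2 on the other two. The category attaining the minimum distance is
#' assigned. Exact ties are broken deterministically in the fixed order
#' Balanced, LF/MF1/MF2-dominant, LF/MF1/MF2-suppressed and flagged.
#'
#' @param triads Tibble with `fpkm_lf`, `fpkm_mf1`, `fpkm_mf2` (typically
#'   after [filter_expressed_triads()]).
#' @return The input with added columns `rel_lf`, `rel_mf1`, `rel_mf2`,
#'   `category` (factor over the seven levels), `min_distance`, `tie`
#'   (logical), plus one `dist_*` column per centroid. Class
#'   `triad_classification`.
#' @export
classify_triads <- function(triads) {
  rel <- ternary_coordinates(triads[, c("fpkm_lf", "fpkm_mf1", "fpkm_mf2")])
  cent <- triad_centroids()
  d <- sapply(seq_len(nrow(cent)), function(k) {
    sqrt(rowSums(sweep(rel, 2, cent[k, ])^2))
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  colnames(d) <- rownames(cent)
  idx <- apply(d, 1, which.min)   # ties: first index = fixed category order
  min_d <- d[cbind(seq_len(nrow(d)), idx)]
  tie <- apply(d, 1, function(x) sum(abs(x - min(x)) < 1e-12) > 1)
  out <- dplyr::mutate(triads,
    rel_lf = rel[, 1], rel_mf1 = rel[, 2], rel_mf2 = rel[, 3],
    category = factor(rownames(cent)[idx], levels = triad_category_levels()),
    min_distance = min_d, tie = tie
  )
  for (k in seq_len(nrow(cent))) {
    out[[paste0("dist_", gsub("-", "_", tolower(rownames(cent)[k])))]] <- d[, k]
  }
  class(out) <- c("triad_classification", class(out))
  out
}

#' Summarise triad categories
#'
#' Counts and percentages per category, plus a Balanced / Dominant /
#' Suppressed rollup (the three dominant and three suppressed categories
#' summed).
#'
#' @param classifications A `triad_classification` tibble from
#'   [classify_triads()], or any tibble with a `category` column.
#' @return A list with `by_category` (tibble: `category`, `n`, `pct`) and
#'   `rollup` (tibble: `group`, `n`, `pct`) and `total`. Percentages are
#'   `100 * n / total`. Empty input yields zero-row tibbles.
#' @export
summarize_categories <- function(classifications) {
  lv <- triad_category_levels()
  total <- nrow(classifications)
  if (total == 0L) {
    return(list(
      by_category = tibble::tibble(category = factor(character(), levels = lv),
                                   n = integer(), pct = numeric()),
      rollup = tibble::tibble(group = character(), n = integer(), pct = numeric()),
      total = 0L
    ))
  }
  cat_f <- factor(as.character(classifications$category), levels = lv)
  n <- as.integer(table(cat_f))
  by_category <- tibble::tibble(category = factor(lv, levels = lv), n = n,
                                pct = 100 * n / total)
  grp <- c("Balanced", rep("Dominant", 3), rep("Suppressed", 3))
  rollup <- tibble::tibble(group = grp, n = n) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(pct = 100 * .data$n / total) |>
    dplyr::arrange(match(.data$group, c("Balanced", "Dominant", "Suppressed")))
  list(by_category = by_category, rollup = rollup, total = total)
}
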