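#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the standard convention: the sum of hypergeometric
#' probabilities of all same-margin tables no more probable than the
#' observed one. The odds ratio reported is the sample (cross-product)
#' ratio `ad / bc`, with `Inf` when `bc == 0` (and `ad > 0`), `0` when
#' `ad == 0` (and `bc > 0`), and `NaN` when both vanish — not the
#' conditional MLE.
#'
#' @param counts a 2x2 matrix, or 4 counts in row-major order
#'   `c(a, b, c, d)` for the table `rbind(c(a, b), c(c, d))`.
#' @return a list with `odds_ratio` and `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(counts) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(m < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(m) == 0) stop("at least one margin must be positive",
                        call. = FALSE)
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  ad <- a * d; bc <- b * cc
  odds_ratio <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf
                else ad / bc
  p <- fisher.test(m)$p.value
  list(odds_ratio = odds_ratio, p_two_sided = min(p, 1))
}

#' Enrichment of positive selection in NEMs at fixed significance levels
#'
#' At each level, a gene counts as positively selected when its BUSTED
#' p-value is at or below the level; the 2x2 table of NEM status against
#' selection status over all records (the whole ortholog background) is
#' tested by Fisher's exact test. A level at which no gene is selected
#' yields `p = 1` with a flag rather than an error.
#'
#' @param records gene-statistics `data.frame`.
#' @param levels significance levels in `(0, 1)`; default
#'   `c(0.05, 0.01, 0.001)`.
#' @return a `data.frame` with one row per level: the four counts
#'   (`nem_selected`, `nem_not`, `nonnem_selected`, `nonnem_not`),
#'   `odds_ratio`, `p_two_sided`, and `flag`.
#' @export
enrichment_test <- function(records, levels = c(0.05, 0.01, 0.001)) {
  if (any(levels <= 0 | levels >= 1))
    stop("levels must lie in (0, 1)", call. = FALSE)
  is_nem <- records$nem_status == "NEM"
  rows <- lapply(levels, function(l) {
    sel <- records$busted_p <= l
    tab <- c(nem_selected = sum(is_nem & sel),
             nem_not = sum(is_nem & !sel),
             nonnem_selected = sum(!is_nem & sel),
             nonnem_not = sum(!is_nem & !sel))
    if (tab["nem_selected"] + tab["nonnem_selected"] == 0) {
      res <- list(odds_ratio = NaN, p_two_sided = 1)
      flag <- "no_selected_genes"
    } else {
      res <- fisher_exact_2x2(matrix(tab, 2, 2, byrow = TRUE))
      flag <- ""
    }
    data.frame(level = l, t(tab), odds_ratio = res$odds_ratio,
               p_two_sided = res$p_two_sided, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
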