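#' Threshold genes by gene-wide selection evidence
#'
#' Keeps records whose BUSTED p-value is at or below the threshold
#' (weak evidence at 0.9 down to strong evidence at 1e-5), preserving order.
#'
#' @param records gene-statistics `data.frame`.
#' @param threshold BUSTED p-value cutoff in `(0, 1]`.
#' @return the thresholded subset.
#' @export
include_genes <- function(records, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  records[records$busted_p <= threshold, , drop = FALSE]
}

#' Per-gene adaptation: mean selected-codon proportion over branches
#'
#' The amount of adaptation a gene experienced is the arithmetic mean of
#' its per-branch proportions of positively selected codons (aBSREL
#' rate-class weights with omega > 1), averaged along all branches.
#'
#' @param records gene-statistics `data.frame` (or a single record row).
#' @return numeric vector, one value in `[0, 1]` per gene.
#' @export
gene_adaptation <- function(records) {
  vapply(records$branch_sel_prop, function(b) {
    if (!length(b)) stop("empty branch proportion vector", call. = FALSE)
    mean(b)
  }, numeric(1))
}

#' Group adaptation: mean of per-gene adaptation over a gene set
#'
#' @param records nonempty gene-statistics `data.frame`.
#' @return a single numeric value.
#' @export
group_adaptation <- function(records) {
  if (!nrow(records))
    stop("group adaptation of an empty gene set is undefined",
         call. = FALSE)
  mean(gene_adaptation(records))
}

#' dN-matching scheme for reference sampling
#'
#' Parameters of the staged sampler that draws non-NEM reference sets whose
#' mean dN matches the NEM mean: the calibration factor `alpha`, the
#' period `x_period` at which draws are unconditional ("completely
#' random"), the fixed +/-5% band factors around `alpha * dN_target`, the
#' number of initial unconditional draws, and a hard try limit per slot.
#' The defaults alpha = 0.95 and X = 3 are the calibrated values that make
#' the matched non-NEM dN/dS variance closest to the NEM variance; see
#' [calibrate_matching()].
#'
#' @param alpha calibration factor in `(0, 1]` (default 0.95).
#' @param x_period every `x_period`-th accepted member is drawn
#'   unconditionally (default 3).
#' @param band_low,band_high band factors (defaults 0.95 and 1.05), so the
#'   target interval is `[band_low * alpha * dn_target,
#'   band_high * alpha * dn_target]`.
#' @param initial_free_draws unconditional draws before any constraint
#'   applies (default 5).
#' @param max_tries_per_slot guard against infeasible pools (default 10000).
#' @return an object of class `matching_scheme`.
#' @export
matching_scheme <- function(alpha = 0.95, x_period = 3L, band_low = 0.95,
                            band_high = 1.05, initial_free_draws = 5L,
                            max_tries_per_slot = 10000L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  if (x_period < 1) stop("x_period must be >= 1", call. = FALSE)
  if (band_low >= band_high) stop("band_low must be < band_high",
                                  call. = FALSE)
  structure(list(alpha = alpha, x_period = as.integer(x_period),
                 band_low = band_low, band_high = band_high,
                 initial_free_draws = as.integer(initial_free_draws),
                 max_tries_per_slot = as.integer(max_tries_per_slot)),
            class = "matching_scheme")
}

#' Target dN interval implied by a matching scheme
#'
#' @param scheme a [matching_scheme()].
#' @param dn_target the NEM mean dN.
#' @return numeric `c(dn_inf, dn_sup)`.
#' @export
matching_interval <- function(scheme, dn_target) {
  c(dn_inf = scheme$band_low * scheme$alpha * dn_target,
    dn_sup = scheme$band_high * scheme$alpha * dn_target)
}

#' Draw one dN-matched reference sample
#'
#' Draws `size` distinct members of the pool, without replacement, by the
#' staged scheme: `initial_free_draws` unconditional draws, then every
#' `x_period`-th accepted member unconditional, all other slots accepting a
#' candidate only if the running mean dN moves into (or strictly closer to)
#' the interval `[dn_inf, dn_sup]`; on return the sample mean dN is inside
#' the interval (deviant unconditional members are swapped out if the last
#' free draw left it outside). Errors rather than returning out-of-band.
#'
#' @param pool non-NEM gene-statistics `data.frame`, or a numeric dN
#'   vector.
#' @param scheme a [matching_scheme()].
#' @param dn_target target mean dN (typically the included-NEM mean dN).
#' @param size sample size (typically the included-NEM count).
#' @return integer vector of `size` distinct 1-based pool indices, with
#'   attribute `free` flagging members drawn unconditionally.
#' @export
matched_sample <- function(pool, scheme, dn_target, size) {
  dn <- if (is.numeric(pool)) pool else pool$dn
  n <- length(dn)
  if (size > n)
    stop(sprintf("sample size %d exceeds pool size %d", size, n),
         call. = FALSE)
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  iv <- matching_interval(scheme, dn_target)
  sorted <- sort(dn)
  lo_mean <- mean(sorted[seq_len(size)])
  hi_mean <- mean(sorted[seq.int(n - size + 1L, n)])
  if (lo_mean > iv[2] || hi_mean < iv[1])
    stop(sprintf(
      "infeasible pool: achievable mean dN spans [%g, %g] but target interval is [%g, %g] (pool n=%d, mean=%g)",
      lo_mean, hi_mean, iv[1], iv[2], n, mean(dn)), call. = FALSE)
  res <- sample_matched_cpp(dn, as.integer(size), iv[1], iv[2],
                            scheme$initial_free_draws, scheme$x_period,
                            scheme$max_tries_per_slot)
  structure(res$idx, free = res$free)
}

#' Excess of adaptation in NEMs over dN-matched non-NEMs
#'
#' After thresholding on BUSTED p-values, the NEM group adaptation
#' `a_nem` is compared with the permutation distribution of group
#' adaptation across `n_perm` dN-matched non-NEM samples of the same size.
#' The excess is `100 * (a_nem - ref_mean) / ref_mean` (percent extra
#' adaptation); the one-sided permutation p-value uses the add-one
#' estimator `(1 + #{ref >= a_nem}) / (n_perm + 1)` so it is never exactly
#' zero; the 95% interval is the 2.5/97.5 percentile of the
#' per-permutation excess `100 * (a_nem - ref_i) / ref_i`. Each
#' permutation reseeds from a counter-derived sub-seed, so results do not
#' depend on iteration order.
#'
#' @param records gene-statistics `data.frame` with NEM/NONNEM labels.
#' @param threshold BUSTED p-value cutoff.
#' @param scheme a [matching_scheme()]; ignored when `matched = FALSE`.
#' @param n_perm number of permutations (>= 100).
#' @param seed master integer seed.
#' @param matched set `FALSE` for the naive unmatched contrast (simple
#'   random non-NEM samples); used to demonstrate the confounding the
#'   matching removes, not for inference.
#' @return a one-row `data.frame` of class `adaptation_estimate` with
#'   columns `threshold`, `n_nem`, `n_pool`, `a_nem`, `ref_mean`,
#'   `ref_sd`, `excess_pct`, `ci_low_pct`, `ci_high_pct`, `p_perm`,
#'   `n_perm`, `seed`, `matched`.
#' @export
quantify_excess <- function(records, threshold = 0.5,
                            scheme = matching_scheme(), n_perm = 1000L,
                            seed = 1L, matched = TRUE) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  incl <- include_genes(records, threshold)
  nem <- incl[incl$nem_status == "NEM", , drop = FALSE]
  pool <- incl[incl$nem_status == "NONNEM", , drop = FALSE]
  if (!nrow(nem) || !nrow(pool))
    stop("both NEM and non-NEM classes must be nonempty after thresholding",
         call. = FALSE)
  if (nrow(pool) < nrow(nem))
    stop("non-NEM pool smaller than the NEM set", call. = FALSE)
  # canonical pool order so estimates are invariant to input row order
  pool <- pool[order(pool$gene_id), , drop = FALSE]
  a_nem <- group_adaptation(nem)
  dn_target <- mean(nem$dn)
  ga_pool <- gene_adaptation(pool)
  ref <- perm_reference(pool$dn, ga_pool, nrow(nem), scheme, dn_target,
                        n_perm, seed, matched)
  ref_mean <- mean(ref)
  if (ref_mean == 0)
    stop("reference adaptation is 0: excess undefined", call. = FALSE)
  e_i <- 100 * (a_nem - ref) / ref
  ci <- unname(quantile(e_i, c(0.025, 0.975)))
  out <- data.frame(threshold = threshold, n_nem = nrow(nem),
                    n_pool = nrow(pool), a_nem = a_nem,
                    ref_mean = ref_mean, ref_sd = sd(ref),
                    excess_pct = 100 * (a_nem - ref_mean) / ref_mean,
                    ci_low_pct = ci[1], ci_high_pct = ci[2],
                    p_perm = (1 + sum(ref >= a_nem)) / (n_perm + 1),
                    n_perm = as.integer(n_perm), seed = as.integer(seed),
                    matched = matched)
  class(out) <- c("adaptation_estimate", "data.frame")
  out
}

perm_reference <- function(pool_dn, ga_pool, size, scheme, dn_target,
                           n_perm, seed, matched) {
  vapply(seq_len(n_perm), function(i) {
    set.seed(sub_seed(seed, i))
    idx <- if (matched)
      matched_sample(pool_dn, scheme, dn_target, size)
    else sample.int(length(pool_dn), size)
    mean(ga_pool[idx])
  }, numeric(1))
}

#' Excess-of-adaptation curve over a threshold grid
#'
#' One [quantify_excess()] estimate per BUSTED threshold, from weak (0.9)
#' to strong (1e-5) evidence. Thresholds must be sorted descending; a
#' threshold leaving fewer than 10 NEM genes is flagged (`flag =
#' "lt10_nem"`), and one leaving either class empty (or a pool smaller
#' than the NEM set) yields an NA row flagged `"insufficient"` rather than
#' being dropped.
#'
#' @param records,scheme,n_perm,seed,matched as in [quantify_excess()].
#' @param thresholds descending threshold grid; the default covers 0.9
#'   down to 1e-5.
#' @return a `data.frame` with one estimate row per threshold plus a
#'   `flag` column.
#' @export
excess_curve <- function(records,
                         thresholds = c(0.9, 0.5, 0.1, 0.05, 0.01, 1e-3,
                                        1e-4, 1e-5),
                         scheme = matching_scheme(), n_perm = 1000L,
                         seed = 1L, matched = TRUE) {
  if (is.unsorted(rev(thresholds), strictly = TRUE))
    stop("thresholds must be sorted in descending order", call. = FALSE)
  rows <- lapply(seq_along(thresholds), function(j) {
    th <- thresholds[j]
    est <- tryCatch(
      quantify_excess(records, th, scheme, n_perm, sub_seed(seed, j * 1000L),
                      matched),
      error = function(e) NULL)
    if (is.null(est)) {
      incl <- include_genes(records, th)
      est <- data.frame(threshold = th,
                        n_nem = sum(incl$nem_status == "NEM"),
                        n_pool = sum(incl$nem_status == "NONNEM"),
                        a_nem = NA_real_, ref_mean = NA_real_,
                        ref_sd = NA_real_, excess_pct = NA_real_,
                        ci_low_pct = NA_real_, ci_high_pct = NA_real_,
                        p_perm = NA_real_, n_perm = as.integer(n_perm),
                        seed = as.integer(seed), matched = matched)
      est$flag <- "insufficient"
    } else {
      est$flag <- if (est$n_nem < 10) "lt10_nem" else ""
    }
    est
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate the matching scheme against dN/dS moments
#'
#' For each candidate `(alpha, X)` the sampler is run `n_cal` times; the
#' sampled non-NEM omega values are pooled and compared with the NEM omega
#' values: variances by the F variance-ratio test, means by the Welch
#' unequal-variance t-test. The chosen candidate minimizes the absolute
#' variance difference among candidates whose variance-comparison p-value
#' exceeds 0.05 (i.e., the "closest dN/dS variance"); if none qualifies
#' the global minimizer is chosen and flagged. Genes with dS = 0 have no
#' omega and are excluded from the diagnostics (with a warning if more
#' than half are).
#'
#' @param records gene-statistics `data.frame`.
#' @param alpha_grid,x_grid candidate grids (defaults cover the calibrated
#'   0.95 / 3).
#' @param n_cal samplings per candidate (>= 100; full calibration uses
#'   1e4).
#' @param seed master integer seed.
#' @param size reference sample size per sampling; defaults to the NEM
#'   count.
#' @return an object of class `calibration_result`: list with `grid` (one
#'   row per candidate: variance/mean diagnostics and p-values), `chosen`
#'   (the selected row), and `fallback` (`TRUE` when no candidate passed
#'   the variance screen).
#' @export
calibrate_matching <- function(records, alpha_grid = c(0.90, 0.95, 1.0),
                               x_grid = c(2L, 3L, 5L), n_cal = 200L,
                               seed = 1L, size = NULL) {
  if (!length(alpha_grid) || !length(x_grid))
    stop("candidate grids must be nonempty", call. = FALSE)
  if (n_cal < 100) stop("n_cal must be >= 100", call. = FALSE)
  nem <- records[records$nem_status == "NEM", , drop = FALSE]
  pool <- records[records$nem_status == "NONNEM", , drop = FALSE]
  if (!nrow(nem) || !nrow(pool))
    stop("both classes must be nonempty", call. = FALSE)
  size <- size %||% nrow(nem)
  dn_target <- mean(nem$dn)
  has_omega <- pool$ds > 0
  if (mean(!has_omega) > 0.5)
    warning("more than 50% of pool genes have dS = 0 and no omega; ",
            "calibration diagnostics are based on the remainder",
            call. = FALSE)
  nem_omega <- nem$omega[nem$ds > 0]
  var_nem <- var(nem_omega)
  mean_nem <- mean(nem_omega)
  cand <- expand.grid(alpha = alpha_grid, x_period = x_grid)
  rows <- lapply(seq_len(nrow(cand)), function(ci) {
    scheme <- matching_scheme(alpha = cand$alpha[ci],
                              x_period = cand$x_period[ci])
    samplings <- lapply(seq_len(n_cal), function(i) {
      set.seed(sub_seed(seed, (ci - 1L) * n_cal + i))
      idx <- matched_sample(pool$dn, scheme, dn_target, size)
      pool$omega[idx][pool$ds[idx] > 0]
    })
    # moments summarize all samplings; the significance tests compare the
    # NEM omegas with one representative sampling (the median-variance
    # one) so the tests run at matched sample size rather than against a
    # pooled vector whose huge df would flag any tiny difference
    v_i <- vapply(samplings, var, numeric(1))
    m_i <- vapply(samplings, mean, numeric(1))
    rep_s <- samplings[[order(v_i)[ceiling(length(v_i) / 2)]]]
    vt <- var.test(nem_omega, rep_s)
    tt <- t.test(nem_omega, rep_s)
    data.frame(alpha = cand$alpha[ci], x_period = cand$x_period[ci],
               var_nem = var_nem, var_nonnem = mean(v_i),
               var_diff = abs(var_nem - mean(v_i)),
               var_p = vt$p.value,
               mean_nem = mean_nem, mean_nonnem = mean(m_i),
               mean_p = tt$p.value)
  })
  grid <- do.call(rbind, rows)
  ok <- grid$var_p > 0.05
  fallback <- !any(ok)
  pickable <- if (fallback) seq_len(nrow(grid)) else which(ok)
  chosen <- pickable[which.min(grid$var_diff[pickable])]
  structure(list(grid = grid, chosen = grid[chosen, , drop = FALSE],
                 fallback = fallback),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration: chose alpha = %g, X = %d (|var diff| = %.3g, var p = %.3g%s)\n",
    x$chosen$alpha, x$chosen$x_period, x$chosen$var_diff, x$chosen$var_p,
    if (x$fallback) "; FALLBACK: no candidate passed the variance screen"
    else ""))
  invisible(x)
}

#' GO-stratified excess of adaptation
#'
#' For each GO category with at least `min_genes` included NEM members,
#' the NEM set is restricted to that category while the full non-NEM pool
#' is kept; the matching target (mean dN) and sample size are recomputed
#' from the restricted set and [quantify_excess()] is run. The `top_k`
#' categories by included-NEM gene count are reported, each with its
#' excess, permutation p, and a Benjamini-Hochberg q-value across the
#' reported categories (raw permutation p-values remain the primary
#' output).
#'
#' @param records,threshold,scheme,n_perm,seed as in [quantify_excess()].
#' @param min_genes minimum included-NEM genes per category (default 20).
#' @param top_k number of categories reported (default 10); fewer if fewer
#'   qualify.
#' @return a `data.frame`, one row per category (`go_term`, `n_nem`,
#'   excess columns, `p_perm`, `q_value`); zero rows (with a message) if
#'   no category qualifies.
#' @export
go_excess <- function(records, threshold = 0.5, scheme = matching_scheme(),
                      n_perm = 1000L, min_genes = 20L, top_k = 10L,
                      seed = 1L) {
  incl <- include_genes(records, threshold)
  nem <- incl[incl$nem_status == "NEM", , drop = FALSE]
  pool <- incl[incl$nem_status == "NONNEM", , drop = FALSE]
  if (!nrow(nem) || !length(unlist(nem$go_terms)))
    stop("no GO terms present on included NEM genes", call. = FALSE)
  counts <- sort(table(unlist(nem$go_terms)), decreasing = TRUE)
  counts <- counts[counts >= min_genes]
  if (!length(counts)) {
    message("go_excess: no GO category reaches min_genes = ", min_genes)
    return(data.frame(go_term = character(0), n_nem = integer(0),
                      excess_pct = numeric(0), ci_low_pct = numeric(0),
                      ci_high_pct = numeric(0), p_perm = numeric(0),
                      q_value = numeric(0)))
  }
  cats <- names(counts)[seq_len(min(top_k, length(counts)))]
  rows <- lapply(seq_along(cats), function(j) {
    cat_j <- cats[j]
    in_cat <- vapply(nem$go_terms, function(g) cat_j %in% g, logical(1))
    sub <- rbind(nem[in_cat, , drop = FALSE], pool)
    est <- quantify_excess(sub, threshold = threshold, scheme = scheme,
                           n_perm = n_perm, seed = sub_seed(seed, j * 131L))
    data.frame(go_term = cat_j, n_nem = est$n_nem, a_nem = est$a_nem,
               ref_mean = est$ref_mean, excess_pct = est$excess_pct,
               ci_low_pct = est$ci_low_pct, ci_high_pct = est$ci_high_pct,
               p_perm = est$p_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_perm, method = "BH")
  rownames(out) <- NULL
  out
}
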