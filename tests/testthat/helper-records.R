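# Shared constructors and independent oracles for the test suite.

# minimal gene-statistics table with the package's column contract
make_records <- function(nem_status, busted_p, dn,
                         ds = rep(1, length(dn)),
                         branch = NULL, go = NULL) {
  n <- length(dn)
  stopifnot(length(nem_status) == n, length(busted_p) == n)
  if (is.null(branch))
    branch <- replicate(n, c(0.1, 0.2, 0.3), simplify = FALSE)
  if (is.null(go))
    go <- replicate(n, character(0), simplify = FALSE)
  data.frame(gene_id = sprintf("u%04d", seq_len(n)),
             nem_status = nem_status, busted_p = busted_p,
             dn = dn, ds = ds,
             omega = ifelse(ds > 0, dn / ds, NA_real_),
             branch_sel_prop = I(branch), go_terms = I(go),
             stringsAsFactors = FALSE)
}

# small HyPhy-style BUSTED result document
busted_json <- function(p, file_name = "geneX.fasta") {
  sprintf(paste0(
    '{"analysis":{"version":"4.5"},',
    '"input":{"file name":"/data/aln/%s","number of sequences":8},',
    '"test results":{"LRT":4.2,"p-value":%.12g},',
    '"unexpected extra field":true}'), file_name, p)
}

# small HyPhy-style aBSREL result document; branches is a named list of
# list(omega = ..., weight = ..., corrected_p = ...)
absrel_json <- function(branches, file_name = "geneY.fasta") {
  br <- vapply(names(branches), function(b) {
    cl <- branches[[b]]
    rd <- paste(mapply(function(o, w) sprintf("[%.12g,%.12g]", o, w),
                       cl$omega, cl$weight), collapse = ",")
    cp <- if (is.null(cl$corrected_p)) ""
          else sprintf(',"Corrected P-value":%.12g', cl$corrected_p)
    sprintf('"%s":{"Rate Distributions":[%s]%s}', b, rd, cp)
  }, character(1))
  sprintf('{"input":{"file name":"/data/aln/%s"},"branch attributes":{"0":{%s}}}',
          file_name, paste(br, collapse = ","))
}

# independent two-sided Fisher p: exhaustive same-margin hypergeometric
# enumeration, summing probabilities no larger than the observed table's
# (with the conventional 1e-7 relative slack for ties)
fisher_p_enum <- function(a, b, c, d) {
  m1 <- a + b; n1 <- c + d; k <- a + c
  x <- max(0, k - n1):min(k, m1)
  pr <- stats::dhyper(x, m1, n1, k)
  p_obs <- stats::dhyper(a, m1, n1, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# brute-force exclusive intersection counts: walk every element of the
# union and tally its exact membership pattern
exclusive_enum <- function(family) {
  sp <- names(family)
  universe <- sort(unique(unlist(family)))
  key <- vapply(universe, function(el)
    paste(sp[vapply(family, function(s) el %in% s, logical(1))],
          collapse = "+"), character(1))
  table(key)
}
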