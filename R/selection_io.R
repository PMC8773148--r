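#' Read a gene-level selection-statistics table
#'
#' The canonical table is UTF-8, tab-separated, "." decimal, no quoting,
#' with header columns `gene_id`, `nem_status`, `busted_p`, `dn`, `ds`,
#' `branch_sel_prop` (semicolon-separated reals) and `go_terms`
#' (pipe-separated, may be empty). Every record is validated: `busted_p`
#' and each branch proportion must lie in `[0, 1]`, `dn`/`ds` must be
#' nonnegative, `nem_status` must be NEM/NONNEM/UNKNOWN, and `gene_id` must
#' be unique. Violations raise errors naming the offending row and column.
#' `omega = dn/ds` is derived (NA when `ds == 0`). Plain and
#' gzip-compressed input are accepted.
#'
#' @param source path to a TSV file (optionally `.gz`).
#' @return a `data.frame` of gene selection records (list columns
#'   `branch_sel_prop`, `go_terms`), row order preserved.
#' @export
read_gene_stats <- function(source) {
  lines <- read_text_maybe_gz(source)
  if (!length(lines)) stop("empty gene-stats file", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("gene_id", "nem_status", "busted_p", "dn", "ds",
                "branch_sel_prop", "go_terms")
  missing <- setdiff(required, header)
  if (length(missing))
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  col <- function(f, name) {
    j <- match(name, header)
    if (length(f) < j) "" else f[[j]]
  }
  num <- function(x, row, name, lo = -Inf, hi = Inf) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) && !identical(toupper(x), "NA"))
      stop(sprintf("row %d: unparsable number in column '%s': '%s'",
                   row, name, x), call. = FALSE)
    if (!is.na(v) && (v < lo || v > hi))
      stop(sprintf("row %d: value %g in column '%s' outside [%g, %g]",
                   row, v, name, lo, hi), call. = FALSE)
    v
  }
  n <- length(fields)
  gene_id <- character(n); nem_status <- character(n)
  busted_p <- numeric(n); dn <- numeric(n); ds <- numeric(n)
  branch <- vector("list", n); go <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    gene_id[i] <- col(f, "gene_id")
    nem_status[i] <- col(f, "nem_status")
    if (!nem_status[i] %in% c("NEM", "NONNEM", "UNKNOWN"))
      stop(sprintf("row %d: invalid value '%s' in column 'nem_status'",
                   i, nem_status[i]), call. = FALSE)
    busted_p[i] <- num(col(f, "busted_p"), i, "busted_p", 0, 1)
    dn[i] <- num(col(f, "dn"), i, "dn", 0)
    ds[i] <- num(col(f, "ds"), i, "ds", 0)
    bs <- col(f, "branch_sel_prop")
    if (!nzchar(bs))
      stop(sprintf("row %d: empty column 'branch_sel_prop'", i),
           call. = FALSE)
    parts <- strsplit(bs, ";", fixed = TRUE)[[1]]
    branch[[i]] <- vapply(parts, num, 0, row = i, name = "branch_sel_prop",
                          lo = 0, hi = 1, USE.NAMES = FALSE)
    gt <- col(f, "go_terms")
    go[[i]] <- if (nzchar(gt)) strsplit(gt, "|", fixed = TRUE)[[1]]
               else character(0)
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop(sprintf("duplicate gene_id in column 'gene_id': %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  data.frame(gene_id = gene_id, nem_status = nem_status,
             busted_p = busted_p, dn = dn, ds = ds,
             omega = ifelse(ds > 0, dn / ds, NA_real_),
             branch_sel_prop = I(branch), go_terms = I(go),
             stringsAsFactors = FALSE)
}

#' Write a gene-statistics table
#'
#' Numbers are written with `%.17g` so that write-then-read is the identity
#' on valid record lists (full double precision survives the round trip).
#'
#' @param records a gene-statistics `data.frame` (see [read_gene_stats()]).
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(records, path) {
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste(c("gene_id", "nem_status", "busted_p", "dn", "ds",
            "branch_sel_prop", "go_terms"), collapse = "\t"),
    vapply(seq_len(nrow(records)), function(i) paste(c(
      records$gene_id[i], records$nem_status[i], fmt(records$busted_p[i]),
      fmt(records$dn[i]), fmt(records$ds[i]),
      paste(fmt(records$branch_sel_prop[[i]]), collapse = ";"),
      paste(records$go_terms[[i]], collapse = "|")), collapse = "\t"),
      character(1)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Extract the gene-wide p-value from a HyPhy BUSTED result
#'
#' BUSTED tests a gene for episodic diversifying selection anywhere in the
#' tree; its JSON result carries one gene-wide p-value under
#' `test results / p-value`. Extra fields are tolerated (HyPhy versions
#' drift), absent ones are an error naming the file.
#'
#' @param source path to a BUSTED JSON file (optionally `.gz`), or a JSON
#'   string.
#' @return a list with `gene_id` (from the input file name recorded in the
#'   document, falling back to the source file name) and `busted_p`.
#' @export
parse_busted_json <- function(source) {
  doc <- read_hyphy_json(source)
  p <- doc[["test results"]][["p-value"]]
  if (is.null(p) || !is.numeric(p))
    stop(sprintf("BUSTED adapter: no 'test results'/'p-value' field in '%s'",
                 json_label(source)), call. = FALSE)
  list(gene_id = hyphy_gene_id(doc, source), busted_p = as.numeric(p))
}

#' Extract per-branch selected-codon proportions from a HyPhy aBSREL result
#'
#' aBSREL fits each branch a small set of omega rate classes with weights;
#' the proportion of selected codons on a branch is the summed weight of
#' classes with omega > 1 in the maximum-likelihood distribution
#' (`Rate Distributions` under `branch attributes`). All branches are
#' reported regardless of the branch's own test significance, matching the
#' convention of averaging proportions along all branches; set
#' `corrected_p_cutoff` to zero out branches whose corrected p-value exceeds
#' the cutoff instead.
#'
#' @param source path to an aBSREL JSON file (optionally `.gz`), or a JSON
#'   string.
#' @param corrected_p_cutoff optional significance cutoff; `NULL` (default)
#'   keeps every branch's proportion.
#' @return a list with `gene_id` and `branch_sel_prop`, a named numeric
#'   vector ordered by branch name.
#' @export
parse_absrel_json <- function(source, corrected_p_cutoff = NULL) {
  doc <- read_hyphy_json(source)
  ba <- doc[["branch attributes"]][["0"]]
  if (is.null(ba))
    stop(sprintf("aBSREL adapter: no 'branch attributes' in '%s'",
                 json_label(source)), call. = FALSE)
  branches <- sort(names(ba))
  prop <- vapply(branches, function(b) {
    rd <- ba[[b]][["Rate Distributions"]]
    if (is.null(rd))
      stop(sprintf("aBSREL adapter: branch '%s' lacks 'Rate Distributions' in '%s'",
                   b, json_label(source)), call. = FALSE)
    omega <- vapply(rd, function(cl) as.numeric(cl[[1]]), 0)
    w <- vapply(rd, function(cl) as.numeric(cl[[2]]), 0)
    if (abs(sum(w) - 1) > 1e-6)
      stop(sprintf("aBSREL adapter: rate-class weights on branch '%s' sum to %g, not 1",
                   b, sum(w)), call. = FALSE)
    p <- sum(w[omega > 1])
    if (!is.null(corrected_p_cutoff)) {
      cp <- ba[[b]][["Corrected P-value"]]
      if (!is.null(cp) && as.numeric(cp) > corrected_p_cutoff) p <- 0
    }
    p
  }, 0)
  list(gene_id = hyphy_gene_id(doc, source), branch_sel_prop = prop)
}

read_hyphy_json <- function(source) {
  txt <- if (length(source) == 1 && !grepl("[{\n]", source) &&
             file.exists(source)) {
    paste(read_text_maybe_gz(source), collapse = "\n")
  } else source
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed HyPhy JSON in '%s': %s",
                                 json_label(source), conditionMessage(e)),
                         call. = FALSE))
  doc
}

json_label <- function(source) {
  if (length(source) == 1 && !grepl("[{\n]", source)) source else "<json text>"
}

hyphy_gene_id <- function(doc, source) {
  fn <- doc[["input"]][["file name"]]
  if (is.null(fn)) fn <- json_label(source)
  sub("\\.[A-Za-z0-9.]*$", "", basename(as.character(fn)))
}
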