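#' Classify genes as NEM or non-NEM from similarity evidence
#'
#' A gene is a nematocyst protein (NEM) if its best e-value against the
#' nematocyst-proteome repertory is at or below the cutoff; genes absent
#' from the similarity table are non-NEMs. Classification is monotone in
#' the cutoff: raising it never removes a gene from the NEM class.
#'
#' @param similarity `data.frame` with columns `gene_id`, `best_evalue`
#'   (strictly positive); one row per gene with a hit.
#' @param evalue_cutoff positive e-value cutoff (default 1e-5; similarity
#'   searches in this context conventionally use 1e-5, and the cutoff is
#'   deliberately configurable).
#' @param gene_ids universe of genes to classify; defaults to the genes in
#'   the table (in which case no NONNEM-by-absence can arise).
#' @return a named character vector over `gene_ids` with values `"NEM"` or
#'   `"NONNEM"`.
#' @export
classify_genes <- function(similarity, evalue_cutoff = 1e-5,
                           gene_ids = similarity$gene_id) {
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be > 0", call. = FALSE)
  if (any(similarity$best_evalue <= 0))
    stop("e-values must be > 0", call. = FALSE)
  dup <- similarity$gene_id[duplicated(similarity$gene_id)]
  if (length(dup))
    stop(sprintf("duplicate gene_id in similarity table: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  ev <- setNames(similarity$best_evalue, similarity$gene_id)[gene_ids]
  out <- ifelse(!is.na(ev) & ev <= evalue_cutoff, "NEM", "NONNEM")
  setNames(out, gene_ids)
}

#' Apply a similarity-based classification to a gene-statistics table
#'
#' @param records gene-statistics `data.frame`.
#' @param similarity,evalue_cutoff see [classify_genes()].
#' @return `records` with `nem_status` replaced by the classification.
#' @export
classify_records <- function(records, similarity, evalue_cutoff = 1e-5) {
  records$nem_status <- unname(
    classify_genes(similarity, evalue_cutoff, gene_ids = records$gene_id))
  records
}

#' Ortholog-group core set
#'
#' The core set is the intersection of all per-species ortholog-group sets:
#' groups present in every compared nematocyst proteome.
#'
#' @param family named list: species id -> character vector of ortholog
#'   group ids.
#' @return character vector of ortholog-group ids shared by all species.
#' @export
core_set <- function(family) {
  validate_family(family, min_species = 2)
  sort(Reduce(intersect, family))
}

#' Exclusive intersection profile of ortholog sets (UpSet semantics)
#'
#' Assigns each element of the union to exactly one species subset (the
#' subset of species whose sets contain it) and counts elements per subset,
#' for all nonempty subsets. Because the prose convention for "shared"
#' counts is ambiguous between exclusive regions and total overlaps, the
#' pairwise total-overlap matrix (Venn semantics) is reported alongside.
#'
#' @param family named list: species id -> character vector of ortholog
#'   group ids; 2 to 16 species.
#' @param keep_members if `TRUE`, also return the element lists per subset.
#' @return an object of class `intersection_profile`: list with `exclusive`
#'   (named integer vector over all nonempty subsets, names like `"A+B"`),
#'   `pairwise` (matrix of total overlaps `|Si n Sj|`), `union_size`, and
#'   optionally `members`.
#' @export
intersection_profile <- function(family, keep_members = FALSE) {
  validate_family(family, min_species = 2)
  k <- length(family)
  if (k > 16)
    stop("more than 16 species: restrict the family to a subset of interest",
         call. = FALSE)
  sp <- names(family)
  universe <- sort(unique(unlist(family)))
  memb <- vapply(family, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, sp))
  key <- apply(memb, 1, function(r) paste(sp[r], collapse = "+"))
  all_subsets <- unlist(lapply(seq_len(2^k - 1), function(mask) {
    paste(sp[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0],
          collapse = "+")
  }))
  exclusive <- setNames(integer(length(all_subsets)), all_subsets)
  tab <- table(key)
  exclusive[names(tab)] <- as.integer(tab)
  pairwise <- crossprod(memb)
  out <- list(exclusive = exclusive, pairwise = pairwise,
              union_size = length(universe))
  if (keep_members)
    out$members <- split(universe, factor(key, levels = all_subsets))
  structure(out, class = "intersection_profile")
}

#' @export
print.intersection_profile <- function(x, ...) {
  cat(sprintf("intersection profile: %d species, union %d elements\n",
              nrow(x$pairwise), x$union_size))
  nz <- x$exclusive[x$exclusive > 0]
  print(nz[order(-nz)])
  invisible(x)
}

validate_family <- function(family, min_species = 2) {
  if (!length(family)) stop("empty ortholog family", call. = FALSE)
  if (is.null(names(family)) || anyDuplicated(names(family)) ||
      any(!nzchar(names(family))))
    stop("family must be a named list with unique species ids",
         call. = FALSE)
  if (length(family) < min_species)
    stop(sprintf("need at least %d species", min_species), call. = FALSE)
  invisible(family)
}

#' Read an ortholog family from a two-column TSV
#'
#' @param source TSV (optionally `.gz`) with header columns `species_id`,
#'   `og_id`.
#' @return named list: species id -> character vector of ortholog-group ids.
#' @export
read_ortholog_family <- function(source) {
  lines <- read_text_maybe_gz(source)
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   colClasses = "character")
  if (!all(c("species_id", "og_id") %in% names(df)))
    stop("family TSV needs columns species_id, og_id", call. = FALSE)
  lapply(split(df$og_id, df$species_id), unique)
}
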