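#' Configuration for the synthetic gene-statistics generator
#'
#' Defines the study conditions under which gene-level selection statistics
#' are simulated: group sizes, gamma-distributed dN and dS, a three-class
#' selection-evidence mixture (null / moderate / strong), label-specific
#' multiplicative effects on the per-gene adaptation level, multiplicative
#' lognormal noise, and multi-label GO assignment.
#'
#' Per gene the adaptation level is \eqn{\mu = \kappa\, dN \cdot
#' e(\mathrm{label}, z) \cdot \mathrm{LogNormal}(0, \sigma)} for genes in the
#' moderate/strong classes and 0 for null-class genes, where the effect
#' \eqn{e} is 1 for non-NEMs and `effect_moderate`/`effect_strong` for NEMs.
#' Adaptation is linear in dN by construction, so constraining a sample's
#' mean dN removes the label-dN confound (the point of the matched sampler).
#'
#' @param n_nem number of NEM genes (default 1500).
#' @param n_nonnem number of non-NEM genes (default 15000).
#' @param n_branches branches per gene; default 13 = 2*8 - 3 for an 8-taxon
#'   unrooted tree.
#' @param class_probs length-3 probabilities (null, moderate, strong) of the
#'   selection-evidence classes; must sum to 1 within 1e-12.
#' @param class_probs_nem optional separate class probabilities for NEM
#'   genes; `NULL` (default) reuses `class_probs`, making selection evidence
#'   independent of the NEM label.
#' @param dn_shape,dn_scale_nem,dn_scale_nonnem gamma parameters for dN.
#' @param ds_shape,ds_scale gamma parameters for dS.
#' @param kappa baseline adaptation per unit dN.
#' @param effect_moderate,effect_strong NEM/non-NEM adaptation ratios for
#'   moderate- and strong-evidence genes.
#' @param noise_sigma lognormal sd of per-gene adaptation noise.
#' @param n_go_categories,go_terms_per_gene GO assignment parameters.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [scenario_preset()], [generate_gene_stats()]
#' @export
synthetic_config <- function(n_nem = 1500L, n_nonnem = 15000L,
                             n_branches = 13L,
                             class_probs = c(null = 0.5, moderate = 0.4,
                                             strong = 0.1),
                             class_probs_nem = NULL,
                             dn_shape = 2, dn_scale_nem = 0.025,
                             dn_scale_nonnem = 0.025,
                             ds_shape = 4, ds_scale = 0.25,
                             kappa = 0.2,
                             effect_moderate = 1.5, effect_strong = 1.6,
                             noise_sigma = 0.5,
                             n_go_categories = 15L, go_terms_per_gene = 2L,
                             seed = 1L) {
  cfg <- list(n_nem = as.integer(n_nem), n_nonnem = as.integer(n_nonnem),
              n_branches = as.integer(n_branches),
              class_probs = as.numeric(class_probs),
              class_probs_nem = if (is.null(class_probs_nem)) NULL else
                as.numeric(class_probs_nem),
              dn_shape = dn_shape, dn_scale_nem = dn_scale_nem,
              dn_scale_nonnem = dn_scale_nonnem,
              ds_shape = ds_shape, ds_scale = ds_scale,
              kappa = kappa, effect_moderate = effect_moderate,
              effect_strong = effect_strong, noise_sigma = noise_sigma,
              n_go_categories = as.integer(n_go_categories),
              go_terms_per_gene = as.integer(go_terms_per_gene),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  counts <- c(cfg$n_nem, cfg$n_nonnem, cfg$n_branches, cfg$n_go_categories,
              cfg$go_terms_per_gene)
  stopifnot_msg(all(counts > 0), "all counts must be > 0")
  for (p in list(cfg$class_probs, cfg$class_probs_nem)) {
    if (is.null(p)) next
    stopifnot_msg(length(p) == 3 && all(p >= 0) && all(p <= 1),
                  "class probabilities must be 3 values in [0,1]")
    stopifnot_msg(abs(sum(p) - 1) <= 1e-12,
                  "class probabilities must sum to 1 within 1e-12")
  }
  stopifnot_msg(cfg$effect_moderate > 0 && cfg$effect_strong > 0,
                "effect ratios must be > 0")
  stopifnot_msg(all(c(cfg$dn_shape, cfg$dn_scale_nem, cfg$dn_scale_nonnem,
                      cfg$ds_shape, cfg$ds_scale) > 0),
                "gamma parameters must be > 0")
  stopifnot_msg(cfg$kappa >= 0 && cfg$noise_sigma >= 0,
                "kappa and noise_sigma must be >= 0")
  stopifnot_msg(cfg$go_terms_per_gene <= cfg$n_go_categories,
                "go_terms_per_gene cannot exceed n_go_categories")
  invisible(cfg)
}

#' Named scenario presets for the synthetic generator
#'
#' * `headline`: the default regime — NEM effect ratios 1.5 (moderate
#'   evidence) and 1.6 (strong evidence) over non-NEMs, identical dN
#'   distributions in both groups.
#' * `strong_only`: no moderate-evidence class; classes (0.6, 0, 0.4).
#' * `null`: effect ratios forced to 1 (no group difference in adaptation).
#' * `confounded_null`: effect ratios 1 but NEM dN scale 1.4x the non-NEM
#'   scale — a pure label-dN confound that naive (unmatched) contrasts
#'   mistake for adaptation excess and dN-matching removes.
#'
#' @param name one of `"headline"`, `"strong_only"`, `"null"`,
#'   `"confounded_null"`.
#' @param ... further overrides passed to [synthetic_config()]; explicit
#'   arguments win over the preset.
#' @return a `synthetic_config`.
#' @export
scenario_preset <- function(name = c("headline", "strong_only", "null",
                                     "confounded_null"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    headline = list(effect_moderate = 1.5, effect_strong = 1.6),
    strong_only = list(class_probs = c(0.6, 0, 0.4),
                       effect_moderate = 1, effect_strong = 1.6),
    null = list(effect_moderate = 1, effect_strong = 1),
    confounded_null = list(effect_moderate = 1, effect_strong = 1,
                           dn_scale_nem = 0.035, dn_scale_nonnem = 0.025))
  args <- modifyList(preset, list(...))
  do.call(synthetic_config, args)
}

#' Generate a synthetic gene-level selection-statistics table
#'
#' Produces one row per ortholog with NEM label, BUSTED-style p-value,
#' per-branch selected-codon proportions, dN, dS, omega and GO terms.
#' Group sizes are realized exactly (labels shuffled, counts fixed).
#' BUSTED p-values are Uniform(0,1) for null-class genes, Uniform(0, 0.05)
#' for moderate and Uniform(0, 1e-6) for strong — only their threshold
#' behaviour matters downstream. The per-gene adaptation level mu is spread
#' over `m = min(1 + Poisson(1), n_branches)` randomly placed branches, each
#' receiving `min(1, mu * n_branches / m)` so that the per-gene branch mean
#' equals mu unless a branch saturates at 1.
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` with columns `gene_id`, `nem_status`, `busted_p`,
#'   `dn`, `ds`, `omega`, and list columns `branch_sel_prop`, `go_terms`;
#'   the selection class is kept in a `sim_class` column for ground-truth
#'   checks.
#' @export
generate_gene_stats <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_nem + config$n_nonnem
  status <- sample(rep(c("NEM", "NONNEM"), c(config$n_nem, config$n_nonnem)))
  is_nem <- status == "NEM"

  dn <- rgamma(n, shape = config$dn_shape,
               scale = ifelse(is_nem, config$dn_scale_nem,
                              config$dn_scale_nonnem))
  ds <- rgamma(n, shape = config$ds_shape, scale = config$ds_scale)

  cp_nem <- config$class_probs_nem %||% config$class_probs
  z <- integer(n)
  z[is_nem] <- sample.int(3L, sum(is_nem), replace = TRUE, prob = cp_nem)
  z[!is_nem] <- sample.int(3L, sum(!is_nem), replace = TRUE,
                           prob = config$class_probs)
  sim_class <- c("null", "moderate", "strong")[z]

  busted_p <- runif(n) * c(1, 0.05, 1e-6)[z]

  eff <- rep(1, n)
  eff[is_nem & z == 2L] <- config$effect_moderate
  eff[is_nem & z == 3L] <- config$effect_strong
  noise <- rlnorm(n, 0, config$noise_sigma)
  mu <- ifelse(z == 1L, 0, config$kappa * dn * eff * noise)

  nb <- config$n_branches
  m <- pmin(1L + rpois(n, 1), nb)
  val <- pmin(1, mu * nb / m)
  branch_sel_prop <- mapply(function(mi, vi) {
    x <- numeric(nb)
    x[sample.int(nb, mi)] <- vi
    x
  }, m, val, SIMPLIFY = FALSE)
  n_sat <- sum(mu * nb / m > 1)
  if (n_sat / n > 0.01)
    warning(sprintf(
      "%.1f%% of genes have saturated branch proportions (capped at 1); %s",
      100 * n_sat / n, "group contrasts will be attenuated"), call. = FALSE)

  go_pool <- sprintf("GO:SYN%04d", seq_len(config$n_go_categories))
  go_terms <- replicate(n,
    go_pool[sample.int(config$n_go_categories, config$go_terms_per_gene)],
    simplify = FALSE)

  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             nem_status = status, busted_p = busted_p,
             dn = dn, ds = ds,
             omega = ifelse(ds > 0, dn / ds, NA_real_),
             branch_sel_prop = I(branch_sel_prop),
             go_terms = I(go_terms),
             sim_class = sim_class,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic similarity (best-hit) table
#'
#' Emulates blasting gene models against a nematocyst-proteome repertory:
#' true NEM genes receive a strong best hit (e-value <= 1e-10) with
#' probability `hit_rate_nem`; non-NEM genes receive a weak spurious hit
#' (e-value >= 1e-3) with probability `false_hit_rate`, and are otherwise
#' absent from the table.
#'
#' @param records a gene-statistics table with `gene_id` and `nem_status`.
#' @param hit_rate_nem,false_hit_rate probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return a `data.frame` with columns `gene_id`, `best_evalue`, one row per
#'   gene with a hit.
#' @export
generate_similarity_table <- function(records, hit_rate_nem = 0.9,
                                      false_hit_rate = 0.05, seed = 1L) {
  if (hit_rate_nem < 0 || hit_rate_nem > 1 ||
      false_hit_rate < 0 || false_hit_rate > 1)
    stop("hit rates must be probabilities in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  is_nem <- records$nem_status == "NEM"
  hit <- runif(nrow(records)) < ifelse(is_nem, hit_rate_nem, false_hit_rate)
  ev <- ifelse(is_nem, 10^-runif(nrow(records), 10, 50),
               10^-runif(nrow(records), 0, 3))
  data.frame(gene_id = records$gene_id[hit], best_evalue = ev[hit],
             stringsAsFactors = FALSE)
}

#' Generate a paired nematocyst/organismal chronogram with a known lag
#'
#' Builds a random ultrametric organismal tree whose internal node ages are
#' evenly spaced ranks up to `root_age - lag`, then an identical-topology
#' nematocyst tree whose every internal node age is shifted `+lag` (plus an
#' optional per-node jitter). The even rank spacing guarantees any jitter
#' smaller than half the rank gap cannot violate parent/child age ordering.
#'
#' @param n_taxa number of tips (>= 3).
#' @param lag constructed age offset, My (nematocyst node minus organismal
#'   node).
#' @param root_age nematocyst-tree root age, My; must exceed `lag`.
#' @param seed integer seed.
#' @param jitter half-width of a uniform per-node perturbation on the
#'   nematocyst ages, My; must be < half the internal rank gap.
#' @return a list with `nem_tree` and `org_tree` (class [chronogram]) and a
#'   `clade_map` data.frame (clade label, leaf sets for both trees, and the
#'   realized `true_lag` per clade for bookkeeping).
#' @export
generate_paired_chronograms <- function(n_taxa = 8L, lag = 40,
                                        root_age = 740, seed = 1L,
                                        jitter = 0) {
  if (n_taxa < 3) stop("n_taxa must be >= 3", call. = FALSE)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  if (root_age <= lag) stop("root_age must exceed lag", call. = FALSE)
  set.seed(as.integer(seed))
  n_int <- n_taxa - 1L
  gap <- (root_age - lag) / n_int
  if (jitter < 0 || 2 * jitter >= gap)
    stop(sprintf("jitter must be in [0, %.3f) for this tree size", gap / 2),
         call. = FALSE)

  topo <- ape::rcoal(n_taxa, tip.label = sprintf("t%d", seq_len(n_taxa)))
  ages0 <- chronogram_node_ages(topo)
  int_nodes <- (n_taxa + 1L):(n_taxa + n_int)
  # rank-remap coalescent ages to an even grid; preserves parent > child
  rank_age <- rank(ages0[int_nodes], ties.method = "first") * gap
  ages_b <- numeric(n_taxa + n_int)
  ages_b[int_nodes] <- rank_age
  jit <- runif(n_int, -jitter, jitter)
  ages_a <- ages_b
  ages_a[int_nodes] <- ages_b[int_nodes] + lag + jit

  org_tree <- chronogram(set_node_ages(topo, ages_b))
  nem_tree <- chronogram(set_node_ages(topo, ages_a))

  leafsets <- lapply(int_nodes, function(nd)
    sort(topo$tip.label[unlist(phangorn_free_desc(topo, nd))]))
  clade_map <- data.frame(
    clade = sprintf("c%02d", seq_len(n_int)),
    leaves_a = vapply(leafsets, paste, "", collapse = ","),
    leaves_b = vapply(leafsets, paste, "", collapse = ","),
    true_lag = lag + jit,
    stringsAsFactors = FALSE)
  list(nem_tree = nem_tree, org_tree = org_tree, clade_map = clade_map)
}

# tip indices descending from an internal node (simple stack traversal;
# avoids pulling in a whole-tree descendants dependency)
phangorn_free_desc <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, ch[ch <= n_tip])
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}

# rewrite a phylo's edge lengths from a vector of node ages (tips at 0)
set_node_ages <- function(phy, ages) {
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(phy$edge.length < 0))
    stop("node ages violate parent >= child ordering", call. = FALSE)
  phy
}
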