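test_that("gene-stats write then read is the identity", {
  recs <- generate_gene_stats(synthetic_config(n_nem = 40L, n_nonnem = 160L,
                                               seed = 9L))
  recs$sim_class <- NULL  # ground-truth column is not part of the format
  path <- tempfile(fileext = ".tsv")
  write_gene_stats(recs, path)
  back <- read_gene_stats(path)
  expect_equal(back$gene_id, recs$gene_id)
  expect_equal(back$nem_status, recs$nem_status)
  expect_equal(back$busted_p, recs$busted_p, tolerance = 0)
  expect_equal(back$dn, recs$dn, tolerance = 0)
  expect_equal(back$ds, recs$ds, tolerance = 0)
  expect_equal(unclass(back$branch_sel_prop),
               unname(unclass(recs$branch_sel_prop)), tolerance = 0)
  expect_equal(unclass(back$go_terms), unname(unclass(recs$go_terms)))
})

test_that("gzip-compressed gene-stats round trip", {
  recs <- make_records(c("NEM", "NONNEM"), c(0.01, 0.2), c(0.05, 0.04),
                       go = list("GO:1|weird", character(0)))
  recs$go_terms <- I(list(c("GO:1", "GO:2"), character(0)))
  path <- tempfile(fileext = ".tsv.gz")
  write_gene_stats(recs, path)
  back <- read_gene_stats(path)
  expect_equal(back$dn, recs$dn, tolerance = 0)
  expect_equal(back$go_terms[[1]], c("GO:1", "GO:2"))
  expect_equal(back$go_terms[[2]], character(0))
})

test_that("malformed gene-stats tables fail naming row and column", {
  write_tsv <- function(lines) {
    p <- tempfile(fileext = ".tsv")
    writeLines(lines, p)
    p
  }
  hdr <- "gene_id\tnem_status\tbusted_p\tdn\tds\tbranch_sel_prop\tgo_terms"
  ok <- "g1\tNEM\t0.01\t0.05\t1\t0.1;0.2\tGO:1"
  expect_error(read_gene_stats(write_tsv(c(
    "gene_id\tnem_status\tbusted_p", "g1\tNEM\t0.1"))),
    "missing required column")
  expect_error(read_gene_stats(write_tsv(c(
    hdr, ok, "g2\tNEM\t1.5\t0.05\t1\t0.1\t"))),
    "row 2.*busted_p")
  expect_error(read_gene_stats(write_tsv(c(
    hdr, ok, "g2\tNEM\tabc\t0.05\t1\t0.1\t"))),
    "row 2.*unparsable.*busted_p")
  expect_error(read_gene_stats(write_tsv(c(
    hdr, "g1\tMAYBE\t0.1\t0.05\t1\t0.1\t"))),
    "row 1.*nem_status")
  expect_error(read_gene_stats(write_tsv(c(
    hdr, "g1\tNEM\t0.1\t-0.05\t1\t0.1\t"))),
    "row 1.*dn")
  expect_error(read_gene_stats(write_tsv(c(
    hdr, "g1\tNEM\t0.1\t0.05\t1\t0.1;1.4\t"))),
    "row 1.*branch_sel_prop")
  expect_error(read_gene_stats(write_tsv(c(
    hdr, "g1\tNEM\t0.1\t0.05\t1\t\t"))),
    "row 1.*branch_sel_prop")
  expect_error(read_gene_stats(write_tsv(c(hdr, ok, ok))),
    "duplicate gene_id")
})

test_that("BUSTED JSON adapter extracts the gene-wide p-value", {
  res <- parse_busted_json(busted_json(0.007, "astacin.fasta"))
  expect_equal(res$busted_p, 0.007)
  expect_equal(res$gene_id, "astacin")
  expect_error(parse_busted_json('{"input":{"file name":"x.fa"}}'),
               "p-value")
  expect_error(parse_busted_json("{not json"), "malformed")
  # file input (also gzipped) works
  path <- tempfile(fileext = ".json")
  writeLines(busted_json(0.03, "toxin.fasta"), path)
  expect_equal(parse_busted_json(path)$busted_p, 0.03)
})

test_that("aBSREL adapter sums the selected rate-class weights per branch", {
  doc <- absrel_json(list(
    nodeB = list(omega = c(0.2, 4.0), weight = c(0.9, 0.1),
                 corrected_p = 0.001),
    nodeA = list(omega = c(0.5, 1.0), weight = c(0.7, 0.3),
                 corrected_p = 0.8),
    nodeC = list(omega = c(0.1, 2.0, 8.0), weight = c(0.5, 0.3, 0.2),
                 corrected_p = 0.2)))
  res <- parse_absrel_json(doc)
  # branches ordered by name; omega > 1 classes only
  expect_equal(names(res$branch_sel_prop), c("nodeA", "nodeB", "nodeC"))
  expect_equal(unname(res$branch_sel_prop), c(0, 0.1, 0.5))
  expect_true(all(res$branch_sel_prop >= 0 & res$branch_sel_prop <= 1))
  # optional significance gating zeroes non-significant branches
  gated <- parse_absrel_json(doc, corrected_p_cutoff = 0.05)
  expect_equal(unname(gated$branch_sel_prop), c(0, 0.1, 0))
  # weights must sum to 1
  bad <- absrel_json(list(n1 = list(omega = c(0.5, 2), weight = c(0.5, 0.2))))
  expect_error(parse_absrel_json(bad), "sum to")
  expect_error(parse_absrel_json('{"analysis":{}}'), "branch attributes")
})

test_that("dated Newick reading enforces ultrametricity", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:10,B:12):5,C:15);", path)
  expect_error(read_dated_newick(path), "ultrametric")
  writeLines("((A:10,B:10):5,C:15);", path)
  ch <- read_dated_newick(path)
  expect_equal(ch$root_age, 15)
  expect_equal(node_age(ch, c("A", "B")), 10)
})

test_that("chronogram Newick round trip preserves node ages", {
  pair <- generate_paired_chronograms(n_taxa = 10L, lag = 44, root_age = 600,
                                      seed = 4L, jitter = 10)
  path <- tempfile(fileext = ".nwk")
  write_dated_newick(pair$nem_tree, path)
  back <- read_dated_newick(path)
  # same labels, same MRCA ages
  for (i in seq_len(nrow(pair$clade_map))) {
    leaves <- strsplit(pair$clade_map$leaves_a[i], ",")[[1]]
    expect_equal(node_age(back, leaves), node_age(pair$nem_tree, leaves),
                 tolerance = 1e-9)
  }
})
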