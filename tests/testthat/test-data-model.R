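test_that("count tables read, validate and round-trip through TSV", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(toy_counts(), tsv)
  tb <- read_count_table(tsv, "tsv")
  expect_equal(sample_depths(tb)$tau, c(7, 4))

  rt <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tb, rt)
  expect_identical(
    as.data.frame(read_count_table(rt, "tsv")),
    as.data.frame(tb))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_count_table(empty, "tsv"))

  dup <- toy_counts()
  dup$taxon_id[2] <- "t1"
  expect_error(validate_counts(dup), "t1")
  neg <- toy_counts(); neg$s1[1] <- -1
  expect_error(validate_counts(neg), "invalid count")
  frac <- toy_counts(); frac$s1[1] <- 0.5
  expect_error(validate_counts(frac), "invalid count")
})

test_that("taxonomy parsing handles QIIME strings, blanks and extra ranks", {
  tax <- parse_taxonomy(tibble::tibble(
    taxon_id = "t1",
    lineage = "k__Bacteria;p__Proteobacteria;c__;o__;f__;g__Pseudomonas"))
  expect_equal(tax$class, "unassigned")
  expect_equal(tax$genus, "Pseudomonas")

  tax2 <- parse_taxonomy(toy_taxonomy())
  expect_equal(tax2$genus, c("Pseudomonas", "Pseudomonas", "Lactobacillus"))

  expect_message(
    tax7 <- parse_taxonomy(tibble::tibble(
      taxon_id = "t1",
      lineage = "k__Bacteria;p__P;c__C;o__O;f__F;g__G;s__species")),
    "beyond genus")
  expect_false("species" %in% names(tax7))
  expect_equal(tax7$genus, "G")

  rc <- parse_taxonomy(tibble::tibble(
    taxon_id = "t1", kingdom = "Bacteria", phylum = "P", class = "C",
    order = "O", family = "F", genus = ""), dialect = "rank_columns")
  expect_equal(rc$genus, "unassigned")
})

test_that("strict vs lenient taxonomy alignment", {
  tb <- toy_counts()
  tax <- parse_taxonomy(toy_taxonomy())[1:2, ]
  expect_error(align_taxonomy(tb, tax, strict = TRUE), "t3")
  expect_message(lax <- align_taxonomy(tb, tax, strict = FALSE), "all-unassigned")
  expect_equal(lax$genus[3], "unassigned")
})

test_that("genus aggregation computes n, y, tau, n_plus and conserves depth", {
  agg <- aggregate_by_rank(toy_counts(), parse_taxonomy(toy_taxonomy()))
  ps <- agg[agg$group == "Pseudomonas", ]
  expect_equal(ps$n, c(2, 1))
  expect_equal(ps$y, c(7, 1))
  expect_equal(unique(agg$tau[agg$sample == "s1"]), 7)
  expect_equal(unique(agg$n_plus[agg$sample == "s1"]), 2)
  # conservation: groups partition taxa
  tot <- tapply(agg$y, agg$sample, sum)
  expect_equal(as.numeric(tot[c("s1", "s2")]), c(7, 4))
})

test_that("unassigned taxa pool per parent family and conserve depth; drop mode removes them", {
  tax <- parse_taxonomy(tibble::tibble(
    taxon_id = c("t1", "t2", "t3"),
    lineage = c("k__B;p__P;c__C;o__O;f__Fam1;g__",
                "k__B;p__P;c__C;o__O;f__Fam1;g__",
                "k__B;p__P;c__C;o__O;f__Fam2;g__G2")))
  agg <- aggregate_by_rank(toy_counts(), tax)
  expect_true("unassigned@Fam1" %in% agg$group)
  expect_equal(as.numeric(tapply(agg$y, agg$sample, sum)[c("s1", "s2")]), c(7, 4))
  dropped <- aggregate_by_rank(toy_counts(), tax, unassigned = "drop")
  expect_false(any(grepl("^unassigned@", dropped$group)))
  expect_equal(unique(dropped$tau), c(7, 4))  # tau frozen from full table
})

test_that("aggregating a one-taxon-per-genus table gives indicator richness", {
  tb <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(3, 0), s2 = c(2, 9))
  tax <- tibble::tibble(taxon_id = c("a", "b"),
                        lineage = c("k__K;p__P;c__C;o__O;f__F;g__GA",
                                    "k__K;p__P;c__C;o__O;f__F;g__GB"))
  agg <- aggregate_by_rank(tb, parse_taxonomy(tax))
  expect_true(all(agg$n %in% c(0L, 1L)))
  expect_true(all((agg$n == 0) == (agg$y == 0)))
})

test_that("zero-depth samples are flagged but kept", {
  tb <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(0, 0), s2 = c(2, 9))
  tax <- parse_taxonomy(tibble::tibble(
    taxon_id = c("a", "b"),
    lineage = rep("k__K;p__P;c__C;o__O;f__F;g__G", 2)))
  expect_message(agg <- aggregate_by_rank(tb, tax), "zero depth")
  expect_equal(agg$y[agg$sample == "s1"], 0)
})

test_that("design matrices use treatment coding with lexicographic reference", {
  d <- two_group_design(2)
  X <- design_matrix(d)
  expect_equal(colnames(X), c("(Intercept)", "groupB"))
  expect_equal(unname(X[, "groupB"]), c(0, 0, 1, 1))
  Xr <- design_matrix(d, ref = list(group = "B"))
  expect_equal(colnames(Xr)[2], "groupA")
  d$flat <- 1
  expect_error(design_matrix(d), "rank deficient")
})

test_that("BIOM-JSON input matches the TSV reader", {
  skip_if_not_installed("biomformat")
  m <- matrix(c(5, 0, 2, 1, 0, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m), f)
  tb <- read_count_table(f, "biom")
  expect_identical(as.data.frame(tb), as.data.frame(toy_counts()))
})
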