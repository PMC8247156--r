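test_that("specific-activity conversion equals 0.06 * SA * MW", {
  expect_equal(sa_to_kcat(1, 50000), 3000)
  expect_equal(sa_to_kcat(10, 100000), 60000)
  set.seed(2)
  sa <- runif(500, 1e-4, 1e3); mw <- runif(500, 5e3, 5e6)
  expect_equal(sa_to_kcat(sa, mw), 0.06 * sa * mw, tolerance = 1e-12)
  expect_error(sa_to_kcat(-1, 100), "positive")
  expect_error(sa_to_kcat(1, 0), "positive")
})

ktab <- function(...) as_kcat_table(rbind(...))
krow <- function(protein = "P", reaction = "r1", kcat = NA, sa = NA, mw = 5e4,
                 source = "s")
  data.frame(protein = protein, reaction = reaction, kcat_per_h = kcat,
             sa = sa, mw_da = mw, source = source, stringsAsFactors = FALSE)

test_that("kcat selection: max of direct kcats, SA only as fallback", {
  t1 <- ktab(krow(kcat = 9.70), krow(kcat = 12.0))
  expect_equal(select_kcat(t1, "P", "r1")$kcat, 12.0)
  expect_identical(select_kcat(t1, "P", "r1")$rule, "BRENDA-max")
  t2 <- ktab(krow(sa = 2))
  expect_equal(select_kcat(t2, "P", "r1")$kcat, sa_to_kcat(2, 5e4))
  expect_identical(select_kcat(t2, "P", "r1")$rule, "SA-derived")
  expect_null(select_kcat(t1, "P", "r9"))
  expect_null(select_kcat(t1, "Q", "r1"))
})

test_that("direct kcats beat SA conversions in every record ordering", {
  # the SA record converts to 6000 1/h, far above both direct kcats; the
  # rule must still prefer the direct maximum (enumerate all 6 orderings)
  rows <- list(krow(kcat = 5), krow(kcat = 9), krow(sa = 2))
  for (ord in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))) {
    tab <- as_kcat_table(do.call(rbind, rows[ord]))
    expect_equal(select_kcat(tab, "P", "r1")$kcat, 9)
  }
})

test_that("reaction-specific records beat wildcard records", {
  tab <- ktab(krow(reaction = "*", kcat = 1000), krow(reaction = "r1", kcat = 10))
  expect_equal(select_kcat(tab, "P", "r1")$kcat, 10)
  expect_equal(select_kcat(tab, "P", "r2")$kcat, 1000)  # wildcard applies
})

arow <- function(protein = "P", abundance, taxon = "t", rank)
  data.frame(protein = protein, abundance = abundance, unit = "mmol_gDW",
             taxon = taxon, rank = rank, stringsAsFactors = FALSE)

test_that("abundance matching is greedy by taxonomic rank", {
  tab <- as_abundance_table(rbind(arow(abundance = 3, rank = "species"),
                                  arow(abundance = 7, rank = "species"),
                                  arow(abundance = 9, rank = "class")))
  hit <- match_abundance(tab, "P")
  expect_equal(hit$abundance, 7)
  expect_identical(hit$rank, "species")
  # no species entry: genus wins over class even when class value is larger
  tab2 <- as_abundance_table(rbind(arow(abundance = 2, rank = "genus"),
                                   arow(abundance = 9, rank = "class")))
  expect_equal(match_abundance(tab2, "P")$abundance, 2)
  expect_identical(match_abundance(tab2, "P")$rank, "genus")
  # exhaustive rank-chain oracle: first non-empty rank in order wins
  ranks <- c("species", "genus", "family", "order", "class")
  set.seed(8)
  for (i in 1:30) {
    present <- ranks[runif(5) < 0.5]
    if (!length(present)) next
    rows <- do.call(rbind, lapply(present, function(rk)
      arow(abundance = runif(1, 1, 10), rank = rk)))
    tab <- as_abundance_table(rows)
    expected_rank <- ranks[ranks %in% present][1]
    hit <- match_abundance(tab, "P")
    expect_identical(hit$rank, expected_rank)
    expect_equal(hit$abundance,
                 max(rows$abundance[rows$rank == expected_rank]))
  }
  expect_null(match_abundance(as_abundance_table(arow(abundance = 1,
                                                      rank = "genus")), "Q"))
})

test_that("adding a species record can only raise the species maximum", {
  tab <- as_abundance_table(arow(abundance = 5, rank = "species"))
  base <- match_abundance(tab, "P")$abundance
  for (v in c(1, 5, 20)) {
    tab2 <- as_abundance_table(rbind(tab, arow(abundance = v, rank = "species")))
    expect_gte(match_abundance(tab2, "P")$abundance, base)
  }
})

test_that("ppm conversion and table readers work from TSV", {
  expect_equal(ppm_to_mmol_gdw(100, 5e4, ptot = 0.5), 100 * 1e-6 * 0.5 / 5e4 * 1e3)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(protein = "P", abundance = 100, unit = "ppm", taxon = "t",
               rank = "species", mw_da = 5e4),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_abundance_table(f)
  expect_equal(tab$abundance, ppm_to_mmol_gdw(100, 5e4))
  expect_identical(tab$unit, "mmol_gDW")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(krow(kcat = 12), f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(select_kcat(read_kcat_table(f2), "P", "r1")$kcat, 12)
  # missing evidence is rejected
  expect_error(as_kcat_table(krow(kcat = NA, sa = NA)), "without")
})
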