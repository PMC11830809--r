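toy_indicators <- function() {
  tibble::tibble(
    reactor_id = c("a", "b", "c"),
    biofilm = c(5L, 2L, 0L),
    bacterial_qpcr = c(1e10, 5e9, 0),
    archaeal_qpcr = c(1e8, 1e10, 0),
    organic_acids = c(1, 2, 4),
    biocoulombs = c(200, 50, 0))
}

test_that("activity components are max-normalized with biofilm on its scale", {
  sc <- activity_scores(toy_indicators())
  expect_equal(sc$organic_acids, c(0.25, 0.5, 1))
  expect_equal(sc$biofilm, c(1, 0.4, 0))
  expect_equal(sc$bacterial_qpcr[1], 1)
  expect_equal(sc$total, rowSums(sc[, c("biofilm", "bacterial_qpcr",
                                        "archaeal_qpcr", "organic_acids",
                                        "biocoulombs")]))
  expect_true(all(sc$total >= 0 & sc$total <= 5))
})

test_that("a reactor holding every maximum with full biofilm scores 5", {
  ind <- toy_indicators()[1, ]
  sc <- activity_scores(ind)
  expect_equal(sc$total, 5)
})

test_that("all-zero columns score zero instead of dividing by zero", {
  ind <- toy_indicators()
  ind$biocoulombs <- 0
  sc <- activity_scores(ind)
  expect_equal(sc$biocoulombs, c(0, 0, 0))
})

test_that("activity components are scale-invariant in each indicator", {
  ind <- toy_indicators()
  sc1 <- activity_scores(ind)
  ind$bacterial_qpcr <- ind$bacterial_qpcr * 1e3
  sc2 <- activity_scores(ind)
  expect_equal(sc1$bacterial_qpcr, sc2$bacterial_qpcr)
})

test_that("activity scores validate their inputs", {
  ind <- toy_indicators()
  ind$biofilm[1] <- 7L
  expect_error(activity_scores(ind), "0..5")
  ind2 <- toy_indicators()
  ind2$organic_acids[2] <- -1
  expect_error(activity_scores(ind2), ">= 0")
})

test_that("depth normalization excludes shallow samples and rescales the rest", {
  res <- depth_normalize(toy_amplicon(), target_depth = 1e5, min_depth = 1e5)
  expect_setequal(res$exclusions$sample_id, c("s3"))
  expect_match(res$exclusions$reason, "below minimum depth")
  expect_equal(unname(colSums(res$table$counts)), c(1e5, 1e5))
  # proportional mode: a 200,000-read sample is exactly halved
  expect_equal(res$table$counts[, "s2"], c(ASV_a = 50000, ASV_b = 40000,
                                           ASV_c = 10000))
})

test_that("exclusion is monotone in the depth threshold", {
  tab <- toy_amplicon()
  excluded_at <- function(th) depth_normalize(tab, 100,
                                              min_depth = th)$exclusions$sample_id
  prev <- character(0)
  for (th in c(100, 500, 1e5, 2e5, 1e6)) {
    cur <- excluded_at(th)
    expect_true(all(prev %in% cur), info = paste("threshold", th))
    prev <- cur
  }
})

test_that("seeded subsampling is reproducible and unbiased", {
  tab <- toy_amplicon()
  r1 <- depth_normalize(tab, 5e4, min_depth = 1e5, method = "subsample",
                        seed = 42)
  r2 <- depth_normalize(tab, 5e4, min_depth = 1e5, method = "subsample",
                        seed = 42)
  expect_identical(r1$table$counts, r2$table$counts)
  expect_equal(unname(colSums(r1$table$counts)), c(5e4, 5e4))
  # expected proportions within multinomial-like tolerance
  p_in <- tab$counts[, "s1"] / sum(tab$counts[, "s1"])
  p_out <- r1$table$counts[, "s1"] / 5e4
  sigma <- sqrt(p_in * (1 - p_in) / 5e4)
  expect_true(all(abs(p_out - p_in) < 4 * sigma))
  expect_error(depth_normalize(tab, 5e4, method = "subsample"), "seed")
})

test_that("qPCR projection conserves the 100% total", {
  # archaea at 3x bacteria: f = 0.25; a 40% taxon displays at 10%
  q <- qpcr_result("r", 1e9, 3e9)
  proj <- qpcr_domain_normalize(c(x = 40, y = 60), q)
  expect_equal(unname(proj$displayed_percent["x"]), 10)
  expect_equal(proj$archaeal_block_percent, 75)
  expect_equal(sum(proj$displayed_percent) + proj$archaeal_block_percent, 100)

  # no archaea: abundances unchanged
  q0 <- qpcr_result("r", 1e9, 0)
  proj0 <- qpcr_domain_normalize(c(x = 40, y = 60), q0)
  expect_equal(unname(proj0$displayed_percent), c(40, 60))
  expect_equal(proj0$archaeal_block_percent, 0)

  # no signal at all: flagged, not normalized
  qna <- qpcr_result("r", 0, 0)
  expect_true(qpcr_domain_normalize(c(x = 100), qna)$excluded)

  # conservation over random tables
  set.seed(7)
  for (i in 1:20) {
    rel <- stats::runif(5); rel <- rel / sum(rel) * 100
    names(rel) <- letters[1:5]
    q <- qpcr_result("r", stats::runif(1, 0, 1e10), stats::runif(1, 0, 1e10))
    pr <- qpcr_domain_normalize(rel, q)
    expect_equal(sum(pr$displayed_percent) + pr$archaeal_block_percent, 100)
  }
})

test_that("rank aggregation sums, pools rare taxa, and truncates to top n", {
  tab <- toy_amplicon()
  agg <- aggregate_taxa(tab, "genus")
  # two Bacillus ASVs collapse to one row
  expect_equal(agg$taxon, c("Bacillus", "NA"))
  expect_equal(agg$s1[agg$taxon == "Bacillus"],
               sum(tab$counts[c("ASV_a", "ASV_b"), "s1"]))
  # column sums are conserved
  expect_equal(colSums(agg[, c("s1", "s2", "s3")]),
               colSums(tab$counts))

  # a taxon below min_percent everywhere is pooled into "other"
  counts <- cbind(s1 = c(995, 5, 0), s2 = c(990, 5, 5))
  rownames(counts) <- c("ASV_a", "ASV_b", "ASV_c")
  tab2 <- toy_amplicon(counts)
  agg2 <- aggregate_taxa(tab2, "class", min_percent = 1)
  expect_true("other" %in% agg2$taxon)
  expect_false("Gammaproteobacteria" %in% agg2$taxon)
  expect_equal(colSums(agg2[, c("s1", "s2")]), colSums(counts))

  # top-n truncation on a 15-genus table keeps 10 rows plus "other"
  counts15 <- matrix(c(15:1) * 100, ncol = 1,
                     dimnames = list(paste0("ASV_", 1:15), "s1"))
  tax15 <- tibble::tibble(asv_id = rownames(counts15), domain = "Bacteria",
                          phylum = "P", class = "C", order = "O",
                          family = "F", genus = paste0("G", 1:15))
  agg15 <- aggregate_taxa(amplicon_table(counts15, tax15), "genus",
                          top_n = 10)
  expect_equal(nrow(agg15), 11)
  expect_equal(sum(agg15$s1), sum(counts15))
  expect_equal(agg15$s1[agg15$taxon == "other"], sum((5:1) * 100))

  expect_error(aggregate_taxa(tab, "species"), "unknown rank")
})

test_that("indicator matrix standardizes to unit variance", {
  m <- indicator_matrix(toy_indicators())
  expect_equal(unname(apply(m, 2, stats::sd)), rep(1, 5))
  expect_equal(unname(colMeans(m)), rep(0, 5), tolerance = 1e-12)
})
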