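test_that("rarefaction conserves depth and never exceeds original counts", {
  cfg <- tiny_config(seed = 2)
  mb <- simulate_microbiome(cfg)
  rar <- rarefy_counts(mb$counts, depth = 1500, seed = 4)
  expect_true(all(rowSums(rar) == 1500))
  expect_true(all(rar <= mb$counts))
  expect_identical(rar, rarefy_counts(mb$counts, depth = 1500, seed = 4))
  expect_false(identical(rar, rarefy_counts(mb$counts, depth = 1500, seed = 5)))
})

test_that("a single-ASV sample rarefies onto that ASV alone", {
  m <- matrix(c(5000L, 0L, 0L), 1, dimnames = list("s1", paste0("a", 1:3)))
  r <- rarefy_counts(m, depth = 100, seed = 1)
  expect_identical(as.integer(r), c(100L, 0L, 0L))
})

test_that("samples below the target depth abort with their names", {
  m <- matrix(c(50L, 5000L), 2, 1, dimnames = list(c("shallow", "deep"), "a1"))
  expect_error(rarefy_counts(m, depth = 100), "shallow")
})

test_that("relative abundances normalize each sample to one", {
  m <- matrix(c(3L, 1L), 1, dimnames = list("s1", c("a", "b")))
  expect_equal(as.numeric(relative_abundance(m)), c(0.75, 0.25))
  one <- matrix(42L, 1, dimnames = list("s1", "a"))
  expect_equal(as.numeric(relative_abundance(one)), 1)
  mb <- simulate_microbiome(tiny_config())
  expect_equal(unname(rowSums(relative_abundance(mb$counts))),
               rep(1, nrow(mb$counts)), tolerance = 1e-9)
  zero <- matrix(0L, 1, 2, dimnames = list("empty", c("a", "b")))
  expect_error(relative_abundance(zero), "empty")
})

test_that("rare-ASV filtering uses a strict < boundary and drops empty columns", {
  m <- matrix(c(9L, 10L, 9981L,
                100L, 100L, 9800L), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("low", "edge", "big")))
  f <- filter_rare_asvs(m, threshold = 0.001)
  expect_identical(f["s1", "edge"], 10L)  # exactly 0.1% is retained
  expect_identical(f["s1", "low"], 0L)    # 0.09% is zeroed
  expect_identical(f["s2", "low"], 100L)  # kept where abundant enough

  expect_identical(filter_rare_asvs(m, threshold = 0), m)

  m2 <- matrix(c(5L, 9995L, 4L, 9996L), 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("alwayslow", "big")))
  f2 <- filter_rare_asvs(m2, threshold = 0.001)
  expect_identical(colnames(f2), "big")

  # idempotence at a fixed threshold (counts are not renormalized)
  mb <- simulate_microbiome(tiny_config(seed = 9))
  once <- filter_rare_asvs(mb$counts)
  expect_identical(filter_rare_asvs(once), once)
  expect_error(filter_rare_asvs(m, threshold = 1), "threshold")
})

test_that("rank aggregation is additive and conserves per-sample mass", {
  rel <- matrix(c(0.2, 0.3, 0.4, 0.1), 1,
                dimnames = list("s1", paste0("ASV_", 1:4)))
  ag <- aggregate_at_rank(rel, toy_taxonomy(), "genus")
  expect_equal(ag[1, "G1"], 0.5)
  expect_equal(ag[1, "G2"], 0.4)
  expect_equal(unname(rowSums(ag)), 1, tolerance = 1e-9)

  # all-distinct genera: a pure relabelling
  tax <- toy_taxonomy(); tax$genus <- paste0("U", 1:4)
  ag2 <- aggregate_at_rank(rel, tax, "genus")
  expect_equal(sort(as.numeric(ag2)), sort(as.numeric(rel)))

  # unassigned pooling and missing-ASV error
  tax2 <- toy_taxonomy(); tax2$genus[3:4] <- "unassigned"
  ag3 <- aggregate_at_rank(rel, tax2, "genus")
  expect_equal(ag3[1, "unassigned"], 0.5)
  expect_error(aggregate_at_rank(rel, tax2[-1, ], "genus"), "ASV_1")
})

test_that("alpha diversity matches closed forms and a direct-summation oracle", {
  uni <- matrix(rep(25L, 4), 1, dimnames = list("s", paste0("a", 1:4)))
  d <- alpha_diversity(uni)
  expect_equal(d$shannon, log(4), tolerance = 1e-12)
  expect_equal(d$inverse_simpson, 4, tolerance = 1e-12)
  expect_identical(d$observed, 4L)

  single <- matrix(100L, 1, dimnames = list("s", "a"))
  d1 <- alpha_diversity(single)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$inverse_simpson, 1)

  # p = (0.5, 0.25, 0.25): hand-summed Shannon and inverse Simpson
  m <- matrix(c(500L, 250L, 250L), 1, dimnames = list("s", paste0("a", 1:3)))
  p <- c(0.5, 0.25, 0.25)
  d2 <- alpha_diversity(m)
  expect_equal(d2$shannon, -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(d2$shannon, 1.0397, tolerance = 1e-4)
  expect_equal(d2$inverse_simpson, 1 / sum(p^2), tolerance = 1e-12)
  expect_equal(d2$inverse_simpson, 2.6667, tolerance = 1e-4)
})

test_that("diversity inequalities hold on random compositions", {
  withr::with_seed(99, {
    for (i in 1:25) {
      k <- sample(2:30, 1)
      counts <- matrix(rpois(k, lambda = sample(5:50, 1)) + c(1L, rep(0L, k - 1)),
                       1, dimnames = list("s", paste0("a", 1:k)))
      d <- alpha_diversity(counts)
      expect_lte(d$shannon, log(d$observed) + 1e-12)
      expect_lte(d$inverse_simpson, d$observed + 1e-12)
      expect_gte(d$inverse_simpson, 1 - 1e-12)
    }
  })
})

test_that("F/B ratio follows the phylum sums and reports missing, not infinite", {
  counts <- matrix(c(40L, 20L, 30L, 10L), 1,
                   dimnames = list("s1", paste0("ASV_", 1:4)))
  # Firmicutes = ASV_1+ASV_2 = 0.6, Bacteroidota = 0.3
  fb <- fb_ratio(counts, toy_taxonomy())
  expect_equal(fb$fb_ratio, 2.0)

  eq <- matrix(c(30L, 0L, 30L, 40L), 1,
               dimnames = list("s1", paste0("ASV_", 1:4)))
  expect_equal(fb_ratio(eq, toy_taxonomy())$fb_ratio, 1.0)

  tax <- toy_taxonomy(); tax$phylum[3] <- "Proteobacteria"
  expect_warning(fb2 <- fb_ratio(counts, tax), "undefined")
  expect_true(is.na(fb2$fb_ratio))
  expect_false(is.infinite(fb2$fb_ratio))
})

test_that("the profiling chain runs rarefy -> filter -> summaries in order", {
  mb <- simulate_microbiome(tiny_config(seed = 17))
  prof <- profile_microbiome(mb$counts, mb$taxonomy, seed = 17)
  depth <- min(rowSums(mb$counts))
  expect_true(all(rowSums(prof$rarefied) == depth))
  expect_true(all(prof$filtered <= prof$rarefied[, colnames(prof$filtered)]))
  expect_true(all(rowSums(prof$genus_rel) <= 1 + 1e-9))
  expect_identical(nrow(prof$diversity), nrow(mb$counts))
})
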