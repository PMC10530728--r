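test_that("presence filter applies the >= boundary and is monotone", {
  counts <- matrix(0L, 10, 3)
  counts[, 1] <- 1L                 # present everywhere
  counts[1, 2] <- 5L                # 1/10 of samples
  counts[1:2, 3] <- 5L              # 2/10 of samples
  kept <- filter_rare_taxa(counts, 0.2)
  expect_identical(kept, c(1L, 3L))

  kept10 <- filter_rare_taxa(counts, 0.1)
  expect_true(all(kept %in% kept10))

  expect_error(filter_rare_taxa(matrix(0L, 5, 2), 0.2), "presence filter")
})

test_that("alr transform matches direct evaluation and depends on the pseudocount", {
  counts <- matrix(c(10, 10), 1, 2)
  expect_equal(as.vector(alr_transform(counts, 0.5, reference = 2)), 0)

  counts2 <- matrix(c(0, 9), 1, 2)
  expect_equal(as.vector(alr_transform(counts2, 1, reference = 2)),
               log(1) - log(10))
  expect_equal(as.vector(alr_transform(counts2, 0.5, reference = 2)),
               log(0.5) - log(9.5))
  expect_false(isTRUE(all.equal(
    alr_transform(counts2, 0.5, reference = 2),
    alr_transform(counts2, 1, reference = 2))))
})

test_that("alr between-taxon differences are reference-free", {
  set.seed(502)
  pos <- matrix(rpois(40, 20) + 1L, 5, 8)
  a1 <- alr_transform(pos, 0.5, reference = 1)  # columns 2..8
  a8 <- alr_transform(pos, 0.5, reference = 8)  # columns 1..7
  expect_equal(a1[, 2] - a1[, 4], a8[, 3] - a8[, 5], tolerance = 1e-12)
})

test_that("reference taxon is the most abundant kept null taxon", {
  counts <- matrix(c(100, 50, 10,
                     100, 50, 10), 2, 3, byrow = TRUE)
  expect_identical(choose_reference_taxon(counts), 1L)
  # most abundant taxon causal: next most abundant null chosen
  expect_identical(choose_reference_taxon(counts, null_taxa = 2:3), 2L)
  # ties broken by the lowest index
  tied <- matrix(c(50, 50, 10), 2, 3, byrow = TRUE)
  expect_identical(choose_reference_taxon(tied), 1L)
  expect_error(choose_reference_taxon(counts, null_taxa = integer(0)),
               "no null taxa")
})

test_that("Wilcoxon p-values agree with exact enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3, 4, 5, 6),
                                 c(0, 0, 0, 1, 1, 1)), 0.1)
  expect_identical(wilcoxon_rank_sum(rep(2, 8), rep(c(0, 1), 4)), 1)

  set.seed(503)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    vals <- sample(100, n1 + n2)  # tie-free
    grp <- c(rep(0, n1), rep(1, n2))
    expect_equal(wilcoxon_rank_sum(vals, grp),
                 oracle_wilcoxon_p(vals[grp == 0], vals[grp == 1]),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon type-I error is controlled under the exchangeable null", {
  set.seed(504)
  grp <- rep(c(0, 1), each = 50)
  p <- replicate(4000, wilcoxon_rank_sum(rnorm(100), grp))
  rate <- mean(p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 4000) + 0.005)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p_eq <- rep(0.2, 5)
  expect_equal(bh_adjust(p_eq), p_eq)

  set.seed(505)
  for (rep in 1:25) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("wilcox-alr detects an overwhelming causal effect", {
  cfg <- sim_config(J = 10, n = 40, scheme = "M2", beta = 3,
                    causal_set = 2L, sigma_gamma = 0.4,
                    pinned_top = NULL)
  hits <- vapply(1:20, function(r) {
    ds <- simulate_replicate(cfg, r)
    res <- run_wilcox_alr(ds)
    2L %in% res$detected
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("wilcox-alr output contract holds", {
  ds <- simulate_replicate(tiny_config(beta = 1), 21)
  res <- run_wilcox_alr(ds)
  expect_s3_class(res, "da_result")
  expect_false(res$reference %in% res$taxon_ids)  # reference not tested
  expect_true(all(res$q_values >= res$p_values - 1e-12))
  expect_true(all(res$detected %in% res$taxon_ids))
  expect_identical(res$method_name, "wilcox-alr-half")
  expect_identical(run_wilcox_alr(ds, pseudocount = 1)$method_name,
                   "wilcox-alr-one")

  # permuting sample order leaves the p-values unchanged
  perm <- sample(nrow(ds$counts))
  ds_perm <- ds
  ds_perm$counts <- ds$counts[perm, ]
  ds_perm$trait <- ds$trait[perm]
  expect_equal(run_wilcox_alr(ds_perm)$p_values, res$p_values,
               tolerance = 1e-12)

  ds_cont <- simulate_replicate(tiny_config(trait_type = "continuous"), 5)
  expect_error(run_wilcox_alr(ds_cont), "binary trait")
})

test_that("the method registry enforces the adapter contract", {
  expect_true(all(c("wilcox-alr-half", "wilcox-alr-one") %in%
                    da_methods()))
  expect_error(get_da_method("no-such-method"), "unknown method")
  expect_error(register_da_method("wilcox-alr-half", identity),
               "already registered")

  register_da_method("stub-nothing",
    function(dataset, level, presence_fraction) {
      kept <- filter_rare_taxa(dataset$counts, presence_fraction)
      da_result(kept, rep(1, length(kept)), rep(1, length(kept)),
                "stub-nothing", level)
    }, overwrite = TRUE)
  register_da_method("stub-everything",
    function(dataset, level, presence_fraction) {
      kept <- filter_rare_taxa(dataset$counts, presence_fraction)
      da_result(kept, rep(0, length(kept)), rep(0, length(kept)),
                "stub-everything", level)
    }, overwrite = TRUE)

  ds <- simulate_replicate(tiny_config(beta = 1), 8)
  nothing <- get_da_method("stub-nothing")(ds, 0.2, 0.2)
  expect_length(nothing$detected, 0)
  everything <- get_da_method("stub-everything")(ds, 0.2, 0.2)
  truly <- which(ds$beta1 != 0)
  fs <- fdp_and_sensitivity(everything$detected, truly,
                            everything$taxon_ids)
  expect_identical(fs$sensitivity, 1)
  expect_equal(fs$fdp,
               length(setdiff(everything$taxon_ids, truly)) /
                 length(everything$taxon_ids))
})
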