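two_trait_fixture <- function(m, seed, beta_sd = 0.05) {
  list(r1 = random_dataset(m, "trait1", seed = seed, beta_sd = beta_sd),
       r2 = random_dataset(m, "trait2", seed = seed + 1000,
                           beta_sd = beta_sd))
}

test_that("Wakefield log-ABF matches the closed form", {
  expect_equal(wakefield_labf(0.5, 0.1, 0.04), 9.19528, tolerance = 1e-5)
  expect_equal(wakefield_labf(0.5, 0.1, 0.04),
               0.5 * (log(0.2) + 0.8 * 25))
  # null data favour the null for any positive prior variance
  expect_lt(wakefield_labf(0, 0.1, 0.04), 0)
  # degenerate prior: no evidence either way
  expect_equal(wakefield_labf(1.3, 0.1, 0), 0)
  expect_error(wakefield_labf(0.1, 0, 0.04))
})

test_that("a single strongly shared variant gives PP4 ~ 1 and PP3 = 0", {
  mk <- function(id, beta, se) summary_dataset(
    data.frame(variant_id = "rs1", chrom = "17", pos = 7e6,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta = beta, se = se, pvalue = 1e-12, n = 5e4, n_cases = NA),
    trait_id = id, validate = FALSE)
  # choose beta/se so that labf is large for both traits
  res <- coloc_abf(mk("t1", 0.45, 0.05), mk("t2", 0.45, 0.05))
  expect_gt(res$labf1[1], 20)
  expect_gt(unname(res$pp["PP4"]), 0.999)
  expect_equal(unname(res$pp["PP3"]), 0)   # H3 impossible with one variant
  expect_equal(res$top_shared_variant, "rs1")
})

test_that("uninformative data leave the posterior mass on H0", {
  m <- 100
  flat <- function(id) summary_dataset(
    data.frame(variant_id = paste0("rs", 1:m), chrom = "17",
               pos = 7e6 + 1:m, effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta = 0, se = 0.01, pvalue = 1, n = 5e4,
               n_cases = NA),
    trait_id = id, validate = FALSE)
  cfg <- coloc_config(w1 = 0, w2 = 0)   # all lABFs exactly 0
  res <- coloc_abf(flat("t1"), flat("t2"), config = cfg)
  # closed form: PP0 = 1 / (1 + m p1 + m p2 + m(m-1) p1 p2 + m p12)
  denom <- 1 + m * 1e-4 + m * 1e-4 + m * (m - 1) * 1e-8 + m * 1e-5
  expect_equal(unname(res$pp["PP0"]), 1 / denom, tolerance = 1e-10)
  expect_gt(unname(res$pp["PP0"]), 0.97)
})

test_that("swapping the traits swaps PP1 and PP2 only", {
  fx <- two_trait_fixture(10, seed = 5)
  a <- coloc_abf(fx$r1, fx$r2)
  b <- coloc_abf(fx$r2, fx$r1)
  expect_equal(unname(a$pp["PP1"]), unname(b$pp["PP2"]), tolerance = 1e-12)
  expect_equal(unname(a$pp["PP2"]), unname(b$pp["PP1"]), tolerance = 1e-12)
  expect_equal(unname(a$pp[c("PP0", "PP3", "PP4")]),
               unname(b$pp[c("PP0", "PP3", "PP4")]), tolerance = 1e-12)
})

test_that("posteriors match the brute-force enumeration oracle", {
  for (s in 1:50) {
    set.seed(s)
    m <- sample(1:12, 1)
    fx <- oracle_pair(m, seed = s * 7)
    res <- coloc_abf(fx$r1, fx$r2)
    rec1 <- fx$r1$records; rec2 <- fx$r2$records
    oracle <- coloc_enum_oracle(labf_oracle(rec1$beta, rec1$se, 0.04),
                                labf_oracle(rec2$beta, rec2$se, 0.04),
                                1e-4, 1e-4, 1e-5)
    expect_lt(max(abs(res$pp - oracle)), 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-10)
    expect_gte(unname(res$pp["PP3"]), 0)
  }
})

test_that("per-variant shared posterior is a softmax with the right argmax", {
  fx <- two_trait_fixture(12, seed = 31)
  res <- coloc_abf(fx$r1, fx$r2)
  expect_equal(sum(res$per_variant_pp4), 1, tolerance = 1e-12)
  expect_equal(res$top_shared_variant,
               names(which.max(res$labf1 + res$labf2)))
})

test_that("the cis window restricts variants (inclusive bounds)", {
  fx <- two_trait_fixture(10, seed = 13)    # pos = 7e6 + (1:10)*1000
  region <- gene_region("GENE", "17", 7.004e6, 7.005e6)
  cfg <- coloc_config(window_bp = 2000)
  res <- coloc_abf(fx$r1, fx$r2, region = region, config = cfg)
  expect_equal(res$n_variants, 6)           # pos 7.002e6 .. 7.007e6
  expect_setequal(names(res$labf1), paste0("rs", 2:7))
})

test_that("conditional colocalization probability is PP4/(PP3+PP4)", {
  fake <- structure(list(pp = c(PP0 = 0.1, PP1 = 0.05, PP2 = 0.05,
                                PP3 = 0.2, PP4 = 0.6)),
                    class = "coloc_result")
  expect_equal(conditional_coloc_prob(fake), 0.75)
  fake$pp <- c(PP0 = 0.5, PP1 = 0, PP2 = 0, PP3 = 0.5, PP4 = 0)
  expect_equal(conditional_coloc_prob(fake), 0)
  fake$pp <- c(PP0 = 0.6, PP1 = 0, PP2 = 0, PP3 = 0, PP4 = 0.4)
  expect_equal(conditional_coloc_prob(fake), 1)
  fake$pp <- c(PP0 = 1, PP1 = 0, PP2 = 0, PP3 = 0, PP4 = 0)
  expect_true(is.na(conditional_coloc_prob(fake)))
  # conditional >= marginal whenever PP3+PP4 <= 1
  fx <- two_trait_fixture(8, seed = 17)
  res <- coloc_abf(fx$r1, fx$r2)
  expect_gte(conditional_coloc_prob(res), unname(res$pp["PP4"]))
})

test_that("PP4 shrinks monotonically as the shared prior shrinks", {
  sim <- simulate_coloc_pair(shared = TRUE, m = 30, rho = 0.9, seed = 3)
  tab <- coloc_sensitivity(sim$region1, sim$region2,
                           p12_grid = c(1e-5, 1e-6, 1e-7))
  expect_true(all(diff(tab$PP4) < 0))
  # independence-prior baseline row can be requested
  tab2 <- coloc_sensitivity(sim$region1, sim$region2, p12_grid = 1e-4 * 1e-4)
  expect_equal(tab2$p12, 1e-8)
  # a grid of length one reproduces coloc_abf
  one <- coloc_sensitivity(sim$region1, sim$region2, p12_grid = 1e-5)
  full <- coloc_abf(sim$region1, sim$region2)
  expect_equal(unname(unlist(one[paste0("PP", 0:4)])), unname(full$pp),
               tolerance = 1e-12)
})

test_that("binary traits are moved to the log-odds scale before ABFs", {
  m <- 10
  set.seed(44)
  mu <- 0.1
  base <- random_dataset(m, "cc", seed = 45)
  lin <- base
  lin$trait_type <- "binary_linear"
  lin$case_fraction <- mu
  logit <- base
  logit$trait_type <- "binary_logistic"
  logit$records$beta <- base$records$beta / (mu * (1 - mu))
  logit$records$se <- base$records$se / (mu * (1 - mu))
  other <- random_dataset(m, "quant", seed = 46)
  expect_message(a <- coloc_abf(other, lin), "log-odds")
  b <- coloc_abf(other, logit)
  expect_equal(a$pp, b$pp, tolerance = 1e-12)
})

test_that("disjoint regions and missing priors error cleanly", {
  fx <- two_trait_fixture(5, seed = 51)
  shifted <- fx$r2
  shifted$records$variant_id <- paste0("other", 1:5)
  expect_error(coloc_abf(fx$r1, shifted), "no overlapping")
  expect_error(coloc_config(p12 = 0.5), "p12")
})
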