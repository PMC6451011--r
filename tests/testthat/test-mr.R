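test_that("wald_ratio matches its definition and invariances", {
  ins <- mr_instruments("s1", 0.1, 0.01, 0.05, 0.01)
  wr <- wald_ratio(ins)
  expect_equal(wr$estimate, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(mr_instruments("s", 0.1, 0.01, 0, 0.02))$estimate, 0)
  # simultaneous sign flip leaves the ratio unchanged
  flip <- mr_instruments("s1", -0.1, 0.01, -0.05, 0.01)
  expect_equal(wald_ratio(flip)$estimate, wr$estimate)
  expect_error(wald_ratio(list(beta_exposure = 0, beta_outcome = 1,
                               se_outcome = 0.1)), "zero")
})

test_that("mr_ivw equals closed forms and degenerates correctly", {
  # all ratios equal c -> estimate c, Q = 0
  ins <- mr_instruments(paste0("s", 1:4), c(0.1, 0.2, 0.1, 0.05), 0.01,
                        0.7 * c(0.1, 0.2, 0.1, 0.05), 0.02)
  est <- mr_ivw(ins)
  expect_equal(est$estimate, 0.7)
  expect_equal(est$Q, 0)
  expect_error(mr_ivw(ins[1, ]), "wald_ratio")
  # order and joint sign-flip invariance
  set.seed(14)
  ins2 <- simulate_instruments(n = 20, theta = 0.4, seed = 14)
  e1 <- mr_ivw(ins2)
  p <- sample(20)
  expect_equal(mr_ivw(ins2[p, ])$estimate, e1$estimate)
  ins3 <- ins2
  ins3$beta_exposure <- -ins3$beta_exposure
  ins3$beta_outcome <- -ins3$beta_outcome
  expect_equal(mr_ivw(ins3)$estimate, e1$estimate)
  expect_equal(mr_ivw(ins3)$se, e1$se)
})

test_that("mr_egger recovers slope and intercept", {
  # 3 collinear points: exact algebraic line
  ins <- mr_instruments(paste0("s", 1:3), c(0.1, 0.2, 0.3), 0.01,
                        0.02 + 0.5 * c(0.1, 0.2, 0.3), 0.02)
  e <- mr_egger(ins)
  expect_equal(e$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(ins[1:2, ]), ">= 3")
  # constant pleiotropy alpha added to every outcome: intercept -> alpha
  set.seed(15)
  reps <- t(vapply(1:200, function(r) {
    ins <- simulate_instruments(n = 50, theta = 0.5,
                                n_invalid = 50, constant_pleiotropy = 0.03)
    e <- mr_egger(ins)
    c(e$estimate, e$intercept)
  }, c(0, 0)))
  expect_lt(abs(mean(reps[, 1]) - 0.5), 0.02)
  expect_lt(abs(mean(reps[, 2]) - 0.03), 0.005)
  # no pleiotropy: intercept centred on zero
  set.seed(16)
  ints <- vapply(1:200, function(r)
    mr_egger(simulate_instruments(n = 50, theta = 0.5))$intercept, 0)
  expect_lt(abs(mean(ints)), 0.005)
})

test_that("weighted median matches the interpolation oracle", {
  ins <- mr_instruments(paste0("s", 1:3), rep(0.1, 3), 0.01,
                        c(0.04, 0.05, 0.06), 0.01)
  wm <- mr_weighted_median(ins, n_boot = 0)
  expect_equal(wm$estimate, 0.5)
  set.seed(17)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    ins <- simulate_instruments(n = n, theta = 0.3,
                                se_outcome = runif(1, 0.02, 0.1))
    rat <- ins$beta_outcome / ins$beta_exposure
    w <- ins$beta_exposure^2 / ins$se_outcome^2
    expect_equal(mr_weighted_median(ins, n_boot = 0)$estimate,
                 oracle_weighted_median(rat, w))
  }
  # penalisation inactive when all Q contributions are small: ratio
  # scatter far below the outcome SE leaves every penalty factor at 1
  quiet <- mr_instruments(paste0("s", 1:3), rep(0.1, 3), 0.001,
                          c(0.04, 0.05, 0.06), 1)
  expect_equal(mr_weighted_median(quiet, penalised = TRUE, n_boot = 0)$estimate,
               mr_weighted_median(quiet, penalised = FALSE, n_boot = 0)$estimate)
  set.seed(18)
  ins <- simulate_instruments(n = 20, theta = 0.3, se_outcome = 0.2)
  # bootstrap SE is reproducible under a fixed seed
  b1 <- mr_weighted_median(ins, n_boot = 200, seed = 5)
  b2 <- mr_weighted_median(ins, n_boot = 200, seed = 5)
  expect_equal(b1$se, b2$se)
  expect_gt(b1$se, 0)
})

test_that("weighted median resists 40% invalid instruments", {
  # strong instruments: the median's contamination shift (an ~83rd
  # percentile effect at 40% invalid weight) stays within the ratio
  # scatter while IVW absorbs the full directional pleiotropy
  set.seed(19)
  est_wm <- est_ivw <- numeric(100)
  for (r in 1:100) {
    ins <- simulate_instruments(n = 30, theta = 0.3,
                                gamma_range = c(0.1, 0.3),
                                se_exposure = 0.002, se_outcome = 0.005,
                                n_invalid = 12, constant_pleiotropy = 0.1)
    est_wm[r] <- mr_weighted_median(ins, n_boot = 0)$estimate
    est_ivw[r] <- mr_ivw(ins)$estimate
  }
  expect_lt(abs(mean(est_wm) - 0.3), 0.05)
  expect_gt(mean(est_ivw) - 0.3, 0.1)        # IVW visibly biased here
})

test_that("cochran_q flags outliers and follows chi-square under the null", {
  ins <- mr_instruments(paste0("s", 1:4), rep(0.1, 4), 0.01,
                        c(0.03, 0.03, 0.03, 0.03), 0.02)
  expect_equal(mr_cochran_q(ins)$Q, 0)
  out <- ins
  out$beta_outcome[2] <- 0.4
  qq <- mr_cochran_q(out)
  expect_equal(names(which.max(qq$q)), "s2")
  set.seed(20)
  Qs <- vapply(1:1000, function(r)
    mr_cochran_q(simulate_instruments(n = 15, theta = 0.5))$Q, 0)
  expect_lt(abs(mean(Qs) - 14), 1)
})

test_that("prune_instruments removes the planted outlier and nothing else", {
  # specificity: all-valid sets keep everything most of the time
  set.seed(22)
  removed <- vapply(1:200, function(r)
    length(mr_prune_instruments(simulate_instruments(n = 20, theta = 0.5))$excluded),
    0L)
  expect_lt(mean(removed > 0), 0.10)
  # sensitivity: a planted 10x pleiotropic outlier among 19 valid
  set.seed(23)
  found <- vapply(1:200, function(r) {
    ins <- simulate_instruments(n = 20, theta = 0.3, n_invalid = 1,
                                constant_pleiotropy = 10 * 0.3 * 0.1)
    "snp001" %in% mr_prune_instruments(ins)$excluded
  }, TRUE)
  expect_gte(mean(found), 0.95)
  # fixed point: re-pruning the retained set removes nothing, and the
  # max Q contribution respects the Bonferroni bound
  set.seed(24)
  ins <- simulate_instruments(n = 20, theta = 0.3, n_invalid = 2,
                              constant_pleiotropy = 0.3)
  pr <- mr_prune_instruments(ins)
  expect_length(mr_prune_instruments(pr$retained)$excluded, 0)
  qq <- mr_cochran_q(pr$retained)
  expect_lte(max(qq$q), qchisq(1 - 0.05 / nrow(pr$retained), 1))
  expect_equal(nrow(pr$retained) + length(pr$excluded), 20L)
})

test_that("mr_run wires pruning, estimators and the report together", {
  set.seed(25)
  ins <- simulate_instruments(n = 25, theta = 0.4, n_invalid = 1,
                              constant_pleiotropy = 0.5)
  res <- mr_run(ins, n_boot = 100)
  expect_named(res$estimates, c("ivw", "egger", "weighted_median",
                                "penalised_weighted_median"))
  expect_equal(res$estimates$ivw$n_instruments_used +
                 length(res$excluded_snps), 25L)
  for (e in res$estimates) expect_s3_class(e, "mr_estimate")
})

test_that("harmonisation matches alleles, flips and drops palindromes", {
  exp <- data.frame(snp = c("a", "b", "c", "d"),
                    ea = c("A", "C", "A", "G"), oa = c("G", "T", "T", "A"),
                    eaf = c(0.3, 0.2, 0.5, 0.4),
                    beta = c(0.1, 0.2, 0.15, 0.1), se = rep(0.01, 4),
                    p = rep(1e-9, 4), log10_p = rep(-9, 4))
  out <- exp
  out$beta <- c(0.05, -0.08, 0.02, 0.03)
  # b reported on the swapped allele; c is palindromic with MAF 0.5
  out$ea <- c("A", "T", "A", "G"); out$oa <- c("G", "C", "T", "A")
  h <- mr_harmonise(exp, out)
  expect_setequal(h$snp, c("a", "b", "d"))
  expect_equal(h$beta_outcome[h$snp == "b"], 0.08)
  expect_equal(h$beta_outcome[h$snp == "a"], 0.05)
})

test_that("instrument files round-trip through read_instruments", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  df <- data.frame(SNP = c("s1", "s2", "s3"), beta_exp = c(0.1, 0.2, 0.15),
                   se_exp = 0.01, beta_out = c(0.05, 0.1, 0.07),
                   se_out = 0.02)
  write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  ins <- read_instruments(tmp)
  expect_s3_class(ins, "mr_instruments")
  expect_equal(ins$beta_exposure, df$beta_exp)
  df2 <- df[, -3]
  write.table(df2, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_instruments(tmp), "se_exp")
})
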