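# 20-probe x 6-sample fixture with two groups of three.
t_fixture <- function(seed = 13) {
  set.seed(seed)
  beta <- matrix(runif(20 * 6, 0.2, 0.8), 20, 6,
                 dimnames = list(sprintf("p%02d", 1:20),
                                 sprintf("S%d", 1:6)))
  groups <- setNames(rep(c("healthy", "AK"), each = 3), colnames(beta))
  list(beta = beta, groups = groups)
}

test_that("d0 = 0 reduces the moderated t to the ordinary two-sample t", {
  fx <- t_fixture()
  res <- moderated_group_test(fx$beta, fx$groups,
                              comparison = c("healthy", "AK"),
                              statistic = "t", d0 = 0)
  for (i in seq_len(nrow(fx$beta))) {
    ht <- t.test(fx$beta[i, 4:6], fx$beta[i, 1:3], var.equal = TRUE)
    expect_equal(res$statistic[i], unname(ht$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], ht$p.value, tolerance = 1e-10)
    expect_equal(res$delta_beta[i],
                 mean(fx$beta[i, 4:6]) - mean(fx$beta[i, 1:3]),
                 tolerance = 1e-12)
  }
})

test_that("moderated F equals the squared moderated t for two groups", {
  fx <- t_fixture()
  rt <- moderated_group_test(fx$beta, fx$groups,
                             comparison = c("healthy", "AK"),
                             statistic = "t")
  rf <- moderated_group_test(fx$beta, fx$groups,
                             comparison = c("healthy", "AK"),
                             statistic = "F")
  expect_equal(rf$statistic, rt$statistic^2, tolerance = 1e-8)
  expect_equal(rf$p_value, rt$p_value, tolerance = 1e-8)
})

test_that("variance shrinkage matches the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(31)
  # heteroskedastic probes so the prior df estimate is finite
  sds <- runif(200, 0.02, 0.12)
  beta <- matrix(rnorm(200 * 8, 0.5, sds), 200, 8,
                 dimnames = list(sprintf("p%03d", 1:200),
                                 sprintf("S%d", 1:8)))
  beta <- pmin(pmax(beta, 0), 1)
  groups <- setNames(rep(c("healthy", "cSCC"), each = 4), colnames(beta))
  res <- moderated_group_test(beta, groups,
                              comparison = c("healthy", "cSCC"),
                              statistic = "t")
  design <- cbind(1, rep(0:1, each = 4))
  fit <- limma::eBayes(limma::lmFit(beta, design))
  mod <- attr(res, "moderation")
  expect_equal(mod$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_2, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$sigma2_tilde, unname(fit$s2.post), tolerance = 1e-8)
  expect_equal(res$statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("a huge prior df pools every variance onto s0^2", {
  fx <- t_fixture()
  res <- moderated_group_test(fx$beta, fx$groups,
                              comparison = c("healthy", "AK"), d0 = 1e6)
  mod <- attr(res, "moderation")
  expect_equal(res$sigma2_tilde, rep(mod$s0_2, nrow(res)), tolerance = 1e-4)
})

test_that("null groups yield (almost) no BH-significant probes", {
  set.seed(91)
  beta <- matrix(runif(2000 * 12, 0.3, 0.7), 2000, 12,
                 dimnames = list(sprintf("p%04d", 1:2000),
                                 sprintf("S%d", 1:12)))
  groups <- setNames(rep(c("healthy", "AK"), each = 6), colnames(beta))
  res <- moderated_group_test(beta, groups, comparison = c("healthy", "AK"))
  expect_lte(sum(res$significant), 0.001 * nrow(res))
})

test_that("planted effects are fully recovered with at most one false flag", {
  set.seed(17)
  n_probes <- 2000
  planted <- sprintf("p%04d", 1:100)
  beta <- matrix(rnorm(n_probes * 16, 0.5, 0.05), n_probes, 16,
                 dimnames = list(sprintf("p%04d", 1:n_probes),
                                 sprintf("S%d", 1:16)))
  beta[planted, 9:16] <- beta[planted, 9:16] + 0.3
  beta <- pmin(pmax(beta, 0), 1)
  groups <- setNames(rep(c("healthy", "AK"), each = 8), colnames(beta))
  res <- moderated_group_test(beta, groups, comparison = c("healthy", "AK"))
  hits <- res$probe_id[res$significant]
  expect_true(all(planted %in% hits))
  # realized false-discovery proportion within the BH guarantee (with
  # sampling slack: E[V] ~ alpha * m0/m * R ~ 5 here)
  expect_lte(length(setdiff(hits, planted)) / length(hits), 0.10)
})

test_that("errors and edge contracts hold", {
  fx <- t_fixture()
  g <- fx$groups; g[1] <- "cSCC"
  expect_error(moderated_group_test(fx$beta, g,
                                    comparison = c("cSCC", "AK")),
               "group with < 2 samples: cSCC")
  # all-missing probes are dropped and counted
  b <- fx$beta; b[3, ] <- NA
  res <- moderated_group_test(b, fx$groups, comparison = c("healthy", "AK"))
  expect_equal(attr(res, "dropped_all_missing"), 1)
  expect_false("p03" %in% res$probe_id)
  # zero-variance probes are indeterminate at d0 = 0, not infinite
  b2 <- fx$beta; b2[5, ] <- 0.4
  r2 <- moderated_group_test(b2, fx$groups, comparison = c("healthy", "AK"),
                             d0 = 0)
  expect_true(is.na(r2$statistic[r2$probe_id == "p05"]))
  # adjusted p never below raw p; flag consistent with alpha
  r3 <- moderated_group_test(fx$beta, fx$groups,
                             comparison = c("healthy", "AK"))
  expect_true(all(r3$p_adjusted >= r3$p_value - 1e-15))
  expect_equal(r3$significant, r3$p_adjusted < 0.05)
})

test_that("bh_adjust matches hand enumeration and the reference stepup", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")

  set.seed(23)
  for (i in 1:40) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), brute_force_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # a thousand random vectors against base R's independent implementation
  for (i in 1:1000) {
    p <- runif(20)
    expect_identical(all.equal(bh_adjust(p), p.adjust(p, "BH"),
                               tolerance = 1e-12), TRUE)
  }
})
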