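test_that("VIP satisfies its normalization identity on arbitrary fits", {
  set.seed(71)
  for (i in 1:5) {
    p <- sample(5:40, 1)
    m <- matrix(rlnorm(p * 12), p, 12,
                dimnames = list(paste0("f", seq_len(p)), paste0("s", 1:12)))
    fit <- suppressWarnings(plsda_vip(m, rep(c("a", "b"), each = 6),
                                      n_components = 3))
    for (k in seq_len(fit$n_components))
      expect_equal(mean(fit$vip[[paste0("VIP_", k)]]^2), 1,
                   tolerance = 1e-8)
  }
})

test_that("a single informative feature takes all the importance", {
  m <- rbind(c(rep(0, 4), rep(1, 4)),
             matrix(5, 3, 8))
  rownames(m) <- paste0("f", 1:4)
  colnames(m) <- paste0("s", 1:8)
  fit <- suppressWarnings(plsda_vip(m, rep(c("a", "b"), each = 4),
                                    n_components = 3))
  expect_identical(fit$n_components, 1L)
  expect_equal(fit$vip$VIP, c(2, 0, 0, 0), tolerance = 1e-9)  # sqrt(p) = 2
})

test_that("VIP agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(72)
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:12)))
  m[1:3, 7:12] <- m[1:3, 7:12] + 2
  labels <- rep(c("a", "b"), each = 6)
  fit <- plsda_vip(m, labels, n_components = 2)
  ref <- mixOmics::plsda(t(m), factor(labels), ncomp = 2, scale = TRUE)
  ref_vip <- mixOmics::vip(ref)
  expect_equal(fit$vip$VIP_1, unname(ref_vip[, 1]), tolerance = 1e-8)
  expect_equal(fit$vip$VIP_2, unname(ref_vip[, 2]), tolerance = 1e-8)
})

test_that("degenerate PLS-DA inputs are rejected or reduced", {
  m <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  expect_error(plsda_vip(m, rep("a", 8)), "two classes",
               class = "mipror_domain_error")
  expect_error(plsda_vip(m, c(rep("a", 6), "b", "b")), "at least 3")
  expect_warning(plsda_vip(m, rep(c("a", "b"), each = 4),
                           n_components = 10), "reduced")
})

test_that("feature selection uses a strict threshold", {
  set.seed(73)
  m <- matrix(rlnorm(10 * 10), 10, 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
  fit <- suppressWarnings(plsda_vip(m, rep(c("a", "b"), each = 5)))
  # VIP exactly at the threshold is excluded
  fake <- fit
  fake$vip$VIP <- rep(1, 10)
  expect_length(select_features(fake, 1), 0)
  fake$vip$VIP[3] <- 1.0000001
  expect_identical(select_features(fake, 1), "f3")
  # all-components mode is a conjunction over cumulative models
  cols <- paste0("VIP_", seq_len(fit$n_components))
  fake2 <- fit
  for (cn in cols) fake2$vip[[cn]] <- rep(2.5, 10)
  fake2$vip[[cols[1]]][1] <- 1.9
  sel <- select_features(fake2, 2, all_components = TRUE)
  expect_identical(sel, paste0("f", 2:10))
})

test_that("planted differential proteins rank at the top by VIP", {
  # 100 proteins, 5 planted 4x effects, multiplicative noise 0.3
  recover_one <- function(seed) {
    set.seed(seed)
    base <- rlnorm(100, 10, 1)
    eff <- rep(1, 100)
    eff[1:5] <- 4
    m <- cbind(
      matrix(base, 100, 6) * exp(matrix(rnorm(600, 0, 0.3), 100)),
      matrix(base * eff, 100, 6) * exp(matrix(rnorm(600, 0, 0.3), 100)))
    dimnames(m) <- list(paste0("f", 1:100), paste0("s", 1:12))
    fit <- plsda_vip(log(m), rep(c("ctl", "trt"), each = 6))
    top10 <- fit$vip$feature[order(-fit$vip$VIP)][1:10]
    all(paste0("f", 1:5) %in% top10)
  }
  hits <- vapply(1:10, recover_one, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("label permutation destroys the planted VIP signal", {
  set.seed(74)
  base <- rlnorm(60, 10, 1)
  eff <- rep(1, 60); eff[1:5] <- 4
  m <- cbind(matrix(base, 60, 6),
             matrix(base * eff, 60, 6)) *
    exp(matrix(rnorm(60 * 12, 0, 0.3), 60))
  dimnames(m) <- list(paste0("f", 1:60), paste0("s", 1:12))
  labels <- rep(c("ctl", "trt"), each = 6)
  ranks <- vapply(1:50, function(i) {
    fit <- suppressWarnings(plsda_vip(log(m), sample(labels)))
    r <- rank(-fit$vip$VIP)
    stats::median(r[1:5])
  }, numeric(1))
  # under permuted labels the planted features sit anywhere: median rank
  # close to the uniform expectation, far from the top
  expect_gt(mean(ranks), 60 / 4)
  expect_lt(mean(ranks), 3 * 60 / 4)
})

test_that("change tables pair arms and recover planted directions", {
  eff <- data.frame(target = "Phylum_01", level = "phylum", effect = 4)
  cfg <- small_config(noise_sigma = 0, detection_quantile = 0,
                      treatment_effects = eff, seed = 75)
  com <- sim_community(cfg)
  des <- design_drug_response(n_subjects = 3)
  vitro <- sim_dataset(com, des[des$Arm == "in_vitro", ], cfg)$dataset
  vivo <- sim_dataset(com, des[des$Arm == "in_vivo", ], cfg)$dataset
  ch <- ivivc_changes(vitro, vivo, level = "Phylum",
                      min_distinct_peptides = 1)
  target <- ch[ch$feature == "Phylum_01", ]
  expect_true(all(target$in_vitro_change > 0))
  expect_true(all(target$in_vivo_change > 0))
  res <- ivivc_correlation(ch)
  expect_equal(res$quadrant_agreement_pct, 100)
  expect_true(all(res$per_subject$r > 0.99))
})

test_that("IVIVC summary statistics follow their definitions", {
  ch <- tibble::tibble(
    Subject = "M1", feature = paste0("f", 1:4), invivo_timepoint = 14,
    in_vitro_change = c(1, 2, -1, -2),
    in_vivo_change = c(2, 4, -2, -4),
    in_vitro_log2 = 0, in_vivo_log2 = 0)
  class(ch) <- c("change_table", class(ch))
  res <- ivivc_correlation(ch)
  expect_equal(res$per_subject$r, 1)
  expect_equal(res$quadrant_agreement_pct, 100)
  # one discordant sign out of four gives 75% agreement
  ch2 <- ch
  ch2$in_vivo_change[4] <- 2
  expect_equal(ivivc_correlation(ch2)$quadrant_agreement_pct, 75)
  # rescaling either change vector leaves r unchanged
  ch3 <- ch
  ch3$in_vitro_change <- ch3$in_vitro_change * 1000
  expect_equal(ivivc_correlation(ch3)$per_subject$r, 1)
  # zero-change rows are excluded from the agreement denominator
  ch4 <- ch
  ch4$in_vitro_change[1] <- 0
  expect_equal(ivivc_correlation(ch4)$quadrant_agreement_pct, 100)
})

test_that("group comparison is an exact rank-sum test for small samples", {
  expect_equal(group_compare(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(group_compare(c(5, 5, 5), c(5, 5, 5)), 1)
  p <- group_compare(c(1, 2, 3), c(10, 11, 12))
  # oracle: enumerate all 20 assignments of ranks to group A
  picks <- combn(6, 3)
  w_obs <- sum(rank(c(1, 2, 3, 10, 11, 12))[1:3]) - 6
  ws <- apply(picks, 2, function(sel) sum(sel) - 6)
  p_exact <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  expect_equal(p, p_exact, tolerance = 1e-12)
  expect_equal(p, 0.1, tolerance = 1e-12)
  expect_equal(group_compare(c(10, 11, 12), c(1, 2, 3)), p)
  expect_error(group_compare(c(1, 2), c(1, 2, 3)), "at least 3")
})
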