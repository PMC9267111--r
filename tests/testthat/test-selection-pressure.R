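test_that("pr2_point pools the eight four-codon pools correctly", {
  # toy Ala counts {GCA:2, GCT:1, GCG:3, GCC:1} -> at = 2/3, gc = 3/4
  counts <- setNames(rep(0, 61), SENSE)
  counts[c("GCA", "GCT", "GCG", "GCC")] <- c(2, 1, 3, 1)
  p <- pr2_point(counts)
  expect_equal(unname(p["at_bias"]), 2 / 3)
  expect_equal(unname(p["gc_bias"]), 3 / 4)
})

test_that("pr2 midpoint and degenerate cases behave as specified", {
  counts <- setNames(rep(0, 61), SENSE)
  counts[mycocub:::PR2_CODONS] <- 7  # perfectly symmetric usage
  expect_equal(unname(pr2_point(counts)), c(0.5, 0.5))
  # all third positions A: at_bias forced to 1, gc_bias undefined
  onlyA <- setNames(rep(0, 61), SENSE)
  pr2A <- mycocub:::PR2_CODONS[substr(mycocub:::PR2_CODONS, 3, 3) == "A"]
  onlyA[pr2A] <- 5
  p <- pr2_point(onlyA)
  expect_equal(unname(p["at_bias"]), 1)
  expect_true(is.na(p["gc_bias"]))
  # two-fold families do not contribute (AAA is Lys)
  lysOnly <- setNames(rep(0, 61), SENSE)
  lysOnly["AAA"] <- 100
  expect_true(all(is.na(pr2_point(lysOnly))))
})

test_that("pr2 biases are invariant under count scaling", {
  set.seed(31)
  counts <- random_count_table()
  expect_equal(pr2_point(counts), pr2_point(counts * 17))
})

test_that("neutrality_fit recovers exact lines and matches closed form", {
  gc3 <- c(20, 35, 50, 65, 80)
  gc12 <- 0.5 * gc3 + 10
  fit <- neutrality_fit(gc12, gc3, outlier_rule = "none")
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 10, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  # 5-point irregular set against the normal equations
  set.seed(32)
  x <- c(22.1, 34.7, 41.3, 58.9, 71.2)
  y <- c(41.5, 44.2, 40.9, 49.8, 51.3)
  fit <- neutrality_fit(y, x, outlier_rule = "none")
  ref <- normal_eq_ols(x, y)
  expect_equal(fit$slope, unname(ref["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(ref["intercept"]), tolerance = 1e-12)
  expect_equal(fit$r, unname(cor(x, y)), tolerance = 1e-12)
})

test_that("neutrality_fit handles degenerate inputs per contract", {
  expect_equal(neutrality_fit(rep(45, 5), c(30, 40, 50, 60, 70),
                              outlier_rule = "none")$slope, 0)
  expect_error(neutrality_fit(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(neutrality_fit(c(1, 2, 3), rep(5, 3),
                              outlier_rule = "none"), "zero variance")
})

test_that("the 1.5 IQR rule removes and reports planted outliers", {
  set.seed(33)
  gc3 <- runif(30, 40, 60)
  gc12 <- 0.4 * gc3 + rnorm(30, sd = 0.5)
  ids <- paste0("g", 1:31)
  gc3 <- c(gc3, 50)
  gc12 <- c(gc12, 95)  # wild GC12 outlier
  fit <- neutrality_fit(gc12, gc3, ids = ids)
  expect_equal(fit$removed_ids, "g31")
  expect_equal(fit$n_used, 30)
  fit_none <- neutrality_fit(gc12, gc3, ids = ids, outlier_rule = "none")
  expect_equal(fit_none$n_used, 31)
  expect_gt(abs(fit_none$slope - 0.4), abs(fit$slope - 0.4))
})

test_that("slope is invariant under shifting GC12; r^2 is symmetric", {
  set.seed(34)
  gc3 <- runif(20, 30, 70)
  gc12 <- 0.3 * gc3 + rnorm(20, sd = 2)
  f1 <- neutrality_fit(gc12, gc3, outlier_rule = "none")
  f2 <- neutrality_fit(gc12 + 7, gc3, outlier_rule = "none")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  # r^2 = slope(y~x) * slope(x~y)
  back <- neutrality_fit(gc3, gc12, outlier_rule = "none")
  expect_equal(f1$r^2, f1$slope * back$slope, tolerance = 1e-12)
})

test_that("enc_gc3s_table flags points strictly below the curve", {
  tab <- data.frame(id = c("a", "b", "c"), gc3s = c(50, 50, 30),
                    enc = c(expected_enc(0.5) - 5, expected_enc(0.5),
                            expected_enc(0.3) + 1))
  out <- enc_gc3s_table(tab)
  expect_equal(out$below_curve, c(TRUE, FALSE, FALSE))
  expect_equal(attr(out, "n_below"), 1L)
  expect_equal(out$expected, expected_enc(out$gc3s / 100))
})

test_that("unbiased GC3-tilted sequences hug the expected ENc curve", {
  set.seed(35)
  devs <- unlist(lapply(c(0.3, 0.5, 0.7), function(g) {
    m <- make_codon_model(g, 0, seed = round(1000 * g))
    vapply(1:5, function(i) {
      s <- generate_cds(m, 800)
      enc(count_codons(s))$enc - expected_enc(gc3s(s) / 100)
    }, numeric(1))
  }))
  expect_lt(max(abs(devs)), 3)  # concentrate near the curve
  expect_lt(abs(mean(devs)), 1.5)
})

test_that("pearson_cor matches direct formula and handles extremes", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(unname(pearson_cor(x, 2 * x + 1)["r"]), 1)
  expect_equal(unname(pearson_cor(x, -x)["r"]), -1)
  y <- c(2.3, 1.1, 4.8, 3.9, 6.1, 5.2)
  got <- pearson_cor(x, y)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_ref <- r_ref * sqrt((length(x) - 2) / (1 - r_ref^2))
  p_ref <- 2 * pt(abs(t_ref), df = length(x) - 2, lower.tail = FALSE)
  expect_equal(unname(got["r"]), r_ref, tolerance = 1e-12)
  expect_equal(unname(got["p"]), p_ref, tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), 1:5), "degenerate")
  expect_silent(pearson_cor(x, y, method = "spearman"))
})
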