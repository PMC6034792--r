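test_that("KS normality gate behaves as a normality test should", {
  accept <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    ks_normality(rnorm(200))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(accept), 0.90)                 # simulation oracle
  reject <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    ks_normality(rexp(200))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.90)
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(4, 20)), "degenerate")
})

test_that("two-group comparison routes through the decision tree", {
  set.seed(31)
  g1 <- rnorm(50); g2 <- rnorm(50, 2)
  res <- compare_two_groups(g1, g2)
  expect_identical(res$test_name, "Student_t")
  expect_lt(res$p_value, 0.001)
  expect_match(res$decision_path, "Student t")

  same <- rnorm(20)
  res0 <- compare_two_groups(same, same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  set.seed(32)
  h1 <- rcauchy(60); h2 <- rcauchy(60)           # heavy tails fail KS
  resh <- compare_two_groups(h1, h2)
  expect_identical(resh$test_name, "Kruskal_Wallis")
  expect_match(resh$decision_path, "Kruskal-Wallis")
  expect_error(compare_two_groups(1:3, 1:10), "at least 5")
})

test_that("two-group comparison is symmetric in its arguments", {
  set.seed(33)
  g1 <- rnorm(30, 5, 1); g2 <- rnorm(30, 5.5, 1)
  a <- compare_two_groups(g1, g2)
  b <- compare_two_groups(g2, g1)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, -b$statistic)
  set.seed(34)
  c1 <- rcauchy(30); c2 <- rcauchy(30)
  expect_equal(compare_two_groups(c1, c2)$p_value,
               compare_two_groups(c2, c1)$p_value)
})

test_that("multi-group comparison: type-I behaviour and power", {
  type1 <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    groups <- replicate(4, rnorm(20, 50, 5), simplify = FALSE)
    compare_multi_groups(groups)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(type1), 0.88)                 # ~95% expected

  power <- vapply(1:50, function(i) {
    set.seed(4000 + i)
    groups <- lapply(c(0, 1, 2, 3), function(mu) rnorm(20, mu, 1))
    compare_multi_groups(groups)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(power), 0.80)

  same <- rnorm(20)
  res <- compare_multi_groups(list(same, same, same, same))
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_gte(res$p_value, 0.999)
  expect_error(compare_multi_groups(list(1:10, 1:10)), "at least 3")
})

test_that("multi-group routing matches the normality gate", {
  set.seed(35)
  normals <- replicate(4, rnorm(30), simplify = FALSE)
  expect_identical(compare_multi_groups(normals)$test_name, "F_equal_means")
  skewed <- replicate(4, rexp(200), simplify = FALSE)
  expect_identical(compare_multi_groups(skewed)$test_name, "Kruskal_Wallis")
})

test_that("glaucoma staging follows the printed thresholds", {
  stg <- function(md) classify_glaucoma_stage(md)$stage
  expect_equal(stg(-5.0), 1L)
  expect_equal(stg(-6.0), 1L)                   # MD >= -6.00 is stage 1
  expect_equal(stg(-6.01), 2L)
  expect_equal(stg(-12.0), 2L)                  # boundary to the milder stage
  expect_equal(stg(-12.005), 3L)                # the printed -12.01 gap
  expect_equal(stg(-13.0), 3L)
  expect_equal(stg(-20.0), 4L)                  # printed stage-4 endpoint
  expect_equal(stg(-25.0), 4L)
  expect_equal(classify_glaucoma_stage(NA, vf_performed = FALSE)$stage, 5L)
  expect_equal(classify_glaucoma_stage(-1, field_normal = TRUE)$stage, 0L)
  expect_error(classify_glaucoma_stage(NaN), "finite")
})

test_that("staging is total and monotone in MD", {
  md_grid <- seq(-30, 2, by = 0.05)
  stages <- vapply(md_grid, function(md) classify_glaucoma_stage(md)$stage,
                   integer(1))
  expect_true(all(stages %in% 1:4))
  expect_true(all(diff(stages) <= 0))           # lower MD never lowers stage
})
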