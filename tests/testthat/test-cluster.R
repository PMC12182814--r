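# Standardization, Ward clustering against a Lance-Williams reference,
# majority-vote k selection, and the characterization statistics.

test_that("standardization gives population z-scores and is idempotent", {
  set.seed(4)
  x <- matrix(rnorm(200, 5, 3), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  std <- standardize_features(x)
  expect_lt(max(abs(colMeans(std$z))), 1e-12)
  expect_equal(unname(apply(std$z, 2, lvmech:::.sd_pop)), rep(1, 4))
  expect_equal(unname(standardize_features(std$z)$z), unname(std$z),
               tolerance = 1e-12)
  # two-point column maps to -1/+1
  std2 <- standardize_features(cbind(a = c(0, 2)))
  expect_equal(as.vector(std2$z), c(-1, 1))
  # constant column errors naming the feature
  expect_error(standardize_features(cbind(good = rnorm(10), flat = rep(1, 10))),
               "flat")
})

test_that("rows with missing features are dropped with a count", {
  x <- cbind(a = c(1, 2, NA, 4, 5), b = c(2, 1, 3, 4, 2))
  expect_message(std <- standardize_features(x), "1 rows")
  expect_equal(nrow(std$z), 4)
  expect_equal(std$kept, c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("Ward labels match the naive Lance-Williams reference", {
  blobs <- make_blobs(n_per = 10, seed = 41)   # 40 points, 4 blobs
  w <- ward_cluster(blobs$X, 4)
  ref <- ward_lw_oracle(blobs$X, 4)
  expect_true(same_partition(w$labels, ref))
  expect_true(same_partition(w$labels, blobs$labels))
  # merge heights are monotone non-decreasing
  expect_true(all(diff(w$tree$height) >= -1e-12))
})

test_that("Ward clustering splits separated clouds and respects duplicates", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 30, 0.2), ncol = 2))
  w <- ward_cluster(X, 2)
  expect_true(same_partition(w$labels, rep(1:2, each = 20)))
  # duplicated rows always co-cluster
  Xd <- rbind(X, X)
  wd <- ward_cluster(Xd, 2)
  expect_equal(wd$labels[1:40], wd$labels[41:80])
  expect_error(ward_cluster(X, 1), "k = 1")
  expect_error(ward_cluster(X[1:2, ], 2), "at least 3")
})

test_that("clustering is permutation invariant", {
  blobs <- make_blobs(n_per = 8, seed = 13)
  perm <- sample(nrow(blobs$X))
  w1 <- ward_cluster(blobs$X, 4)
  w2 <- ward_cluster(blobs$X[perm, ], 4)
  expect_true(same_partition(w1$labels[perm], w2$labels))
})

test_that("majority vote finds four separated blobs and survives one blob", {
  blobs <- make_blobs(n_per = 50, sd = 0.6, seed = 23)  # n = 200
  sel <- select_k(blobs$X, 2:8, seed = 5)
  expect_equal(sel$chosen_k, 4L)
  expect_equal(length(sel$votes), 12L)
  # deterministic given data and seed
  sel2 <- select_k(blobs$X, 2:8, seed = 5)
  expect_identical(sel$votes, sel2$votes)
  # a single Gaussian blob: indices disagree but a full vote table comes back
  set.seed(2)
  one <- matrix(rnorm(300), 100, 3)
  sel1 <- select_k(one, 2:6, seed = 5)
  expect_true(sel1$chosen_k %in% 2:6)
  expect_equal(dim(sel1$values), c(12L, 5L))
  expect_error(select_k(one, 2:6, indices = character()), "empty")
})

test_that("characterization flags separated clusters and not identical ones", {
  set.seed(6)
  base <- data.frame(f = rnorm(50), g = factor(rep(c("a", "b"), 25)))
  # identical clusters: the same data labelled twice -> ANOVA p = 1
  tab <- rbind(base, base)
  ch <- characterize_clusters(tab, rep(1:2, each = 50), vars = "f")
  expect_gte(ch$summary$p_value[1], 0.99)
  expect_false(ch$summary$significant[1])
  # 5-SD shift -> flagged at alpha = 0.01
  tab2 <- data.frame(f = c(rnorm(50), rnorm(50, 5)))
  ch2 <- characterize_clusters(tab2, rep(1:2, each = 50), vars = "f")
  expect_true(ch2$summary$significant[1])
  expect_equal(ch2$summary$test[1], "anova")
})

test_that("pairwise t statistics match the closed-form hand calculation", {
  tab <- data.frame(f = c(-1, 0, 1, 2, 3, 4))
  labels <- rep(1:2, each = 3)
  ch <- characterize_clusters(tab, labels, vars = "f")
  # equal-variance t: t = (0 - 3) / sqrt(1 * (1/3 + 1/3)); df = 4
  t_hand <- -3 / sqrt(2 / 3)
  p_hand <- 2 * stats::pt(t_hand, df = 4)
  expect_equal(ch$pairwise$f[1, 2], p_hand, tolerance = 1e-12)
  expect_equal(ch$summary$mean_1, 0)
  expect_equal(ch$summary$mean_2, 3)
  expect_equal(ch$summary$sd_1, 1)
})

test_that("categorical variables get a chi-square test", {
  set.seed(9)
  tab <- data.frame(flag = rep(c(0, 1), c(60, 40)))
  labels <- c(rep(1, 50), rep(2, 50))   # flag strongly depends on cluster
  ch <- characterize_clusters(tab, labels, vars = "flag")
  expect_equal(ch$summary$test[1], "chi_square")
  expect_lt(ch$summary$p_value[1], 0.01)
})

test_that("Pearson correlations hit the exact reference cases", {
  x <- rnorm(30)
  expect_equal(correlate_features(data.frame(x = x, y = x),
                                  cbind("x", "y"))$r, 1)
  expect_equal(correlate_features(data.frame(x = x, y = -x),
                                  cbind("x", "y"))$r, -1)
  y <- rnorm(30)
  y_orth <- residuals(lm(y ~ x))            # orthogonal by construction
  r <- correlate_features(data.frame(x = x - mean(x), y = y_orth),
                          cbind("x", "y"))$r
  expect_lt(abs(r), 1e-12)
})
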