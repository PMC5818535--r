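test_that("linkage classification handles singles, pairs and chains", {
  # all pairwise distances > 250: everything single
  far <- data.frame(x_nm = c(0, 1000, 2000, 3000), y_nm = 0)
  cls <- classify_clusters(far)
  expect_equal(cls$pct_singles, 100)
  expect_equal(cls$n_components, 4L)

  # one pair + two singles: 50% singles, 50% pairs (of vesicles)
  mix <- data.frame(x_nm = c(0, 100, 5000, 9000),
                    y_nm = c(0, 0, 5000, 1000))
  cm <- classify_clusters(mix)
  expect_equal(cm$pct_singles, 50)
  expect_equal(cm$pct_pairs, 50)
  expect_equal(cm$pct_multi, 0)
  expect_equal(cm$pct_singles + cm$pct_pairs + cm$pct_multi, 100,
               tolerance = 0.01)

  # transitive chain A-B-C with A-C > 250 is one cluster of three
  chain <- data.frame(x_nm = c(0, 200, 400), y_nm = 0)
  cc <- classify_clusters(chain)
  expect_equal(cc$pct_multi, 100)
  expect_equal(cc$n_components, 1L)

  # component-based denominators on the same input
  cp <- classify_clusters(mix, denominator = "components")
  expect_equal(cp$pct_singles, 2 / 3 * 100)
  expect_equal(cp$pct_pairs, 1 / 3 * 100)

  expect_error(classify_clusters(data.frame(x_nm = numeric(0),
                                            y_nm = numeric(0))), "empty")
})

test_that("duplicates within 1 nm are merged with a warning", {
  d <- data.frame(x_nm = c(0, 0.5, 5000), y_nm = c(0, 0, 0))
  expect_warning(cls <- classify_clusters(d), "duplicate")
  expect_equal(cls$n_vesicles, 2L)
  expect_equal(cls$pct_singles, 100)
})

test_that("classification is invariant under rigid motions", {
  f <- generate_vesicle_field(seed = 5, preset = "calcium")
  base <- classify_clusters(f)
  th <- 0.7
  rot <- data.frame(
    x_nm = cos(th) * f$x_nm - sin(th) * f$y_nm + 12345,
    y_nm = sin(th) * f$x_nm + cos(th) * f$y_nm - 999)
  expect_equal(classify_clusters(rot)[, 1:3], base[, 1:3])
})

test_that("growing the linkage radius never increases the singles fraction", {
  set.seed(21)
  for (i in 1:5) {
    fld <- data.frame(x_nm = runif(120, 0, 6000), y_nm = runif(120, 0, 6000))
    pct <- vapply(c(100, 250, 400, 800),
                  function(r) classify_clusters(fld, radius = r)$pct_singles,
                  numeric(1))
    expect_true(all(diff(pct) <= 1e-9))
  }
})

test_that("generated fields recover the preset singles fraction", {
  targets <- c(egta = 88, calcium = 84, asyn_ca = 81)
  for (p in names(targets)) {
    pct <- vapply(1:20, function(i) {
      classify_clusters(generate_vesicle_field(seed = i, preset = p))$pct_singles
    }, numeric(1))
    se <- stats::sd(pct) / sqrt(length(pct))
    expect_lte(abs(mean(pct) - targets[[p]]), max(2 * se, 0.5))
  }
})

test_that("generated pair members stay within the linkage radius", {
  f <- generate_vesicle_field(seed = 2, preset = "egta")
  truth <- attr(f, "truth")
  expect_equal(truth$realized_fractions$single, 0.88)
  cls <- classify_clusters(f)
  # construction guarantees: realized classification matches the component
  # sizes exactly (pair members <= 250 nm apart, components > 250 nm apart)
  sizes <- truth$component_sizes
  expect_equal(cls$pct_singles, 100 * sum(sizes == 1) / sum(sizes))
  expect_equal(cls$pct_pairs, 100 * 2 * sum(sizes == 2) / sum(sizes))
})

test_that("condition comparison runs ANOVA with Tukey adjustment", {
  mk <- function(p, seeds) {
    do.call(rbind, lapply(seeds, function(i) {
      classify_clusters(generate_vesicle_field(seed = i, preset = p,
                                               n_vesicles = 150))
    }))
  }
  a <- mk("egta", 1:6)
  b <- mk("asyn_ca", 1:6)
  cmp <- compare_conditions(list(g1 = a, g2 = b))
  sing <- cmp$anova[cmp$anova$category == "singles", ]
  expect_lt(sing$p, 0.01)
  tuk <- cmp$pairwise$singles
  expect_equal(nrow(tuk), 1)

  # swapping which data carries which label flips the mean difference
  cmp2 <- compare_conditions(list(g1 = b, g2 = a))
  expect_equal(cmp2$pairwise$singles$diff, -tuk$diff)

  # identical replicates across conditions: degenerate, flagged not tested
  same <- classify_clusters(generate_vesicle_field(seed = 3, preset = "egta"))
  dup <- rbind(same, same)
  res <- compare_conditions(list(a = dup, b = dup))
  expect_true(all(res$anova$degenerate))

  expect_error(compare_conditions(list(a = a, b = b[1, ])), "'b'")
})
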