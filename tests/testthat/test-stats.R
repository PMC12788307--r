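test_that("ANCOVA matches the normal-equations oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    group <- c(rep("patient", n1), rep("control", n2))
    age <- stats::runif(n1 + n2, 20, 80)
    values <- stats::rnorm(n1 + n2) + 0.02 * age +
      0.5 * (group == "patient")
    got <- ancova_group(values, group, age)
    want <- ne_ancova(values, group, age)
    expect_equal(got$f, want$f, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$df[2], n1 + n2 - 3)
  }
})

test_that("ANCOVA is null when both groups share the same values and ages", {
  vals <- c(1.3, 2.1, 0.7, 1.9, 1.3, 2.1, 0.7, 1.9)
  group <- rep(c("patient", "control"), each = 4)
  age <- rep(c(30, 45, 60, 70), 2)
  got <- ancova_group(vals, group, age)
  expect_lt(got$f, 1e-9)
  expect_gt(got$p, 0.9999)
})

test_that("ANCOVA reduces to one-way ANOVA when age is constant", {
  set.seed(22)
  values <- stats::rnorm(20)
  group <- rep(c("patient", "control"), 10)
  expect_warning(got <- ancova_group(values, group, rep(50, 20)), "degenerate")
  ref <- stats::anova(stats::lm(values ~ factor(group)))
  expect_equal(got$f, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(got$p, ref$`Pr(>F)`[1], tolerance = 1e-8)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(23)
  for (rep in 1:20) {
    p <- stats::runif(sample(2:15, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, stepup_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("Cohen's d uses the pooled SD and patient-minus-control sign", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(5, 6, 7), c(5, 7, 6)), 0)
  set.seed(24)
  a <- stats::rnorm(10); b <- stats::rnorm(12, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("group comparison applies FDR within (task, band) families", {
  set.seed(25)
  regions <- lobe_names()
  feats <- expand.grid(subject_id = sprintf("S%02d", 1:20),
                       task = c("resting", "cognitive"),
                       band = c("alpha", "gamma"),
                       region = regions, stringsAsFactors = FALSE)
  feats$group <- ifelse(as.integer(sub("S", "", feats$subject_id)) <= 8,
                        "patient", "control")
  feats$age <- 30 + as.integer(sub("S", "", feats$subject_id))
  feats$value <- stats::rnorm(nrow(feats))
  out <- run_group_comparison(feats)
  expect_equal(nrow(out), 2 * 2 * 5)
  for (task in c("resting", "cognitive")) for (band in c("alpha", "gamma")) {
    fam <- out[out$task == task & out$band == band, ]
    expect_equal(sort(fam$p_fdr), sort(bh_fdr(fam$p_raw)))
  }
  # permuting rows leaves each family's adjusted p multiset unchanged
  out2 <- run_group_comparison(feats[sample(nrow(feats)), ])
  m1 <- out[order(out$task, out$band, out$feature), ]
  m2 <- out2[order(out2$task, out2$band, out2$feature), ]
  expect_equal(m1$p_fdr, m2$p_fdr)
})

test_that("a family of identical p-values adjusts to that common value", {
  # five regions engineered to give identical group differences
  set.seed(26)
  base <- stats::rnorm(14)
  feats <- do.call(rbind, lapply(lobe_names(), function(rg)
    data.frame(subject_id = sprintf("S%02d", 1:14), task = "resting",
               band = "alpha", region = rg,
               group = rep(c("patient", "control"), each = 7),
               age = rep(seq(30, 60, 5), 2),
               value = base + 0.8 * rep(c(1, 0), each = 7))))
  out <- run_group_comparison(feats)
  expect_equal(length(unique(round(out$p_fdr, 12))), 1)
  expect_equal(out$p_fdr, out$p_raw)  # equal p: step-up keeps the raw value
})

test_that("network features default to raw p (family of one)", {
  set.seed(27)
  feats <- expand.grid(subject_id = sprintf("S%02d", 1:16),
                       task = "resting", band = "delta",
                       metric = c("global_efficiency", "clustering"),
                       stringsAsFactors = FALSE)
  feats$group <- rep(c("patient", "control"), each = 8)
  feats$age <- stats::runif(nrow(feats), 25, 75)
  feats$auc_value <- stats::rnorm(nrow(feats))
  out <- run_group_comparison(feats)
  expect_equal(out$p_fdr, out$p_raw)
  out_fdr <- run_group_comparison(feats, fdr_network = TRUE)
  expect_true(all(out_fdr$p_fdr >= out_fdr$p_raw))
})

test_that("age adjustment shrinks the group F when age drives a confounded outcome", {
  set.seed(28)
  med <- replicate(200, {
    n <- 20
    group <- rep(c("patient", "control"), each = n)
    age <- c(stats::runif(n, 50, 80), stats::runif(n, 20, 50))
    values <- 0.05 * age + stats::rnorm(2 * n, sd = 0.5)
    with_cov <- ancova_group(values, group, age)$f
    without <- stats::anova(stats::lm(values ~ factor(group)))$`F value`[1]
    with_cov < without
  })
  expect_gt(mean(med), 0.5)
})

test_that("d and the ANCOVA group coefficient agree in sign without confounding", {
  set.seed(29)
  agree <- replicate(200, {
    group <- rep(c("patient", "control"), each = 15)
    age <- stats::runif(30, 20, 80)
    values <- stats::rnorm(30) + stats::rnorm(1, 0, 0.5) * (group == "patient")
    d <- cohens_d(values[group == "patient"], values[group == "control"])
    a <- ancova_group(values, group, age)
    sign(d) == a$direction
  })
  expect_gte(mean(agree), 0.99)
})
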