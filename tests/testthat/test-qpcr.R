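mk_ct <- function(df, reference = "Gapdh") {
  if (is.null(df$technical_replicate)) df$technical_replicate <- 1L
  if (is.null(df$group)) df$group <- "g1"
  structure(df, reference_gene = reference,
            class = c("ct_table", "data.frame"))
}

test_that("delta-Ct folds follow the 2^-dCt transform exactly", {
  tab <- mk_ct(data.frame(
    sample_id = rep(c("s1", "s2"), each = 2),
    gene = rep(c("Gapdh", "geneA"), 2),
    ct = c(20, 20, 21, 21)))
  rel <- relative_expression(tab, mode = "delta_ct")
  expect_equal(rel$fold[rel$gene == "geneA"], 1.0)
  expect_equal(rel$sem_fold[rel$gene == "geneA"], 0)
  expect_equal(rel$fold[rel$gene == "Gapdh"], 1.0)

  tab2 <- mk_ct(data.frame(sample_id = c("s1", "s1"),
                           gene = c("Gapdh", "geneA"), ct = c(20, 25)))
  rel2 <- relative_expression(tab2, mode = "delta_ct")
  expect_equal(rel2$fold[rel2$gene == "geneA"], 2^-5)
})

test_that("technical replicates are mean-collapsed before delta-Ct", {
  with_reps <- mk_ct(data.frame(
    sample_id = "s1", gene = c("Gapdh", "geneA", "geneA"),
    technical_replicate = c(1L, 1L, 2L), ct = c(20, 24, 26)))
  single <- mk_ct(data.frame(sample_id = "s1", gene = c("Gapdh", "geneA"),
                             ct = c(20, 25)))
  expect_equal(relative_expression(with_reps)$fold,
               relative_expression(single)$fold)
})

test_that("delta-delta-Ct centers the calibrator group at fold 1", {
  d <- ct_design(c(geneA = 2), ct_noise_sd = 0,
                 group_folds = list(control = numeric(0),
                                    treated = c(geneA = 4)),
                 n_biological = 3)
  ct <- generate_ct_table(d)
  rel <- relative_expression(ct, mode = "delta_delta_ct",
                             calibrator_group = "control")
  expect_equal(rel$fold[rel$gene == "geneA" & rel$group == "control"], 1)
  expect_equal(rel$fold[rel$gene == "geneA" & rel$group == "treated"], 4)
  expect_error(relative_expression(ct, mode = "delta_delta_ct"),
               "calibrator_group")
  expect_error(relative_expression(ct, mode = "delta_delta_ct",
                                   calibrator_group = "nope"), "empty")
})

test_that("folds are invariant to per-sample Ct shifts (loading effects)", {
  d <- ct_design(c(geneA = 3, geneB = 0.5), ct_noise_sd = 0.2,
                 n_biological = 4, seed = 8)
  ct <- generate_ct_table(d)
  base <- relative_expression(ct)
  shifted <- ct
  for (s in unique(ct$sample_id)) {
    shift <- runif(1, -2, 2)
    shifted$ct[shifted$sample_id == s] <- shifted$ct[shifted$sample_id == s] +
      shift
  }
  shifted <- mk_ct(as.data.frame(shifted))
  expect_equal(relative_expression(shifted)$fold, base$fold,
               tolerance = 1e-12)
})

test_that("missing reference gene for a sample is an explicit error", {
  tab <- mk_ct(data.frame(sample_id = c("s1", "s2"),
                          gene = c("Gapdh", "geneA"), ct = c(20, 25)))
  expect_error(relative_expression(tab), "missing for sample")
})

test_that("one-way ANOVA handles flat, degenerate and two-group cases", {
  flat <- rep(c(1, 2, 3), 3)
  g3 <- rep(c("a", "b", "c"), each = 3)
  r <- anova_tukey(flat, g3)
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)
  expect_true(all(r$tukey$adjusted_p == 1))
  expect_equal(r$df_between, 2L)
  expect_equal(r$df_within, 6L)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(13)
  x <- rnorm(8); y <- rnorm(9, 0.7)
  r2 <- anova_tukey(c(x, y), rep(c("x", "y"), c(8, 9)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-9)

  dg <- anova_tukey(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 0)

  expect_error(anova_tukey(1:3, c("a", "a", "b")), "at least 2 observations")
  expect_error(anova_tukey(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("ANOVA F is invariant under location and scale changes", {
  set.seed(17)
  v <- rnorm(15, sd = 2)
  g <- rep(c("a", "b", "c"), each = 5)
  f0 <- anova_tukey(v, g)$F
  expect_equal(anova_tukey(v + 100, g)$F, f0, tolerance = 1e-9)
  expect_equal(anova_tukey(v * 3.7, g)$F, f0, tolerance = 1e-9)
})

test_that("Tukey adjusted p-values match stats::TukeyHSD", {
  set.seed(19)
  for (i in 1:5) {
    v <- rnorm(18, mean = rep(c(0, 0.5, 1.5), each = 6))
    g <- factor(rep(c("a", "b", "c"), each = 6))
    ours <- anova_tukey(v, g)$tukey
    ref <- stats::TukeyHSD(stats::aov(v ~ g))$g
    # TukeyHSD orders pairs b-a, c-a, c-b
    expect_equal(ours$adjusted_p, unname(ref[, "p adj"]), tolerance = 1e-8)
    expect_equal(abs(ours$mean_diff), unname(abs(ref[, "diff"])),
                 tolerance = 1e-12)
  }
})
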