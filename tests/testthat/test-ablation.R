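# Ablation harness and its statistics: replicate bookkeeping, ANOVA and Tukey
# against hand-coded oracles, and the degrees-of-freedom contract.

test_that("the six configurations carry the stated component flags", {
  cfgs <- ablation_configurations()
  expect_equal(nrow(cfgs), 6L)
  expect_equal(cfgs$head, c("softmax", "quantclass", "quantclass", "quantclass",
                            "softmax", "softmax"))
  expect_equal(cfgs$quantvolution_k, c(NA, 2L, 4L, NA, 2L, 4L))
  expect_equal(cfgs$kind[1], "classical")
})

test_that("the replicate grid matches the cross-validation protocol", {
  expect_equal(nrow(ablation_grid(ablation_config(folds = 2, repeats = 1))), 12L)
  # default scheme: 6 configs x 10 folds x 10 repeats = 600 replicates,
  # so the one-way ANOVA has dfs (5, 594)
  grid <- ablation_grid(ablation_config())
  expect_equal(nrow(grid), 600L)
  fake <- withr::with_seed(1, rnorm(nrow(grid)))
  an <- anova_oneway(split(fake, grid$config))
  expect_equal(an$df_between, 5L)
  expect_equal(an$df_within, 594L)
})

test_that("summaries report mean and n-1 standard deviation per configuration", {
  rows <- data.frame(config = rep(0:5, each = 2),
                     label = rep(sprintf("Test #%d", 0:5), each = 2),
                     fold = 1, rep = 1:2,
                     train_loss = 0.5, train_acc = 0.5,
                     val_loss = 0.5, val_acc = 0.5,
                     test_loss = 0.5, test_acc = rep(c(0.4, 0.6), 6),
                     seconds = 1)
  sm <- summarize_ablation(rows)
  expect_equal(nrow(sm), 6L)
  expect_equal(sm$train_acc_mean, rep(0.5, 6))
  expect_equal(sm$train_acc_sd, rep(0, 6))
  expect_equal(sm$test_acc_mean, rep(0.5, 6))
  expect_equal(sm$test_acc_sd, rep(sd(c(0.4, 0.6)), 6), tolerance = 1e-12)
  expect_equal(sm$test_acc_sd[1], 0.1414214, tolerance = 1e-6)
  expect_error(summarize_ablation(rows[rows$rep == 1, ]),
               class = "qtremor_domain_error")
})

test_that("one-way ANOVA matches the brute-force sum-of-squares oracle", {
  withr::with_seed(9, {
    groups <- lapply(1:3, function(i) rnorm(5, mean = i))
    an <- anova_oneway(groups)
    # double-loop oracle
    all_v <- unlist(groups)
    gm <- mean(all_v)
    ssb <- 0; ssw <- 0
    for (g in groups) {
      ssb <- ssb + length(g) * (mean(g) - gm)^2
      for (v in g) ssw <- ssw + (v - mean(g))^2
    }
    expect_equal(an$ss_between, ssb, tolerance = 1e-10)
    expect_equal(an$ss_within, ssw, tolerance = 1e-10)
    sst <- sum((all_v - gm)^2)
    expect_equal(an$ss_between + an$ss_within, sst, tolerance = 1e-9)
    expect_equal(an$f, (ssb / 2) / (ssw / 12), tolerance = 1e-10)
  })
})

test_that("for two groups F equals the squared pooled t statistic", {
  withr::with_seed(11, {
    a <- rnorm(8, 0); b <- rnorm(10, 0.8)
    an <- anova_oneway(list(a, b))
    # independent pooled two-sample t
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
           (length(a) + length(b) - 2)
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(an$f, t_stat^2, tolerance = 1e-9)
    expect_equal(an$p, 2 * pt(-abs(t_stat), length(a) + length(b) - 2),
                 tolerance = 1e-9)
  })
})

test_that("identical constant groups give zero between-group variation", {
  an <- anova_oneway(lapply(1:3, function(i) rep(0.7, 4)))
  expect_equal(an$ss_between, 0, tolerance = 1e-12)
  expect_equal(an$f, 0)
  expect_error(anova_oneway(list(1:3)), class = "qtremor_domain_error")
})

test_that("Tukey HSD produces all pairs with consistent flags and intervals", {
  withr::with_seed(13, {
    groups <- setNames(lapply(1:6, function(i) rnorm(10, mean = c(0, 0, 0, 0, 2, 2)[i])),
                       sprintf("Test #%d", 0:5))
    tk <- tukey_hsd(groups)
    expect_equal(nrow(tk), choose(6, 2))
    # the difference column is the direct subtraction of group means
    for (r in seq_len(nrow(tk))) {
      expect_equal(tk$diff[r],
                   mean(groups[[tk$model2[r]]]) - mean(groups[[tk$model1[r]]]),
                   tolerance = 1e-10)
      expect_true(tk$lo[r] <= tk$diff[r] && tk$diff[r] <= tk$hi[r])
    }
    # significance iff p < alpha iff the interval excludes zero
    expect_equal(tk$significant, tk$p < 0.05)
    expect_equal(tk$significant, tk$lo > 0 | tk$hi < 0)
  })
  # identical groups: all differences zero, nothing significant
  same <- lapply(1:4, function(i) c(0.3, 0.5, 0.7))
  tk0 <- tukey_hsd(same)
  expect_true(all(abs(tk0$diff) < 1e-12))
  expect_false(any(tk0$significant))
})

test_that("a shifted group separates monotonically in the Tukey analysis", {
  base <- withr::with_seed(17, lapply(1:3, function(i) rnorm(12, 0, 0.5)))
  stats_at <- function(shift) {
    g <- base
    g[[1]] <- g[[1]] + shift
    tk <- tukey_hsd(setNames(g, c("A", "B", "C")))
    rows <- tk$model1 == "A" | tk$model2 == "A"
    list(d = mean(abs(tk$diff[rows])), p = max(tk$p[rows]))
  }
  res <- lapply(c(0.5, 1.5, 3), stats_at)
  d <- vapply(res, `[[`, numeric(1), "d")
  p <- vapply(res, `[[`, numeric(1), "p")
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(p) < 0))
})

test_that("a desk-scale ablation run records every replicate deterministically", {
  ds <- generate_dataset(24, seed = 8)
  cfg <- ablation_config(folds = 2, repeats = 1,
                         train = train_config(epochs = 1, lr0 = 3e-3, seed = 1),
                         base_seed = 5)
  rows <- run_ablation(ds, cfg)
  expect_equal(nrow(rows), 12L)                 # 6 configs x 2 folds x 1 repeat
  expect_equal(sort(unique(rows$config)), 0:5)
  expect_true(all(rows$test_acc >= 0 & rows$test_acc <= 1))
  expect_true(all(rows$train_loss >= 0))
  rows2 <- run_ablation(ds, cfg)
  expect_equal(rows$test_acc, rows2$test_acc)
  expect_equal(rows$train_loss, rows2$train_loss)
  # fold count above the smallest class count is refused
  expect_error(run_ablation(ds, ablation_config(folds = 12, repeats = 1)),
               class = "qtremor_domain_error")
})

test_that("reports land as three CSV tables and a JSON bundle", {
  withr::with_seed(19, {
    acc <- lapply(0:5, function(i) rnorm(6, mean = 70 + 5 * i, sd = 2))
    names(acc) <- sprintf("Test #%d", 0:5)
    rows <- data.frame(config = rep(0:5, each = 6),
                       label = rep(names(acc), each = 6),
                       fold = rep(1:3, 12), rep = rep(1:2, 18),
                       train_loss = 0.2, train_acc = 0.9,
                       val_loss = 0.3, val_acc = 0.8,
                       test_loss = 0.3, test_acc = unlist(acc) / 100,
                       seconds = 1)
    dir <- withr::local_tempdir()
    p <- ablation_report(summarize_ablation(rows), anova_oneway(acc),
                         tukey_hsd(acc), dir)
    expect_true(all(file.exists(file.path(dir, c("summary.csv", "anova.csv",
                                                 "tukey.csv", "ablation.json")))))
    tk <- utils::read.csv(file.path(dir, "tukey.csv"))
    expect_equal(nrow(tk), choose(6, 2))
    # deterministic output
    before <- tools::md5sum(p)
    ablation_report(summarize_ablation(rows), anova_oneway(acc), tukey_hsd(acc), dir)
    expect_identical(tools::md5sum(p), before)
  })
})
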