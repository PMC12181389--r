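# Six-configuration ablation harness: replicated training under k-fold
# cross-validation, and its statistical analysis (one-way ANOVA + Tukey HSD on
# per-replicate test accuracy in percent).

#' The six ablation configurations
#'
#' * #0 classical baseline (no QuantClass, no filter)
#' * #1 QuantClass + Quantvolution 2x2
#' * #2 QuantClass + Quantvolution 4x4
#' * #3 QuantClass, no Quantvolution
#' * #4 no QuantClass (softmax head) + Quantvolution 2x2
#' * #5 no QuantClass (softmax head) + Quantvolution 4x4
#'
#' @param head_mode QuantClass circuit mode for the headed configurations.
#' @return data.frame with one row per configuration.
#' @export
ablation_configurations <- function(head_mode = "functional") {
  data.frame(
    config = 0:5,
    label = c("Test #0", "Test #1", "Test #2", "Test #3", "Test #4", "Test #5"),
    kind = c("classical", rep("hybrid", 5)),
    head = c("softmax", "quantclass", "quantclass", "quantclass", "softmax", "softmax"),
    quantvolution_k = c(NA, 2L, 4L, NA, 2L, 4L),
    head_mode = head_mode,
    stringsAsFactors = FALSE
  )
}

config_model_spec <- function(row) {
  qv <- if (is.na(row$quantvolution_k)) NULL else quantvolution_config(k = row$quantvolution_k)
  model_spec(kind = row$kind, quantvolution = qv, head = row$head,
             head_mode = row$head_mode)
}

#' Ablation study configuration
#'
#' The full protocol is `folds = 10` rotating test folds with `repeats = 10`
#' re-initialisations each, giving 100 replicates per configuration and ANOVA
#' degrees of freedom (5, 594) over the 6 x 100 runs. Training always runs the
#' fixed epoch count.
#'
#' @param folds number of rotating test folds (default 10).
#' @param repeats re-seeded repeats per fold (default 10).
#' @param train a [train_config()]; its `epochs` is the fixed epoch count
#'   (default 100).
#' @param head_mode QuantClass mode for the headed configurations.
#' @param base_seed integer seed from which every replicate's seed derives.
#' @return list of class `ablation_config`.
#' @export
ablation_config <- function(folds = 10L, repeats = 10L,
                            train = train_config(),
                            head_mode = c("functional", "literal"),
                            base_seed = 1L) {
  if (folds < 2L) qt_stop("folds must be >= 2", class = "qtremor_domain_error")
  if (repeats < 1L) qt_stop("repeats must be >= 1", class = "qtremor_domain_error")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 train = train, head_mode = match.arg(head_mode),
                 base_seed = as.integer(base_seed)),
            class = "ablation_config")
}

#' Replicate grid of an ablation study
#'
#' @param cfg an [ablation_config()].
#' @return data.frame with one row per (config, fold, repeat) replicate.
#' @export
ablation_grid <- function(cfg) {
  expand.grid(config = 0:5, fold = seq_len(cfg$folds),
              rep = seq_len(cfg$repeats), KEEP.OUT.ATTRS = FALSE)
}

# Stratified fold assignment: within each class, shuffle and deal into folds.
fold_assignment <- function(labels, folds, seed) {
  if (min(table(labels)) < folds) {
    qt_stop("fold count exceeds the smallest per-class count",
            class = "qtremor_domain_error")
  }
  f <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  f
}

#' Run the six-configuration ablation study
#'
#' Each configuration is trained under `folds`-fold cross-validation: the test
#' fold rotates, the remaining pool is re-partitioned per replicate into
#' training and validation (one tenth of the images validate), and repeats
#' re-seed the initialisation and training randomness. Quantvolution feature
#' maps are computed once per resolution and shared by every replicate.
#'
#' @param dataset a [generate_dataset()] result.
#' @param cfg an [ablation_config()].
#' @return data.frame of class `ablation_metrics`: one row per (config, fold,
#'   repeat) with loss/accuracy for all three splits and wall-clock seconds.
#' @export
run_ablation <- function(dataset, cfg = ablation_config()) {
  configs <- ablation_configurations(cfg$head_mode)
  n <- length(dataset$images)
  folds <- fold_assignment(dataset$labels, cfg$folds, derive_seed(cfg$base_seed, 31L))
  n_val <- max(1L, n %/% 10L)

  # preprocess once per input representation
  specs <- lapply(seq_len(nrow(configs)), function(i) config_model_spec(configs[i, ]))
  rep_key <- vapply(specs, function(s) {
    if (is.null(s$quantvolution)) paste0(s$kind, "_raw") else
      paste0("qv", s$quantvolution$k)
  }, character(1))
  prepared <- list()
  for (key in unique(rep_key)) {
    prepared[[key]] <- prepare_inputs(dataset, specs[[match(key, rep_key)]])
  }

  grid <- ablation_grid(cfg)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ci <- grid$config[g]; fo <- grid$fold[g]; rp <- grid$rep[g]
    spec <- specs[[ci + 1L]]
    data <- prepared[[rep_key[ci + 1L]]]
    seed <- derive_seed(cfg$base_seed, ci, fo, rp)
    pool <- which(folds != fo)
    val_idx <- with_seed(derive_seed(seed, 3L), sample(pool, n_val))
    split <- rep("train", n)
    split[folds == fo] <- "test"
    split[val_idx] <- "val"
    dat <- list(x = data$x, y = data$y,
                split = factor(split, levels = c("train", "val", "test")))
    model <- build_model(spec, seed = derive_seed(seed, 5L))
    tc <- cfg$train; tc$seed <- derive_seed(seed, 9L)
    res <- train(model, dat, tc)
    m <- res$metrics
    rows[[g]] <- data.frame(
      config = ci, label = configs$label[ci + 1L], fold = fo, rep = rp,
      train_loss = m$train$loss, train_acc = m$train$accuracy,
      val_loss = m$val$loss, val_acc = m$val$accuracy,
      test_loss = m$test$loss, test_acc = m$test$accuracy,
      seconds = res$seconds
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ablation_metrics", "data.frame")
  out
}

#' Per-configuration summary (mean and sample sd)
#'
#' @param rows an `ablation_metrics` data.frame.
#' @return data.frame with one row per configuration, mean and sd (n-1
#'   denominator) of every metric, mirroring the study's summary table layout.
#' @export
summarize_ablation <- function(rows) {
  if (any(table(rows$config) < 2L)) {
    qt_stop("need at least 2 replicates per configuration for a standard deviation",
            class = "qtremor_domain_error")
  }
  metrics <- c("train_loss", "train_acc", "val_loss", "val_acc",
               "test_loss", "test_acc")
  out <- do.call(rbind, lapply(split(rows, rows$config), function(d) {
    stats <- unlist(lapply(metrics, function(m) {
      c(mean(d[[m]]), sd(d[[m]]))
    }))
    names(stats) <- as.vector(rbind(paste0(metrics, "_mean"), paste0(metrics, "_sd")))
    cbind(data.frame(config = d$config[1], label = d$label[1], n = nrow(d)),
          as.data.frame(as.list(stats)))
  }))
  out$time_s <- vapply(split(rows, rows$config), function(d) sum(d$seconds), numeric(1))
  rownames(out) <- NULL
  out
}

#' One-way ANOVA across groups
#'
#' Standard fixed-effects decomposition, `F = MS_between / MS_within`, p from
#' the upper tail of the F distribution (computed via [stats::aov()]).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list of class `anova_result` with `ss_between`, `df_between`,
#'   `ss_within`, `df_within`, `f` and `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    qt_stop("need >= 2 groups with >= 2 values each", class = "qtremor_domain_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)),
              labels = names(groups) %||% paste0("g", seq_along(groups)))
  tab <- summary(aov(values ~ g))[[1]]
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (tab$`Sum Sq`[1] <= 1e-10 * (sum(values^2) + 1)) {
    f <- 0; p <- 1      # no between-group variation beyond rounding noise
  }
  structure(list(ss_between = tab$`Sum Sq`[1], df_between = tab$Df[1],
                 ss_within = tab$`Sum Sq`[2], df_within = tab$Df[2],
                 f = f, p = p),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: SS_b %.4g (df %d), SS_w %.4g (df %d), F = %.4g, p = %.4g\n",
              x$ss_between, x$df_between, x$ss_within, x$df_within, x$f, x$p))
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All `choose(g, 2)` pairwise mean differences with studentized-range p-values
#' and simultaneous confidence intervals (Tukey-Kramer for unequal group
#' sizes), computed via [stats::TukeyHSD()]. The difference reported for a pair
#' (model1, model2) is `mean(model2) - mean(model1)`.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level (default 0.05; the confidence level is
#'   `1 - alpha`).
#' @return data.frame with columns `model1`, `model2`, `diff`, `p`, `lo`, `hi`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    qt_stop("need >= 2 groups with >= 2 values each", class = "qtremor_domain_error")
  }
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)), labels = nm)
  tk <- TukeyHSD(aov(values ~ g), conf.level = 1 - alpha)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    model1 = vapply(pairs, `[`, character(1), 2L),
    model2 = vapply(pairs, `[`, character(1), 1L),
    diff = tk[, "diff"], p = tk[, "p adj"],
    lo = tk[, "lwr"], hi = tk[, "upr"]
  )
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  # order rows by (model1, model2) position as listed in `groups`
  out[order(match(out$model1, nm), match(out$model2, nm)), , drop = FALSE]
}

#' Write the ablation report
#'
#' Three CSV tables (per-configuration summary, ANOVA, Tukey HSD) plus a JSON
#' bundle with deterministic field order.
#'
#' @param summary output of [summarize_ablation()].
#' @param anova output of [anova_oneway()].
#' @param tukey output of [tukey_hsd()].
#' @param dir output directory (created if missing).
#' @return invisibly, the JSON path.
#' @export
ablation_report <- function(summary, anova, tukey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(summary, file.path(dir, "summary.csv"), row.names = FALSE)
  adf <- data.frame(source = c("C(test)", "Residual"),
                    sum_sq = c(anova$ss_between, anova$ss_within),
                    df = c(anova$df_between, anova$df_within),
                    f = c(anova$f, NA), p = c(anova$p, NA))
  write.csv(adf, file.path(dir, "anova.csv"), row.names = FALSE)
  write.csv(tukey, file.path(dir, "tukey.csv"), row.names = FALSE)
  path <- file.path(dir, "ablation.json")
  jsonlite::write_json(list(summary = summary, anova = unclass(anova),
                            tukey = tukey),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
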