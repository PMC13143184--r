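# Metrics: confusion matrices, micro/macro accuracy, per-class
# precision/recall/F1, amplitude variability.

test_that("confusion matrices count exactly", {
  truth <- c("a", "a", "b")
  pred <- c("a", "b", "b")
  cm <- confusion_matrix(truth, pred, labels = c("a", "b"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(true = c("a", "b"),
                                      predicted = c("a", "b"))))
  expect_equal(sum(cm), 3)
  all_right <- confusion_matrix(c("a", "b", "b"), c("a", "b", "b"),
                                c("a", "b"))
  expect_true(all(unclass(all_right)[row(all_right) != col(all_right)] == 0))
  expect_error(confusion_matrix("a", "z", labels = "a"), "unknown label")

  pc <- row_percentages(cm)
  expect_equal(unname(rowSums(pc)), c(100, 100))
})

test_that("micro accuracy follows the correct/total definition", {
  cm <- confusion_matrix(rep(c("a", "b"), c(60, 40)),
                         c(rep("a", 50), rep("b", 10), rep("b", 40)),
                         c("a", "b"))
  expect_equal(accuracy_micro(cm), 0.9)
  # micro and macro differ on unbalanced rows...
  expect_equal(accuracy_macro(cm), mean(c(50 / 60, 1)))
  expect_false(isTRUE(all.equal(accuracy_micro(cm), accuracy_macro(cm))))
  # ...and coincide exactly on balanced ones
  set.seed(1)
  truth <- rep(regime_levels(), each = 25)
  pred <- ifelse(runif(200) < 0.8, truth, sample(regime_levels(), 200, TRUE))
  cmb <- confusion_matrix(truth, pred)
  expect_equal(accuracy_micro(cmb), accuracy_macro(cmb), tolerance = 1e-12)

  diagm <- confusion_matrix(rep("a", 3), rep("a", 3), c("a"))
  expect_equal(accuracy_micro(diagm), 1.0)
})

test_that("per-class metrics use one-versus-rest counts with NA sentinels", {
  cm <- confusion_matrix(c("a", "a", "a", "b", "b", "c"),
                         c("a", "a", "b", "b", "a", "b"),
                         labels = c("a", "b", "c"))
  m <- class_metrics(cm)
  expect_equal(m$precision[m$class == "a"], 2 / 3)
  expect_equal(m$recall[m$class == "a"], 2 / 3)
  expect_equal(m$f1[m$class == "a"], 2 / 3)
  # class c is never predicted: precision undefined, not zero
  expect_true(is.na(m$precision[m$class == "c"]))
  expect_true(is.na(m$f1[m$class == "c"]))
  expect_equal(m$recall[m$class == "c"], 0)
  # F1 lies between precision and recall; equals them when they agree
  expect_equal(f1_score(0.7, 0.7), 0.7)
  for (i in seq_len(nrow(m))) {
    if (!is.na(m$f1[i])) {
      expect_gte(m$f1[i], min(m$precision[i], m$recall[i]) - 1e-12)
      expect_lte(m$f1[i], max(m$precision[i], m$recall[i]) + 1e-12)
    }
  }
})

test_that("amplitude variability is near zero for strict alternation and grows with jitter", {
  make_series <- function(jitter, seed = 1) {
    set.seed(seed)
    amps <- rep(c(1, 0.4), 10) * (1 + rnorm(20, 0, jitter))
    prepare_input(make_cycle_signal(amps))
  }
  series <- rbind(make_series(0), make_series(0.02), make_series(0.1))
  out <- amplitude_variability(series, rep("period2", 3))
  expect_equal(nrow(out), 3)
  expect_lt(out$max_variability[1], 0.02)
  expect_true(all(out$max_variability >= 0 & out$max_variability <= 1.5))
  expect_true(all(diff(out$max_variability) > 0))
  expect_equal(out$misclassified, rep(FALSE, 3))

  expect_warning(
    amplitude_variability(matrix(rep(0.5, 2000), 2), rep("period2", 2)),
    "excluded")
})
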