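test_that("AUROC equals the tie-adjusted pairwise probability on known cases", {
  rc <- roc_curve(c(3, 4, 5, 1, 2, 3), rep(c("AD", "Nold"), each = 3))
  expect_equal(auroc(rc), 8.5 / 9)
  expect_equal(auroc(rc), oracle_pairwise_auc(c(3, 4, 5), c(1, 2, 3)))

  # perfect separation
  rc2 <- roc_curve(c(10, 11, 12, 1, 2), c("AD", "AD", "AD", "Nold", "Nold"))
  expect_equal(auroc(rc2), 1)
  expect_true(any(rc2$points$sensitivity == 1 & rc2$points$specificity == 1))

  # all values identical: all ties, chance level
  rc3 <- roc_curve(rep(2, 6), rep(c("AD", "Nold"), 3))
  expect_equal(auroc(rc3), 0.5)
})

test_that("orientation flips so AUROC >= 0.5 and the flip is recorded", {
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c("AD", "AD", "AD", "Nold", "Nold", "Nold")   # AD lower
  rc <- roc_curve(vals, labs)
  expect_true(rc$flipped)
  raw <- oracle_pairwise_auc(vals[1:3], vals[4:6])
  expect_equal(auroc(rc), 1 - raw)
  expect_gte(auroc(rc), 0.5)
})

test_that("AUROC is invariant under strictly increasing transforms", {
  set.seed(40)
  vals <- rnorm(30)
  labs <- rep(c("AD", "Nold"), 15)
  a1 <- auroc(roc_curve(vals, labs))
  expect_equal(auroc(roc_curve(exp(vals), labs)), a1)
  expect_equal(auroc(roc_curve(rank(vals), labs)), a1)
})

test_that("AUROC matches an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (r in 1:10) {
    vals <- round(rnorm(40), 1)   # rounding forces ties
    labs <- sample(rep(c("AD", "Nold"), 20))
    ours <- auroc(roc_curve(vals, labs))
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labs, vals, levels = c("Nold", "AD")))
    ))
    expect_equal(ours, max(ref, 1 - ref), tolerance = 1e-9)
  }
})

test_that("permuted labels give chance-level AUROC on average", {
  set.seed(42)
  vals <- rnorm(60)
  aucs <- vapply(1:200, function(r) {
    labs <- sample(rep(c("AD", "Nold"), 30))
    raw <- oracle_pairwise_auc(vals[labs == "AD"], vals[labs == "Nold"])
    raw  # unoriented, to see symmetric scatter around 0.5
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("the operating point maximizes Youden with the stated tie-breaks", {
  # sens 0.8 / spec 0.6 style case: accuracy is the mean
  rc <- roc_curve(c(1, 3, 4, 5, 7, 2, 2.5, 3.5, 4.5, 6),
                  rep(c("AD", "Nold"), each = 5))
  op <- operating_point(rc)
  expect_equal(op$accuracy, (op$sensitivity + op$specificity) / 2)
  J <- rc$points$sensitivity + rc$points$specificity - 1
  expect_equal(op$youden, max(J))

  # equal-J tie broken toward higher specificity
  rc2 <- roc_curve(c(2, 4, 1, 3), c("AD", "AD", "Nold", "Nold"))
  p2 <- rc2$points
  ties <- which(p2$sensitivity + p2$specificity - 1 ==
                  max(p2$sensitivity + p2$specificity - 1))
  expect_equal(operating_point(rc2)$specificity, max(p2$specificity[ties]))

  # perfect separation reaches J = 1
  expect_equal(operating_point(roc_curve(c(5, 6, 1, 2), c("AD", "AD", "Nold", "Nold")))$youden, 1)
})

test_that("marker evaluation reports screened markers sorted by AUROC with strict selection", {
  set.seed(43)
  n <- 10
  meta <- tibble::tibble(subject = paste0("s", 1:(2 * n)),
                         group = rep(c("AD", "Nold"), each = n))
  # 'exact70' engineered to AUROC = 0.70 exactly; 'strong' clearly higher;
  # 'null' identical across groups (fails the screen)
  mt <- dplyr::bind_rows(
    tibble::tibble(subject = meta$subject, marker = "exact70",
                   value = c(rep(7.5, n), 1:n)),
    tibble::tibble(subject = meta$subject, marker = "strong",
                   value = c(rnorm(n, 3), rnorm(n, 0))),
    tibble::tibble(subject = meta$subject, marker = "null",
                   value = rep(seq_len(n), 2))
  )
  expect_equal(auroc(roc_curve(mt$value[mt$marker == "exact70"], meta$group)), 0.70)
  sc <- screen_markers(mt, meta, direction = "auto")
  expect_false(sc$selected[sc$marker == "null"])
  rs <- evaluate_markers(mt, sc, meta)
  expect_equal(rs$marker[1], "strong")
  expect_false("null" %in% rs$marker)
  expect_false(rs$selected[rs$marker == "exact70"])  # strict > 0.70
  expect_true(all(diff(rs$auroc) <= 0))
  expect_equal(rs$accuracy, (rs$sensitivity + rs$specificity) / 2)

  # empty screened set: warning and empty report
  mt_null <- mt[mt$marker == "null", ]
  sc_null <- screen_markers(mt_null, meta, direction = "auto")
  expect_warning(rs0 <- evaluate_markers(mt_null, sc_null, meta), "no markers")
  expect_equal(nrow(rs0), 0)
})

test_that("tidiers and autoplot produce the documented shapes", {
  rc <- roc_curve(c(3, 4, 5, 1, 2, 3), rep(c("AD", "Nold"), each = 3))
  td <- tidy(rc)
  expect_true(all(c("threshold", "sensitivity", "specificity", "fpr") %in% names(td)))
  gl <- glance(rc)
  expect_equal(gl$auroc, auroc(rc))
  expect_equal(gl$accuracy, (gl$sensitivity + gl$specificity) / 2)
  p <- ggplot2::autoplot(rc)
  expect_s3_class(p, "ggplot")
})
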