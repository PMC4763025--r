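make_activity <- function(values) {
  # values: named list subject -> named band values for one ROI ("occipital")
  purrr::imap_dfr(values, function(v, subj) {
    tidyr::expand_grid(roi = roi_names(), band = names(v)) |>
      dplyr::mutate(subject = subj, value = rep(unname(v), 6), .before = 1)
  })
}

test_that("ratio markers divide numerator by denominator band at the same ROI", {
  act <- make_activity(list(s1 = c(delta = 1.4, theta = 1, alpha1 = 0.7, alpha2 = 0.7),
                            s2 = c(delta = 2, theta = 2, alpha1 = 2, alpha2 = 1)))
  reg <- default_marker_registry()[default_marker_registry()$source == "activity", ]
  mt <- build_markers(act, registry = reg)
  expect_equal(mt$value[mt$marker == "occipital_delta_alpha1" & mt$subject == "s1"], 2)
  expect_equal(mt$value[mt$marker == "occipital_delta_alpha1" & mt$subject == "s2"], 1)
  expect_equal(length(unique(mt$marker)), 12)

  act0 <- act; act0$value[act0$band == "alpha1" & act0$subject == "s1"] <- 0
  expect_error(build_markers(act0, registry = reg), "zero denominator.*s1")
})

test_that("the default registry yields 18 composite markers on a processed cohort", {
  op <- fx_inverse()
  per <- purrr::map(fx_cohort(), process_subject, op = op)
  act <- purrr::map_dfr(per, "activity")
  llc <- purrr::map_dfr(per, "llc")
  mt <- build_markers(act, llc)
  expect_equal(length(unique(mt$marker)), 18)
  expect_equal(nrow(mt), 18 * 8)
  reg <- attr(mt, "registry")
  expect_equal(sum(reg$source == "activity"), 12)
  expect_equal(sum(reg$source == "llc"), 6)
  # with the simple alpha1 connectivity candidate
  mt2 <- build_markers(act, llc, default_marker_registry(include_simple = TRUE))
  expect_equal(length(unique(mt2$marker)), 19)
})

test_that("ratio markers are invariant to the grand normalization constant", {
  act <- make_activity(list(s1 = c(delta = 1.4, theta = 1, alpha1 = 0.7, alpha2 = 0.5)))
  reg <- default_marker_registry()[default_marker_registry()$source == "activity", ]
  act_sc <- act; act_sc$value <- act_sc$value * 37.3
  expect_equal(build_markers(act_sc, registry = reg)$value,
               build_markers(act, registry = reg)$value)
})

test_that("screening is label-symmetric and reduces to the plain test under null covariates", {
  set.seed(30)
  n <- 20
  meta <- tibble::tibble(subject = paste0("s", 1:(2 * n)),
                         group = rep(c("Nold", "AD"), each = n),
                         age = rnorm(2 * n, 70, 5), constant = 1)
  mt <- tibble::tibble(subject = rep(meta$subject, 2),
                       marker = rep(c("m1", "m2"), each = 2 * n),
                       value = c(rnorm(2 * n) + rep(c(0, 1), each = n), rnorm(2 * n)))
  sc <- screen_markers(mt, meta, direction = "auto")
  meta_sw <- meta; meta_sw$group <- ifelse(meta$group == "AD", "Nold", "AD")
  sc_sw <- screen_markers(mt, meta_sw, direction = "auto")
  expect_equal(abs(sc$t), abs(sc_sw$t))
  expect_equal(sc$selected, sc_sw$selected)
  expect_false(identical(sc$direction, sc_sw$direction))

  sc_cov <- screen_markers(mt, meta, covariates = "constant", direction = "auto")
  expect_equal(sc_cov$t, sc$t)
  expect_equal(sc_cov$p, sc$p)
})

test_that("degenerate markers are handled: constant values and exactly equal means", {
  meta <- tibble::tibble(subject = paste0("s", 1:8),
                         group = rep(c("Nold", "AD"), each = 4))
  mt_const <- tibble::tibble(subject = meta$subject, marker = "flat", value = 5)
  expect_warning(sc <- screen_markers(mt_const, meta, direction = "greater"), "constant")
  expect_equal(sc$p, 1)
  expect_false(sc$selected)

  v <- c(1, 2, 3, 4)
  mt_eq <- tibble::tibble(subject = meta$subject, marker = "m", value = c(v, v))
  sc2 <- screen_markers(mt_eq, meta, direction = "greater")
  expect_equal(sc2$t, 0)
  expect_equal(sc2$p, 0.5)
  expect_false(sc2$selected)
})

test_that("a d = 1 shift is detected with high power at n = 30 per group", {
  set.seed(31)
  n <- 30; reps <- 200
  meta <- tibble::tibble(subject = paste0("s", 1:(2 * n)),
                         group = rep(c("Nold", "AD"), each = n))
  hits <- vapply(seq_len(reps), function(r) {
    mt <- tibble::tibble(subject = meta$subject, marker = "m",
                         value = rnorm(2 * n) + ifelse(meta$group == "AD", 1, 0))
    screen_markers(mt, meta, direction = "greater")$selected
  }, TRUE)
  expect_gt(mean(hits), 0.9)
})

test_that("covariate residualization removes a confounded association", {
  set.seed(32)
  n <- 40
  age <- c(rnorm(n, 78, 3), rnorm(n, 65, 3))   # AD older by design
  meta <- tibble::tibble(subject = paste0("s", 1:(2 * n)),
                         group = rep(c("AD", "Nold"), each = n), age = age)
  # marker depends on age only, not on group
  mt <- tibble::tibble(subject = meta$subject, marker = "m",
                       value = 0.1 * age + rnorm(2 * n, sd = 0.1))
  raw <- screen_markers(mt, meta, direction = "greater")
  adj <- screen_markers(mt, meta, covariates = "age", direction = "greater")
  expect_true(raw$selected)       # confounding drives the unadjusted test
  expect_lt(abs(adj$t), abs(raw$t) / 2)
})
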