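fake_qflow <- function() {
  tibble::tibble(
    subject_id = rep(c("A", "B"), each = 4),
    setpoint = rep(c("EIV", "FV", "PV", "GSV"), 2),
    sv = c(5, 4, 1, 0.3, 5, 4, 1.2, 0.5),
    ffv = c(5, 4, 1, 0.5, 5, 4, 1.2, 0.5),
    asv = c(5, 4, 1, 0.7, 5, 4, 1.2, 0.5),
    mf = c(5, 4, 1, 2, 5, 4, 1, 0.4),
    sd = c(4, 3, 2, 1, 4, 3, 2, 1),
    mv = c(4, 3, 2, 1.5, 4, 3, 2, 0.8))
}

fake_labels <- tibble::tibble(subject_id = c("A", "B"), label = c(1L, 0L))

test_that("ratio features divide GSV by PV values", {
  f <- build_features(fake_qflow(), fake_labels)
  a <- f[f$subject_id == "A", ]
  expect_equal(a$mf_gsv_pv, 2)          # GSV MF 2.0 over PV MF 1.0
  expect_equal(a$sd_gsv_pv, 0.5)
  expect_equal(a$sv_gsv, 0.3)
  expect_equal(a$label, 1L)
})

test_that("feature schema is fixed: six named columns in stable order", {
  f <- build_features(fake_qflow(), fake_labels)
  expect_identical(attr(f, "feature_names"),
                   c("sv_gsv", "ffv_gsv", "asv_gsv", "mf_gsv",
                     "sd_gsv_pv", "mf_gsv_pv"))
  expect_identical(names(f),
                   c("subject_id", "sv_gsv", "ffv_gsv", "asv_gsv", "mf_gsv",
                     "sd_gsv_pv", "mf_gsv_pv", "label"))
  fm <- build_features(fake_qflow(), fake_labels, ratio = "mv")
  expect_identical(attr(fm, "feature_names")[6], "mv_gsv_pv")
  expect_equal(fm$mv_gsv_pv[fm$subject_id == "A"], 0.75)
})

test_that("subjects with a zero PV denominator are excluded with a reason", {
  q <- fake_qflow()
  q$mf[q$subject_id == "B" & q$setpoint == "PV"] <- 0
  expect_message(f <- build_features(q, fake_labels), "excluded")
  expect_equal(nrow(f), 1L)
  excl <- attr(f, "excluded")
  expect_equal(excl$subject_id, "B")
  expect_match(excl$reason, "zero PV")
})

test_that("subjects missing a setpoint are excluded with a reason", {
  q <- fake_qflow()
  q <- q[!(q$subject_id == "A" & q$setpoint == "GSV"), ]
  expect_message(f <- build_features(q, fake_labels), "missing")
  expect_equal(f$subject_id, "B")
})

test_that("the default cohort yields 41 vectors with 26 positives", {
  co <- generate_cohort(seed = 12, render = FALSE)
  f <- build_features(batch_qflow(co))
  expect_equal(nrow(f), 41L)
  expect_equal(sum(f$label == 1L), 26L)
  expect_true(all(is.finite(as.matrix(f[, attr(f, "feature_names")]))))
})

test_that("the standardizer centers and scales, and round-trips", {
  f <- tibble::tibble(a = c(0, 2), b = c(0, 2))
  attr(f, "feature_names") <- c("a", "b")
  s <- fit_standardizer(f)
  z <- apply_standardizer(f, s)
  expect_equal(unname(as.matrix(z)), matrix(c(-1, 1, -1, 1), 2, 2))
  set.seed(8)
  g <- tibble::tibble(a = rnorm(30, 5, 2), b = runif(30), c = rnorm(30, -3, 9))
  attr(g, "feature_names") <- c("a", "b", "c")
  sg <- fit_standardizer(g)
  zg <- apply_standardizer(g, sg)
  zm <- as.matrix(zg)
  expect_true(all(abs(colMeans(zm)) < 1e-10))
  expect_equal(unname(sqrt(colMeans(sweep(zm, 2, colMeans(zm))^2))), rep(1, 3))
  expect_equal(rbf_sigma(zm), 1)
  back <- invert_standardizer(zg, sg)
  expect_equal(as.matrix(back), as.matrix(g), tolerance = 1e-12)
})

test_that("zero-dispersion features are rejected by the standardizer", {
  f <- tibble::tibble(a = c(1, 1, 1), b = c(1, 2, 3))
  attr(f, "feature_names") <- c("a", "b")
  expect_error(fit_standardizer(f), "zero-dispersion")
})
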