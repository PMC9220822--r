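test_that("Haar single level reproduces the pairwise hand computation", {
  sp <- wavelet_spec("haar", padding = "periodic")
  r <- dwt_single_level(c(4, 6, 10, 12), sp)
  # (a+b)/sqrt(2) and (a-b)/sqrt(2) per non-overlapping pair
  expect_equal(r$approx, c(10, 22) / sqrt(2), tolerance = 1e-12)
  expect_equal(r$detail, c(-2, -2) / sqrt(2), tolerance = 1e-12)
  expect_equal(round(r$approx, 4), c(7.0711, 15.5563))
  expect_equal(round(r$detail, 4), c(-1.4142, -1.4142))

  const <- dwt_single_level(rep(3.7, 16), sp)
  expect_true(all(abs(const$detail) < 1e-12))
})

test_that("multilevel cascade equals repeated single-level application", {
  sp <- wavelet_spec("haar", padding = "periodic")
  x <- as.numeric(1:8)
  s1 <- dwt_single_level(x, sp)
  s2 <- dwt_single_level(s1$approx, sp)
  d <- dwt_multilevel(x, sp, level = 2)
  expect_equal(d$details[[1]], s1$detail)
  expect_equal(d$details[[2]], s2$detail)
  expect_equal(d$approx, s2$approx)

  d1 <- dwt_multilevel(x, sp, level = 1)
  expect_equal(d1$approx, s1$approx)
  expect_equal(d1$details[[1]], s1$detail)
})

test_that("reconstruction is exact for every shipped wavelet, mode and depth", {
  set.seed(41)
  for (nm in c("haar", "db2", "db3", "db4")) {
    for (pd in c("periodic", "symmetric", "zero")) {
      sp <- wavelet_spec(nm, padding = pd)
      for (n in c(64, 100, 256)) {
        x <- rnorm(n)
        for (lev in seq_len(min(4L, max_dwt_level(n, sp)))) {
          rec <- idwt(dwt_multilevel(x, sp, lev))
          expect_lt(max(abs(rec - x)), 1e-8)
        }
      }
    }
  }
})

test_that("periodic-padding transform conserves energy (Parseval)", {
  set.seed(42)
  for (nm in c("haar", "db2", "db4")) {
    sp <- wavelet_spec(nm, padding = "periodic")
    x <- rnorm(256)
    s <- dwt_single_level(x, sp)
    expect_lt(abs(sum(s$approx^2) + sum(s$detail^2) - sum(x^2)), 1e-8)
    d <- dwt_multilevel(x, sp, 3)
    coef_energy <- sum(d$approx^2) + sum(unlist(d$details)^2)
    expect_lt(abs(coef_energy - sum(x^2)), 1e-8)
  }
})

test_that("coefficients agree with the PyWavelets oracle in every mode", {
  set.seed(43)
  for (nm in c("haar", "db2", "db4")) {
    for (pd in c("periodic", "symmetric", "zero")) {
      sp <- wavelet_spec(nm, padding = pd)
      for (n in c(64, 100)) {
        x <- rnorm(n)
        lev <- min(2L, max_dwt_level(n, sp))
        mine <- dwt_multilevel(x, sp, lev)
        ref <- pywt_wavedec(x, nm, pd, lev)
        expect_equal(length(mine$approx), length(ref$approx))
        expect_lt(max(abs(mine$approx - ref$approx)), 1e-8)
        for (l in seq_len(lev)) {
          expect_lt(max(abs(mine$details[[l]] - ref$details[[l]])), 1e-8)
        }
      }
    }
  }
})

test_that("circularly shifting the input by 2 shifts Haar level-1 coefficients by 1", {
  set.seed(44)
  sp <- wavelet_spec("haar", padding = "periodic")
  x <- rnorm(64)
  x_shift <- c(x[63:64], x[1:62])
  a <- dwt_single_level(x, sp)
  b <- dwt_single_level(x_shift, sp)
  expect_equal(b$approx, c(a$approx[32], a$approx[1:31]), tolerance = 1e-12)
  expect_equal(b$detail, c(a$detail[32], a$detail[1:31]), tolerance = 1e-12)
})

test_that("coefficient lengths follow the dyadic length recurrence", {
  per <- wavelet_spec("db4", padding = "periodic")
  d <- dwt_multilevel(rnorm(256), per, 2)
  expect_equal(length(d$approx), 64L)
  expect_equal(lengths(d$details), c(128L, 64L))

  sym <- wavelet_spec("db4", padding = "symmetric")
  expect_equal(feature_length(256, sym, 2), 69L)
  expect_equal(feature_length(256, wavelet_spec("haar", padding = "periodic"), 2), 64L)

  # sizing contract: feature_length always equals the realised vector length
  for (pd in c("periodic", "symmetric", "zero")) {
    for (nm in c("haar", "db4")) {
      sp <- wavelet_spec(nm, padding = pd)
      for (n in c(100, 256)) {
        f <- denoise_features(rnorm(n), sp, 2)
        expect_length(f, feature_length(n, sp, 2))
      }
    }
  }
  expect_length(denoise_features(rnorm(256), sym, 2, target_length = 76), 76L)
})

test_that("degenerate inputs raise informative errors", {
  sp <- wavelet_spec("db4")
  expect_error(dwt_multilevel(rnorm(64), sp, 10), "maximum admissible")
  expect_error(dwt_single_level(numeric(0), sp), "Empty")
  expect_error(dwt_single_level(rnorm(4), sp), "shorter than")
  expect_error(wavelet_spec("nosuchwavelet"), "Unknown wavelet")
  expect_error(dwt_single_level(c(1, NA, 3, 4), wavelet_spec("haar")),
               "non-finite")
})

test_that("approximation-only reconstruction is a low-pass smoother", {
  set.seed(45)
  x <- rnorm(256)
  sp <- wavelet_spec("db4", padding = "periodic")
  d <- dwt_multilevel(x, sp, 2)
  d$details <- lapply(d$details, function(v) v * 0)
  smooth <- idwt(d)
  expect_lte(sum(smooth^2), sum(x^2))
  d$approx <- d$approx * 0
  expect_equal(idwt(d), numeric(256) + 0, tolerance = 1e-12)
})
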