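# NNLS refitting, strict removal, NMF extraction, difference spectra and
# reference-set assembly

test_that("refit recovers exact and mixed signature exposures", {
  sigs <- synthetic_signatures()
  y <- 100 * sigs[, "sim_hd"]
  f <- refit(y, sigs)
  expect_equal(unname(f$exposures["sim_hd"]), 100, tolerance = 1e-9)
  expect_equal(unname(f$exposures[c("sim_bg", "sim_ox")]), c(0, 0),
               tolerance = 1e-9)
  expect_equal(f$cosine, 1, tolerance = 1e-12)

  z <- refit(numeric(96), sigs)
  expect_equal(unname(z$exposures), rep(0, 3))

  # mixture of two signatures with disjoint support, vs projected gradient
  A <- matrix(0, 96, 2)
  A[1:40, 1] <- 1 / 40
  A[41:96, 2] <- 1 / 56
  colnames(A) <- c("u", "v")
  rownames(A) <- sbs96_labels()
  y2 <- 70 * A[, 1] + 30 * A[, 2]
  f2 <- refit(y2, A)
  expect_equal(unname(f2$exposures), c(70, 30), tolerance = 1e-6)
  expect_equal(unname(f2$exposures), oracle_nnls(A, y2), tolerance = 1e-5)

  # noisy overdetermined case agrees with the independent solver
  set.seed(12)
  y3 <- as.numeric(sigs %*% c(50, 120, 30)) + abs(rnorm(96, 0, 0.5))
  f3 <- refit(y3, sigs)
  expect_equal(unname(f3$exposures), oracle_nnls(sigs, y3), tolerance = 1e-4)
  expect_error(refit(y3[1:50], sigs), "match")
})

test_that("refit residual beats random non-negative exposure vectors", {
  sigs <- synthetic_signatures()
  set.seed(8)
  y <- as.numeric(sigs %*% c(10, 60, 20)) + abs(rnorm(96, 0, 1))
  f <- refit(y, sigs)
  res_fit <- sum((y - as.numeric(sigs %*% f$exposures))^2)
  for (i in 1:50) {
    cand <- abs(f$exposures + rnorm(3, 0, 10))
    expect_lte(res_fit, sum((y - as.numeric(sigs %*% cand))^2) + 1e-9)
  }
})

test_that("strict refitting prunes decoys and matches exhaustive search", {
  sigs <- synthetic_signatures()
  decoys <- random_signatures(96, 5, seed = 77)
  rownames(decoys) <- sbs96_labels()
  set <- cbind(sigs[, "sim_hd", drop = FALSE], decoys)
  y <- 1000 * sigs[, "sim_hd"]
  f <- refit_strict(y, set, max_delta = 0.004)
  expect_setequal(f$removed, colnames(decoys))
  expect_equal(unname(f$exposures["sim_hd"]), 1000, tolerance = 1e-6)

  # exhaustive subset search: the surviving set is (one of) the smallest
  # subsets whose cosine is within max_delta-per-removal of the full fit
  full_cos <- refit(y, set)$cosine
  subsets <- unlist(lapply(1:6, function(k) {
    utils::combn(colnames(set), k, simplify = FALSE)
  }), recursive = FALSE)
  cosines <- vapply(subsets, function(ss) {
    refit(y, set[, ss, drop = FALSE])$cosine
  }, numeric(1))
  best_small <- min(lengths(subsets)[cosines >= full_cos - 6 * 0.004])
  expect_equal(sum(f$exposures > 0), best_small)

  # limit behaviours
  f0 <- refit_strict(y, set, max_delta = 0)
  expect_equal(f0$removed, character(0))
  expect_equal(unname(f0$exposures), unname(refit(y, set)$exposures))
  set.seed(41)
  ynoise <- as.numeric(set %*% runif(6, 10, 50))
  f1 <- refit_strict(ynoise, set, max_delta = 1)
  expect_equal(sum(f1$exposures > 0), 1)
})

test_that("strict removal obeys the telescoping cosine bound", {
  sigs <- cbind(synthetic_signatures(),
                random_signatures(96, 4, seed = 13))
  rownames(sigs) <- sbs96_labels()
  set.seed(14)
  y <- as.numeric(sigs[, 1:3] %*% c(100, 300, 50)) + abs(rnorm(96, 0, 2))
  f <- refit_strict(y, sigs, max_delta = 0.004)
  k <- length(f$removed)
  expect_gte(f$cosine, refit(y, sigs)$cosine - k * 0.004)
})

test_that("NMF reproduces planted factorisations deterministically", {
  # identical columns, k = 1
  v <- synthetic_signatures()[, "sim_hd"] * 500
  V <- cbind(a = v, b = v, c = v)
  r <- nmf_extract(V, 1, n_starts = 5, seed = 2)
  expect_equal(cosine(r$signatures[, 1], v), 1, tolerance = 1e-8)

  # bit-reproducible for a fixed seed
  r2 <- nmf_extract(V, 1, n_starts = 5, seed = 2)
  expect_identical(r$signatures, r2$signatures)
  expect_identical(r$exposures, r2$exposures)

  # objective non-increasing with more iterations
  set.seed(6)
  V2 <- matrix(rpois(96 * 6, 20), 96, 6)
  errs <- vapply(c(5, 20, 80, 300), function(it) {
    nmf_extract(V2, 2, n_starts = 1, seed = 3, max_iter = it)$error
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))

  expect_error(nmf_extract(V2, 6, n_starts = 1), "rank")
})

test_that("difference spectrum isolates a planted added component", {
  sigs <- synthetic_signatures()
  s1 <- sigs[, "sim_hd"]; s2 <- sigs[, "sim_ox"]
  low <- mut_spectrum(s1 * 50, "SBS96")
  high <- mut_spectrum(s1 * 50 + s2 * 60, "SBS96")
  d <- difference_spectrum(high, low, 1, 1)
  expect_gte(cosine(d, s2), 0.999)
  expect_equal(sum(d), 1, tolerance = 1e-12)

  # equal normalised spectra are undefined
  expect_error(difference_spectrum(low, low, 1, 1), "undefined")
  expect_error(difference_spectrum(mut_spectrum(s1 * 100, "SBS96"),
                                   mut_spectrum(s1 * 50, "SBS96"),
                                   norm_high = 2, norm_low = 1), "undefined")
  # floored channels are reported
  set.seed(9)
  high2 <- mut_spectrum(pmax(s1 * 50 + rnorm(96, 0, 0.01), 0), "SBS96")
  d2 <- difference_spectrum(high2, low, 1, 1)
  expect_gt(attr(d2, "floored"), 0)
})

test_that("two-component decomposition tracks a planted monotone mixture", {
  sigs <- synthetic_signatures()
  lowc <- mut_spectrum(sigs[, "sim_hd"], "SBS96", normalized = TRUE)
  diffc <- mut_spectrum(sigs[, "sim_ox"], "SBS96", normalized = TRUE)
  n <- 1000
  shares <- seq(0, 0.8, length.out = 9)
  strata <- lapply(shares, function(w) {
    mut_spectrum(n * ((1 - w) * as.numeric(lowc) + w * as.numeric(diffc)),
                 "SBS96")
  })
  fit <- two_component_fit(strata, lowc, diffc)
  expect_true(all(diff(fit$diff) > 0))
  expect_equal(fit$low[1], n, tolerance = 1e-6)
  expect_equal(fit$diff[1], 0, tolerance = 1e-6)
  expect_warning(two_component_fit(strata[1], lowc, lowc), "collinear")
})

test_that("reference-set assembly is order-preserving and validated", {
  base <- cbind(synthetic_signatures(), random_signatures(96, 6, seed = 5,
                                                          prefix = "SBS"))
  rownames(base) <- sbs96_labels()
  expect_identical(assemble_reference_set(base), base)
  add <- random_signatures(96, 4, seed = 6, prefix = "new")
  rownames(add) <- sbs96_labels()
  out <- assemble_reference_set(base, drop = paste0("SBS", 1:6), add = add)
  expect_equal(ncol(out), ncol(base) - 6 + 4)
  expect_identical(colnames(out), c("sim_bg", "sim_hd", "sim_ox",
                                    paste0("new", 1:4)))
  expect_error(assemble_reference_set(base, drop = "nope"), "unknown")
  dup <- base[, 1, drop = FALSE]
  expect_error(assemble_reference_set(base, add = dup), "duplicate")
})

test_that("MMRd sample selection applies the strict exposure threshold", {
  f <- structure(list(exposures = c(`MMRd-A` = 600, `MMRd-B` = 500)),
                 class = "signature_fit")
  expect_true(select_mmrd(f))
  f$exposures <- c(`MMRd-A` = 500, `MMRd-B` = 500)
  expect_false(select_mmrd(f))
  f$exposures <- c(`MMRd-A` = 0, `MMRd-B` = 0)
  expect_false(select_mmrd(f))
  f$exposures <- c(`MMRd-A` = 2000)
  expect_error(select_mmrd(f), "lacks")
})
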