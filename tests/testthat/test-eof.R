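test_that("a planted rank-1 mode is recovered almost perfectly", {
  set.seed(50)
  ncell <- 400; nt <- 240
  w <- runif(ncell, 0.7, 1.3)
  pattern <- sin(seq(0, pi, length.out = ncell))
  index <- as.numeric(arima.sim(list(ar = 0.8), nt))
  X <- outer(index, pattern) + matrix(rnorm(nt * ncell, 0, 1e-3), nt, ncell)
  e <- eof_decompose(X, k = 3, weights = w)
  expect_gt(e$variance_fraction[1], 0.99)
  expect_gt(abs(cor(e$pcs[, 1], index)), 0.99)
  # recovered spatial mode is proportional to the planted pattern
  r_mode <- abs(cor(e$modes[, 1], pattern))
  expect_gt(r_mode, 0.99)
})

test_that("two orthogonal planted modes recover a 4:1 variance split", {
  set.seed(51)
  ncell <- 300; nt <- 200
  w <- runif(ncell, 0.5, 1.5)
  p1 <- rep(1, ncell)
  p2 <- sin(seq(-pi, pi, length.out = ncell))
  p2 <- p2 - sum(p2 * p1 * w) / sum(p1^2 * w) * p1 # weighted orthogonality
  p1 <- p1 / sqrt(sum(p1^2 * w)); p2 <- p2 / sqrt(sum(p2^2 * w))
  i1 <- rnorm(nt); i1 <- (i1 - mean(i1))
  i2 <- rnorm(nt); i2 <- i2 - mean(i2)
  i2 <- i2 - sum(i1 * i2) / sum(i1^2) * i1 # sample-orthogonal indices
  i1 <- i1 / sd(i1); i2 <- i2 / sd(i2) / 2 # variance ratio exactly 4:1
  X <- outer(i1, p1) + outer(i2, p2) +
    matrix(rnorm(nt * ncell, 0, 2e-4), nt, ncell)
  e <- eof_decompose(X, k = 2, weights = w)
  expect_equal(e$variance_fraction[1], 0.8, tolerance = 0.02)
  expect_equal(e$variance_fraction[2], 0.2, tolerance = 0.02)
})

test_that("full-rank fractions sum to one and the decomposition reconstructs", {
  set.seed(52)
  X <- matrix(rnorm(30 * 50), 30, 50)
  w <- runif(50, 0.5, 2)
  expect_warning(e <- eof_decompose(X, k = 40, weights = w), "rank")
  expect_equal(sum(e$variance_fraction), 1, tolerance = 1e-8)
  rec <- e$pcs %*% t(e$modes)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(max(abs(rec - Xc)), 1e-8)
  # PCs are mutually orthogonal
  gram <- crossprod(e$pcs)
  off <- gram - diag(diag(gram))
  expect_lt(max(abs(off)) / max(diag(gram)), 1e-8)
})

test_that("variance fractions are invariant to sign flips and cell splitting", {
  set.seed(53)
  ncell <- 100; nt <- 80
  w <- runif(ncell, 0.5, 1.5)
  X <- matrix(rnorm(nt * ncell), nt, ncell) +
    outer(rnorm(nt), runif(ncell, -1, 1)) * 3
  e1 <- eof_decompose(X, k = 4, weights = w)
  e2 <- eof_decompose(-X, k = 4, weights = w)
  expect_equal(e1$variance_fraction, e2$variance_fraction, tolerance = 1e-10)
  # splitting each cell into two half-area copies changes nothing
  X_split <- X[, rep(seq_len(ncell), each = 2)]
  w_split <- rep(w / 2, each = 2)
  e3 <- eof_decompose(X_split, k = 4, weights = w_split)
  expect_equal(e3$variance_fraction, e1$variance_fraction, tolerance = 1e-10)
  expect_equal(abs(cor(e3$pcs[, 1], e1$pcs[, 1])), 1, tolerance = 1e-8)
})

test_that("low-coverage cells are dropped and gaps carry no leverage", {
  set.seed(54)
  ncell <- 60; nt <- 100
  X <- outer(rnorm(nt), runif(ncell, -1, 1)) + matrix(rnorm(nt * ncell, 0, 0.1), nt, ncell)
  X[1:50, 1] <- NA # 50% coverage: dropped
  X[1:5, 2] <- NA # 95% coverage: kept, gap zero-filled
  e <- eof_decompose(X, k = 2, weights = rep(1, ncell))
  expect_false(1 %in% e$cells)
  expect_true(2 %in% e$cells)
})

test_that("index correlation ranks the matching index first", {
  set.seed(55)
  nt <- 120
  time <- month_seq("2000-01", nt)
  pcs <- cbind(as.numeric(arima.sim(list(ar = 0.7), nt)), rnorm(nt))
  e <- structure(list(pcs = pcs, k = 2, time = time), class = "eof_result")
  idx <- list(
    match = data.frame(date = time, value = pcs[, 1]),
    anti = data.frame(date = time, value = -pcs[, 2]),
    noise = data.frame(date = time, value = rnorm(nt)))
  tab <- correlate_indices(e, idx)
  best1 <- tab[tab$mode == 1 & tab$best, ]
  expect_equal(best1$index, "match")
  expect_equal(best1$r, 1, tolerance = 1e-12)
  best2 <- tab[tab$mode == 2 & tab$best, ]
  expect_equal(best2$index, "anti")
  expect_equal(best2$r, -1, tolerance = 1e-12)
  # indices with too little overlap are skipped with a warning
  idx_short <- list(short = data.frame(date = time[1:10], value = rnorm(10)))
  expect_warning(expect_error(correlate_indices(e, idx_short), "overlap"),
                 "skipped")
})

test_that("the PC global range follows the closed-form integral arithmetic", {
  nt <- 24
  pcs <- matrix(rep(c(1, -1), nt / 2), nt, 1)
  modes <- matrix(1, 10, 1) # uniform 1 mg C m-2 d-1 per unit PC
  areas <- rep(3.6e13, 10) # 3.6e14 m2 total
  e <- structure(list(pcs = pcs, modes = modes, weights = areas, k = 1,
                      time = month_seq("2000-01", nt),
                      units = "mg C m-2 d-1"), class = "eof_result")
  oracle <- 2 * (1e-3 * 3.6e14 * 365.25) / 1e15 # grams to petagrams by hand
  expect_equal(pc_npp_range(e), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 3), 0.263)
  # linearity: doubling the PC amplitude doubles the range
  e2 <- e; e2$pcs <- 2 * e$pcs
  expect_equal(pc_npp_range(e2), 2 * oracle, tolerance = 1e-12)
  # zero-amplitude PC gives zero range
  e0 <- e; e0$pcs[] <- 0
  expect_equal(pc_npp_range(e0), 0)
  # wrong units are refused
  e_bad <- e; e_bad$units <- "m-1"
  expect_error(pc_npp_range(e_bad), "units")
})
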