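test_that("LCMV weights satisfy the closed form at identity covariance", {
  lf <- toyLeadField(nSensors = 10, roiLabels = "rAMG", seed = 1)
  flt <- lcmvFilters(lf, diag(10), reg = 0)
  # single unit-norm column, C = I: w reduces to l'
  expect_equal(drop(flt@weights), lf@gain[, 1], tolerance = 1e-10)
})

test_that("unit gain holds for every source on generic inputs", {
  lf <- toyLeadField(nSensors = 25, sourcesPerRoi = 2, seed = 2)
  set.seed(3)
  A <- matrix(rnorm(25 * 200), 25)
  cov <- tcrossprod(A) / 200
  flt <- lcmvFilters(lf, cov, reg = 0.05)
  expect_lt(max(abs(diag(flt@weights %*% lf@gain) - 1)), 1e-8)
  # invariance to uniform sensor rescaling: same unit-gain weights scale by 1/c
  flt2 <- lcmvFilters(lf, 4 * cov, reg = 0.05)
  expect_lt(max(abs(diag(flt2@weights %*% lf@gain) - 1)), 1e-8)
})

test_that("beamformer reconstructs simulated uncorrelated sources", {
  cfg <- deskConfig(nTrials = 10, epochLenS = 1)
  s <- simulateSubject(cfg, "responder", seed = 4)
  lf <- toyLeadField(nSensors = 30, seed = 5)
  sens <- projectToSensors(s$roi, lf, snrDb = 10, seed = 6)
  flt <- lcmvFilters(lf, sensorCovariance(sens))
  rec <- applyFilters(sens, flt, lf)
  for (r in seq_along(seriesLabels(rec))) {
    truth <- as.vector(seriesData(s$roi)[, r, ])
    est <- as.vector(seriesData(rec)[, r, ])
    expect_gt(abs(cor(truth, est)), 0.95)
  }
})

test_that("ROI aggregation handles singleton, duplicate and flipped sources", {
  # identity filters isolate the aggregation step from beamformer leakage
  set.seed(7)
  s0 <- rnorm(3 * 200)                            # ground-truth rAMG series
  sOther <- rnorm(3 * 200)
  mkSensors <- function(cols) {
    d <- array(0, c(3, length(cols), 200))
    for (j in seq_along(cols)) d[, j, ] <- matrix(cols[[j]], 3)
    epochedSeries(d, fs = 200)
  }
  idFilters <- function(k) new("SpatialFilterSet", weights = diag(k),
                               regularization = 0)

  # singleton ROI: the ROI series is that source's series, exactly
  lf1 <- new("ToyLeadField", gain = diag(2), roiMap = c("rAMG", "rTHA"))
  rec1 <- applyFilters(mkSensors(list(s0, sOther)), idFilters(2), lf1)
  expect_equal(as.vector(seriesData(rec1)[, 1, ]), s0, ignore_attr = TRUE)

  # duplicated source: mean of identical series is the common series
  lf2 <- new("ToyLeadField",
             gain = cbind(c(1, 0, 0), c(1, 1e-6, 0), c(0, 0, 1)),
             roiMap = c("rAMG", "rAMG", "rTHA"))
  rec2 <- applyFilters(mkSensors(list(s0, s0, sOther)), idFilters(3), lf2)
  expect_equal(as.vector(seriesData(rec2)[, 1, ]), s0, ignore_attr = TRUE)

  # opposite polarities: sign alignment recovers the signal, a plain mean
  # would cancel it
  noisy1 <- s0 + rnorm(600, sd = 0.05)
  noisy2 <- -s0 + rnorm(600, sd = 0.05)
  rec3 <- applyFilters(mkSensors(list(noisy1, noisy2, sOther)),
                       idFilters(3), lf2)
  expect_gt(abs(cor(as.vector(seriesData(rec3)[, 1, ]), s0)), 0.99)
  expect_lt(abs(cor((noisy1 + noisy2) / 2, s0)), 0.1)
})

test_that("orthogonalization removes zero-lag correlations and is idempotent", {
  set.seed(9)
  d <- array(rnorm(2 * 4 * 250), c(2, 4, 250))
  d[, 2, ] <- d[, 2, ] + 0.7 * d[, 1, ]          # induce leakage
  for (j in 1:4) d[, j, ] <- d[, j, ] * j        # well-separated norms
  r <- roiSeries(d, fs = 250)
  o <- symmetricOrthogonalize(r)
  cc <- cor(pooledMatrix(o)); diag(cc) <- 0
  expect_lt(max(abs(cc)), 1e-8)
  o2 <- symmetricOrthogonalize(o)
  expect_lt(max(abs(seriesData(o2) - seriesData(o))) /
              max(abs(seriesData(o))), 1e-8)
  # norm ordering preserved (norms are well separated here)
  n0 <- apply(pooledMatrix(r), 2, function(v) sum((v - mean(v))^2))
  n1 <- apply(pooledMatrix(o), 2, function(v) sum((v - mean(v))^2))
  expect_identical(order(n0), order(n1))
})

test_that("already-uncorrelated input is a fixed point", {
  set.seed(10)
  M <- matrix(rnorm(300 * 3), 300)
  M <- sweep(M, 2, colMeans(M))                  # zero-mean column space
  X <- qr.Q(qr(M)) %*% diag(c(5, 3, 2))          # orthogonal and zero-mean
  r <- roiSeries(aperm(array(t(X), c(3, 1, 300)), c(2, 1, 3)), fs = 100)
  o <- symmetricOrthogonalize(r)
  expect_equal(seriesData(o), seriesData(r), tolerance = 1e-6)
})

test_that("orthogonalization matches a brute-force constrained minimizer", {
  # objective: || X - U diag(d) ||_F^2 over orthonormal U (via Cayley
  # parameterization of the rotation) with d eliminated in closed form
  set.seed(12)
  X <- matrix(rnorm(200 * 3), 200)
  r <- roiSeries(aperm(array(t(sweep(X, 2, colMeans(X))), c(3, 1, 200)),
                       c(2, 1, 3)), fs = 100)
  o <- symmetricOrthogonalize(r)
  Y <- pooledMatrix(o)
  objPkg <- sum((sweep(X, 2, colMeans(X)) - sweep(Y, 2, colMeans(Y)))^2)

  Xc <- sweep(X, 2, colMeans(X))
  base <- svd(Xc, nu = 3, nv = 3)
  obj <- function(theta) {
    S <- matrix(0, 3, 3)
    S[upper.tri(S)] <- theta
    S <- S - t(S)
    R <- solve(diag(3) - S, diag(3) + S)         # Cayley rotation
    U <- base$u %*% R
    dd <- colSums(U * Xc)
    sum((Xc - sweep(U, 2, dd, "*"))^2)
  }
  best <- Inf
  for (i in 1:20) {
    th0 <- rnorm(3, sd = 0.5)
    opt <- optim(th0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  expect_lt(abs(objPkg - best) / best, 1e-6)
})

test_that("a known 2x2 mixing is undone for modest mixing angles", {
  set.seed(13)
  s1 <- rnorm(500); s2 <- rnorm(500)
  th <- 25 * pi / 180
  M <- matrix(c(cos(th), sin(th), sin(th), cos(th)), 2)
  X <- cbind(s1, s2) %*% M
  r <- roiSeries(aperm(array(t(X), c(2, 1, 500)), c(2, 1, 3)), fs = 100)
  o <- symmetricOrthogonalize(r)
  Y <- pooledMatrix(o)
  expect_lt(abs(cor(Y[, 1], Y[, 2])), 1e-8)
  expect_gt(abs(cor(Y[, 1], s1)), 0.9)
  expect_gt(abs(cor(Y[, 2], s2)), 0.9)
})

test_that("collinear regions are rejected with the pair named", {
  set.seed(14)
  d <- array(rnorm(1 * 3 * 100), c(1, 3, 100))
  d[1, 3, ] <- 2 * d[1, 1, ]
  r <- roiSeries(d, fs = 100, regionLabels = c("rAMG", "rTHA", "rOFC"))
  expect_error(symmetricOrthogonalize(r), "rAMG.*rOFC|rOFC.*rAMG")
})
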