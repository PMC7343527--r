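test_that("linearization recovers the closed-form single-population Jacobian", {
  net <- single_pop_network(T_ms = 10)
  nat <- apply_condition_effects(NULL, net)
  lin <- linearize(net, nat)
  Tsec <- 0.010
  expect_equal(lin$J, rbind(c(0, 1), c(-1 / Tsec^2, -2 / Tsec)),
               tolerance = 1e-6)
  expect_error(linearize(net, nat, operating_point = c(1, 1)),
               "not a fixed point")
})

test_that("fast analytic linearization agrees with finite differences", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  set.seed(42)
  th <- pack_theta(theta_template(pr), pr)
  th[] <- rnorm(length(th), 0, 0.1)
  nat <- apply_condition_effects(unpack_theta(th, pr), net, pr)
  a <- gdcm:::.analytic_spectral_model(net, nat)
  b <- linearize(net, nat)
  expect_equal(a$J, b$J, tolerance = 1e-6)
  expect_equal(a$U, b$U, tolerance = 1e-9)
  expect_equal(a$Lrow, b$Lrow, tolerance = 1e-12)
})

test_that("delay embedding: identity at zero delay, scalar closed form,
           first-order eigenvalue drift", {
  set.seed(3)
  J <- matrix(rnorm(16), 4)
  expect_equal(delay_embed(J, matrix(0, 4, 4)), J)
  ## 1x1: -a with delay d gives -a / (1 - d a)
  a <- 3; d <- 0.05
  expect_equal(delay_embed(matrix(-a, 1, 1), matrix(d, 1, 1)),
               matrix(-a / (1 - d * a), 1, 1))
  ## halving the delays halves the spectral shift, to first order
  net <- cbg_network()
  lin <- linearize(net, apply_condition_effects(NULL, net))
  lead <- function(M) max(Re(eigen(M, only.values = TRUE)$values))
  ds1 <- build_delay_matrix(net, c(1, 8, 8, 4) / 8)
  ds2 <- build_delay_matrix(net, c(1, 8, 8, 4) / 16)
  shift1 <- lead(delay_embed(lin$J, ds1)) - lead(lin$J)
  shift2 <- lead(delay_embed(lin$J, ds2)) - lead(lin$J)
  expect_equal(shift1 / shift2, 2, tolerance = 0.15)
})

test_that("predicted spectra reduce to the observation-noise floor without
           signal and to the kernel closed form without noise", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  freq <- seq(5, 45, by = 2)
  th <- theta_template(pr)
  th$L[] <- -40                      # observation gain ~ 0
  g <- predict_csd(net, th, freq = freq, priors = pr)$G$baseline
  for (k in seq_along(freq)) {
    floor_k <- matrix(1 / freq[k], 2, 2) + diag(1 / freq[k], 2)
    expect_equal(g[, , k], floor_k + 0i, tolerance = 1e-8)
  }
  ## isolated population, no channel noise: |T/(1+iwT)|^2 kernel spectrum
  net1 <- single_pop_network(T_ms = 10)
  g1 <- predict_csd(net1, freq = freq, channel_noise = FALSE)$G$baseline
  Tsec <- 0.010
  closed <- 512 * freq^(-1) * Tsec^2 / ((1 - (2 * pi * freq)^2 * Tsec^2)^2 +
                                          4 * (2 * pi * freq)^2 * Tsec^2)
  expect_lt(max(abs(Re(g1[1, 1, ]) - closed) / closed), 1e-8)
})

test_that("auto-spectra dominate cross-spectra and coherence is bounded", {
  net <- cbg_network()
  csd <- predict_csd(net, freq = seq(5, 45, 2))
  g <- csd$G$baseline
  for (k in seq_len(dim(g)[3])) {
    expect_true(Mod(g[1, 2, k])^2 <= Re(g[1, 1, k]) * Re(g[2, 2, k]) + 1e-15)
  }
  co <- coherence(csd)$baseline
  expect_true(all(co >= 0 & co <= 1))
  expect_true(all(co[1, 1, ] == 1))
  ## independent channels: zero coherence; a rank-1 field: unit coherence
  f <- c(10, 20)
  Gd <- array(0 + 0i, c(2, 2, 2)); Gd[1, 1, ] <- 1; Gd[2, 2, ] <- 2
  expect_equal(coherence(csd_dataset(f, list(a = Gd), c("x", "y")))$a[1, 2, ],
               c(0, 0))
  h <- c(1 + 2i, 3 - 1i)
  G1 <- array(outer(h, Conj(h)), c(2, 2, 2))
  expect_equal(coherence(csd_dataset(f, list(a = G1), c("x", "y")))$a[1, 2, ],
               c(1, 1), tolerance = 1e-12)
})

test_that("channel spectra are the quadratic form of population spectra", {
  ## four channels: the mixed readout plus one virtual electrode per
  ## pyramidal population; bilinearity in the observation row means the
  ## mixed auto-spectrum equals w' G_pop w over the population block
  mix <- c(SP = 0.2, MP = 0.2, DP = 0.6)
  net <- dcm_network(
    sources = list(mmc = "MMC", bgt = "BGT"),
    extrinsic = cbg_network()$extrinsic,
    A_prior = list(pi = c(110, 588, 672, 127), sigma2 = 1 / 4),
    channels = list(
      M1 = list(source = "mmc", mixture = mix),
      SP = list(source = "mmc", mixture = c(SP = 1)),
      MP = list(source = "mmc", mixture = c(MP = 1)),
      DP = list(source = "mmc", mixture = c(DP = 1))))
  freq <- seq(10, 40, 10)
  g <- predict_csd(net, freq = freq, channel_noise = FALSE)$G$baseline
  w <- unname(mix)
  for (k in seq_along(freq)) {
    quad <- Re(drop(t(w) %*% g[2:4, 2:4, k] %*% w))
    expect_equal(Re(g[1, 1, k]), quad, tolerance = 1e-10)
  }
  ## interneurons are addressable even though absent from the mixture
  ps <- population_spectra(cbg_network(), source = "mmc", population = "II",
                           freq = freq)
  expect_true(all(Re(ps$G[[1]][1, 1, ]) >= 0))
  expect_true(all(abs(Im(ps$G[[1]][1, 1, ])) < 1e-14))
  expect_error(population_spectra(cbg_network(), source = "mmc",
                                  population = "Str"), "unknown population")
})

test_that("predictions are Hermitian PSD across prior draws and the noise
           floor acts only on the diagonal", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  sdv <- sqrt(gdcm:::.packed_prior(pr)$var)
  set.seed(2024)
  freq <- seq(5, 45, 8)
  n_ok <- 0
  for (i in 1:25) {
    th <- rnorm(length(sdv), 0, sdv * 0.5)
    csd <- predict_csd(net, th, freq = freq,
                       conditions = c(OFF = "baseline", ON = "modulated"))
    if (!isTRUE(attr(csd, "stable"))) next
    n_ok <- n_ok + 1
    for (cn in csd$conditions) for (k in seq_along(freq)) {
      gk <- csd$G[[cn]][, , k]
      expect_lt(max(abs(gk - Conj(t(gk)))), 1e-10 * max(abs(gk)))
      expect_true(all(eigen(gk, only.values = TRUE)$values > -1e-12))
    }
    co <- coherence(csd)
    expect_true(all(unlist(co) >= 0 & unlist(co) <= 1))
  }
  expect_gt(n_ok, 10)
  ## raising channel-specific noise raises only auto-spectra
  th0 <- theta_template(pr)
  th1 <- th0; th1$alpha_s[] <- 0.7
  g0 <- predict_csd(net, th0, freq = freq)$G$baseline
  g1 <- predict_csd(net, th1, freq = freq)$G$baseline
  expect_true(all(Re(g1[1, 1, ]) > Re(g0[1, 1, ])))
  expect_true(all(Re(g1[2, 2, ]) > Re(g0[2, 2, ])))
  expect_equal(g1[1, 2, ], g0[1, 2, ], tolerance = 1e-12)
})

test_that("feature stacking counts real components and inverts exactly", {
  net <- cbg_network()
  csd <- predict_csd(net, freq = 5:45,
                     conditions = c(OFF = "baseline", ON = "modulated"))
  v <- feature_vector(csd)
  ## per frequency and condition: 2 real auto-spectra + re/im cross
  expect_length(v, 2 * 41 * (2 + 2))
  back <- feature_to_csd(v, csd)
  expect_equal(back$G$OFF, csd$G$OFF, tolerance = 1e-14)
  expect_equal(back$G$ON, csd$G$ON, tolerance = 1e-14)
  ## zero matrices give the zero vector
  z <- csd
  z$G <- lapply(z$G, function(g) g * 0)
  expect_equal(feature_vector(z), rep(0, length(v)))
  ## non-Hermitian input beyond tolerance is refused
  bad <- csd
  bad$G$OFF[1, 2, 1] <- bad$G$OFF[1, 2, 1] + 1
  expect_error(feature_vector(bad), "Hermitian")
})
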