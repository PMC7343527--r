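test_that("sigmoid rate deviation is zero at baseline, bounded and odd", {
  expect_equal(sigmoid_rate(0, 2 / 3), 0)
  expect_equal(sigmoid_rate(1e6, 2 / 3), 0.5, tolerance = 1e-12)
  expect_equal(sigmoid_rate(-1e6, 2 / 3), -0.5, tolerance = 1e-12)
  ## direct evaluation oracle at v = 1
  expect_equal(sigmoid_rate(1, 2 / 3), 1 / (1 + exp(-2 / 3)) - 0.5,
               tolerance = 1e-12)
  v <- seq(-5, 5, by = 0.37)
  expect_equal(sigmoid_rate(v, 1.3), -sigmoid_rate(-v, 1.3))
  expect_true(all(abs(sigmoid_rate(v, 1.3)) < 0.5))
  expect_error(sigmoid_rate(Inf, 2 / 3), "non-finite")
  expect_error(sigmoid_rate(1, 0), "positive")
})

test_that("shipped priors carry the published values", {
  mmc <- default_priors("MMC")
  expect_equal(unname(mmc$T$pi), c(3.7, 3.2, 14.1, 10.6))
  expect_equal(mmc$T$sigma2, 1 / 8)
  expect_equal(mmc$gamma$pi,
               c(357, 872, 387, 340, 311, 405, 377, 429, 331, 403, 753,
                 376, 382, 414))
  expect_equal(mmc$gamma$sigma2, 1 / 4)
  bgt <- default_priors("BGT")
  expect_equal(bgt$gamma$pi,
               c(962, 828, 1403, 719, 526, 568, 345, 780, 301))
  expect_equal(bgt$gamma$sigma2, 1 / 2)
  expect_equal(unname(bgt$T$pi), c(9.3, 12.2, 3.5, 12.1, 10.1))
  expect_equal(bgt$T$sigma2, 1 / 4)
  ## structural consistency with the model specs
  expect_length(bgt$gamma$pi, nrow(model_spec("BGT")$connections))
  expect_length(bgt$T$pi, length(model_spec("BGT")$populations))
  expect_equal(model_spec("MMC")$priors$R$sigma2, 1 / 32)
  expect_equal(model_spec("BGT")$priors$R$sigma2, 1 / 16)
  expect_error(default_priors("NOPE"), "unknown model kind")
})

test_that("model architecture matches the drawn circuit", {
  mmc <- model_spec("MMC")
  bgt <- model_spec("BGT")
  expect_equal(nrow(mmc$connections), 14)
  expect_equal(nrow(bgt$connections), 9)
  expect_setequal(mmc$populations, c("SP", "MP", "DP", "II"))
  expect_setequal(bgt$populations, c("Str", "GPe", "STN", "GPi", "Tha"))
  ## every population self-inhibits except STN and Tha; interneurons and
  ## all pallidal/striatal structures carry self-connections
  selfs <- function(s) with(s$connections, from[from == to])
  expect_setequal(selfs(mmc), c("MP", "SP", "II", "DP"))
  expect_setequal(selfs(bgt), c("Str", "GPe", "GPi"))
  ## excitatory/inhibitory signs follow transmitter identity: the only
  ## excitatory basal-ganglia projections originate from STN
  exc <- with(bgt$connections, from[sign > 0])
  expect_true(all(exc == "STN"))
  expect_equal(mmc$output_mixture, c(SP = 0.2, MP = 0.2, DP = 0.6))
  expect_equal(bgt$output_mixture, c(STN = 1))
  expect_equal(mmc$input_population, "MP")
  expect_equal(bgt$input_population, "Str")
})

test_that("flow has a fixed point at the origin and is linear in inputs", {
  for (kind in c("MMC", "BGT")) {
    spec <- model_spec(kind)
    p <- length(spec$populations)
    params <- list(gamma = spec$priors$gamma$pi, T = spec$priors$T$pi,
                   R = spec$priors$R$pi)
    expect_equal(model_flow(kind, rep(0, 2 * p), params), rep(0, 2 * p))
    ## exactly linear in afferent and drive
    x <- sin(seq_len(2 * p))
    f0 <- model_flow(kind, x, params)
    f1 <- model_flow(kind, x, params, afferent = 2, drive = -1)
    f2 <- model_flow(kind, x, params, afferent = 4, drive = -2)
    expect_equal(f2 - f0, 2 * (f1 - f0), tolerance = 1e-12)
    expect_error(model_flow(kind, rep(0, 3), params), "length")
  }
  expect_error(model_flow("NOPE", 0, list()), "unknown model kind")
})

test_that("an isolated population reaches v* = T I and has the kernel
           impulse response", {
  register_single_pop(T_ms = 10)
  spec <- model_spec("ONEPOP")
  params <- list(gamma = numeric(), T = 10, R = 2 / 3)
  Tsec <- 0.010
  I0 <- 3
  f <- function(x) model_flow("ONEPOP", x, params, drive = I0)
  sim <- rk4(f, c(0, 0), t_end = 0.2, dt = 1e-4)
  expect_equal(sim$x[nrow(sim$x), 1], Tsec * I0, tolerance = 1e-6)
  ## unit rate impulse at t = 0 <=> initial vdot = 1/T; response is the
  ## synaptic kernel (t/T) exp(-t/T), peaking at t = T
  f0 <- function(x) model_flow("ONEPOP", x, params)
  sim <- rk4(f0, c(0, 1 / Tsec), t_end = 0.06, dt = 1e-5)
  kernel <- (sim$t / Tsec) * exp(-sim$t / Tsec)
  keep <- sim$t > 0
  expect_lt(max(abs(sim$x[keep, 1] - kernel[keep]) / max(kernel)), 1e-6)
  expect_equal(sim$t[which.max(sim$x[, 1])], Tsec, tolerance = 1e-3)
})

test_that("exponential scale factors map theta = 0 to the prior mean", {
  pr <- default_priors("BGT")
  expect_equal(scale_parameters(rep(0, 9), pr$gamma), pr$gamma$pi)
  ## doubling the STN time constant
  expect_equal(scale_parameters(log(2), list(pi = 3.5)), 7.0)
  theta <- seq(-1, 1, length.out = 9)
  nat <- scale_parameters(theta, pr$gamma)
  expect_equal(log(nat / pr$gamma$pi), theta, tolerance = 1e-14)
  expect_true(all(nat > 0))
  expect_error(scale_parameters(1:3, list(pi = 1:2)), "conformable")
})

test_that("the assembled system is stable at the prior means", {
  net <- cbg_network()
  nat <- apply_condition_effects(NULL, net)
  lin <- linearize(net, nat)
  expect_lt(max(Re(eigen(lin$J, only.values = TRUE)$values)), 0)
})

test_that("each coupling strength moves its own Jacobian entry with the
           declared sign", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  tab <- gdcm:::.population_tables(net, apply_condition_effects(NULL, net))
  base <- linearize(net, apply_condition_effects(NULL, net))$J
  for (s in net$sources) {
    con <- s$spec$connections
    for (i in seq_len(nrow(con))) {
      th <- theta_template(pr)
      th[[paste0("gamma_", s$name)]][i] <- 0.1
      J2 <- linearize(net, apply_condition_effects(th, net, pr))$J
      jrow <- tab$a_index[which(tab$source == s$name &
                                  tab$population == con$to[i])]
      jcol <- tab$v_index[which(tab$source == s$name &
                                  tab$population == con$from[i])]
      expect_equal(sign(J2[jrow, jcol] - base[jrow, jcol]), con$sign[i],
                   label = paste0(s$name, " connection ", i))
    }
  }
})

test_that("isolated-population frequency response equals T/(1+iwT)^2", {
  net <- single_pop_network(T_ms = 10)
  nat <- apply_condition_effects(NULL, net)
  lin <- linearize(net, nat)
  Tsec <- 0.010
  freq <- seq(5, 45, by = 0.5)
  for (k in seq_along(freq)) {
    w <- 2i * pi * freq[k]
    H <- drop(lin$Lrow %*% solve(diag(w, 2) - lin$J, lin$U))
    closed <- Tsec / (1 + w * Tsec)^2
    expect_lt(Mod(H - closed) / Mod(closed), 1e-8)
  }
})
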