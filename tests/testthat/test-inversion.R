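test_that("condition effects act multiplicatively on the modulated condition
           only", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  th <- theta_template(pr)
  off <- apply_condition_effects(th, net, pr, "baseline")
  on <- apply_condition_effects(th, net, pr, "modulated")
  expect_equal(off, on)
  th$B_bgt[["GPe->STN"]] <- log(0.5)
  off <- apply_condition_effects(th, net, pr, "baseline")
  on <- apply_condition_effects(th, net, pr, "modulated")
  expect_equal(on$sources$bgt$gamma[["GPe->STN"]],
               0.5 * off$sources$bgt$gamma[["GPe->STN"]])
  ## everything else identical across conditions
  on$sources$bgt$gamma["GPe->STN"] <- off$sources$bgt$gamma["GPe->STN"]
  expect_equal(off, on)
  ## an effect outside the declared modulable set is refused
  net2 <- cbg_network(b_indices = list(mmc = 1:3, bgt = 1:3))
  pr2 <- dcm_priors(net2)
  th2 <- theta_template(pr2)
  th2$B_bgt[[4]] <- 0.2   # GPe->STN not modulable here
  expect_error(apply_condition_effects(th2, net2, pr2, "modulated"),
               "outside b_indices")
  ## extrinsic slots shift their A entries
  th3 <- theta_template(pr)
  th3$B_ext[["MMC->STN"]] <- log(2)
  on3 <- apply_condition_effects(th3, net, pr, "modulated")
  expect_equal(unname(on3$A[4]), 2 * 127)
  expect_equal(unname(on3$A[1:3]), c(110, 588, 672))
})

test_that("free energy penalizes residuals quadratically and deviation from
           the priors", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  freq <- seq(5, 45, 10)
  data <- tiny_dataset(freq = freq, network = net, priors = pr)
  n <- length(feature_vector(data))
  ## exact prediction at the prior means, lambda at its hyperprior mean:
  ## only the log-precision volume term remains
  expect_equal(free_energy(NULL, 16, data, net, pr), 0.5 * n * 16)
  ## doubling a residual quadruples the accuracy penalty
  y <- feature_vector(data)
  d1 <- feature_to_csd(y + c(0.01, rep(0, n - 1)), data)
  d2 <- feature_to_csd(y + c(0.02, rep(0, n - 1)), data)
  F0 <- free_energy(NULL, 16, data, net, pr)
  expect_equal((free_energy(NULL, 16, d2, net, pr) - F0) /
                 (free_energy(NULL, 16, d1, net, pr) - F0), 4,
               tolerance = 1e-9)
  ## worse fit, all else equal, lowers F
  expect_lt(free_energy(NULL, 16, d1, net, pr), F0)
})

test_that("variational Laplace matches the conjugate linear-Gaussian
           posterior", {
  set.seed(11)
  n <- 40; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  theta_true <- rnorm(p)
  lambda <- 2
  y <- drop(X %*% theta_true) + rnorm(n, sd = exp(-lambda / 2))
  prior_var <- rep(0.8, p)
  g <- function(th) drop(X %*% th)
  fit <- vl_fit(g, y, prior_mean = rep(0, p), prior_var = prior_var,
                hE = lambda, hC = 4,
                control = list(update_lambda = FALSE))
  A <- exp(lambda) * crossprod(X) + diag(1 / prior_var)
  mean_cl <- solve(A, exp(lambda) * crossprod(X, y))
  expect_lt(max(abs(fit$mean - drop(mean_cl))), 1e-6)
  expect_lt(max(abs(fit$cov - solve(A))), 1e-6)
  expect_false(is.unsorted(fit$F_trace))
})

test_that("an empty dataset returns the prior", {
  fit <- vl_fit(function(th) numeric(0), numeric(0),
                prior_mean = c(0.5, -1), prior_var = c(1, 2))
  expect_equal(fit$mean, c(0.5, -1))
  expect_equal(fit$cov, diag(c(1, 2)))
})

test_that("zero-variance parameters stay fixed at their prior mean", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  fit <- vl_fit(function(th) drop(X %*% th), y, prior_mean = rep(0, 3),
                prior_var = c(1, 0, 1),
                control = list(update_lambda = FALSE))
  expect_equal(fit$mean[2], 0)
  expect_equal(fit$cov[2, ], rep(0, 3))
  expect_equal(fit$free, c(TRUE, FALSE, TRUE))
})

test_that("inversion recovers a self-generated dataset and improves free
           energy from a perturbed start", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  freq <- seq(5, 45, by = 4)
  data <- tiny_dataset(freq = freq, network = net, priors = pr)
  fit <- dcm_csd(data, net, pr, restarts = 1,
                 control = list(maxit = 32))
  F_init <- fit$F_trace[1]
  expect_gt(fit$F, F_init)
  expect_false(is.unsorted(fit$F_trace))
  ## per-block max-norm of the posterior mean stays near the truth (zero)
  for (nm in names(fit$theta))
    expect_lt(max(abs(fit$theta[[nm]]), 0), 0.05 + 1e-12)
  ## posterior covariance is symmetric positive semidefinite
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  ## fitted features and residuals are consistent
  expect_equal(fitted(fit) + residuals(fit), fit$y)
})

test_that("chained restarts never lose free energy and match a single run
           when n_restarts = 1", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  freq <- seq(5, 45, by = 8)
  data <- tiny_dataset(freq = freq, network = net, priors = pr)
  ## deliberately distant initialization
  init <- pack_theta(theta_template(pr), pr)
  init[names(init) == "L[M1]"] <- 2
  init[names(init) == "L[STN]"] <- -2
  one <- multistart_invert(data, net, pr, n_restarts = 1, init = init,
                           control = list(maxit = 12))
  single <- variational_laplace(data, net, pr, init = init,
                                control = list(maxit = 12))
  expect_equal(one$F, single$F)
  multi <- multistart_invert(data, net, pr, n_restarts = 3, init = init,
                             control = list(maxit = 12))
  expect_gte(multi$F, one$F)
  expect_gte(multi$F, max(multi$restart_F) - 1e-9)
})

test_that("fit methods expose the posterior coherently", {
  net <- cbg_network()
  pr <- dcm_priors(net)
  data <- tiny_dataset(freq = seq(5, 45, 8), network = net, priors = pr)
  fit <- dcm_csd(data, net, pr, control = list(maxit = 4))
  expect_s3_class(fit, "dcm_csd")
  expect_output(print(fit), "free energy")
  s <- summary(fit)
  expect_equal(nrow(s$table), length(fit$mean))
  expect_true(all(s$table$upper >= s$table$lower))
  expect_equal(coef(fit), fit$theta)
  nat <- coef(fit, natural = TRUE)
  expect_equal(nat$sources$bgt$T,
               stats::setNames(pr$blocks$T_bgt$pi * exp(fit$theta$T_bgt),
                               model_spec("BGT")$populations))
  expect_equal(dim(vcov(fit)), c(76, 76))
  expect_equal(as.numeric(logLik(fit)), fit$F)
  pred <- predict(fit)
  expect_s3_class(pred, "csd_dataset")
  expect_equal(pred$conditions, data$conditions)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
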