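test_that("the shipped circuit wires cortex and basal ganglia as described", {
  net <- cbg_network()
  expect_equal(n_states(net), 18L)
  ex <- net$extrinsic
  expect_equal(nrow(ex), 4L)
  arrows <- paste0(ex$from_population, "->", ex$to_population)
  expect_setequal(arrows, c("Tha->MP", "Tha->DP", "DP->Str", "DP->STN"))
  expect_true(all(net$A_prior$pi > 0))
  expect_equal(net$A_prior$pi, c(110, 588, 672, 127))
  ## innovations enter middle-layer pyramidal cells and striatum only
  nat <- apply_condition_effects(NULL, net)
  lin <- linearize(net, nat)
  tab <- gdcm:::.population_tables(net, nat)
  hit <- which(lin$U != 0, arr.ind = TRUE)
  expect_setequal(tab$population[match(hit[, 1], tab$a_index)],
                  c("MP", "Str"))
  ## delay priors follow [within cortex; down; up; within basal ganglia]
  expect_equal(as.numeric(net$delay_prior$pi), c(1, 8, 8, 4))
  expect_equal(net$delay_prior$sigma2, 1 / 32)
})

test_that("global flow decouples exactly when extrinsic strengths vanish", {
  net <- cbg_network()
  nat <- apply_condition_effects(NULL, net)
  nat$A <- rep(0, 4)
  flow <- assemble_flow(net, nat)
  expect_equal(flow(rep(0, 18)), rep(0, 18))
  set.seed(1)
  x <- rnorm(18, sd = 0.5)
  fx <- flow(x)
  f_mmc <- model_flow("MMC", x[1:8], nat$sources$mmc)
  f_bgt <- model_flow("BGT", x[9:18], nat$sources$bgt)
  expect_equal(fx, c(f_mmc, f_bgt), tolerance = 1e-12)
  ## full network still fixes the origin (baseline-subtracted sigmoid)
  nat2 <- apply_condition_effects(NULL, net)
  expect_equal(assemble_flow(net, nat2)(rep(0, 18)), rep(0, 18))
})

test_that("a deep-pyramidal perturbation reaches only its efferent targets", {
  net <- cbg_network()
  nat <- apply_condition_effects(NULL, net)
  flow <- assemble_flow(net, nat)
  tab <- gdcm:::.population_tables(net, nat)
  vDP <- tab$v_index[which(tab$population == "DP")]
  x <- rep(0, 18); x[vDP] <- 1e-3
  fx <- flow(x)
  bgt_pops <- c("Str", "GPe", "STN", "GPi", "Tha")
  acc_change <- abs(fx[tab$a_index[match(bgt_pops, tab$population)]]) > 1e-12
  expect_equal(stats::setNames(acc_change, bgt_pops),
               c(Str = TRUE, GPe = FALSE, STN = TRUE, GPi = FALSE,
                 Tha = FALSE))
})

test_that("coupling is local: sources only reach their extrinsic targets", {
  net <- cbg_network()
  nat <- apply_condition_effects(NULL, net)
  J <- linearize(net, nat)$J
  tab <- gdcm:::.population_tables(net, nat)
  ## BGT state columns may only enter MMC rows via Tha -> MP / Tha -> DP
  mmc_acc <- tab$a_index[tab$source == "mmc"]
  bgt_v <- tab$v_index[tab$source == "bgt"]
  nonzero <- which(abs(J[mmc_acc, bgt_v]) > 1e-9, arr.ind = TRUE)
  from_pops <- tab$population[tab$source == "bgt"][nonzero[, 2]]
  expect_true(all(from_pops == "Tha"))
})

test_that("reordering sources permutes states but leaves spectra invariant", {
  net1 <- cbg_network()
  net2 <- dcm_network(
    sources = list(bgt = "BGT", mmc = "MMC"),
    extrinsic = data.frame(
      index = 1:4,
      from_source = c("bgt", "bgt", "mmc", "mmc"),
      from_population = c("Tha", "Tha", "DP", "DP"),
      to_source = c("mmc", "mmc", "bgt", "bgt"),
      to_population = c("MP", "DP", "Str", "STN")),
    A_prior = list(pi = c(110, 588, 672, 127), sigma2 = 1 / 4),
    b_ext = list("Tha->MMC" = c(1, 2), "MMC->Str" = 3, "MMC->STN" = 4),
    channels = list(
      M1 = list(source = "mmc", mixture = c(SP = 0.2, MP = 0.2, DP = 0.6)),
      STN = list(source = "bgt", mixture = c(STN = 1))))
  f <- seq(5, 45, by = 5)
  g1 <- predict_csd(net1, freq = f)$G$baseline
  g2 <- predict_csd(net2, freq = f)$G$baseline
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("delay matrix distinguishes source pairs and spares within-population
           state pairs", {
  net <- cbg_network()
  ds <- build_delay_matrix(net, c(1, 8, 8, 4))
  lay <- state_layout(net)
  ## two states of two different cortical populations: within-cortex delay
  i <- which(lay$source == "mmc" & lay$population == "SP" & lay$deriv == "v")
  j <- which(lay$source == "mmc" & lay$population == "DP" & lay$deriv == "v")
  expect_equal(ds$D[i, j], 1e-3)
  ## a cortical state influenced by a basal-ganglia state
  k <- which(lay$source == "bgt" & lay$population == "Tha" & lay$deriv == "v")
  expect_equal(ds$D[i, k], 8e-3)
  expect_true(all(diag(ds$D) == 0))
  ## a population's own v/vdot pair carries no delay
  i2 <- which(lay$source == "mmc" & lay$population == "SP" &
                lay$deriv == "vdot")
  expect_equal(ds$D[i2, i], 0)
  expect_error(build_delay_matrix(net, c(-1, 8, 8, 4)), "nonnegative")
})

test_that("new models can be registered and coupled to the shipped ones", {
  expect_true(all(c("MMC", "BGT") %in% registered_models()))
  register_single_pop(kind = "TOYCPL", T_ms = 8)
  net <- dcm_network(
    sources = list(mmc = "MMC", toy = "TOYCPL"),
    extrinsic = data.frame(index = 1, from_source = "mmc",
                           from_population = "DP", to_source = "toy",
                           to_population = "P1"))
  expect_equal(n_states(net), 8L + 2L)
  csd <- predict_csd(net, freq = seq(5, 45, 10))
  expect_true(isTRUE(attr(csd, "stable")))
  ## duplicate registration is refused
  expect_error(register_model("MMC", populations = "X",
                              connections = data.frame(index = integer(),
                                                       from = character(),
                                                       to = character(),
                                                       sign = numeric()),
                              priors = list(gamma = list(pi = numeric(),
                                                         sigma2 = 1),
                                            T = list(pi = 1, sigma2 = 1),
                                            R = list(pi = 1, sigma2 = 1)),
                              input_population = "X",
                              output_mixture = c(X = 1)),
               "already registered")
  ## dangling extrinsic endpoint is refused
  expect_error(dcm_network(
    sources = list(mmc = "MMC", toy = "TOYCPL"),
    extrinsic = data.frame(index = 1, from_source = "mmc",
                           from_population = "DP", to_source = "toy",
                           to_population = "NOPE")), "dangling")
})

test_that("a custom flow function is honoured by the assembly", {
  ## same dynamics as the generic one-population model, supplied by hand
  myflow <- function(state, params, afferent, drive) {
    Ts <- params$T / 1000
    c(state[2], (afferent + drive - 2 * state[2] - state[1] / Ts) / Ts)
  }
  register_model("HANDFLOW",
    populations = "P1",
    connections = data.frame(index = integer(), from = character(),
                             to = character(), sign = numeric()),
    priors = list(gamma = list(pi = numeric(), sigma2 = 1 / 4),
                  T = list(pi = 10, sigma2 = 1 / 8),
                  R = list(pi = 2 / 3, sigma2 = 1 / 32)),
    input_population = "P1", output_mixture = c(P1 = 1),
    flow = myflow, overwrite = TRUE)
  net_custom <- dcm_network(sources = list(pop = "HANDFLOW"))
  net_generic <- single_pop_network(T_ms = 10)
  f <- seq(5, 45, 10)
  g1 <- predict_csd(net_custom, freq = f, channel_noise = FALSE)
  g2 <- predict_csd(net_generic, freq = f, channel_noise = FALSE)
  expect_equal(g1$G[[1]], g2$G[[1]], tolerance = 1e-6)
})
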