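test_that("scenario registry encodes the measured affinities consistently", {
  tab <- bli_scenarios()
  kd <- setNames(tab$K_D_nM, tab$name)
  expect_equal(unname(kd["unmethylated"]), 630)
  expect_equal(unname(kd["5mC4"]), 12000)
  expect_equal(unname(kd["5mC1+2+4"]), 9200)
  expect_equal(unname(kd[c("5mC1", "5mC2")]), c(630, 630))
  # K_D = k_off / k_on holds exactly for every scenario
  expect_equal(tab$k_off_s / tab$k_on_Ms * 1e9, tab$K_D_nM, tolerance = 1e-12)
  expect_error(bli_scenario("nope"), "unknown scenario")
  # the stand-in duplex carries the W-box core in the displayed orientation
  expect_true(grepl("GGTCAA", wbox_duplex_sequence()))
})

test_that("the 1:1 model obeys its closed-form identities", {
  k_on <- 2e5; k_off <- 0.126; R_max <- 1.2
  K_D <- k_off / k_on * 1e9  # 630 nM
  # long-time association at C = K_D approaches half-saturation
  expect_equal(model_response(1e6, K_D, k_on, k_off, R_max), R_max / 2,
               tolerance = 1e-9)
  # zero concentration gives zero response
  expect_equal(model_response(c(1, 10, 100), 0, k_on, k_off, R_max),
               rep(0, 3))
  # dissociation half-life
  R0 <- 0.8
  expect_equal(model_response(log(2) / k_off, K_D, k_on, k_off, R_max,
                              phase = "dissociation", R0 = R0),
               R0 / 2, tolerance = 1e-12)
  # initial association slope equals R_eq * k_obs (finite differences)
  C <- 400
  R_eq <- R_max * C / (C + K_D)
  k_obs <- k_on * C * 1e-9 + k_off
  h <- 1e-6
  slope <- model_response(h, C, k_on, k_off, R_max) / h
  expect_equal(slope, R_eq * k_obs, tolerance = 1e-4)
  expect_error(model_response(-1, C, k_on, k_off, R_max), "non-negative")
  expect_error(model_response(1, -5, k_on, k_off, R_max), "non-negative")
})

test_that("simulated sensorgrams follow the model plus calibrated noise", {
  sc <- bli_scenario("unmethylated")
  set <- generate_sensorgram_set(sc, noise_sd = 0, seed = 1)
  expect_length(set, 5)  # default five-concentration ladder
  sg <- set[[3]]  # C = K_D
  expect_equal(sg$concentration_nM[1], 630)
  # default phase schedule: 120/300/120/300/900 s
  expect_equal(as.integer(table(sg$phase)[c("baseline1", "loading", "baseline2",
                                            "association", "dissociation")]),
               c(120L, 300L, 120L, 300L, 900L))
  # at C = K_D the association end sits at R_max/2 (equilibrated)
  assoc <- sg[sg$phase == "association", ]
  expect_equal(assoc$response_nm[nrow(assoc)], sc$R_max_nm / 2, tolerance = 1e-3)
  # times strictly increasing
  expect_true(all(diff(sg$time_s) > 0))

  # noise standard deviation converges to the requested value
  sched <- phase_schedule(association = 3000, dissociation = 3000, interval = 0.5)
  noisy <- generate_sensorgram_set(sc, concentrations = c(315, 630),
                                   schedule = sched, noise_sd = 0.05, seed = 2)
  clean <- generate_sensorgram_set(sc, concentrations = c(315, 630),
                                   schedule = sched, noise_sd = 0)
  resid <- noisy[[1]]$response_nm - clean[[1]]$response_nm
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.05) / 0.05, 0.05)

  expect_error(generate_sensorgram_set(sc, concentrations = numeric(0)),
               "concentrations")
  expect_error(generate_sensorgram_set(sc, noise_sd = -1), "non-negative")
})

test_that("R_eq extraction is exact when equilibrated and falls back when short", {
  sc <- bli_scenario("unmethylated")
  set <- generate_sensorgram_set(sc, noise_sd = 0)
  for (sg in set) {
    C <- sg$concentration_nM[1]
    expect_equal(as.numeric(extract_req(sg)),
                 sc$R_max_nm * C / (C + sc$K_D_nM), tolerance = 1e-3)
  }
  # constant-zero trace
  zero <- set[[1]]
  zero$response_nm <- 0
  expect_equal(as.numeric(extract_req(zero)), 0)

  # slow binding (k_obs * t_end = 1): tail mean is biased low,
  # the exponential plateau stays within 1%
  slow <- list(K_D_nM = 630, k_off_s = 0.00252, R_max_nm = 1.2,
               k_on_Ms = 0.00252 / 630e-9, name = "slow")
  C <- 630  # k_obs = 2 * k_off = 0.00336... pick schedule so k_obs * t = 1
  k_obs <- slow$k_on_Ms * C * 1e-9 + slow$k_off_s
  sched <- phase_schedule(association = round(1 / k_obs), dissociation = 900)
  sg <- generate_sensorgram_set(slow, concentrations = c(C, 2 * C),
                                schedule = sched, noise_sd = 0)[[1]]
  truth <- slow$R_max_nm * C / (C + 630)
  tail_est <- as.numeric(extract_req(sg, method = "tail_mean"))
  plat_est <- as.numeric(extract_req(sg, method = "plateau"))
  expect_lt(tail_est, 0.8 * truth)                 # visibly biased low
  expect_lt(abs(plat_est - truth) / truth, 0.01)   # within 1%

  assoc_start <- min(sg$time_s[sg$phase == "association"])
  short <- sg[sg$phase != "association" | sg$time_s <= assoc_start + 14, ]
  expect_warning(extract_req(short), "fewer than 20")
})

test_that("steady-state hyperbola fits recover exact inputs and flag limits", {
  K_D <- 630; R_max <- 1.2
  C <- c(126, 315, 630, 1260, 3150)
  Req <- R_max * C / (C + K_D)
  fit <- fit_steady_state(C, Req)
  expect_equal(fit$K_D_nM, K_D, tolerance = 1e-9)
  expect_equal(fit$R_max_nm, R_max, tolerance = 1e-9)
  expect_equal(fit$flag, "ok")

  # saturation: R_eq flat in C, K_D below the tested range
  sat <- fit_steady_state(C, R_max * C / (C + 1))
  expect_equal(sat$flag, "saturated")
  # linear regime: all C far below K_D, only a lower bound on K_D
  lin <- fit_steady_state(C, R_max * C / (C + 1e6))
  expect_equal(lin$flag, "lower_bound_only")

  expect_error(fit_steady_state(C[1:2], Req[1:2]), "at least 3")
  expect_error(fit_steady_state(C, rep(-1, 5)), "non-positive")
})

test_that("global kinetic fit round-trips noiseless parameters", {
  sc <- bli_scenario("unmethylated")  # k_on 2e5, k_off 0.126
  set <- generate_sensorgram_set(sc, noise_sd = 0)
  fit <- fit_kinetic_global(set)
  expect_true(fit$converged)
  expect_equal(fit$k_on_Ms, sc$k_on_Ms, tolerance = 1e-6)
  expect_equal(fit$k_off_s, sc$k_off_s, tolerance = 1e-6)
  expect_equal(fit$R_max_nm, sc$R_max_nm, tolerance = 1e-6)
  # K_D identity holds exactly for the returned fit
  expect_identical(fit$K_D_nM, fit$k_off_s / fit$k_on_Ms * 1e9)
  expect_equal(fit$K_D_nM, 630, tolerance = 1e-6)

  expect_error(fit_kinetic_global(set[3]), "single concentration")
})

test_that("kinetic K_D stays near truth under moderate noise", {
  sc <- bli_scenario("unmethylated")
  kds <- vapply(1:10, function(s) {
    set <- generate_sensorgram_set(sc, noise_sd = 0.02 * sc$R_max_nm, seed = 40 + s)
    fit_kinetic_global(set)$K_D_nM
  }, numeric(1))
  expect_lt(abs(median(kds) - 630) / 630, 0.1)
})

test_that("per-concentration fits agree with the shared-parameter truth", {
  # the slow (tight-binding) scenario: k_obs is resolvable at 1 Hz sampling
  sc <- bli_scenario("unmethylated")
  set <- generate_sensorgram_set(sc, noise_sd = 0)
  tab <- fit_kinetic_per_concentration(set)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$k_off_s, rep(sc$k_off_s, 5), tolerance = 1e-3)
  expect_equal(tab$K_D_nM, rep(sc$K_D_nM, 5), tolerance = 0.05)
})

test_that("sensorgram CSV round-trips", {
  set <- generate_sensorgram_set("5mC4", noise_sd = 0.01, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensorgrams_csv(set, path)
  back <- read_sensorgrams_csv(path)
  expect_length(back, 5)
  expect_equal(back[[1]]$response_nm, set[[1]]$response_nm, tolerance = 1e-6)
  expect_equal(back[[5]]$concentration_nM[1], set[[5]]$concentration_nM[1])
})

test_that("model R_eq is increasing in concentration and bounded by R_max", {
  sc <- bli_scenario("unmethylated")
  C <- sort(runif(20, 1, 1e5))
  req <- vapply(C, function(cc) model_response(1e7, cc, sc$k_on_Ms,
                                               sc$k_off_s, sc$R_max_nm),
                numeric(1))
  expect_true(all(diff(req) > 0))
  expect_true(all(req < sc$R_max_nm))
})
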