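#' Ground-truth binding scenarios for W-box duplex methylation states
#'
#' Registry of 1:1 binding scenarios for the interaction between the
#' AtWRKY40 DNA-binding domain and a 16-mer W-box duplex, one scenario per
#' duplex methylation state. Steady-state affinities anchor the registry:
#' 630 nM for the unmethylated duplex, essentially unchanged when the
#' reverse-strand cytosines at W-box positions 1 or 2 are methylated,
#' 12 uM when the forward-strand position-4 cytosine is methylated, and
#' 9.2 uM for the triple-methylated duplex (no additive effect beyond
#' position 4). The `C4T_mutant` scenario (cytosine-to-thymine substitution,
#' which abolishes W-box function) is illustrative only: its affinity is set
#' slightly weaker than the 5mC4 state, mirroring the qualitative observation
#' that methylation at position 4 is almost as disruptive as the mutation.
#'
#' Dissociation rates are representative of fast-exchange TF-DNA binding;
#' `k_on = k_off / K_D` holds exactly for every scenario.
#'
#' @return a data frame with one row per scenario: `name`, `K_D_nM`,
#'   `k_off_s` (1/s), `k_on_Ms` (1/(M s)) and `R_max_nm`.
#' @export
bli_scenarios <- function() {
  tab <- data.frame(
    name = c("unmethylated", "5mC1", "5mC2", "5mC4", "5mC1+2+4", "C4T_mutant"),
    K_D_nM = c(630, 630, 630, 12000, 9200, 20000),
    k_off_s = c(0.126, 0.126, 0.126, 2.4, 1.84, 4.0),
    R_max_nm = c(1.2, 1.2, 1.2, 1.2, 1.2, 1.2),
    stringsAsFactors = FALSE
  )
  tab$k_on_Ms <- tab$k_off_s / (tab$K_D_nM * 1e-9)
  tab
}

#' @rdname bli_scenarios
#' @param name scenario name.
#' @return for `bli_scenario`, a list of class `"bli_scenario"` with the
#'   scenario's parameters.
#' @export
bli_scenario <- function(name) {
  tab <- bli_scenarios()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown scenario '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  }
  kd_from_rates <- row$k_off_s / row$k_on_Ms * 1e9
  stopifnot(abs(kd_from_rates - row$K_D_nM) <= 1e-9 * row$K_D_nM)
  structure(as.list(row), class = "bli_scenario")
}

#' Representative W-box duplex forward strand (synthetic stand-in)
#'
#' A 16-mer containing the W-box core in the displayed orientation
#' `GGTCAA` (reverse complement of `TTGACC`). This is a synthetic stand-in
#' for the promoter-derived duplex used in the wet-lab experiments, whose
#' exact flanking sequence is not part of this package's inputs; it exists so
#' that the scenario registry can be tied to a concrete sequence with the
#' position-4 cytosine in a CHH context.
#'
#' @return a single character string of length 16.
#' @export
wbox_duplex_sequence <- function() {
  "CTAGTGGTCAAGCTAG"
}

#' Bio-Layer Interferometry phase schedule
#'
#' Default schedule: baseline 120 s, loading 300 s, baseline 120 s,
#' association 300 s, dissociation 900 s, sampled every second.
#'
#' @param baseline1,loading,baseline2,association,dissociation phase
#'   durations in seconds (all positive).
#' @param interval sampling interval in seconds.
#' @return a list of class `"phase_schedule"` with `phases` (named durations)
#'   and `interval`.
#' @export
phase_schedule <- function(baseline1 = 120, loading = 300, baseline2 = 120,
                           association = 300, dissociation = 900,
                           interval = 1) {
  phases <- c(baseline1 = baseline1, loading = loading, baseline2 = baseline2,
              association = association, dissociation = dissociation)
  if (any(phases <= 0) || interval <= 0) stop("phase durations and interval must be positive")
  structure(list(phases = phases, interval = interval), class = "phase_schedule")
}

#' 1:1 Langmuir binding model response
#'
#' Association: `R(t) = R_eq * (1 - exp(-(k_on*C + k_off) * t))` with
#' `R_eq = R_max * C / (C + K_D)` and `K_D = k_off / k_on`. Dissociation:
#' `R(t) = R0 * exp(-k_off * t)`. Baseline and loading phases are constant at
#' `R0` (loading is treated as an immobilization offset that reference
#' subtraction removes before analysis).
#'
#' @param t time in seconds, relative to the phase start (vectorized).
#' @param C analyte concentration in nM.
#' @param k_on association rate in 1/(M s).
#' @param k_off dissociation rate in 1/s.
#' @param R_max saturating response in nm.
#' @param phase one of `"association"`, `"dissociation"`, `"baseline1"`,
#'   `"baseline2"`, `"loading"`.
#' @param R0 starting response of the phase (dissociation) or constant level
#'   (baselines/loading).
#' @return response in nm, same length as `t`.
#' @export
model_response <- function(t, C, k_on, k_off, R_max,
                           phase = "association", R0 = 0) {
  if (any(t < 0)) stop("time must be non-negative")
  if (C < 0) stop("concentration must be non-negative")
  stopifnot(k_on > 0, k_off > 0, R_max >= 0)
  switch(phase,
    association = {
      K_D_nM <- k_off / k_on * 1e9
      R_eq <- R_max * C / (C + K_D_nM)
      k_obs <- k_on * C * 1e-9 + k_off
      R_eq * (1 - exp(-k_obs * t))
    },
    dissociation = R0 * exp(-k_off * t),
    baseline1 = ,
    baseline2 = ,
    loading = rep(R0, length(t)),
    stop("unknown phase '", phase, "'")
  )
}

#' Simulate a set of BLI sensorgrams from a binding scenario
#'
#' One sensorgram per analyte concentration, following the 1:1 model of
#' [model_response()] plus i.i.d. Gaussian noise. Responses are
#' reference-subtracted: the baseline and loading phases sit at zero (plus
#' noise) and the dissociation phase starts from the model's end-of-association
#' response. The default concentration ladder has five members spanning
#' 0.2-5x the scenario's K_D, matching a five-concentration experimental
#' design.
#'
#' @param scenario a scenario name (see [bli_scenarios()]), a
#'   `"bli_scenario"`, or a list with `K_D_nM`, `k_on_Ms`, `k_off_s`,
#'   `R_max_nm`.
#' @param concentrations analyte concentrations in nM (>= 2 distinct,
#'   positive); default `K_D * c(0.2, 0.5, 1, 2, 5)`.
#' @param schedule a [phase_schedule()].
#' @param noise_sd standard deviation of the Gaussian noise in response units
#'   (nm).
#' @param seed optional integer seed.
#' @return a list of class `"sensorgram_set"`; each element is a data frame
#'   (class `"sensorgram"`) with `time_s` (cumulative), `phase`,
#'   `response_nm` and `concentration_nM`.
#' @export
generate_sensorgram_set <- function(scenario, concentrations = NULL,
                                    schedule = phase_schedule(),
                                    noise_sd = 0, seed = NULL) {
  if (is.character(scenario)) scenario <- bli_scenario(scenario)
  stopifnot(inherits(schedule, "phase_schedule"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(concentrations)) {
    concentrations <- scenario$K_D_nM * c(0.2, 0.5, 1, 2, 5)
  }
  if (length(concentrations) < 2L || length(unique(concentrations)) < 2L) {
    stop("at least 2 distinct concentrations are required")
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (!is.null(seed)) set.seed(seed)

  out <- lapply(concentrations, function(C) {
    .simulate_one(scenario, C, schedule, noise_sd)
  })
  structure(out, class = "sensorgram_set", scenario = scenario$name)
}

.simulate_one <- function(scenario, C, schedule, noise_sd) {
  int <- schedule$interval
  pieces <- list()
  t0 <- 0
  assoc_end_R <- NA_real_
  for (ph in names(schedule$phases)) {
    dur <- schedule$phases[[ph]]
    t_rel <- seq(int, dur, by = int)
    resp <- if (ph == "dissociation") {
      model_response(t_rel, C, scenario$k_on_Ms, scenario$k_off_s,
                     scenario$R_max_nm, phase = "dissociation", R0 = assoc_end_R)
    } else if (ph == "association") {
      r <- model_response(t_rel, C, scenario$k_on_Ms, scenario$k_off_s,
                          scenario$R_max_nm, phase = "association")
      assoc_end_R <- model_response(dur, C, scenario$k_on_Ms, scenario$k_off_s,
                                    scenario$R_max_nm, phase = "association")
      r
    } else {
      rep(0, length(t_rel))
    }
    pieces[[ph]] <- data.frame(time_s = t0 + t_rel, phase = ph,
                               response_nm = resp, stringsAsFactors = FALSE)
    t0 <- t0 + dur
  }
  sg <- do.call(rbind, pieces)
  rownames(sg) <- NULL
  if (noise_sd > 0) sg$response_nm <- sg$response_nm + rnorm(nrow(sg), 0, noise_sd)
  sg$concentration_nM <- C
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

#' Read / write sensorgrams as CSV
#'
#' Column layout: `time_s`, `response_nm`, `phase`, `concentration_nM`.
#' Multiple concentrations may share one file; the reader splits them back
#' into a sensorgram set.
#'
#' @param path CSV file path.
#' @return for the reader, a `"sensorgram_set"`.
#' @export
read_sensorgrams_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "response_nm", "phase", "concentration_nM")
  if (!all(required %in% names(df))) {
    stop("sensorgram CSV must have columns: ", paste(required, collapse = ", "))
  }
  out <- lapply(split(df, df$concentration_nM), function(x) {
    x <- x[order(x$time_s), , drop = FALSE]
    rownames(x) <- NULL
    class(x) <- c("sensorgram", "data.frame")
    x
  })
  out <- out[order(as.numeric(names(out)))]
  structure(unname(out), class = "sensorgram_set")
}

#' @rdname read_sensorgrams_csv
#' @param sensorgrams a `"sensorgram_set"` or single sensorgram data frame.
#' @export
write_sensorgrams_csv <- function(sensorgrams, path) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  df <- do.call(rbind, lapply(sensorgrams, function(x) {
    as.data.frame(x)[, c("time_s", "response_nm", "phase", "concentration_nM")]
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Equilibrium response of a sensorgram's association phase
#'
#' Default estimator: mean of the final 5% of association-phase samples
#' (`tail_mean`). Alternative: plateau of a single-exponential fit
#' (`plateau`), which is unbiased even when the association phase has not
#' equilibrated. With fewer than 20 association samples the tail mean is
#' unreliable and the function falls back to the plateau fit with a warning.
#'
#' @param sensorgram a sensorgram data frame.
#' @param method `"tail_mean"` or `"plateau"`.
#' @param tail_frac fraction of the association phase averaged by
#'   `tail_mean`.
#' @return the R_eq estimate (nm) with attribute `method`.
#' @export
extract_req <- function(sensorgram, method = c("tail_mean", "plateau"),
                        tail_frac = 0.05) {
  method <- match.arg(method)
  assoc <- sensorgram[sensorgram$phase == "association", , drop = FALSE]
  if (nrow(assoc) == 0L) stop("sensorgram has no association phase")
  t <- assoc$time_s - min(assoc$time_s) + diff(range(assoc$time_s)) / (nrow(assoc) - 1L)
  if (method == "tail_mean" && nrow(assoc) < 20L) {
    warning("association phase has fewer than 20 samples; using the exponential-plateau estimate")
    method <- "plateau"
  }
  est <- if (method == "tail_mean") {
    k <- max(1L, ceiling(tail_frac * nrow(assoc)))
    mean(utils::tail(assoc$response_nm, k))
  } else {
    .plateau_fit(t, assoc$response_nm)
  }
  structure(est, method = method)
}

.plateau_fit <- function(t, y) {
  a0 <- max(max(y), 1e-9)
  thalf <- t[which.min(abs(y - a0 / 2))]
  k0 <- log(2) / max(thalf, t[1L])
  dat <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = dat,
                           start = list(A = a0, k = k0),
                           lower = c(A = 0, k = 1e-8),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  unname(coef(fit)[["A"]])
}

#' Steady-state fit of the binding hyperbola
#'
#' Least-squares fit of `R_eq = R_max * C / (C + K_D)` to equilibrium
#' responses at several concentrations. Positivity of both parameters is
#' enforced by fitting on the log scale. Initialization:
#' `R_max = 1.1 * max(R_eq)`, `K_D = median(C)`.
#'
#' The fit is flagged `lower_bound_only` when the estimated K_D lies far
#' above the highest tested concentration (the data only constrain a lower
#' bound) and `saturated` when it lies far below the lowest concentration
#' (R_eq is flat in C and the R_max/K_D split is unidentifiable).
#'
#' @param C concentrations in nM (>= 3), or a data frame with columns `C`
#'   and `Req`.
#' @param Req equilibrium responses (nm).
#' @return a list of class `"steady_state_fit"`: `K_D_nM`, `R_max_nm`,
#'   `rss`, `se` (named, delta-method), `flag` (`"ok"`, `"lower_bound_only"`
#'   or `"saturated"`) and `converged`.
#' @export
fit_steady_state <- function(C, Req = NULL) {
  if (is.data.frame(C)) {
    Req <- C$Req
    C <- C$C
  }
  stopifnot(length(C) == length(Req))
  if (length(unique(C)) < 3L) stop("at least 3 distinct concentrations are required")
  if (all(Req <= 0)) stop("all equilibrium responses are non-positive; nothing to fit")

  start <- list(lR = log(1.1 * max(Req)), lK = log(median(C)))
  fit <- tryCatch(
    minpack.lm::nlsLM(Req ~ exp(lR) * C / (C + exp(lK)), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # a flat response curve (saturation) makes the R_max/K_D split
    # unidentifiable and the optimizer can fail outright; report it as the
    # saturation limit rather than a bare failure
    spread <- diff(range(Req)) / max(abs(Req))
    flag <- if (spread < 0.05) "saturated" else "failed"
    return(structure(list(K_D_nM = NA_real_, R_max_nm = NA_real_, rss = NA_real_,
                          se = c(K_D_nM = NA_real_, R_max_nm = NA_real_),
                          flag = flag, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "steady_state_fit"))
  }
  cf <- coef(fit)
  K_D <- exp(cf[["lK"]])
  R_max <- exp(cf[["lR"]])
  sm <- summary(fit)$coefficients
  se <- c(K_D_nM = K_D * sm["lK", "Std. Error"],
          R_max_nm = R_max * sm["lR", "Std. Error"])
  flag <- if (K_D > 3 * max(C)) "lower_bound_only"
          else if (K_D < min(C) / 3) "saturated"
          else "ok"
  structure(list(K_D_nM = K_D, R_max_nm = R_max,
                 rss = sum(residuals(fit)^2), se = se, flag = flag,
                 converged = TRUE),
            class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("steady-state 1:1 fit: K_D = %.4g nM, R_max = %.4g nm [%s]\n",
              x$K_D_nM, x$R_max_nm, x$flag))
  invisible(x)
}

# association/dissociation segments with phase-relative times, stacked
.kinetic_frame <- function(sensorgrams) {
  do.call(rbind, lapply(sensorgrams, function(sg) {
    keep <- sg$phase %in% c("association", "dissociation")
    x <- sg[keep, , drop = FALSE]
    starts <- tapply(x$time_s, x$phase, min)
    x$t <- x$time_s - (starts[x$phase] - diff(sort(unique(sg$time_s)))[1L])
    assoc_t <- x$t[x$phase == "association"]
    x$t_assoc_end <- max(assoc_t)
    x
  }))
}

#' Global kinetic fit of the 1:1 binding model
#'
#' Nonlinear least squares over the association and dissociation segments of
#' all sensorgrams jointly, with `k_on`, `k_off` and `R_max` shared across
#' concentrations (fitted on the log scale). Dissociation curves start from
#' the model's end-of-association response, so the whole set is described by
#' the three shared parameters.
#'
#' Initialization: `k_off` from a log-linear regression on the early
#' dissociation of the highest-concentration curve; per-concentration
#' `k_obs` from single-exponential association fits; `k_on` from the slope
#' of `k_obs` versus concentration.
#'
#' @param sensorgrams a `"sensorgram_set"` (or list of sensorgram data
#'   frames) covering at least 2 distinct concentrations.
#' @return a list of class `"kinetic_fit"`: `k_on_Ms`, `k_off_s`,
#'   `R_max_nm`, `K_D_nM` (`= k_off / k_on`, exactly), `rss`, `se` (named,
#'   delta-method) and `converged`. On non-convergence the parameters are
#'   `NA`, `converged` is `FALSE` and `message` holds the diagnostics; no
#'   silent failure.
#' @export
fit_kinetic_global <- function(sensorgrams) {
  conc <- vapply(sensorgrams, function(x) x$concentration_nM[1L], numeric(1L))
  if (length(unique(conc)) < 2L) {
    stop("kinetic parameters are not identifiable from a single concentration")
  }
  df <- .kinetic_frame(sensorgrams)
  init <- .kinetic_init(sensorgrams, conc)

  pred <- function(lkon, lkoff, lRmax, C, t, phase, t_assoc_end) {
    k_on <- exp(lkon); k_off <- exp(lkoff); R_max <- exp(lRmax)
    K_D_nM <- k_off / k_on * 1e9
    R_eq <- R_max * C / (C + K_D_nM)
    k_obs <- k_on * C * 1e-9 + k_off
    ifelse(phase == "association",
           R_eq * (1 - exp(-k_obs * t)),
           R_eq * (1 - exp(-k_obs * t_assoc_end)) * exp(-k_off * t))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response_nm ~ pred(lkon, lkoff, lRmax, concentration_nM, t, phase, t_assoc_end),
      data = df,
      start = list(lkon = log(init$k_on), lkoff = log(init$k_off),
                   lRmax = log(init$R_max)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("global kinetic fit did not converge: ", conditionMessage(fit))
    return(structure(list(k_on_Ms = NA_real_, k_off_s = NA_real_,
                          R_max_nm = NA_real_, K_D_nM = NA_real_,
                          rss = NA_real_, se = NULL, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "kinetic_fit"))
  }
  cf <- coef(fit)
  k_on <- exp(cf[["lkon"]]); k_off <- exp(cf[["lkoff"]]); R_max <- exp(cf[["lRmax"]])
  sm <- summary(fit)$coefficients
  se <- c(k_on_Ms = k_on * sm["lkon", "Std. Error"],
          k_off_s = k_off * sm["lkoff", "Std. Error"],
          R_max_nm = R_max * sm["lRmax", "Std. Error"])
  structure(list(k_on_Ms = k_on, k_off_s = k_off, R_max_nm = R_max,
                 K_D_nM = k_off / k_on * 1e9, rss = sum(residuals(fit)^2),
                 se = se, converged = TRUE),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("kinetic fit: NOT converged -", x$message, "\n")
  } else {
    cat(sprintf("kinetic 1:1 fit: k_on = %.4g /M/s, k_off = %.4g /s, K_D = %.4g nM\n",
                x$k_on_Ms, x$k_off_s, x$K_D_nM))
  }
  invisible(x)
}

#' @rdname fit_kinetic_global
#' @details `fit_kinetic_per_concentration()` analyses each sensorgram on its
#'   own: `k_off` from an exponential fit of the dissociation, `k_obs` and
#'   `R_eq` from a single-exponential fit of the association, then
#'   `k_on = (k_obs - k_off) / C`. One row per concentration; useful as a
#'   heterogeneity diagnostic. The global fit is the default analysis.
#' @export
fit_kinetic_per_concentration <- function(sensorgrams) {
  rows <- lapply(sensorgrams, function(sg) {
    C <- sg$concentration_nM[1L]
    assoc <- sg[sg$phase == "association", , drop = FALSE]
    dis <- sg[sg$phase == "dissociation", , drop = FALSE]
    int <- min(diff(assoc$time_s))
    ta <- assoc$time_s - (min(assoc$time_s) - int)  # first sample at t = interval
    td <- dis$time_s - (min(dis$time_s) - int)
    a0 <- max(max(assoc$response_nm), 1e-9)
    adat <- data.frame(t = ta, y = assoc$response_nm)
    ddat <- data.frame(t = td, y = dis$response_nm)
    afit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = adat,
                              start = list(A = a0, k = 0.05),
                              lower = c(A = 0, k = 1e-8))
    dfit <- minpack.lm::nlsLM(y ~ R0 * exp(-k * t), data = ddat,
                              start = list(R0 = max(ddat$y[1L], 1e-9),
                                           k = 0.05),
                              lower = c(R0 = 0, k = 1e-8))
    k_obs <- coef(afit)[["k"]]
    k_off <- coef(dfit)[["k"]]
    k_on <- max((k_obs - k_off) / (C * 1e-9), 1e-12)
    data.frame(concentration_nM = C, R_eq_nm = coef(afit)[["A"]],
               k_obs_s = k_obs, k_off_s = k_off, k_on_Ms = k_on,
               K_D_nM = k_off / k_on * 1e9)
  })
  do.call(rbind, rows)
}

.kinetic_init <- function(sensorgrams, conc) {
  top <- sensorgrams[[which.max(conc)]]
  dis <- top[top$phase == "dissociation", , drop = FALSE]
  t <- dis$time_s - min(dis$time_s)
  early <- t <= 0.2 * max(t) & dis$response_nm > 0
  k_off <- if (sum(early) >= 3L) {
    max(-coef(lm(log(dis$response_nm[early]) ~ t[early]))[[2L]], 1e-5)
  } else 0.1

  k_obs <- vapply(sensorgrams, function(sg) {
    assoc <- sg[sg$phase == "association", , drop = FALSE]
    int <- min(diff(assoc$time_s))
    ta <- assoc$time_s - (min(assoc$time_s) - int)
    a0 <- max(max(assoc$response_nm), 1e-9)
    adat <- data.frame(t = ta, y = assoc$response_nm)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * (1 - exp(-k * t)), data = adat,
                        start = list(A = a0, k = k_off + 1e-3),
                        lower = c(A = 0, k = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(fit)) k_off * 2 else coef(fit)[["k"]]
  }, numeric(1L))
  slope <- coef(lm(k_obs ~ I(conc * 1e-9)))[[2L]]
  k_on <- if (is.finite(slope) && slope > 0) slope else k_off / (median(conc) * 1e-9)
  K_D_nM <- k_off / k_on * 1e9
  A_top <- max(vapply(sensorgrams, function(sg)
    max(sg$response_nm[sg$phase == "association"]), numeric(1L)))
  R_max <- max(A_top * (max(conc) + K_D_nM) / max(conc), 1e-6)
  list(k_on = k_on, k_off = k_off, R_max = R_max)
}

#' Steady-state K_D recovery from simulated sensorgram sets
#'
#' Repeatedly simulates a five-concentration sensorgram set from a scenario,
#' estimates R_eq per concentration and fits the steady-state hyperbola;
#' returns all recovered K_D values. This is the round-trip used to check
#' that the fitting pipeline recovers the registry affinities under noise.
#'
#' @param scenario scenario name or `"bli_scenario"`.
#' @param n_seeds number of simulation replicates.
#' @param noise_frac Gaussian noise standard deviation as a fraction of
#'   R_max.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param schedule a [phase_schedule()].
#' @return numeric vector of recovered K_D values (nM), length `n_seeds`.
#' @export
recover_steady_state_kd <- function(scenario, n_seeds = 50, noise_frac = 0.02,
                                    seed = 1, schedule = phase_schedule()) {
  if (is.character(scenario)) scenario <- bli_scenario(scenario)
  vapply(seq_len(n_seeds), function(i) {
    set <- generate_sensorgram_set(scenario,
                                   noise_sd = noise_frac * scenario$R_max_nm,
                                   schedule = schedule, seed = seed + i)
    req <- vapply(set, extract_req, numeric(1L))
    C <- vapply(set, function(x) x$concentration_nM[1L], numeric(1L))
    fit_steady_state(C, req)$K_D_nM
  }, numeric(1L))
}
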