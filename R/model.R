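#' @useDynLib somnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# State variable ordering shared with the compiled integrator.
.state_names <- c(
  "Ve_CA3", "Vi_CA3", "c_CA3", "Ve_CA1", "Vi_CA1", "c_CA1",
  "Ve_CX", "c_CX", "Vi_CX", "Ve_CXp", "c_CXp", "Vi_CXp",
  "Ve_MD", "u_e", "Vi_TRN", "u_i", "Ve_REU")

#' Sigmoid firing rate of cortical, hippocampal and reuniens populations
#'
#' Population firing rate as a sigmoid function of mean membrane potential:
#' `r(V) = r0 + r1 / (1 + exp(-(V - Vstar) / g))`, strictly increasing in
#' `V`, bounded in `[r0, r0 + r1]`.
#'
#' @param V membrane potential (mV); vectorized.
#' @param p list with `r0`, `r1` (Hz), `g` (mV, sharpness > 0) and
#'   `Vstar` (mV, threshold).
#' @return firing rate in Hz.
#' @export
sigmoid_rate <- function(V, p) {
  stopifnot(is.list(p), p$r1 > 0, p$g > 0, p$r0 >= 0)
  if (any(!is.finite(V))) stop("non-finite membrane potential")
  p$r0 + p$r1 / (1 + exp(-(V - p$Vstar) / p$g))
}

#' Tonic/burst firing rate of thalamic (MD, TRN) populations
#'
#' Convex blend of a tonic and a burst sigmoid, weighted by `exp(L * u)`
#' and `1 - exp(L * u)` where `u <= 0` is the burst variable: `u = 0`
#' gives the pure tonic rate, strongly negative `u` the pure burst rate.
#'
#' @param V membrane potential (mV).
#' @param u burst variable (must be `<= 0`; positive values are an error
#'   for user-supplied states).
#' @param p list with tonic (`RT`, `VT`, `gT`) and burst (`RB`, `VB`,
#'   `gB`) sigmoid parameters and switch sharpness `L > 0`.
#' @return firing rate in Hz.
#' @export
burst_tonic_rate <- function(V, u, p) {
  stopifnot(p$L > 0, p$gT > 0, p$gB > 0)
  if (any(u > 1e-12)) stop("burst variable u must be <= 0 (exp(L*u) <= 1)")
  w <- exp(p$L * pmin(u, 0))
  rt <- p$RT / (1 + exp(-(V - p$VT) / p$gT))
  rb <- p$RB / (1 + exp(-(V - p$VB) / p$gB))
  w * rt + (1 - w) * rb
}

#' Adapted excitatory-to-excitatory synaptic strength
#'
#' Spike-frequency adaptation scales the maximal E-E strength by a
#' decreasing sigmoid of the adaptation variable:
#' `J(c) = J0 / (1 + exp((c - cstar) / gc))`.
#'
#' @param c adaptation variable (nonnegative under nonnegative increments).
#' @param p list with `J0` (maximal strength), `gc > 0` (sharpness) and
#'   `cstar` (threshold).
#' @return effective synaptic strength, in `(0, J0)`.
#' @export
adapted_strength <- function(c, p) {
  stopifnot(p$gc > 0, p$J0 > 0)
  if (any(!is.finite(c))) stop("non-finite adaptation variable")
  p$J0 / (1 + exp((c - p$cstar) / p$gc))
}

#' Model parameters
#'
#' Reads the shipped calibrated default parameter file (key = value,
#' one symbol per line, grouped by network/pathway) and applies any
#' overrides. Every constant of the rate equations is addressable by its
#' key, e.g. `J.ee.CA3_CA1`, `P.ee.CX`, `tau.REU`, `RT.MD`.
#'
#' All numeric values are this package's own calibration: they were tuned
#' so that the isolated subnetworks generate their characteristic rhythms
#' (CA3 sharp waves, cortical slow oscillation, MD-TRN spindle
#' oscillations, CA1 ripples) and the coupled network operates in the
#' NREM-like coupling regime; see the methods vignette.
#'
#' @param file optional path to a parameter file; defaults to the shipped
#'   calibration.
#' @param ... named overrides, e.g. `model_params(alpha.CA1_REU = 0.5)`.
#' @return named list of parameters, class `"somnet_params"`.
#' @export
model_params <- function(file = NULL, ...) {
  if (is.null(file))
    file <- system.file("extdata", "model_params_default.txt",
                        package = "somnet")
  p <- read_params(file)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(p)
  structure(p, class = "somnet_params")
}

#' Read / write a model parameter file
#'
#' Plain-text `key = value` format; `#` starts a comment.
#'
#' @param file path.
#' @return named list of numeric parameters.
#' @export
read_params <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, 1L) != 2L)
  if (length(bad))
    stop("malformed parameter line ", bad[1], ": ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric parameter value for key ",
                        keys[which(is.na(vals))[1]])
  stats::setNames(as.list(vals), keys)
}

#' @rdname read_params
#' @param params named list of parameters.
#' @export
write_params <- function(params, file) {
  writeLines(sprintf("%s = %.10g", names(params), unlist(params)), file)
  invisible(file)
}

validate_params <- function(p) {
  taus <- grep("^tau\\.", names(p), value = TRUE)
  for (k in taus) if (p[[k]] <= 0) stop("time constant ", k, " must be > 0")
  for (k in grep("^P\\.", names(p), value = TRUE))
    if (p[[k]] < 0 || p[[k]] > 1) stop("connection probability ", k,
                                       " outside [0, 1]")
  for (k in grep("^N\\.", names(p), value = TRUE))
    if (p[[k]] < 0) stop("neuron count ", k, " must be >= 0")
  for (k in grep("^(g|gc|gT|gB|q)\\.", names(p), value = TRUE))
    if (p[[k]] <= 0) stop("sharpness ", k, " must be > 0")
  if (p$r1 <= 0 || p$r0 < 0) stop("need r1 > 0 and r0 >= 0")
  invisible(TRUE)
}

# Pathways of the rate equations: target term name -> (N key, P key, J key).
.pathways <- list(
  W.ee.CA3     = c("N.e.CA3", "P.ee.CA3", "J.ee.CA3"),
  W.ie.CA3     = c("N.i.CA3", "P.ie.CA3", "J.ie.CA3"),
  W.ei.CA3     = c("N.e.CA3", "P.ei.CA3", "J.ei.CA3"),
  W.ii.CA3     = c("N.i.CA3", "P.ii.CA3", "J.ii.CA3"),
  W.ie.CA1     = c("N.i.CA1", "P.ie.CA1", "J.ie.CA1"),
  W.ei.CA1     = c("N.e.CA1", "P.ei.CA1", "J.ei.CA1"),
  W.ii.CA1     = c("N.i.CA1", "P.ii.CA1", "J.ii.CA1"),
  W.ee.CA3_CA1 = c("N.e.CA3", "P.ee.CA3_CA1", "J.ee.CA3_CA1"),
  W.ei.CA3_CA1 = c("N.e.CA3", "P.ei.CA3_CA1", "J.ei.CA3_CA1"),
  W.ee.REU_CA1 = c("N.e.REU", "P.ee.REU_CA1", "J.ee.REU_CA1"),
  W.ei.REU_CA1 = c("N.e.REU", "P.ei.REU_CA1", "J.ei.REU_CA1"),
  W.ee.CX      = c("N.e.CX", "P.ee.CX", "J.ee.CX"),
  W.ie.CX      = c("N.i.CX", "P.ie.CX", "J.ie.CX"),
  W.ei.CX      = c("N.e.CX", "P.ei.CX", "J.ei.CX"),
  W.ii.CX      = c("N.i.CX", "P.ii.CX", "J.ii.CX"),
  W.ee.CXp_CX  = c("N.e.CXp", "P.ee.CXp_CX", "J.ee.CXp_CX"),
  W.ei.CXp_CX  = c("N.e.CXp", "P.ei.CXp_CX", "J.ei.CXp_CX"),
  W.ee.REU_CX  = c("N.e.REU", "P.ee.REU_CX", "J.ee.REU_CX"),
  W.ei.REU_CX  = c("N.e.REU", "P.ei.REU_CX", "J.ei.REU_CX"),
  W.ee.CA1_CX  = c("N.e.CA1", "P.ee.CA1_CX", "J.ee.CA1_CX"),
  W.ei.CA1_CX  = c("N.e.CA1", "P.ei.CA1_CX", "J.ei.CA1_CX"),
  W.ee.CXp     = c("N.e.CXp", "P.ee.CXp", "J.ee.CXp"),
  W.ie.CXp     = c("N.i.CXp", "P.ie.CXp", "J.ie.CXp"),
  W.ei.CXp     = c("N.e.CXp", "P.ei.CXp", "J.ei.CXp"),
  W.ii.CXp     = c("N.i.CXp", "P.ii.CXp", "J.ii.CXp"),
  W.ee.CX_CXp  = c("N.e.CX", "P.ee.CX_CXp", "J.ee.CX_CXp"),
  W.ei.CX_CXp  = c("N.e.CX", "P.ei.CX_CXp", "J.ei.CX_CXp"),
  W.ee.MD_CXp  = c("N.e.MD", "P.ee.MD_CXp", "J.ee.MD_CXp"),
  W.ei.MD_CXp  = c("N.e.MD", "P.ei.MD_CXp", "J.ei.MD_CXp"),
  W.ie.TRN_MD  = c("N.i.TRN", "P.ie.TRN_MD", "J.ie.TRN_MD"),
  W.ee.CXp_MD  = c("N.e.CXp", "P.ee.CXp_MD", "J.ee.CXp_MD"),
  W.ii.TRN     = c("N.i.TRN", "P.ii.TRN", "J.ii.TRN"),
  W.ei.MD_TRN  = c("N.e.MD", "P.ei.MD_TRN", "J.ei.MD_TRN"),
  W.ei.CXp_TRN = c("N.e.CXp", "P.ei.CXp_TRN", "J.ei.CXp_TRN"),
  W.ie.TRN_REU = c("N.i.TRN", "P.ie.TRN_REU", "J.ie.TRN_REU"),
  W.ee.CX_REU  = c("N.e.CX", "P.ee.CX_REU", "J.ee.CX_REU"),
  W.ee.CA1_REU = c("N.e.CA1", "P.ee.CA1_REU", "J.ee.CA1_REU"))

# Effective weights W = N * P * J for the integrator; the two CA1<->REU
# E-E pathways carry the alpha scaling factors of the connectivity sweeps.
# Adaptation-drive weights Wc = N * P of each adapted E-E pathway.
build_weights <- function(p) {
  need <- unique(unlist(.pathways))
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("parameter set missing pathway constant(s): ",
         paste(miss, collapse = ", "))
  w <- lapply(.pathways, function(k) p[[k[1]]] * p[[k[2]]] * p[[k[3]]])
  w$W.ee.REU_CA1 <- w$W.ee.REU_CA1 * p$alpha.REU_CA1
  w$W.ee.CA1_REU <- w$W.ee.CA1_REU * p$alpha.CA1_REU
  np <- function(nk, pk) p[[nk]] * p[[pk]]
  w$Wc.CA3     <- np("N.e.CA3", "P.ee.CA3")
  w$Wc.CA3_CA1 <- np("N.e.CA3", "P.ee.CA3_CA1")
  w$Wc.REU_CA1 <- np("N.e.REU", "P.ee.REU_CA1")
  w$Wc.CX      <- np("N.e.CX", "P.ee.CX")
  w$Wc.CXp_CX  <- np("N.e.CXp", "P.ee.CXp_CX")
  w$Wc.REU_CX  <- np("N.e.REU", "P.ee.REU_CX")
  w$Wc.CA1_CX  <- np("N.e.CA1", "P.ee.CA1_CX")
  w$Wc.CXp     <- np("N.e.CXp", "P.ee.CXp")
  w$Wc.CX_CXp  <- np("N.e.CX", "P.ee.CX_CXp")
  w$Wc.MD_CXp  <- np("N.e.MD", "P.ee.MD_CXp")
  scal <- c("r0", "r1",
            grep("^(g|Vstar)\\.(e|i)\\.", names(p), value = TRUE),
            grep("^(RT|VT|gT|RB|VB|gB|L)\\.(MD|TRN)$", names(p), value = TRUE),
            grep("^(f\\.max|f\\.th|q|tau\\.u|b|Vb)\\.(MD|TRN)$", names(p),
                 value = TRUE),
            "gc", "cstar", "tau.c",
            grep("^dc\\.", names(p), value = TRUE),
            grep("^tau\\.(e|i)\\.", names(p), value = TRUE),
            "tau.MD", "tau.TRN", "tau.REU",
            grep("^I\\.", names(p), value = TRUE))
  c(w, p[scal])
}

#' Right-hand side of the 17 rate equations
#'
#' Reference implementation in R of the full model derivative (the
#' compiled integrator carries its own copy; the two are cross-checked in
#' the test suite). E-E terms onto excitatory populations are scaled by
#' the adaptation sigmoid of the target network; MD/TRN firing uses the
#' tonic/burst blend; the burst switch `b` is `b.MD` (default -200 mA)
#' while the membrane potential is at or below `Vb.MD` (default -0.1 mV),
#' 0 above (analogously for TRN with threshold `Vb.TRN` = 0 mV).
#'
#' @param state named numeric vector of the 17 state variables (see
#'   `somnet:::.state_names`).
#' @param params a `somnet_params` list.
#' @return named numeric vector d(state)/dt.
#' @export
model_derivatives <- function(state, params) {
  if (length(state) != 17) stop("state must have 17 elements")
  if (any(!is.finite(state))) stop("non-finite state")
  s <- as.numeric(state)
  names(s) <- .state_names
  w <- build_weights(params)
  p <- params
  rate <- function(V, pop) sigmoid_rate(V, list(
    r0 = p$r0, r1 = p$r1, g = p[[paste0("g.", pop)]],
    Vstar = p[[paste0("Vstar.", pop)]]))
  brate <- function(V, u, nw) burst_tonic_rate(V, min(u, 0), list(
    RT = p[[paste0("RT.", nw)]], VT = p[[paste0("VT.", nw)]],
    gT = p[[paste0("gT.", nw)]], RB = p[[paste0("RB.", nw)]],
    VB = p[[paste0("VB.", nw)]], gB = p[[paste0("gB.", nw)]],
    L = p[[paste0("L.", nw)]]))
  af <- function(cc) 1 / (1 + exp((cc - p$cstar) / p$gc))

  re3 <- rate(s["Ve_CA3"], "e.CA3"); ri3 <- rate(s["Vi_CA3"], "i.CA3")
  re1 <- rate(s["Ve_CA1"], "e.CA1"); ri1 <- rate(s["Vi_CA1"], "i.CA1")
  rex <- rate(s["Ve_CX"], "e.CX");   rix <- rate(s["Vi_CX"], "i.CX")
  rep_ <- rate(s["Ve_CXp"], "e.CXp"); rip <- rate(s["Vi_CXp"], "i.CXp")
  rre <- rate(s["Ve_REU"], "e.REU")
  rmd <- brate(s["Ve_MD"], s["u_e"], "MD")
  rtr <- brate(s["Vi_TRN"], s["u_i"], "TRN")
  a3 <- af(s["c_CA3"]); a1 <- af(s["c_CA1"])
  ax <- af(s["c_CX"]);  ap <- af(s["c_CXp"])

  d <- numeric(17); names(d) <- .state_names
  d["Ve_CA3"] <- -s["Ve_CA3"] / p$tau.e.CA3 + w$W.ee.CA3 * a3 * re3 -
    w$W.ie.CA3 * ri3 + p$I.CA3
  d["Vi_CA3"] <- -s["Vi_CA3"] / p$tau.i.CA3 + w$W.ei.CA3 * re3 -
    w$W.ii.CA3 * ri3
  d["c_CA3"] <- -s["c_CA3"] / p$tau.c + w$Wc.CA3 * p$dc.CA3 * re3
  d["Ve_CA1"] <- -s["Ve_CA1"] / p$tau.e.CA1 - w$W.ie.CA1 * ri1 +
    w$W.ee.CA3_CA1 * a1 * re3 + w$W.ee.REU_CA1 * a1 * rre + p$I.CA1
  d["Vi_CA1"] <- -s["Vi_CA1"] / p$tau.i.CA1 + w$W.ei.CA1 * re1 +
    w$W.ei.CA3_CA1 * re3 - w$W.ii.CA1 * ri1 + w$W.ei.REU_CA1 * rre
  d["c_CA1"] <- -s["c_CA1"] / p$tau.c +
    p$dc.CA1 * (w$Wc.CA3_CA1 * re3 + w$Wc.REU_CA1 * rre)
  d["Ve_CX"] <- -s["Ve_CX"] / p$tau.e.CX + w$W.ee.CX * ax * rex -
    w$W.ie.CX * rix + w$W.ee.CXp_CX * ax * rep_ +
    w$W.ee.REU_CX * ax * rre + w$W.ee.CA1_CX * ax * re1 + p$I.CX
  d["c_CX"] <- -s["c_CX"] / p$tau.c +
    p$dc.CX * (w$Wc.CX * rex + w$Wc.CXp_CX * rep_ +
               w$Wc.REU_CX * rre + w$Wc.CA1_CX * re1)
  d["Vi_CX"] <- -s["Vi_CX"] / p$tau.i.CX - w$W.ii.CX * rix +
    w$W.ei.CX * rex + w$W.ei.CXp_CX * rep_ + w$W.ei.REU_CX * rre +
    w$W.ei.CA1_CX * re1
  d["Ve_CXp"] <- -s["Ve_CXp"] / p$tau.e.CXp + w$W.ee.CXp * ap * rep_ -
    w$W.ie.CXp * rip + w$W.ee.CX_CXp * ap * rex +
    w$W.ee.MD_CXp * ap * rmd + p$I.CXp
  d["c_CXp"] <- -s["c_CXp"] / p$tau.c +
    p$dc.CXp * (w$Wc.CXp * rep_ + w$Wc.CX_CXp * rex + w$Wc.MD_CXp * rmd)
  d["Vi_CXp"] <- -s["Vi_CXp"] / p$tau.i.CXp + w$W.ei.CXp * rep_ -
    w$W.ii.CXp * rip + w$W.ei.CX_CXp * rex + w$W.ei.MD_CXp * rmd
  d["Ve_MD"] <- -s["Ve_MD"] / p$tau.MD -
    p$f.max.MD / (1 + exp((s["u_e"] + p$f.th.MD) / p$q.MD)) -
    w$W.ie.TRN_MD * rtr + w$W.ee.CXp_MD * rep_ + p$I.MD
  be <- if (s["Ve_MD"] > p$Vb.MD) 0 else p$b.MD
  d["u_e"] <- (be - s["u_e"]) / p$tau.u.MD
  d["Vi_TRN"] <- -s["Vi_TRN"] / p$tau.TRN -
    p$f.max.TRN / (1 + exp((s["u_i"] + p$f.th.TRN) / p$q.TRN)) -
    w$W.ii.TRN * rtr + w$W.ei.MD_TRN * rmd + w$W.ei.CXp_TRN * rep_ + p$I.TRN
  bi <- if (s["Vi_TRN"] > p$Vb.TRN) 0 else p$b.TRN
  d["u_i"] <- (bi - s["u_i"]) / p$tau.u.TRN
  d["Ve_REU"] <- -s["Ve_REU"] / p$tau.REU - w$W.ie.TRN_REU * rtr +
    w$W.ee.CX_REU * rex + w$W.ee.CA1_REU * re1 + p$I.REU
  d
}

#' Default initial state
#'
#' All membrane potentials at a small seeded perturbation around 0 mV,
#' adaptation variables at 0, burst variables at rest (0).
#'
#' @param seed integer seed for the perturbation; `NULL` leaves the RNG
#'   state alone.
#' @param sd perturbation SD in mV.
#' @return named numeric state vector.
#' @export
initial_state <- function(seed = NULL, sd = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  s <- stats::setNames(numeric(17), .state_names)
  vpos <- grep("^V", .state_names)
  s[vpos] <- stats::rnorm(length(vpos), 0, sd)
  s
}

#' Simulate the hippocampo-thalamo-cortical network
#'
#' Integrates the 17 rate equations with a fixed-step fourth-order
#' Runge-Kutta scheme (default step 1 ms) and discards a burn-in. The
#' default simulation is fully deterministic; a seeded additive Gaussian
#' input on the membrane-potential states is available for robustness
#' experiments (`noise_sd > 0`).
#'
#' @param params `somnet_params` list (see [model_params()]).
#' @param duration total simulated time in s (including burn-in).
#' @param dt integration step in s (default 1 ms).
#' @param burn_in initial time discarded, s; must satisfy
#'   `duration > burn_in >= 0`.
#' @param init initial state; default [initial_state()] seeded from `seed`.
#' @param noise_sd SD of the optional additive Gaussian input (mV per
#'   sqrt(s)); 0 (default) for the deterministic model.
#' @param seed seed for the initial perturbation and the optional noise.
#' @return object of class `sim_trace`: list with `time` (s), `states`
#'   (matrix, one column per state variable), `fs` (1/dt), `params`.
#' @export
simulate_network <- function(params, duration, dt = 1e-3, burn_in = 20,
                             init = NULL, noise_sd = 0, seed = 1) {
  stopifnot(duration > burn_in, burn_in >= 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- initial_state(seed = NULL)
  w <- build_weights(params)
  n_steps <- round(duration / dt)
  n_burn <- round(burn_in / dt)
  st <- .simulate_cpp(as.numeric(init[.state_names]), w, dt,
                      as.integer(n_steps), as.integer(n_burn), 1L,
                      noise_sd)
  structure(list(
    time = burn_in + dt * seq_len(nrow(st)),
    states = st, fs = 1 / dt, dt = dt, burn_in = burn_in,
    params = params, seed = seed, noise_sd = noise_sd),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %d samples at %g Hz (%.1f s after %.1f s burn-in)\n",
              nrow(x$states), x$fs, nrow(x$states) / x$fs, x$burn_in))
  invisible(x)
}

#' Firing-rate series derived from a simulation trace
#'
#' @param trace a `sim_trace`.
#' @return matrix of firing rates (Hz) for the 9 neuron populations.
#' @export
trace_rates <- function(trace) {
  p <- trace$params
  s <- trace$states
  rate <- function(V, pop) sigmoid_rate(V, list(
    r0 = p$r0, r1 = p$r1, g = p[[paste0("g.", pop)]],
    Vstar = p[[paste0("Vstar.", pop)]]))
  brate <- function(V, u, nw) burst_tonic_rate(V, pmin(u, 0), list(
    RT = p[[paste0("RT.", nw)]], VT = p[[paste0("VT.", nw)]],
    gT = p[[paste0("gT.", nw)]], RB = p[[paste0("RB.", nw)]],
    VB = p[[paste0("VB.", nw)]], gB = p[[paste0("gB.", nw)]],
    L = p[[paste0("L.", nw)]]))
  cbind(
    re_CA3 = rate(s[, "Ve_CA3"], "e.CA3"),
    ri_CA3 = rate(s[, "Vi_CA3"], "i.CA3"),
    re_CA1 = rate(s[, "Ve_CA1"], "e.CA1"),
    ri_CA1 = rate(s[, "Vi_CA1"], "i.CA1"),
    re_CX = rate(s[, "Ve_CX"], "e.CX"),
    ri_CX = rate(s[, "Vi_CX"], "i.CX"),
    re_CXp = rate(s[, "Ve_CXp"], "e.CXp"),
    ri_CXp = rate(s[, "Vi_CXp"], "i.CXp"),
    r_MD = brate(s[, "Ve_MD"], s[, "u_e"], "MD"),
    r_TRN = brate(s[, "Vi_TRN"], s[, "u_i"], "TRN"),
    r_REU = rate(s[, "Ve_REU"], "e.REU"))
}
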