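#' KineticModel: reduced network of mitochondrial ATP production
#'
#' A deliberately small reaction network that preserves the three contracts
#' a proteome-scaled bioenergetic model needs: maximal rates proportional to
#' measured enzyme abundance, a hyperbolic ATP-consumption (load) law, and
#' group-wise in-silico rectification. The network:
#' \itemize{
#'   \item \code{supply}: substrate influx with product inhibition
#'     (pyruvate-carrier-mapped);
#'   \item \code{tcaA}, \code{tcaB}, \code{tcaC}: three sequential TCA-cycle
#'     segments (Idh3-, Ogdh/Sdh- and Mdh2-mapped), each reducing NAD to
#'     NADH via Michaelis--Menten kinetics;
#'   \item \code{etc}: lumped electron transport chain (complexes I--IV):
#'     NADH oxidation pumping protons against a membrane-potential
#'     back-pressure;
#'   \item \code{synthase}: complex V, Δψ-driven ADP phosphorylation;
#'   \item \code{leak}: saturating Δψ-dependent proton leak (a reduced form
#'     of a Goldman--Hodgkin--Katz ion flux; not protein-scalable);
#'   \item \code{load}: hyperbolic ATP sink
#'     \code{v_ATP = k_load * ATP/(ATP + K_m)}.
#' }
#' State variables: three substrate pools S1--S3 (mM), NADH (mM), ATP (mM)
#' and the inner-membrane potential psi (mV). NAD and ADP are derived from
#' the conserved totals, so adenine and NAD pools are conserved exactly.
#'
#' @slot params named numeric vector of kinetic constants, pools and the
#'   load parameters.
#' @slot vmaxScale named numeric multiplier per scalable reaction
#'   (proteome-derived; all 1 in the reference model).
#' @slot proteinMap named list: reaction id -> list of character vectors,
#'   each vector one slot of redundant isoforms/subunits.
#' @slot initialState named numeric starting state for integration.
#' @export
setClass("KineticModel",
  slots = c(params = "numeric", vmaxScale = "numeric",
            proteinMap = "list", initialState = "numeric"))

.SCALABLE <- c("supply", "tcaA", "tcaB", "tcaC", "etc", "synthase")

setValidity("KineticModel", function(object) {
  msg <- NULL
  need <- c("vmax_supply", "ki_supply", "vmax_tcaA", "vmax_tcaB",
            "vmax_tcaC", "km_s", "km_nad", "vmax_etc", "km_nadh",
            "psi_max", "k_psi", "p_etc", "p_syn", "vmax_synthase",
            "km_adp", "psi_syn0", "k_syn", "vmax_leak", "km_leak_psi",
            "c_mem", "a_total", "nad_total", "k_load", "km_load")
  miss <- setdiff(need, names(object@params))
  if (length(miss))
    msg <- c(msg, paste("missing parameter(s):", paste(miss, collapse = ", ")))
  else {
    pos <- object@params[grep("^(vmax|km|ki|p_|a_total|nad_total|c_mem|k_load)",
                              names(object@params))]
    if (any(pos < 0)) msg <- c(msg, "rates, K_m values and pools must be >= 0")
    if (object@params["a_total"] <= 0 || object@params["nad_total"] <= 0)
      msg <- c(msg, "conserved pools must be > 0")
  }
  if (!setequal(names(object@vmaxScale), .SCALABLE))
    msg <- c(msg, "vmaxScale must cover exactly the scalable reactions")
  if (!all(.SCALABLE %in% names(object@proteinMap)))
    msg <- c(msg, "every scalable reaction needs mapped proteins")
  else if (any(!vapply(object@proteinMap[.SCALABLE], length, integer(1))))
    msg <- c(msg, "every scalable reaction needs >= 1 mapped protein")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel: supply -> 3 TCA segments -> ETC -> synthase",
      "(+ leak, load)\n")
  cat("  A_total =", object@params["a_total"], "mM, NAD_total =",
      object@params["nad_total"], "mM, k_load =",
      object@params["k_load"], "mM/s\n")
  sc <- object@vmaxScale
  cat("  vmax scaling:",
      paste(names(sc), signif(sc, 3), sep = "=", collapse = ", "), "\n")
})

#' Build the reference kinetic model
#'
#' Reference parameters describe a healthy resting neuronal state: membrane
#' potential near 150 mV, ATP/ADP well above 1, and spare capacity in both
#' the TCA segments and the ETC so a load titration has room to run.
#' Concentrations in mM, time in s, potential in mV. Any parameter can be
#' overridden through \code{config}.
#'
#' @param config named list/vector of parameter overrides; unknown names are
#'   an error.
#' @return a \linkS4class{KineticModel} with unit abundance scaling.
#' @examples
#' m <- buildReferenceModel()
#' ss <- steadyState(m)
#' atpAdpRatio(ss)
#' @export
buildReferenceModel <- function(config = list()) {
  params <- c(
    vmax_supply = 0.5, ki_supply = 5,
    vmax_tcaA = 0.6, vmax_tcaB = 0.6, vmax_tcaC = 0.6,
    km_s = 0.5, km_nad = 0.1,
    vmax_etc = 4, km_nadh = 0.1, psi_max = 160, k_psi = 12,
    p_etc = 10, p_syn = 3,
    vmax_synthase = 6, km_adp = 0.4, psi_syn0 = 100, k_syn = 15,
    vmax_leak = 5, km_leak_psi = 100,
    c_mem = 0.02,
    a_total = 5, nad_total = 1,
    k_load = 2, km_load = 1)
  if (length(config)) {
    bad <- setdiff(names(config), names(params))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    params[names(config)] <- unlist(config)
  }
  protein_map <- list(
    supply = list("Mpc1"),
    tcaA = list(c("Idh3a", "Idh3b", "Idh3g")),
    tcaB = list("Ogdh", "Sdha"),
    tcaC = list("Mdh2"),
    etc = list("Ndufs1", "Ndufv1", "Uqcrc1", "Cox4i1"),
    synthase = list("Atp5f1a", "Atp5f1b"))
  init <- c(S1 = 0.5, S2 = 0.5, S3 = 0.5, NADH = 0.3,
            ATP = 0.8 * unname(params["a_total"]), psi = 140)
  new("KineticModel", params = params,
      vmaxScale = setNames(rep(1, length(.SCALABLE)), .SCALABLE),
      proteinMap = protein_map, initialState = init)
}

#' Hyperbolic ATP-consumption law
#'
#' \code{v_ATP = k_load * ATP / (ATP + K_m)}: half-saturated at
#' \code{ATP = K_m}, saturating at \code{k_load}; the consumed ATP returns
#' stoichiometrically as ADP.
#'
#' @param atp ATP concentration (mM, vectorized).
#' @param k_load maximal consumption rate (mM/s, > 0).
#' @param km half-saturation constant (mM, > 0).
#' @return consumption flux (mM/s).
#' @export
atpLoad <- function(atp, k_load, km) {
  if (any(k_load <= 0) || any(km <= 0)) stop("k_load and km must be > 0")
  k_load * atp / (atp + km)
}

# Reaction fluxes at a state. psi back-pressure and synthase activation are
# logistic in psi; leak saturates hyperbolically.
.fluxes <- function(y, p, sc, k_load = p[["k_load"]]) {
  nad <- p[["nad_total"]] - y[["NADH"]]
  adp <- p[["a_total"]] - y[["ATP"]]
  mm <- function(x, km) x / (x + km)
  c(supply = sc[["supply"]] * p[["vmax_supply"]] /
      (1 + y[["S1"]] / p[["ki_supply"]]),
    tcaA = sc[["tcaA"]] * p[["vmax_tcaA"]] * mm(y[["S1"]], p[["km_s"]]) *
      mm(nad, p[["km_nad"]]),
    tcaB = sc[["tcaB"]] * p[["vmax_tcaB"]] * mm(y[["S2"]], p[["km_s"]]) *
      mm(nad, p[["km_nad"]]),
    tcaC = sc[["tcaC"]] * p[["vmax_tcaC"]] * mm(y[["S3"]], p[["km_s"]]) *
      mm(nad, p[["km_nad"]]),
    etc = sc[["etc"]] * p[["vmax_etc"]] * mm(y[["NADH"]], p[["km_nadh"]]) /
      (1 + exp((y[["psi"]] - p[["psi_max"]]) / p[["k_psi"]])),
    synthase = sc[["synthase"]] * p[["vmax_synthase"]] *
      mm(adp, p[["km_adp"]]) /
      (1 + exp(-(y[["psi"]] - p[["psi_syn0"]]) / p[["k_syn"]])),
    leak = p[["vmax_leak"]] * max(y[["psi"]], 0) /
      (max(y[["psi"]], 0) + p[["km_leak_psi"]]),
    load = atpLoad(max(y[["ATP"]], 0), k_load, p[["km_load"]]))
}

# Damped Newton iteration on the flux-balance system, used to polish a
# near-converged state to the requested residual tolerance. States leaving
# physical bounds (pool overflows, negative concentrations) abort the
# polish and the caller falls back to integration.
.newtonPolish <- function(y, parms, scale_ref, residual_of, tol,
                          max_iter = 25) {
  f_of <- function(y) .derivs(0, y, parms)[[1]]
  best <- list(y = y, resid = residual_of(y))
  for (it in seq_len(max_iter)) {
    f <- f_of(y)
    J <- matrix(0, length(y), length(y))
    for (j in seq_along(y)) {
      h <- max(1e-7 * abs(y[j]), 1e-9)
      yp <- y; yp[j] <- yp[j] + h
      J[, j] <- (f_of(yp) - f) / h
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- y + lambda * step
      ok <- all(cand[c("S1", "S2", "S3")] >= 0) &&
        cand[["NADH"]] > 0 && cand[["NADH"]] < parms$p[["nad_total"]] &&
        cand[["ATP"]] > 0 && cand[["ATP"]] < parms$p[["a_total"]] &&
        cand[["psi"]] > 0
      if (ok && residual_of(cand) < best$resid) break
      lambda <- lambda / 2
      if (lambda < 1e-4) return(best)
    }
    y <- y + lambda * step
    r <- residual_of(y)
    if (r < best$resid) best <- list(y = y, resid = r)
    if (r < tol) break
  }
  best
}

.derivs <- function(t, y, parms) {
  v <- .fluxes(y, parms$p, parms$sc, parms$k_load)
  dy <- c(
    S1 = v[["supply"]] - v[["tcaA"]],
    S2 = v[["tcaA"]] - v[["tcaB"]],
    S3 = v[["tcaB"]] - v[["tcaC"]],
    NADH = v[["tcaA"]] + v[["tcaB"]] + v[["tcaC"]] - v[["etc"]],
    ATP = v[["synthase"]] - v[["load"]],
    psi = (parms$p[["p_etc"]] * v[["etc"]] -
             parms$p[["p_syn"]] * v[["synthase"]] - v[["leak"]]) /
      parms$p[["c_mem"]])
  list(dy)
}

#' SteadyState: converged metabolic state of a KineticModel
#'
#' @slot state named numeric state-variable values (including derived NAD
#'   and ADP).
#' @slot fluxes named numeric per-reaction fluxes (mM/s).
#' @slot converged logical.
#' @slot residual maximal relative time-derivative at the final state.
#' @export
setClass("SteadyState",
  slots = c(state = "numeric", fluxes = "numeric",
            converged = "logical", residual = "numeric"))

setMethod("show", "SteadyState", function(object) {
  cat("SteadyState (", if (object@converged) "converged" else "NOT converged",
      ", residual ", format(object@residual, digits = 3), ")\n", sep = "")
  cat("  ATP =", signif(object@state[["ATP"]], 4), "mM, ATP/ADP =",
      signif(object@state[["ATP"]] / object@state[["ADP"]], 4),
      ", psi =", signif(object@state[["psi"]], 4), "mV\n")
  cat("  v_ATP (load) =", signif(object@fluxes[["load"]], 4), "mM/s\n")
})

#' @describeIn steadyState ATP/ADP ratio of a steady state.
#' @param ss a \linkS4class{SteadyState}.
#' @export
atpAdpRatio <- function(ss) ss@state[["ATP"]] / ss@state[["ADP"]]

#' Integrate the model to its steady state
#'
#' Stiff integration (lsoda) from the configured initial state in growing
#' time chunks until the largest relative time-derivative falls below
#' \code{tol}, or the time budget is exhausted (then the result is flagged,
#' not thrown).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param k_load optional load override (mM/s); defaults to the model's.
#' @param init optional initial state (warm starts).
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_time total integration time budget in s (default 2e5).
#' @return a \linkS4class{SteadyState}.
#' @export
steadyState <- function(model, k_load = NULL, init = NULL, tol = 1e-8,
                        max_time = 2e5) {
  stopifnot(is(model, "KineticModel"))
  p <- model@params
  kl <- if (is.null(k_load)) p[["k_load"]] else k_load
  parms <- list(p = p, sc = model@vmaxScale, k_load = kl)
  y <- if (is.null(init)) model@initialState else init[names(model@initialState)]
  scale_ref <- c(S1 = 1, S2 = 1, S3 = 1, NADH = p[["nad_total"]],
                 ATP = p[["a_total"]], psi = 100)
  t_chunk <- 100
  t_used <- 0
  resid <- Inf
  residual_of <- function(y) {
    dy <- .derivs(0, y, parms)[[1]]
    max(abs(dy) / scale_ref[names(dy)])
  }
  while (t_used < max_time) {
    sol <- suppressWarnings(
      deSolve::lsoda(y, c(0, t_chunk), .derivs, parms,
                     rtol = 1e-9, atol = 1e-11, maxsteps = 100000))
    y <- setNames(as.numeric(sol[nrow(sol), -1]), names(y))
    t_used <- t_used + t_chunk
    resid <- residual_of(y)
    if (resid < tol) break
    if (resid < 1e-3) {   # close to the fixed point: Newton polish
      pol <- .newtonPolish(y, parms, scale_ref, residual_of, tol)
      if (pol$resid < resid) { y <- pol$y; resid <- pol$resid }
      if (resid < tol) break
    }
    t_chunk <- min(t_chunk * 2, 2000, max_time - t_used)
    if (t_chunk <= 0) break
  }
  v <- .fluxes(y, p, model@vmaxScale, kl)
  state <- c(y, NAD = p[["nad_total"]] - y[["NADH"]],
             ADP = p[["a_total"]] - y[["ATP"]])
  new("SteadyState", state = state, fluxes = v,
      converged = resid < tol, residual = resid)
}

#' Scale maximal rates by a relative enzyme-abundance profile
#'
#' Implements the proportionality of maximal enzyme activity to enzyme
#' protein abundance: each scalable reaction's v_max is multiplied by the
#' aggregate relative abundance of its mapped proteins,
#' \code{v_max(case) = v_max(reference) * E(case)/E(mean control)}.
#' Multi-subunit aggregates use the arithmetic mean of the mapped subunit
#' factors by default (\code{aggregate = "geometric"} is available).
#'
#' @param model the reference \linkS4class{KineticModel}.
#' @param profile named numeric of relative abundances (> 0), e.g. from
#'   \code{\link{simulateAbundanceProfile}} or a differential table.
#' @param missing_policy for mapped proteins absent from the profile:
#'   \code{"hold-at-1"} (contribute a factor of 1) or \code{"error"}.
#' @param aggregate \code{"mean"} (default) or \code{"geometric"}.
#' @return a KineticModel with updated \code{vmaxScale}; a unit profile
#'   returns scaling identical to the reference.
#' @export
scaleVmax <- function(model, profile,
                      missing_policy = c("hold-at-1", "error"),
                      aggregate = c("mean", "geometric")) {
  stopifnot(is(model, "KineticModel"))
  missing_policy <- match.arg(missing_policy)
  aggregate <- match.arg(aggregate)
  if (any(profile <= 0)) stop("abundance factors must be > 0")
  sc <- model@vmaxScale
  for (rx in .SCALABLE) {
    prots <- unlist(model@proteinMap[[rx]])
    f <- profile[prots]
    if (anyNA(f)) {
      if (missing_policy == "error")
        stop("reaction '", rx, "': mapped protein(s) absent from profile: ",
             paste(prots[is.na(f)], collapse = ", "))
      f[is.na(f)] <- 1
    }
    sc[[rx]] <- if (aggregate == "mean") mean(f) else exp(mean(log(f)))
  }
  model@vmaxScale <- sc
  model
}

#' Metabolic-load titration
#'
#' Raises \code{k_load} in geometric steps from the resting value, solving
#' for the steady state at each step (warm-started from the previous one),
#' until the ATP production rate converges to its maximum (relative
#' increase below \code{rel_tol}) or the step budget runs out (flagged).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param k_start starting load; defaults to the model's resting
#'   \code{k_load}.
#' @param step_factor geometric step multiplier (default 1.25).
#' @param rel_tol relative v_ATP convergence threshold (default 1e-3).
#' @param max_steps step budget (default 60).
#' @param ss_tol,ss_max_time steady-state solver settings.
#' @return list with \code{curve} (data.frame: k_load, ATP, ADP, atp_adp,
#'   v_atp, psi, converged), \code{max_v_atp}, \code{k_load_at_max},
#'   \code{converged}.
#' @export
loadTitration <- function(model, k_start = NULL, step_factor = 1.25,
                          rel_tol = 1e-3, max_steps = 60,
                          ss_tol = 1e-8, ss_max_time = 2e5) {
  stopifnot(is(model, "KineticModel"))
  k <- if (is.null(k_start)) model@params[["k_load"]] else k_start
  rows <- list()
  init <- NULL
  prev_v <- NA_real_
  converged <- FALSE
  for (i in seq_len(max_steps)) {
    ss <- steadyState(model, k_load = k, init = init, tol = ss_tol,
                      max_time = ss_max_time)
    init <- ss@state[names(model@initialState)]
    v <- ss@fluxes[["load"]]
    rows[[i]] <- data.frame(k_load = k, ATP = ss@state[["ATP"]],
                            ADP = ss@state[["ADP"]],
                            atp_adp = atpAdpRatio(ss), v_atp = v,
                            psi = ss@state[["psi"]],
                            converged = ss@converged)
    if (!is.na(prev_v) && prev_v > 0 && (v - prev_v) / prev_v < rel_tol) {
      converged <- TRUE
      break
    }
    prev_v <- v
    k <- k * step_factor
  }
  curve <- do.call(rbind, rows)
  list(curve = curve, max_v_atp = max(curve$v_atp),
       k_load_at_max = curve$k_load[which.max(curve$v_atp)],
       converged = converged)
}

#' In-silico rectification of protein groups
#'
#' Starting from a case abundance profile, each named protein group is reset
#' to control levels (factor 1) in turn, the model is rebuilt from the
#' reference, and the resting steady state (optionally the full load
#' titration) is compared against the un-rectified case and the full
#' control. Rectifying all groups jointly reproduces the control model when
#' the groups cover every perturbed protein.
#'
#' @param model the reference (control) \linkS4class{KineticModel}.
#' @param profile_case named numeric case abundance factors.
#' @param groups named list: group name -> protein ids (nonempty subsets of
#'   the mapped proteins). A joint \code{"all"} rectification of every
#'   listed group is appended automatically.
#' @param titrate also run a load titration per condition and report the
#'   maximal ATP production rate (slower; default FALSE).
#' @param ... passed to \code{\link{steadyState}}.
#' @return list with \code{table} (data.frame per condition: case, each
#'   group, all, control — ATP, atp_adp, v_atp, optionally max_v_atp) and
#'   \code{states} (named list of \linkS4class{SteadyState}s).
#' @export
rectifyGroups <- function(model, profile_case, groups, titrate = FALSE, ...) {
  stopifnot(is(model, "KineticModel"), length(groups) >= 1)
  mapped <- unlist(model@proteinMap)
  for (g in names(groups)) {
    if (!length(groups[[g]])) stop("group '", g, "' is empty")
    if (!all(groups[[g]] %in% mapped))
      stop("group '", g, "' contains proteins not mapped to any reaction")
  }
  conds <- list(case = profile_case)
  for (g in names(groups)) {
    pr <- profile_case
    pr[intersect(names(pr), groups[[g]])] <- 1
    conds[[paste0("rectify_", g)]] <- pr
  }
  pr_all <- profile_case
  pr_all[intersect(names(pr_all), unlist(groups))] <- 1
  conds[["rectify_all"]] <- pr_all
  conds[["control"]] <- setNames(rep(1, length(profile_case)),
                                 names(profile_case))
  states <- list()
  rows <- lapply(names(conds), function(nm) {
    m <- scaleVmax(model, conds[[nm]])
    ss <- steadyState(m, ...)
    states[[nm]] <<- ss
    row <- data.frame(condition = nm, ATP = ss@state[["ATP"]],
                      atp_adp = atpAdpRatio(ss),
                      v_atp = ss@fluxes[["load"]],
                      psi = ss@state[["psi"]], converged = ss@converged)
    if (titrate) row$max_v_atp <- loadTitration(m)$max_v_atp
    row
  })
  list(table = do.call(rbind, rows), states = states)
}

#' Model-coverage quality scores for an abundance profile
#'
#' QC score: percentage of the model's mapped proteins present in the
#' profile. QSM score: mean over scalable reactions of (mapped proteins
#' found / isoform slots), as a percentage — redundant isoforms sharing a
#' slot can push a reaction's coverage above 1, so QSM may exceed 100%.
#' Both are reported against the 75% suitability cutoff.
#'
#' @param profile named numeric abundance profile.
#' @param model a \linkS4class{KineticModel}.
#' @return list: qc_score, qsm_score (percent), cutoff (75),
#'   passes_cutoff.
#' @export
qcScores <- function(profile, model) {
  stopifnot(is(model, "KineticModel"))
  found <- names(profile)
  mapped <- unlist(model@proteinMap[.SCALABLE])
  qc <- 100 * mean(mapped %in% found)
  per_rx <- vapply(.SCALABLE, function(rx) {
    slots <- model@proteinMap[[rx]]
    sum(unlist(slots) %in% found) / length(slots)
  }, numeric(1))
  qsm <- 100 * mean(per_rx)
  list(qc_score = qc, qsm_score = qsm, cutoff = 75,
       passes_cutoff = qc >= 75 && qsm >= 75)
}

#' Mapped proteins of a kinetic model
#' @param model a \linkS4class{KineticModel}.
#' @return character vector of all mapped protein ids.
#' @export
mappedProteins <- function(model) unique(unlist(model@proteinMap))

#' Protein groups of the reduced model (TCA cycle vs ETC)
#'
#' Convenience grouping used by the rectification analysis: the TCA-segment
#' proteins versus the ETC/oxphos proteins.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return named list with \code{TCA} and \code{ETC} protein id vectors.
#' @export
defaultProteinGroups <- function(model) {
  list(TCA = unique(unlist(model@proteinMap[c("tcaA", "tcaB", "tcaC")])),
       ETC = unique(unlist(model@proteinMap[c("etc", "synthase")])))
}
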