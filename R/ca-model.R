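#' Cellular-automaton parameters
#'
#' Parameter container for the lattice model of post-irradiation tumor
#' regrowth. Cells live on a 2-D square lattice with a Moore (8-site)
#' neighborhood and occupy three states: proliferative, quiescent
#' (transiently arrested: viable but fully enclosed, so unable to divide or
#' migrate) and NPMA (non-proliferative but metabolically active — stably
#' arrested survivors of irradiation that never divide but persist and can
#' secrete inhibitory factors).
#'
#' Each day, in freshly shuffled order, every cell makes one decision:
#' an NPMA cell is cleared with probability `npma_clearance`, otherwise
#' persists; a viable cell dies with probability `p_a`, divides with
#' probability `p_d` (mutually exclusive draws, so the low-density growth
#' factor is exactly `1 + p_d - p_a`) provided it is mature (`maturity >= m`),
#' has a free neighbor, total occupancy is below `capacity` and its site is
#' not suppressed by local inhibition; failing division it makes on average
#' `mu` migration attempts to random neighboring sites. Non-dividing viable
#' cells accrue one step of dormancy; division resets the dormancy of mother
#' and daughter.
#'
#' Defaults are calibrated so the unirradiated population doubles roughly
#' every 2.5-3 days, in line with U87-MG glioblastoma cultures.
#'
#' @param p_d Probability of mitosis per day.
#' @param p_a Probability of cell death per day (baseline).
#' @param p_s Probability an irradiation-inactivated cell becomes NPMA
#'   rather than dying outright.
#' @param mu Migration attempts per day (expected; need not be integer).
#' @param m Maturation steps a newborn needs before division-competence.
#' @param inhibition_radius Chebyshev radius (cell diameters) of local
#'   growth inhibition around NPMA cells; 0 disables it.
#' @param global_pa Optional elevated death probability replacing `p_a` for
#'   all viable cells after irradiation (the host-mediated, systemic
#'   inhibition scenario).
#' @param lattice_size Sites per side (>= 8).
#' @param capacity Maximum occupied sites; defaults to the whole lattice.
#' @param npma_clearance Probability per day an NPMA cell is removed
#'   (0 in vitro, where arrested giant cells persist; > 0 in vivo where the
#'   host clears them).
#' @return A `ca_params` list, validated.
#' @export
ca_params <- function(p_d = 0.28, p_a = 0.01, p_s = 0.5, mu = 5, m = 1,
                      inhibition_radius = 0, global_pa = NULL,
                      lattice_size = 300, capacity = NULL,
                      npma_clearance = 0) {
  if (is.null(capacity)) capacity <- lattice_size^2
  probs <- c(p_d = p_d, p_a = p_a, p_s = p_s, npma_clearance = npma_clearance)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_a + p_d > 1) stop("p_a + p_d must not exceed 1", call. = FALSE)
  if (!is.null(global_pa) && (global_pa < 0 || global_pa > 1)) {
    stop("global_pa must lie in [0, 1]", call. = FALSE)
  }
  if (lattice_size < 8) stop("lattice_size must be >= 8", call. = FALSE)
  if (inhibition_radius < 0 || inhibition_radius != round(inhibition_radius)) {
    stop("inhibition_radius must be a non-negative integer", call. = FALSE)
  }
  if (mu < 0 || m < 0) stop("mu and m must be non-negative", call. = FALSE)
  if (capacity > lattice_size^2 || capacity < 1) {
    stop("capacity must lie in [1, lattice_size^2]", call. = FALSE)
  }
  structure(
    list(p_d = p_d, p_a = p_a, p_s = p_s, mu = mu, m = as.integer(m),
         inhibition_radius = as.integer(inhibition_radius),
         global_pa = global_pa, lattice_size = as.integer(lattice_size),
         capacity = as.integer(capacity), npma_clearance = npma_clearance),
    class = "ca_params"
  )
}

#' Initialize a lattice state
#'
#' Places `n0` proliferative cells in a compact disc at the lattice center,
#' all mature (`maturity = m`) with dormancy 0.
#'
#' @param params A [ca_params()] object.
#' @param n0 Initial cell count (<= capacity).
#' @param placement `"disc"` (default): a deterministic compact disc at the
#'   lattice center, the geometry of an implanted bolus. `"scattered"`:
#'   uniformly random free sites (uses the current RNG) — the low-density
#'   regime used to verify the step rules against their mean-field limit.
#' @return A `sim_state`: matrices `state` (0 empty / 1 viable / 2 NPMA),
#'   `maturity`, `dormancy`, plus elapsed time `t` and the parameters.
#' @export
init_state <- function(params, n0, placement = c("disc", "scattered")) {
  placement <- match.arg(placement)
  stopifnot(inherits(params, "ca_params"))
  if (n0 > params$capacity) stop("n0 exceeds capacity", call. = FALSE)
  if (n0 > params$lattice_size^2) stop("n0 exceeds lattice", call. = FALSE)
  L <- params$lattice_size
  c0 <- (L + 1) / 2
  ij <- expand.grid(i = seq_len(L), j = seq_len(L))
  if (placement == "disc") {
    d2 <- (ij$i - c0)^2 + (ij$j - c0)^2
    ord <- order(d2, ij$i, ij$j) # deterministic compact disc
    sel <- ord[seq_len(n0)]
  } else {
    sel <- sample.int(nrow(ij), n0)
  }
  state <- matrix(0L, L, L)
  maturity <- matrix(0L, L, L)
  dormancy <- matrix(0L, L, L)
  state[cbind(ij$i[sel], ij$j[sel])] <- 1L
  maturity[cbind(ij$i[sel], ij$j[sel])] <- params$m
  structure(list(state = state, maturity = maturity, dormancy = dormancy,
                 t = 0, params = params),
            class = "sim_state")
}

#' Apply an acute irradiation to a lattice state
#'
#' Each non-NPMA cell independently retains clonogenic viability with
#' probability `surviving_fraction` (e.g. the linear-quadratic survival at
#' the delivered dose); inactivated cells become NPMA with probability `p_s`
#' and are removed (immediate death) otherwise.
#'
#' @param state A `sim_state`.
#' @param surviving_fraction Clonogenic surviving fraction in (0, 1].
#' @param p_s NPMA-conversion probability; defaults to the state's
#'   parameters.
#' @return The irradiated `sim_state`.
#' @export
apply_irradiation <- function(state, surviving_fraction, p_s = NULL) {
  stopifnot(inherits(state, "sim_state"))
  if (surviving_fraction <= 0 || surviving_fraction > 1) {
    stop("surviving_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(p_s)) p_s <- state$params$p_s
  viable <- which(state$state == 1L)
  hit <- viable[stats::runif(length(viable)) >= surviving_fraction]
  to_npma <- hit[stats::runif(length(hit)) < p_s]
  to_die <- setdiff(hit, to_npma)
  state$state[to_npma] <- 2L
  state$state[to_die] <- 0L
  state$maturity[to_die] <- 0L
  state$dormancy[to_die] <- 0L
  state
}

#' Advance a lattice state by one day
#'
#' @param state A `sim_state`.
#' @param params Optional parameter override (default: the state's own).
#' @param use_global_pa Use `global_pa` instead of `p_a` for viable cells
#'   (the host-inhibition scenario after irradiation).
#' @return The updated `sim_state`; per-day event counts are attached as
#'   attribute `"events"`.
#' @export
ca_step <- function(state, params = NULL, use_global_pa = FALSE) {
  stopifnot(inherits(state, "sim_state"))
  p <- params %||% state$params
  pa <- if (use_global_pa) {
    if (is.null(p$global_pa)) {
      stop("global scenario requires `global_pa`", call. = FALSE)
    }
    p$global_pa
  } else {
    p$p_a
  }
  ev <- ca_step_cpp(state$state, state$maturity, state$dormancy,
                    pa, p$p_d, p$mu, p$m, p$inhibition_radius,
                    p$npma_clearance, p$capacity)
  state$t <- state$t + 1
  attr(state, "events") <- ev
  state
}

#' Tally a lattice state
#'
#' @param state A `sim_state`.
#' @return One-row tibble: `t`, `n_proliferative` (viable with free
#'   neighbor), `n_quiescent` (viable, enclosed), `n_npma`, `n_viable`,
#'   `n_total`.
#' @export
state_counts <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  ct <- ca_counts_cpp(state$state)
  dplyr::tibble(
    t = state$t,
    n_proliferative = ct[["proliferative"]],
    n_quiescent = ct[["quiescent"]],
    n_npma = ct[["npma"]],
    n_viable = ct[["proliferative"]] + ct[["quiescent"]],
    n_total = sum(ct)
  )
}

#' @export
print.sim_state <- function(x, ...) {
  ct <- state_counts(x)
  cat(sprintf(
    "Lattice %dx%d at t = %g d: %d proliferative, %d quiescent, %d NPMA\n",
    x$params$lattice_size, x$params$lattice_size, x$t,
    ct$n_proliferative, ct$n_quiescent, ct$n_npma))
  invisible(x)
}

#' Sites suppressed by local inhibition
#'
#' Positions within Chebyshev distance `R` of any NPMA cell; during a step,
#' division probability at those positions is zero (migration and survival
#' are unaffected).
#'
#' @param state A `sim_state`.
#' @param R Chebyshev radius in cell diameters (>= 0).
#' @return Logical lattice-sized matrix (TRUE = suppressed); `R = 0` marks
#'   only the NPMA sites themselves.
#' @export
local_inhibition_mask <- function(state, R) {
  stopifnot(inherits(state, "sim_state"))
  ca_mask_cpp(state$state, as.integer(R))
}

#' Fraction of living cells dormant for at least k steps
#'
#' The dormancy counter tracks days since a cell last divided (newborns and
#' fresh mothers sit at 0). NPMA cells never divide, so their counter grows
#' from the moment of conversion; they are included among "living cells"
#' because they are viable, metabolically active members of the population.
#'
#' @param state A `sim_state`.
#' @param k Minimum dormancy in steps (>= 0).
#' @param include_npma Count NPMA cells (default TRUE).
#' @return Fraction in \[0, 1\]; 0 when no cells qualify (or none are alive).
#' @export
dormancy_fraction <- function(state, k, include_npma = TRUE) {
  stopifnot(inherits(state, "sim_state"), k >= 0)
  keep <- if (include_npma) state$state > 0L else state$state == 1L
  n <- sum(keep)
  if (n == 0) return(0)
  sum(state$dormancy[keep] >= k) / n
}

#' Dormancy histogram of a lattice state
#'
#' @param state A `sim_state`.
#' @param include_npma Count NPMA cells (default TRUE).
#' @return Tibble `dormancy` / `n_cells`.
#' @export
dormancy_histogram <- function(state, include_npma = TRUE) {
  keep <- if (include_npma) state$state > 0L else state$state == 1L
  d <- state$dormancy[keep]
  dplyr::tibble(dormancy = as.integer(names(table(d))),
                n_cells = as.integer(table(d)))
}

#' Mean-field per-step growth factor
#'
#' Closed-form low-density, maturity-saturated approximation of the per-day
#' population growth factor: death (probability `p_a`) and division
#' (probability `p_d`) are mutually exclusive, so the expected factor is
#' `1 + p_d - p_a`. Used as an independent oracle for [ca_step()].
#'
#' @param params A [ca_params()] object (or anything with `p_d`, `p_a`).
#' @return The scalar factor.
#' @export
mean_field_growth_factor <- function(params) {
  1 + params$p_d - params$p_a
}

#' Run a post-irradiation regrowth scenario
#'
#' Initializes `n0` cells, applies an acute dose (as a surviving fraction,
#' with NPMA conversion), then iterates daily steps until `t_max`, extinction
#' of all viable cells, or the viable population reaching `stop_size`.
#' Scenarios:
#'
#' * `"none"`: radiation kill only — no inhibition beyond the shared lattice.
#' * `"local"`: NPMA cells suppress division within `inhibition_radius`
#'   (must be >= 1).
#' * `"global"`: host-mediated systemic inhibition — `p_a` is replaced by
#'   `global_pa` for every viable cell from irradiation onward.
#'
#' The growth rate is fitted by [fit_exponential_growth()] to the total
#' living-cell trajectory restricted to counts at or above `detection_size`,
#' mirroring how xenograft growth rates are fitted only above a detectable
#' volume.
#'
#' @param params A [ca_params()] object.
#' @param n0 Cells before irradiation.
#' @param surviving_fraction Clonogenic survival of the delivered dose
#'   (1 = sham irradiation).
#' @param scenario `"none"`, `"local"` or `"global"`.
#' @param t_max Maximum simulated days.
#' @param detection_size Minimum living-cell count entering the rate fit.
#' @param stop_size Stop once the viable count reaches this (keeps runs in
#'   the pre-confluent regime); `Inf` to disable.
#' @param p_s NPMA-conversion override.
#' @param record_state Keep the final `sim_state` in the result.
#' @param placement Engraftment geometry passed to [init_state()]. The
#'   default, `"scattered"`, disperses the implanted population across the
#'   lattice the way an injected cell suspension spreads through tissue; a
#'   packed `"disc"` bolus makes early regrowth front-limited and couples the
#'   fitted rate to colony geometry rather than to cell kinetics.
#' @return A `sim_result`: `trajectory` tibble (per day state counts),
#'   `extinct` flag, `growth_fit` (a [fit_exponential_growth()] object or
#'   NULL when too few detectable points), `final_state` (optional),
#'   `scenario`, `params`.
#' @export
run_scenario <- function(params, n0, surviving_fraction, scenario = c(
                           "none", "local", "global"),
                         t_max = 120, detection_size = 2000,
                         stop_size = 8000, p_s = NULL, record_state = TRUE,
                         placement = "scattered") {
  scenario <- match.arg(scenario)
  stopifnot(inherits(params, "ca_params"))
  if (scenario == "global" && is.null(params$global_pa)) {
    stop("global scenario requires `global_pa` in params", call. = FALSE)
  }
  if (scenario == "local" && params$inhibition_radius < 1) {
    stop("local scenario requires inhibition_radius >= 1", call. = FALSE)
  }
  if (scenario != "local") params$inhibition_radius <- 0L

  st <- init_state(params, n0, placement = placement)
  st <- apply_irradiation(st, surviving_fraction, p_s = p_s)
  traj <- list(state_counts(st))
  for (d in seq_len(t_max)) {
    st <- ca_step(st, use_global_pa = scenario == "global")
    ct <- state_counts(st)
    traj[[length(traj) + 1]] <- ct
    if (ct$n_viable == 0 || ct$n_viable >= stop_size) break
  }
  traj <- dplyr::bind_rows(traj)
  extinct <- traj$n_viable[nrow(traj)] == 0

  fit <- NULL
  pts <- traj[traj$n_total >= detection_size, c("t", "n_total")]
  if (nrow(pts) >= 3 && !extinct) {
    fit <- fit_exponential_growth(
      data.frame(time = pts$t, value = pts$n_total), min_value = 0)
  }
  structure(
    list(trajectory = traj, extinct = extinct, growth_fit = fit,
         final_state = if (record_state) st else NULL,
         scenario = scenario, surviving_fraction = surviving_fraction,
         params = params),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("CA scenario '%s': %d day(s), S = %.4g\n", x$scenario,
              max(x$trajectory$t), x$surviving_fraction))
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf("  final: %d viable (+%d NPMA)%s\n", last$n_viable,
              last$n_npma, if (x$extinct) " [extinct]" else ""))
  if (!is.null(x$growth_fit)) {
    cat(sprintf("  fitted rate %.4g /day (R^2 %.3f)\n",
                x$growth_fit$rate, x$growth_fit$r_squared))
  }
  invisible(x)
}

#' @rdname run_scenario
#' @param x,object A `sim_result`.
#' @param ... Unused.
#' @export
tidy.sim_result <- function(x, ...) x$trajectory

#' @rdname run_scenario
#' @export
glance.sim_result <- function(x, ...) {
  dplyr::tibble(
    scenario = x$scenario,
    surviving_fraction = x$surviving_fraction,
    days = max(x$trajectory$t),
    extinct = x$extinct,
    rate = if (is.null(x$growth_fit)) NA_real_ else x$growth_fit$rate,
    r.squared = if (is.null(x$growth_fit)) NA_real_
    else x$growth_fit$r_squared,
    final_viable = x$trajectory$n_viable[nrow(x$trajectory)],
    final_npma = x$trajectory$n_npma[nrow(x$trajectory)]
  )
}

#' @rdname run_scenario
#' @export
autoplot.sim_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory,
    c("n_proliferative", "n_quiescent", "n_npma"),
    names_to = "compartment", values_to = "n", names_prefix = "n_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$n,
                                     colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (days)", y = "Cells",
                  title = sprintf("Regrowth scenario: %s", object$scenario))
}

#' Extinction probability of a regrowth scenario
#'
#' Fraction of replicate runs in which every viable cell is lost (NPMA cells
#' do not count toward viability), with its binomial standard error.
#'
#' @inheritParams run_scenario
#' @param n_reps Number of replicate runs (>= 2).
#' @param ... Passed to [run_scenario()].
#' @return One-row tibble: `extinction_probability`, `se`, `n_reps`.
#' @export
extinction_probability <- function(params, n0, surviving_fraction,
                                   scenario = "none", n_reps = 20,
                                   t_max = 60, ...) {
  stopifnot(n_reps >= 2)
  ext <- vapply(seq_len(n_reps), function(i) {
    run_scenario(params, n0, surviving_fraction, scenario = scenario,
                 t_max = t_max, record_state = FALSE, ...)$extinct
  }, logical(1))
  p <- mean(ext)
  dplyr::tibble(extinction_probability = p,
                se = sqrt(p * (1 - p) / n_reps),
                n_reps = n_reps)
}

#' Scenario presets for the global host-inhibition death probability
#'
#' Two documented presets exist for the post-irradiation systemic death
#' probability: the primary one (5.5% after 8 Gy, 6% after 12 Gy) and an
#' alternative (4% after 8 Gy, 7% after 12 Gy). The primary preset is used
#' throughout the package's tests.
#'
#' @param dose 8 or 12 (Gy).
#' @param preset `"primary"` or `"alternative"`.
#' @return The death probability per day.
#' @export
global_pa_preset <- function(dose, preset = c("primary", "alternative")) {
  preset <- match.arg(preset)
  tab <- list(primary = c(`8` = 0.055, `12` = 0.06),
              alternative = c(`8` = 0.04, `12` = 0.07))
  v <- tab[[preset]][as.character(dose)]
  if (is.na(v)) stop("presets exist for 8 and 12 Gy only", call. = FALSE)
  unname(v)
}
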