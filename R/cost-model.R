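# Annual cost of running teleemergency-doctor offices. Two structural
# formulas: decentralized C_d = n_districts * (C_f + v), centralized
# C_c = C_f + e * v, where C_f are fixed office costs, v the jump-fixed
# cost per doctor working in parallel and e the number of simultaneous
# doctors. Variable per-emergency costs cancel between the two designs and
# are excluded; ambulance equipment likewise.

#' Cost structure of a teleemergency-doctor office
#'
#' Decomposes annual office costs (euro/year) into fixed components
#' (independent of staffing: rent, support, quality management,
#' supervision/administration) and jump-fixed components that step up with
#' each doctor working in parallel (salary for 24/365 coverage, training,
#' network, equipment depreciation). Defaults are the Vorpommern-Greifswald
#' figures: \eqn{C_f} = 148,876, \eqn{v} = 548,073, total per office
#' 696,949.
#'
#' @param fixed_components named numeric vector of fixed costs, euro/year.
#' @param jump_fixed_components named numeric vector of per-doctor costs,
#'   euro/year per simultaneous doctor.
#' @return an object of class `cost_structure` with the component maps and
#'   the derived totals `fixed_total` (\eqn{C_f}) and `per_doctor_total`
#'   (\eqn{v}).
#' @examples
#' cs <- cost_structure()
#' cs$fixed_total + cs$per_doctor_total # 696949
#' @export
cost_structure <- function(fixed_components = c(rent = 7200,
                                                support = 3116,
                                                quality_management = 27560,
                                                supervision_admin = 111000),
                           jump_fixed_components = c(salary = 508144,
                                                     training = 6924,
                                                     network = 20797,
                                                     equipment_depreciation = 12208)) {
  stopifnot(is.numeric(fixed_components), is.numeric(jump_fixed_components),
            all(fixed_components >= 0), all(jump_fixed_components >= 0))
  structure(
    list(fixed_components = fixed_components,
         jump_fixed_components = jump_fixed_components,
         fixed_total = sum(fixed_components),
         per_doctor_total = sum(jump_fixed_components)),
    class = "cost_structure")
}

#' @export
print.cost_structure <- function(x, ...) {
  cat("Annual cost structure of one office [euro/year]\n")
  cat(sprintf("  fixed (C_f):            %s\n",
              format(x$fixed_total, big.mark = ",")))
  cat(sprintf("  per parallel doctor (v): %s\n",
              format(x$per_doctor_total, big.mark = ",")))
  cat(sprintf("  one-doctor office total: %s\n",
              format(x$fixed_total + x$per_doctor_total, big.mark = ",")))
  invisible(x)
}

#' Annual cost of the decentralized design
#'
#' One office per district, each with one doctor:
#' \eqn{C_d = n \cdot (C_f + v)}.
#'
#' @param districts number of districts (>= 0).
#' @param costs a [cost_structure()].
#' @return euro per year.
#' @examples
#' decentral_cost(1) # 696949
#' @export
decentral_cost <- function(districts, costs = cost_structure()) {
  stopifnot(inherits(costs, "cost_structure"))
  if (any(districts < 0)) stop("`districts` must be >= 0", call. = FALSE)
  districts * (costs$fixed_total + costs$per_doctor_total)
}

#' Annual cost of the centralized design
#'
#' One office with `doctors_in_parallel` doctors serving all districts:
#' \eqn{C_c = C_f + e \cdot v}.
#'
#' @param doctors_in_parallel number of simultaneous doctors \eqn{e} (>= 0).
#' @param costs a [cost_structure()].
#' @return euro per year.
#' @examples
#' central_cost(6) # 3437314
#' @export
central_cost <- function(doctors_in_parallel, costs = cost_structure()) {
  stopifnot(inherits(costs, "cost_structure"))
  if (any(doctors_in_parallel < 0))
    stop("`doctors_in_parallel` must be >= 0", call. = FALSE)
  costs$fixed_total + doctors_in_parallel * costs$per_doctor_total
}

#' Centralization scenario
#'
#' Describes a group of districts pooling one office: how many districts,
#' how many ambulances each runs, which fraction is telemedically equipped
#' and (optionally) how many doctors work in parallel. If
#' `doctors_in_parallel` is `NULL`, [evaluate_scenario()] plans it from a
#' [capacity_policy()].
#'
#' @param districts number of cooperating districts (>= 1).
#' @param ambulances_per_district ambulances run by each district.
#' @param equipped_fraction share of those ambulances with telemedicine,
#'   in (0, 1].
#' @param doctors_in_parallel \eqn{e}, or `NULL` to plan it.
#' @param costs a [cost_structure()].
#' @return an object of class `centralization_scenario`.
#' @examples
#' centralization_scenario(20, 26, doctors_in_parallel = 6)
#' @export
centralization_scenario <- function(districts, ambulances_per_district = 26L,
                                    equipped_fraction = 1,
                                    doctors_in_parallel = NULL,
                                    costs = cost_structure()) {
  stopifnot(inherits(costs, "cost_structure"))
  if (districts < 1) stop("`districts` must be >= 1", call. = FALSE)
  if (equipped_fraction <= 0 || equipped_fraction > 1)
    stop("`equipped_fraction` must lie in (0, 1]", call. = FALSE)
  if (!is.null(doctors_in_parallel) && doctors_in_parallel < 1)
    stop("`doctors_in_parallel` must be >= 1 when given", call. = FALSE)
  structure(
    list(districts = districts,
         ambulances_per_district = ambulances_per_district,
         equipped_fraction = equipped_fraction,
         doctors_in_parallel = doctors_in_parallel,
         costs = costs),
    class = "centralization_scenario")
}

#' Evaluate a centralization scenario
#'
#' Computes the annual cost of one central office for the scenario and the
#' cost per participating district, against the decentralized baseline. If
#' the scenario does not fix `doctors_in_parallel`, the number is planned
#' with [min_teds()] from the supplied policy and the scenario's total
#' equipped-ambulance count.
#'
#' Euro figures are reported raw and rounded to the nearest 100 (the
#' reporting convention of the source figures); the ratio is per-district
#' cost over the one-district decentralized cost \eqn{C_f + v}.
#'
#' @param scenario a [centralization_scenario()].
#' @param policy a [capacity_policy()]; required when the scenario leaves
#'   `doctors_in_parallel` unset.
#' @return a list of class `scenario_report` with fields
#'   `doctors_in_parallel`, `equipped_ambulances`, `total_central`,
#'   `per_district`, `per_district_rounded`, `decentral_per_district`,
#'   `ratio`.
#' @examples
#' evaluate_scenario(centralization_scenario(60, 26, equipped_fraction = 6 / 26),
#'                   capacity_policy(max_overburdening = 0.05))
#' @export
evaluate_scenario <- function(scenario, policy = NULL) {
  stopifnot(inherits(scenario, "centralization_scenario"))
  ambulances <- scenario$districts * scenario$ambulances_per_district *
    scenario$equipped_fraction
  e <- scenario$doctors_in_parallel
  if (is.null(e)) {
    if (is.null(policy))
      stop("scenario has no `doctors_in_parallel`; supply a capacity policy",
           call. = FALSE)
    e <- min_teds(ambulances * policy$per_ambulance_arrival_rate, policy)
  }
  total <- central_cost(e, scenario$costs)
  per_district <- total / scenario$districts
  baseline <- decentral_cost(1, scenario$costs)
  structure(
    list(doctors_in_parallel = e,
         equipped_ambulances = ambulances,
         total_central = total,
         per_district = per_district,
         per_district_rounded = round(per_district / 100) * 100,
         decentral_per_district = baseline,
         ratio = per_district / baseline),
    class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Centralization scenario report\n")
  cat(sprintf("  doctors in parallel (e): %d for %g equipped ambulances\n",
              as.integer(x$doctors_in_parallel), x$equipped_ambulances))
  cat(sprintf("  central office total:  %s euro/year\n",
              format(x$total_central, big.mark = ",")))
  cat(sprintf("  per district: %s euro/year (approx. %s; %.1f%% of decentralized)\n",
              format(round(x$per_district, 1), big.mark = ","),
              format(x$per_district_rounded, big.mark = ","),
              100 * x$ratio))
  invisible(x)
}
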