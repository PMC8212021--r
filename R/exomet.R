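# Exometabolomics: uptake/secretion rates from medium time courses,
# medium composition constraints, and elastic application of measured
# rates to a model.

#' Estimate exchange rates from extracellular time courses
#'
#' Per metabolite, the ordinary-least-squares slope of concentration
#' against time (mM/h), pooling time points across replicates in one
#' regression, converted to a specific flux by
#' `rate = slope * volume / Xbar`, where `Xbar` is the time-averaged
#' biomass under exponential growth:
#' `Xbar = X0 (2^(T/d) - 1) d / (T ln 2)` over the sampled span `T`
#' (with `Xbar = X0` in the constant-biomass limit `d -> Inf`). The
#' standard error is propagated from the slope's standard error by the
#' same factor. Negative rates are uptake.
#'
#' @param timecourses Tibble with columns `metabolite_id`,
#'   `replicate_id`, `time_h`, `conc_mM` and optionally `depleted`
#'   (truncated-at-zero points, which are dropped).
#' @param gp A [growth_params()] (supplies `X0`, doubling time and the
#'   culture volume).
#' @return Tibble `metabolite_id`, `rate`, `std_err` (mmol/gDW/h),
#'   `n_replicates`, `n_points`, `slope_mM_h`.
#' @export
estimate_exchange_rates <- function(timecourses, gp) {
  stopifnot(inherits(gp, "growth_params"))
  tc <- tibble::as_tibble(timecourses)
  if ("depleted" %in% names(tc)) tc <- tc[!tc$depleted, ]
  if (!nrow(tc)) stop("no usable time points", call. = FALSE)
  x0 <- gp$initial_cell_count * gp$dry_weight_per_cell
  if (x0 <= 0) stop("zero biomass; rates undefined", call. = FALSE)
  tc |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$time_h)) < 2) {
        stop("metabolite '", key$metabolite_id,
             "' has fewer than 2 distinct time points", call. = FALSE)
      }
      fit <- stats::lm(conc_mM ~ time_h, data = d)
      sm <- suppressWarnings(summary(fit))$coefficients
      slope <- sm["time_h", "Estimate"]
      se <- sm["time_h", "Std. Error"]
      if (!is.finite(se)) se <- 0
      span <- max(d$time_h) - min(d$time_h)
      xbar <- mean_biomass(gp, span)
      f <- gp$culture_volume / xbar
      tibble::tibble(rate = slope * f, std_err = se * f,
                     n_replicates = length(unique(d$replicate_id)),
                     n_points = nrow(d), slope_mM_h = slope)
    }) |>
    dplyr::ungroup()
}

#' Apply medium-composition constraints to a model
#'
#' Opens uptake for the exchanges of metabolites present in the medium
#' and closes every other uptake; secretion is left untouched.
#' Quantified metabolites may be capped proportionally to their
#' concentration, unquantified ones get the default cap.
#'
#' @param model A `metabolic_model`.
#' @param medium Tibble with column `metabolite_id` (extracellular ids)
#'   and optionally `conc_mM` (`NA` = detected but unquantified).
#' @param uptake_cap Default maximal uptake in mmol/gDW/h
#'   (default 1000).
#' @param cap_per_mM Optional scaling: a quantified metabolite's uptake
#'   cap becomes `conc_mM * cap_per_mM` (default `NULL` = ignore
#'   concentrations and use `uptake_cap` throughout).
#' @return The constrained model. Medium metabolites without an
#'   exchange reaction are reported in a warning and in the
#'   `missing_exchanges` attribute.
#' @export
apply_medium_constraints <- function(model, medium,
                                     uptake_cap = DEFAULT_BOUND,
                                     cap_per_mM = NULL) {
  medium <- tibble::as_tibble(medium)
  ex <- exchange_reactions(model)
  hit <- match(medium$metabolite_id, ex$metabolite_id)
  missing <- medium$metabolite_id[is.na(hit)]
  if (length(missing)) {
    warning("no exchange reaction for medium metabolite(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  # close all uptakes, then open the medium ones
  i <- match(ex$id, model$reactions$id)
  model$reactions$lower_bound[i] <- pmax(model$reactions$lower_bound[i], 0)
  present <- medium[!is.na(hit), ]
  ex_ids <- ex$id[hit[!is.na(hit)]]
  caps <- rep(uptake_cap, nrow(present))
  if (!is.null(cap_per_mM) && "conc_mM" %in% names(present)) {
    quant <- !is.na(present$conc_mM)
    caps[quant] <- present$conc_mM[quant] * cap_per_mM
  }
  if (length(ex_ids)) {
    model <- set_bounds(model, ex_ids, lower = -caps)
  }
  attr(model, "missing_exchanges") <- missing
  model
}

#' Apply measured exchange rates with minimal elastic relaxation
#'
#' Constrains each measured exchange flux to the window
#' `rate +/- tolerance_multiplier * std_err`. If the windows are
#' jointly infeasible with positive growth, an elastic LP distributes
#' the minimal total L1 slack over the measured bounds; each window is
#' widened by exactly its share of slack, so the returned model is
#' feasible and the relaxation is minimal in the L1 sense.
#'
#' @param model A feasible `metabolic_model`.
#' @param rates Tibble `metabolite_id`, `rate`, `std_err` (e.g. from
#'   [estimate_exchange_rates()]); ids are extracellular metabolites.
#' @param tolerance_multiplier Half-width of the measurement window in
#'   standard errors (default 1).
#' @param min_growth Required biomass flux while fitting the
#'   measurements (default 1e-6).
#' @return A list with `model` (bounds updated) and `relaxation`, a
#'   tibble of class `relaxation_report`: per measured exchange the
#'   requested and applied bounds and the slack absorbed on each side;
#'   attribute `total_slack`.
#' @export
apply_measured_rates <- function(model, rates, tolerance_multiplier = 1,
                                 min_growth = 1e-6) {
  rates <- tibble::as_tibble(rates)
  if (!"std_err" %in% names(rates)) rates$std_err <- 0
  ex_id <- exchange_for_metabolite(model, rates$metabolite_id)
  missing <- rates$metabolite_id[is.na(ex_id)]
  if (length(missing)) {
    warning("no exchange reaction for measured metabolite(s): ",
            paste(missing, collapse = ", "), "; skipped", call. = FALSE)
    rates <- rates[!is.na(ex_id), ]
    ex_id <- ex_id[!is.na(ex_id)]
  }
  if (!nrow(rates)) stop("no applicable measured rates", call. = FALSE)
  k <- tolerance_multiplier
  req_lb <- rates$rate - k * rates$std_err
  req_ub <- rates$rate + k * rates$std_err

  S <- stoich_matrix(model)
  m <- nrow(S); n <- ncol(S); p <- nrow(rates)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  j <- match(ex_id, colnames(S))
  # measured exchanges may be pushed outside their structural bounds
  lb[j] <- pmin(lb[j], req_lb); lb[j] <- pmax(lb[j], -DEFAULT_BOUND)
  ub[j] <- pmax(ub[j], req_ub); ub[j] <- pmin(ub[j], DEFAULT_BOUND)
  i_obj <- match(model$objective_id, colnames(S))
  lb[i_obj] <- max(lb[i_obj], min_growth)

  # variables: v (n), sL (p), sU (p); minimize sum(sL + sU)
  Aeq <- cbind(S, matrix(0, m, 2 * p))
  Ev <- matrix(0, p, n); Ev[cbind(seq_len(p), j)] <- 1
  Ale <- rbind(cbind(Ev, matrix(0, p, p), -diag(p)),     #  v - sU <= req_ub
               cbind(-Ev, -diag(p), matrix(0, p, p)))    # -v - sL <= -req_lb
  ble <- c(req_ub, -req_lb)
  res <- solve_lp(c(rep(0, n), rep(-1, 2 * p)),
                  Aeq = Aeq, beq = rep(0, m),
                  lb = c(lb, rep(0, 2 * p)),
                  ub = c(ub, rep(DEFAULT_BOUND, 2 * p)),
                  direction = "max", Ale = Ale, ble = ble)
  if (res$status != "optimal") {
    stop("measured constraints structurally infeasible even with slack",
         call. = FALSE)
  }
  sL <- pmax(res$x[n + seq_len(p)], 0)
  sU <- pmax(res$x[n + p + seq_len(p)], 0)
  sL[sL < 1e-9] <- 0; sU[sU < 1e-9] <- 0
  app_lb <- req_lb - sL
  app_ub <- req_ub + sU
  model <- set_bounds(model, ex_id, lower = app_lb, upper = app_ub)

  rep_tbl <- tibble::tibble(metabolite_id = rates$metabolite_id,
                            exchange_id = ex_id,
                            requested_lb = req_lb, requested_ub = req_ub,
                            applied_lb = app_lb, applied_ub = app_ub,
                            slack_lower = sL, slack_upper = sU)
  class(rep_tbl) <- c("relaxation_report", class(rep_tbl))
  attr(rep_tbl, "total_slack") <- sum(sL) + sum(sU)
  list(model = model, relaxation = rep_tbl)
}
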