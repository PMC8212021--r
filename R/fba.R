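# Flux balance analysis and the LP-based model benchmarks.

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of one reaction subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds.
#'
#' @param model A `metabolic_model`.
#' @param objective_id Reaction id to optimize (default: the model's
#'   objective).
#' @param direction `"max"` (default) or `"min"`.
#' @return An object of class `gem_fba`: list with `status`
#'   (`"optimal"`/`"infeasible"`), `objective_value`, `objective_id`,
#'   `direction` and `fluxes` (tibble `reaction_id`, `flux`; `NULL`
#'   unless optimal). Flux vectors at alternative optima are not
#'   uniquely determined; only the objective value is a contract.
#' @export
fba <- function(model, objective_id = model$objective_id,
                direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (!objective_id %in% model$reactions$id) {
    stop("objective reaction '", objective_id, "' not in model", call. = FALSE)
  }
  S <- stoich_matrix(model)
  n <- ncol(S)
  obj <- as.numeric(colnames(S) == objective_id)
  sol <- solve_lp(obj, Aeq = S, beq = rep(0, nrow(S)),
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound,
                  direction = direction)
  if (sol$status == "maxiter") {
    stop("LP solver failed to converge (status maxiter) for objective ",
         objective_id, call. = FALSE)
  }
  res <- list(status = sol$status,
              objective_value = if (sol$status == "optimal") sol$objective else NA_real_,
              objective_id = objective_id,
              direction = direction,
              model_name = model$name,
              fluxes = if (sol$status == "optimal") {
                tibble::tibble(reaction_id = colnames(S), flux = sol$x)
              })
  class(res) <- "gem_fba"
  res
}

#' @export
print.gem_fba <- function(x, ...) {
  cat("<gem_fba> ", x$direction, " ", x$objective_id, " on ", x$model_name,
      ": ", x$status, sep = "")
  if (x$status == "optimal") cat(", objective = ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the flux vector of an FBA solution
#' @param x A `gem_fba` object.
#' @param ... Unused.
#' @return Tibble `reaction_id`, `flux` (empty when not optimal).
#' @method tidy gem_fba
#' @export
tidy.gem_fba <- function(x, ...) {
  x$fluxes %||% tibble::tibble(reaction_id = character(), flux = numeric())
}

#' One-row summary of an FBA solution
#' @param x A `gem_fba` object.
#' @param ... Unused.
#' @return Tibble with `status`, `objective_id`, `direction`,
#'   `objective_value`.
#' @method glance gem_fba
#' @export
glance.gem_fba <- function(x, ...) {
  tibble::tibble(status = x$status, objective_id = x$objective_id,
                 direction = x$direction, objective_value = x$objective_value)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above `fraction` times its optimum.
#'
#' @param model A `metabolic_model`.
#' @param fraction Required objective fraction in `[0, 1]`; `0` drops
#'   the objective constraint entirely.
#' @param reactions Reaction ids to scan (default: all).
#' @return Tibble `reaction_id`, `min_flux`, `max_flux`, plus the
#'   `fraction` used as an attribute.
#' @export
fva <- function(model, fraction = 1.0, reactions = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction > 0) {
    wt <- fba(model)
    if (wt$status != "optimal") {
      stop("model is infeasible; cannot run FVA", call. = FALSE)
    }
    i <- match(model$objective_id, model$reactions$id)
    floor_ <- fraction * wt$objective_value
    # only tighten; never loosen an existing lower bound
    model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], floor_)
  }
  reactions <- reactions %||% model$reactions$id
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  zero <- rep(0, nrow(S))
  res <- lapply(reactions, function(rid) {
    obj <- as.numeric(colnames(S) == rid)
    lo <- solve_lp(obj, Aeq = S, beq = zero, lb = lb, ub = ub, direction = "min")
    hi <- solve_lp(obj, Aeq = S, beq = zero, lb = lb, ub = ub, direction = "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ", rid, call. = FALSE)
    }
    tibble::tibble(reaction_id = rid, min_flux = lo$objective, max_flux = hi$objective)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "fraction") <- fraction
  out
}

# find (or create) the ATP hydrolysis demand "atp + h2o -> adp + pi + h"
ensure_atp_demand <- function(model) {
  cand <- intersect(c("DM_atp", "DM_atp_c", "ATPM"), model$reactions$id)
  if (length(cand)) return(list(model = model, id = cand[1]))
  need <- c("atp", "h2o", "adp", "pi", "h")
  ids <- vapply(need, function(b) {
    hit <- model$metabolites$id[grepl(paste0("^", b, "_"), model$metabolites$id) &
                                model$metabolites$compartment != model$extracellular]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  if (anyNA(ids)) {
    stop("cannot construct an ATP demand: metabolites not found: ",
         paste(need[is.na(ids)], collapse = ", "), call. = FALSE)
  }
  st <- stats::setNames(c(-1, -1, 1, 1, 1), ids)
  model <- add_reaction(model, "DM_atp", st, lower_bound = 0,
                        upper_bound = DEFAULT_BOUND,
                        name = "ATP hydrolysis demand",
                        subsystem = "Energy demand")
  list(model = model, id = "DM_atp")
}

# exchanges whose metabolite contains carbon
carbon_exchanges <- function(model) {
  ex <- exchange_reactions(model)
  forms <- model$metabolites$formula[match(ex$metabolite_id, model$metabolites$id)]
  has_c <- vapply(forms, function(f) {
    p <- parse_formula(f)
    !is.null(p) && "C" %in% names(p)
  }, logical(1))
  ex$id[has_c]
}

# locate the oxygen exchange by metabolite formula O2
oxygen_exchange <- function(model) {
  ex <- exchange_reactions(model)
  forms <- model$metabolites$formula[match(ex$metabolite_id, model$metabolites$id)]
  hit <- ex$id[forms == "O2"]
  if (length(hit)) hit[1] else NA_character_
}

#' Maximal ATP yield per unit substrate
#'
#' The classic model benchmark: fix the uptake of one carbon substrate,
#' close every other organic-carbon uptake, open or close the oxygen
#' exchange, and maximize flux through the ATP hydrolysis demand.
#'
#' @param model A `metabolic_model`. An ATP demand
#'   (`atp + h2o -> adp + pi + h`) is added as `DM_atp` if absent.
#' @param substrate_exchange_id Exchange reaction id of the substrate.
#' @param aerobic Logical; `FALSE` shuts the oxygen exchange, `TRUE`
#'   leaves it as the model provides it (so a medium constrained
#'   without oxygen stays anoxic even in the "aerobic" assay).
#' @param uptake Fixed substrate uptake rate in mmol/gDW/h (default 1).
#' @return Maximal ATP demand flux divided by `uptake` (mol ATP per mol
#'   substrate). Returns 0 with a warning when the substrate cannot be
#'   catabolized at all.
#' @export
atp_yield <- function(model, substrate_exchange_id, aerobic = TRUE, uptake = 1) {
  stopifnot(uptake > 0)
  if (!substrate_exchange_id %in% model$reactions$id) {
    stop("substrate exchange '", substrate_exchange_id, "' not in model",
         call. = FALSE)
  }
  dm <- ensure_atp_demand(model)
  model <- dm$model
  carbon <- setdiff(carbon_exchanges(model), substrate_exchange_id)
  if (length(carbon)) {
    i <- match(carbon, model$reactions$id)
    model$reactions$lower_bound[i] <- pmax(model$reactions$lower_bound[i], 0)
  }
  # aerobic leaves the oxygen exchange as the model provides it (so a
  # medium without oxygen stays anoxic); anaerobic shuts the uptake
  o2 <- oxygen_exchange(model)
  if (!is.na(o2) && !aerobic) {
    i <- match(o2, model$reactions$id)
    model <- set_bounds(model, o2, lower = 0,
                        upper = max(model$reactions$upper_bound[i], 0))
  }
  model <- set_bounds(model, substrate_exchange_id, lower = -uptake, upper = -uptake)
  sol <- fba(model, objective_id = dm$id, direction = "max")
  if (sol$status != "optimal") {
    warning("no feasible solution at fixed uptake of ", substrate_exchange_id,
            "; substrate unusable, yield 0", call. = FALSE)
    return(0)
  }
  sol$objective_value / uptake
}

#' Sanity-check configuration
#'
#' @param energy_leak_threshold Maximal tolerated energy-from-nothing or
#'   leak flux (default `1e-10` mmol/gDW/h).
#' @param energy_metabolites Base names of the currency couples checked
#'   by the energy test (default ATP, NAD(H), NADP(H)).
#' @param lp_tolerance LP feasibility tolerance (default `1e-9`).
#' @return A list of class `sanity_config`.
#' @export
sanity_config <- function(energy_leak_threshold = 1e-10,
                          energy_metabolites = c("atp", "nadh", "nadph"),
                          lp_tolerance = 1e-9) {
  stopifnot(energy_leak_threshold > 0, lp_tolerance > 0)
  structure(list(energy_leak_threshold = energy_leak_threshold,
                 energy_metabolites = energy_metabolites,
                 lp_tolerance = lp_tolerance),
            class = "sanity_config")
}

# dissipation reactions probing erroneous production of each currency
# couple: maximizing them with all exchanges shut must give ~0 flux.
energy_dissipation_stoich <- function(model, base) {
  find <- function(b) {
    hit <- model$metabolites$id[grepl(paste0("^", b, "_"), model$metabolites$id) &
                                model$metabolites$compartment != model$extracellular]
    if (length(hit)) hit[1] else NA_character_
  }
  tmpl <- switch(base,
    atp = c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1),
    nadh = c(nadh = -1, nad = 1, h = 1),
    nadph = c(nadph = -1, nadp = 1, h = 1),
    stop("no dissipation template for '", base, "'", call. = FALSE))
  ids <- vapply(names(tmpl), find, character(1))
  if (anyNA(ids)) return(NULL)
  stats::setNames(as.numeric(tmpl), ids)
}

#' Biological-feasibility sanity suite
#'
#' Two checks against thermodynamically impossible behavior:
#' (a) energy from nothing - with every exchange closed, the maximal
#' dissipation flux of each currency couple (ATP hydrolysis, NADH and
#' NADPH oxidation) must not exceed the threshold; (b) leak test - with
#' all uptakes shut, no metabolite's temporary sink may carry flux above
#' the threshold.
#'
#' @param model A `metabolic_model`.
#' @param config A [sanity_config()].
#' @return A list of class `sanity_report`: `energy` (tibble `check`,
#'   `max_flux`, `pass`), `leaks` (tibble `metabolite_id`, `max_flux`
#'   for violators only), and `pass` (overall logical).
#' @export
sanity_suite <- function(model, config = sanity_config()) {
  thr <- config$energy_leak_threshold
  ex_ids <- model$reactions$id[model$reactions$is_exchange]

  closed <- model
  i <- match(ex_ids, closed$reactions$id)
  closed$reactions$lower_bound[i] <- 0
  closed$reactions$upper_bound[i] <- 0
  energy <- dplyr::bind_rows(lapply(config$energy_metabolites, function(base) {
    st <- energy_dissipation_stoich(closed, base)
    if (is.null(st)) {
      return(tibble::tibble(check = base, max_flux = NA_real_, pass = NA))
    }
    m2 <- add_reaction(closed, paste0("TMP_DISS_", base), st,
                       lower_bound = 0, upper_bound = DEFAULT_BOUND)
    sol <- fba(m2, objective_id = paste0("TMP_DISS_", base))
    v <- if (sol$status == "optimal") sol$objective_value else 0
    tibble::tibble(check = base, max_flux = v, pass = v <= thr)
  }))

  noupt <- model
  i <- match(ex_ids, noupt$reactions$id)
  noupt$reactions$lower_bound[i] <- pmax(noupt$reactions$lower_bound[i], 0)
  leak_rows <- lapply(noupt$metabolites$id, function(mid) {
    m2 <- add_reaction(noupt, "TMP_SINK", stats::setNames(-1, mid),
                       lower_bound = 0, upper_bound = DEFAULT_BOUND)
    sol <- fba(m2, objective_id = "TMP_SINK")
    v <- if (sol$status == "optimal") sol$objective_value else 0
    tibble::tibble(metabolite_id = mid, max_flux = v)
  })
  leaks <- dplyr::bind_rows(leak_rows)
  leaks <- leaks[leaks$max_flux > thr, ]

  out <- list(energy = energy,
              leaks = leaks,
              threshold = thr,
              pass = all(energy$pass, na.rm = TRUE) && nrow(leaks) == 0)
  class(out) <- "sanity_report"
  out
}

#' @export
print.sanity_report <- function(x, ...) {
  cat("<sanity_report> overall:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  energy-from-nothing (threshold ", format(x$threshold), "):\n", sep = "")
  for (k in seq_len(nrow(x$energy))) {
    cat("    ", x$energy$check[k], ": ", format(x$energy$max_flux[k]),
        if (isTRUE(x$energy$pass[k])) "  ok" else "  FAIL", "\n", sep = "")
  }
  cat("  leaking metabolites: ", nrow(x$leaks), "\n", sep = "")
  invisible(x)
}

#' Single-deletion essentiality scan
#'
#' Reaction deletions close the reaction's bounds to zero; gene
#' deletions disable every reaction whose GPR evaluates false with the
#' gene absent. A deletion is lethal when the biomass optimum drops
#' below `cutoff` times the wild-type optimum.
#'
#' @param model A `metabolic_model` with a positive biomass optimum.
#' @param cutoff Lethality threshold on the growth ratio (default 0.01).
#' @param genes,reactions Logical; which scans to run.
#' @return A tibble (class `essentiality_result`) with columns `type`
#'   (`"reaction"`/`"gene"`), `id`, `growth`, `growth_ratio`, `lethal`.
#' @export
essentiality <- function(model, cutoff = 0.01, genes = TRUE, reactions = TRUE) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 0) {
    stop("wild-type model has no positive growth; growth ratios undefined",
         call. = FALSE)
  }
  wt_val <- wt$objective_value
  del_growth <- function(m) {
    s <- fba(m)
    if (s$status == "optimal") max(s$objective_value, 0) else 0
  }
  rows <- list()
  if (reactions) {
    rows <- c(rows, lapply(model$reactions$id, function(rid) {
      g <- del_growth(set_bounds(model, rid, lower = 0, upper = 0))
      tibble::tibble(type = "reaction", id = rid, growth = g)
    }))
  }
  if (genes) {
    trees <- lapply(model$reactions$gpr, parse_gpr)
    all_genes <- model$genes$id
    rows <- c(rows, lapply(all_genes, function(gid) {
      present <- stats::setNames(all_genes != gid, all_genes)
      off <- model$reactions$id[!vapply(trees, eval_gpr, logical(1),
                                        present = present)]
      m <- model
      if (length(off)) m <- set_bounds(m, off, lower = 0, upper = 0)
      g <- del_growth(m)
      tibble::tibble(type = "gene", id = gid, growth = g)
    }))
  }
  out <- dplyr::bind_rows(rows)
  out$growth_ratio <- out$growth / wt_val
  out$lethal <- out$growth_ratio < cutoff
  class(out) <- c("essentiality_result", class(out))
  out
}

#' Lethal genes from an essentiality scan
#' @param result An `essentiality_result`.
#' @return Character vector of lethal gene ids.
#' @export
lethal_genes <- function(result) {
  result$id[result$type == "gene" & result$lethal]
}

#' Lethal reactions from an essentiality scan
#' @param result An `essentiality_result`.
#' @return Character vector of lethal reaction ids.
#' @export
lethal_reactions <- function(result) {
  result$id[result$type == "reaction" & result$lethal]
}
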