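# Merged two-lineage models and the bound-relaxation program that
# proposes reactions to perturb to move one lineage's flux state toward
# another's.

#' Build a merged (union) two-lineage model
#'
#' The merged model carries the union of both models' reactions.
#' Reactions of the `initial` lineage keep their bounds; reactions
#' exclusive to the `target` lineage are included with bounds closed to
#' `[0, 0]`, so reaching the target flux state requires relaxing them.
#' Metabolites and genes merge by id.
#'
#' @param target,initial `metabolic_model` objects sharing an id
#'   namespace.
#' @return A `metabolic_model` (objective and name from `initial`).
#'   Conflicting stoichiometry for a shared reaction id is an error.
#' @export
build_merged_model <- function(target, initial) {
  shared <- intersect(target$reactions$id, initial$reactions$id)
  st_t <- split(target$stoichiometry, target$stoichiometry$reaction_id)
  st_i <- split(initial$stoichiometry, initial$stoichiometry$reaction_id)
  for (rid in shared) {
    a <- st_t[[rid]][order(st_t[[rid]]$metabolite_id), ]
    b <- st_i[[rid]][order(st_i[[rid]]$metabolite_id), ]
    if (!identical(a$metabolite_id, b$metabolite_id) ||
        max(abs(a$coefficient - b$coefficient)) > 1e-9) {
      stop("conflicting stoichiometry for shared reaction '", rid, "'",
           call. = FALSE)
    }
  }
  t_only <- setdiff(target$reactions$id, shared)
  rx_t <- target$reactions[match(t_only, target$reactions$id), ]
  rx_t$lower_bound <- 0
  rx_t$upper_bound <- 0
  reactions <- dplyr::bind_rows(initial$reactions, rx_t)
  stoich <- dplyr::bind_rows(
    initial$stoichiometry,
    target$stoichiometry[target$stoichiometry$reaction_id %in% t_only, ])
  mets <- dplyr::bind_rows(
    initial$metabolites,
    target$metabolites[!target$metabolites$id %in% initial$metabolites$id, ])
  genes <- dplyr::bind_rows(
    initial$genes,
    target$genes[!target$genes$id %in% initial$genes$id, , drop = FALSE])
  metabolic_model(mets, reactions, stoich, genes = genes,
                  objective_id = initial$objective_id,
                  name = paste0(initial$name, "+", target$name),
                  extracellular = initial$extracellular)
}

#' Target flux state from a flux sample
#'
#' @param sample A `flux_sample` of the target lineage.
#' @return Tibble `reaction_id`, `target_flux` (per-reaction sample
#'   means). Reactions outside the sample are implicitly zero when the
#'   state is used against a merged model.
#' @export
target_state <- function(sample) {
  stopifnot(inherits(sample, "flux_sample"))
  tibble::tibble(reaction_id = sample$reactions,
                 target_flux = colMeans(sample$samples))
}

#' Relaxation configuration
#'
#' @param alpha Mixing weight in (0, 1): stage two minimizes
#'   `alpha * magnitude + (1 - alpha) * K * count` with count scale
#'   `K = 0.1 * bound_cap`, so lower alpha presses harder on the
#'   relaxed-reaction count (default 0.99).
#' @param fallback_alphas Alphas retried in order when the primary
#'   alpha relaxes more than `max_list_length` reactions
#'   (default `c(0.75, 0.9)`).
#' @param max_list_length Longest acceptable relaxed-reaction list
#'   (default 100).
#' @param bound_cap Largest admissible bound expansion per side
#'   (default 1000 mmol/gDW/h).
#' @return A list of class `relaxation_config`.
#' @export
relaxation_config <- function(alpha = 0.99, fallback_alphas = c(0.75, 0.9),
                              max_list_length = 100L, bound_cap = DEFAULT_BOUND) {
  stopifnot(alpha > 0, alpha < 1, all(fallback_alphas > 0),
            all(fallback_alphas < 1), max_list_length >= 1, bound_cap > 0)
  structure(list(alpha = alpha, fallback_alphas = fallback_alphas,
                 max_list_length = as.integer(max_list_length),
                 bound_cap = bound_cap),
            class = "relaxation_config")
}

#' Propose bound relaxations moving a model toward a target flux state
#'
#' Two-stage linear program. Stage one finds the minimal attainable L1
#' distance `sum |v - target|` over flux vectors `v` with `S v = 0` and
#' bounds expandable by per-reaction slacks `r_L, r_U in [0,
#' bound_cap]`. Stage two fixes that distance (within 1e-6) and
#' minimizes `alpha * (total relaxation magnitude) +
#' (1 - alpha) * K * (approximate count of relaxed reactions)`, with
#' count scale `K = 0.1 * bound_cap`; lowering alpha therefore presses
#' harder on sparsity, which is why a too-long list at the primary
#' alpha is retried at the lower fallback alphas. The count surrogate
#' is a capped-L1 term handled by iteratively reweighted L1 (weights
#' `cap_s / (r + cap_s)` with `cap_s = 1e-3 * bound_cap`), which drives
#' small relaxations to exactly zero. If the relaxed list exceeds
#' `max_list_length`, the fallback alphas are tried in order and the
#' alpha that produced the returned list is reported. Deterministic.
#'
#' @param merged A `metabolic_model`, typically from
#'   [build_merged_model()].
#' @param target Tibble `reaction_id`, `target_flux`; reactions of the
#'   merged model missing from it are targeted at zero.
#' @param config A [relaxation_config()].
#' @return An object of class `relaxation_result`: list with `relaxed`
#'   (tibble `reaction_id`, `old_lower`, `old_upper`, `new_lower`,
#'   `new_upper`, `magnitude`), `achieved_distance`, `alpha_used`,
#'   `total_magnitude`, `n_relaxed`.
#' @export
relax_to_target <- function(merged, target, config = relaxation_config()) {
  S <- stoich_matrix(merged)
  n <- ncol(S); m <- nrow(S)
  lb <- merged$reactions$lower_bound
  ub <- merged$reactions$upper_bound
  t_full <- rep(0, n)
  k <- match(target$reaction_id, colnames(S))
  if (anyNA(k)) {
    stop("target references reaction(s) not in the merged model: ",
         paste(utils::head(target$reaction_id[is.na(k)], 5), collapse = ", "),
         call. = FALSE)
  }
  t_full[k] <- target$target_flux
  cap <- config$bound_cap
  cap_s <- 1e-3 * cap

  # variables: v (n), rL (n), rU (n), dp (n), dm (n)
  idx_v <- seq_len(n)
  idx_rL <- n + seq_len(n)
  idx_rU <- 2 * n + seq_len(n)
  idx_dp <- 3 * n + seq_len(n)
  idx_dm <- 4 * n + seq_len(n)
  nv <- 5 * n
  Aeq <- matrix(0, m + n, nv)
  Aeq[seq_len(m), idx_v] <- S
  Aeq[m + seq_len(n), idx_v] <- diag(n)
  Aeq[m + seq_len(n), idx_dp] <- -diag(n)
  Aeq[m + seq_len(n), idx_dm] <- diag(n)
  beq <- c(rep(0, m), t_full)
  Ale <- matrix(0, 2 * n, nv)
  Ale[seq_len(n), idx_v] <- diag(n)        #  v - rU <= ub
  Ale[seq_len(n), idx_rU] <- -diag(n)
  Ale[n + seq_len(n), idx_v] <- -diag(n)   # -v - rL <= -lb
  Ale[n + seq_len(n), idx_rL] <- -diag(n)
  ble <- c(ub, -lb)
  vlb <- c(pmax(lb - cap, -cap), rep(0, 4 * n))
  vub <- c(pmin(ub + cap, cap), rep(cap, 2 * n), rep(2 * cap, 2 * n))

  # stage 1: minimal distance
  obj1 <- numeric(nv); obj1[c(idx_dp, idx_dm)] <- 1
  s1 <- solve_lp(obj1, Aeq = Aeq, beq = beq, lb = vlb, ub = vub,
                 direction = "min", Ale = Ale, ble = ble)
  if (s1$status != "optimal") {
    stop("target state structurally unreachable under any admissible ",
         "relaxation", call. = FALSE)
  }
  dist <- s1$objective

  # stage 2: sparse relaxation at fixed distance
  Ale2 <- rbind(Ale, obj1)
  ble2 <- c(ble, dist + 1e-6)
  K <- 0.1 * cap
  run_alpha <- function(alpha) {
    wgt <- rep(1, n)
    sol <- NULL
    for (it in 1:4) {
      obj2 <- numeric(nv)
      obj2[idx_rL] <- alpha + (1 - alpha) * K * wgt
      obj2[idx_rU] <- alpha + (1 - alpha) * K * wgt
      sol <- solve_lp(obj2, Aeq = Aeq, beq = beq, lb = vlb, ub = vub,
                      direction = "min", Ale = Ale2, ble = ble2)
      if (sol$status != "optimal") return(NULL)
      r <- sol$x[idx_rL] + sol$x[idx_rU]
      wgt <- cap_s / (r + cap_s)
    }
    sol
  }
  alphas <- c(config$alpha, config$fallback_alphas)
  sol <- NULL; alpha_used <- NA_real_
  for (al in alphas) {
    cand <- run_alpha(al)
    if (is.null(cand)) next
    rl <- pmax(cand$x[idx_rL], 0); ru <- pmax(cand$x[idx_rU], 0)
    n_rel <- sum(rl + ru > 1e-6)
    sol <- cand; alpha_used <- al
    if (n_rel <= config$max_list_length) break
  }
  if (is.null(sol)) {
    stop("relaxation program infeasible at the fixed distance", call. = FALSE)
  }
  rl <- pmax(sol$x[idx_rL], 0); ru <- pmax(sol$x[idx_rU], 0)
  rl[rl < 1e-6] <- 0; ru[ru < 1e-6] <- 0
  rel <- which(rl + ru > 0)
  relaxed <- tibble::tibble(
    reaction_id = colnames(S)[rel],
    old_lower = lb[rel], old_upper = ub[rel],
    new_lower = lb[rel] - rl[rel], new_upper = ub[rel] + ru[rel],
    magnitude = rl[rel] + ru[rel])
  res <- list(relaxed = relaxed,
              achieved_distance = dist,
              alpha_used = alpha_used,
              total_magnitude = sum(relaxed$magnitude),
              n_relaxed = nrow(relaxed))
  class(res) <- "relaxation_result"
  res
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat("<relaxation_result> ", x$n_relaxed, " reaction(s) relaxed at alpha ",
      format(x$alpha_used), "; distance ", format(x$achieved_distance),
      "\n", sep = "")
  invisible(x)
}

#' Tidy the relaxed-bound list
#' @param x A `relaxation_result`.
#' @param ... Unused.
#' @return The `relaxed` tibble.
#' @method tidy relaxation_result
#' @export
tidy.relaxation_result <- function(x, ...) x$relaxed

#' One-row summary of a relaxation run
#' @param x A `relaxation_result`.
#' @param ... Unused.
#' @return Tibble `n_relaxed`, `alpha_used`, `achieved_distance`,
#'   `total_magnitude`.
#' @method glance relaxation_result
#' @export
glance.relaxation_result <- function(x, ...) {
  tibble::tibble(n_relaxed = x$n_relaxed, alpha_used = x$alpha_used,
                 achieved_distance = x$achieved_distance,
                 total_magnitude = x$total_magnitude)
}

strip_compartment <- function(ids) sub("_[^_]+$", "", ids)

#' Classify relaxed reactions and their direction of change
#'
#' Labels each relaxed reaction `transport` (it moves metabolites
#' between compartments without chemical change), `exchange/demand`
#' (boundary reactions: exchanges, demands and sinks) or `internal`,
#' and derives the direction of change from the feasible flux signs of
#' the old versus new bounds: `activate` (previously pinned at zero),
#' `reverse` (a previously unavailable flux sign opens up), or
#' `amplify` (the existing direction widens).
#'
#' @param result A `relaxation_result`.
#' @param model The merged `metabolic_model` it refers to.
#' @return The `relaxed` tibble with extra `class` and `direction`
#'   columns.
#' @export
classify_relaxed <- function(result, model) {
  st <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  rel <- result$relaxed
  if (!nrow(rel)) {
    rel$class <- character()
    rel$direction <- character()
    return(rel)
  }
  is_ex <- stats::setNames(model$reactions$is_exchange, model$reactions$id)
  cls <- vapply(rel$reaction_id, function(rid) {
    s <- st[[rid]]
    if (isTRUE(is_ex[[rid]]) || nrow(s) == 1 || grepl("^(DM|SK)_", rid)) {
      return("exchange/demand")
    }
    if (length(unique(comp[s$metabolite_id])) > 1) {
      base_net <- tapply(s$coefficient, strip_compartment(s$metabolite_id), sum)
      if (all(abs(base_net) < 1e-9)) return("transport")
    }
    "internal"
  }, character(1))
  sgn_set <- function(l, u) c(if (l < -1e-9) -1, if (u > 1e-9) 1)
  dir <- vapply(seq_len(nrow(rel)), function(i) {
    old <- sgn_set(rel$old_lower[i], rel$old_upper[i])
    new <- sgn_set(rel$new_lower[i], rel$new_upper[i])
    if (!length(old)) return("activate")
    if (length(setdiff(new, old))) return("reverse")
    "amplify"
  }, character(1))
  rel$class <- unname(cls)
  rel$direction <- dir
  rel
}
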