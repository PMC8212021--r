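# Transcriptome normalization/pooling, expression-to-reaction mapping,
# GIMME context-specific extraction and flux-consistency pruning.

#' Normalize expression datasets to a common scale and pool them
#'
#' Each dataset (assumed already normalized internally by its source
#' pipeline) is rescaled so its maximal intensity equals `target_scale`,
#' preserving the customary magnitude of array intensities; the pooled
#' per-gene value is the mean across the datasets that measured the
#' gene.
#'
#' @param profiles Tibble with columns `dataset_id`, `gene_id`,
#'   `intensity` (or a list of such tibbles, bound together).
#' @param target_scale Common maximal intensity after rescaling
#'   (default 1000).
#' @return Tibble `gene_id`, `intensity` on the common scale, with
#'   attribute `target_scale`. Genes absent from every dataset are
#'   simply absent (unknown downstream).
#' @export
normalize_and_pool <- function(profiles, target_scale = 1000) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- dplyr::bind_rows(profiles)
  }
  profiles <- tibble::as_tibble(profiles)
  if (!nrow(profiles)) stop("no expression data supplied", call. = FALSE)
  if (any(!is.finite(profiles$intensity)) || any(profiles$intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  maxima <- profiles |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::summarise(mx = max(.data$intensity), .groups = "drop")
  if (any(maxima$mx == 0)) {
    stop("all-zero dataset(s) cannot be rescaled: ",
         paste(maxima$dataset_id[maxima$mx == 0], collapse = ", "),
         call. = FALSE)
  }
  out <- profiles |>
    dplyr::left_join(maxima, by = "dataset_id") |>
    dplyr::mutate(intensity = .data$intensity / .data$mx * target_scale) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  attr(out, "target_scale") <- target_scale
  out
}

#' Map pooled gene expression onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR with `and` = min and `or` = max over
#' gene intensities (see [score_gpr()]). Reactions without a GPR, and
#' rules whose genes are all unmeasured, score `NA` (unknown).
#'
#' @param model A `metabolic_model`.
#' @param pooled Tibble `gene_id`, `intensity` from
#'   [normalize_and_pool()].
#' @return Tibble `reaction_id`, `score` with attribute `coverage`, the
#'   fraction of model genes carrying a value.
#' @export
map_expression_to_reactions <- function(model, pooled) {
  vals <- stats::setNames(pooled$intensity, pooled$gene_id)
  scores <- vapply(model$reactions$gpr, function(g) {
    score_gpr(parse_gpr(g), vals)
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble::tibble(reaction_id = model$reactions$id, score = scores)
  attr(out, "coverage") <- mean(model$genes$id %in% pooled$gene_id)
  out
}

#' GIMME configuration
#'
#' @param threshold Expression threshold below which reactions are
#'   penalized. Interpreted per `threshold_type`.
#' @param threshold_type `"quantile"` (default; `threshold` is a
#'   quantile of the scored reactions, default 0.25) or `"absolute"`.
#' @param growth_fraction Required fraction of the parent biomass
#'   optimum, in (0, 1] (default 0.9).
#' @param core_reactions Reaction ids forced into the context model
#'   regardless of expression (treated as maximally expressed).
#' @param prune_tolerance Flux magnitude below which a reaction counts
#'   as inactive (default 1e-6).
#' @return A list of class `gimme_config`.
#' @export
gimme_config <- function(threshold = 0.25,
                         threshold_type = c("quantile", "absolute"),
                         growth_fraction = 0.9,
                         core_reactions = character(),
                         prune_tolerance = 1e-6) {
  threshold_type <- match.arg(threshold_type)
  stopifnot(growth_fraction > 0, growth_fraction <= 1, prune_tolerance > 0)
  if (threshold_type == "quantile") stopifnot(threshold >= 0, threshold <= 1)
  structure(list(threshold = threshold, threshold_type = threshold_type,
                 growth_fraction = growth_fraction,
                 core_reactions = core_reactions,
                 prune_tolerance = prune_tolerance),
            class = "gimme_config")
}

#' GIMME context-specific model extraction
#'
#' Solves the GIMME linear program: split each flux into non-negative
#' forward/backward parts and minimize the expression-weighted total
#' flux through below-threshold reactions,
#' `sum_i max(0, threshold - score_i) (v_i^+ + v_i^-)`, subject to
#' `S v = 0`, the flux bounds, and biomass at or above
#' `growth_fraction` times the parent optimum. A reaction is kept when
#' its score is at or above the threshold, unknown (`NA`), listed as
#' core, or carries flux above `prune_tolerance` in the GIMME solution;
#' everything else is removed. Core reactions are treated as maximally
#' expressed (never penalized, always kept); a core reaction left
#' unable to carry flux is reconnected through the shortest
#' stoichiometric path among removed reactions.
#'
#' @param model A feasible `metabolic_model`.
#' @param rxn_expr Tibble `reaction_id`, `score` from
#'   [map_expression_to_reactions()].
#' @param config A [gimme_config()].
#' @return An object of class `extraction_result`: list with
#'   `context_model`, `inconsistency_score` (the GIMME objective),
#'   `removed_reactions`, `kept_reactions`, `forced_core_added`,
#'   `threshold` (resolved absolute value), `parent_optimum`.
#' @export
gimme_extract <- function(model, rxn_expr, config = gimme_config()) {
  scores <- stats::setNames(rxn_expr$score, rxn_expr$reaction_id)
  bad <- setdiff(rxn_expr$reaction_id, model$reactions$id)
  if (length(bad)) {
    stop("scored reaction(s) not in model: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  s <- unname(scores[model$reactions$id])
  thr <- if (config$threshold_type == "quantile") {
    stats::quantile(s, config$threshold, na.rm = TRUE, names = FALSE)
  } else config$threshold
  if (!is.finite(thr)) stop("expression threshold unresolvable", call. = FALSE)

  parent <- fba(model)
  if (parent$status != "optimal") {
    stop("parent model infeasible; cannot extract", call. = FALSE)
  }
  req <- config$growth_fraction * parent$objective_value

  core <- config$core_reactions
  ids <- model$reactions$id
  w <- pmax(0, thr - s)
  w[is.na(s)] <- 0
  w[ids %in% core] <- 0
  w[ids == model$objective_id] <- 0

  sol <- gimme_lp(model, w, req)
  if (is.null(sol)) {
    stop("GIMME LP infeasible at growth_fraction = ", config$growth_fraction,
         "; consider a lower fraction", call. = FALSE)
  }
  v <- sol$v
  keep <- (!is.na(s) & s >= thr) | is.na(s) | ids %in% core |
    abs(v) > config$prune_tolerance | ids == model$objective_id
  removed <- ids[!keep]
  ctx <- remove_reactions(model, removed)

  added <- reconnect_core(ctx, model, removed, core, config$prune_tolerance)
  ctx <- added$model

  res <- list(context_model = ctx,
              inconsistency_score = sol$objective,
              removed_reactions = setdiff(removed, added$added),
              kept_reactions = ctx$reactions$id,
              forced_core_added = added$added,
              threshold = thr,
              growth_fraction = config$growth_fraction,
              parent_optimum = parent$objective_value)
  class(res) <- "extraction_result"
  res
}

# GIMME LP on split fluxes; returns v and the objective, or NULL if
# infeasible at the required growth.
gimme_lp <- function(model, w, req) {
  S <- stoich_matrix(model)
  m <- nrow(S); n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  # v = vp - vm with vp in [max(lb,0), max(ub,0)], vm in [max(-ub,0), max(-lb,0)]
  lp <- pmax(lb, 0); up <- pmax(ub, 0)
  lm_ <- pmax(-ub, 0); um <- pmax(-lb, 0)
  i_obj <- match(model$objective_id, colnames(S))
  lp[i_obj] <- max(lp[i_obj], req)
  if (lp[i_obj] > up[i_obj] + 1e-12) return(NULL)
  A <- cbind(S, -S)
  obj <- c(w, w)
  res <- solve_lp(obj, Aeq = A, beq = rep(0, m),
                  lb = c(lp, lm_), ub = c(up, um), direction = "min")
  if (res$status != "optimal") return(NULL)
  list(v = res$x[1:n] - res$x[n + 1:n], objective = res$objective)
}

# re-add removed reactions needed to let blocked core reactions carry
# flux: breadth-first search over the metabolite-reaction bipartite
# graph restricted to removed reactions, seeded at the metabolites of
# the kept network.
reconnect_core <- function(ctx, parent, removed, core, tol) {
  core_in <- intersect(core, ctx$reactions$id)
  if (!length(core_in) || !length(removed)) {
    return(list(model = ctx, added = character()))
  }
  fv <- fva(ctx, fraction = 0, reactions = core_in)
  blocked <- fv$reaction_id[pmax(abs(fv$min_flux), abs(fv$max_flux)) < tol]
  if (!length(blocked)) return(list(model = ctx, added = character()))

  st <- parent$stoichiometry[parent$stoichiometry$reaction_id %in% removed, ]
  if (!nrow(st)) return(list(model = ctx, added = character()))
  verts <- unique(c(paste0("m:", st$metabolite_id), paste0("r:", st$reaction_id)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("m:", st$metabolite_id),
               to = paste0("r:", st$reaction_id)),
    directed = FALSE, vertices = verts)
  added <- character()
  for (rid in blocked) {
    # seed at metabolites reachable by the kept network, excluding the
    # blocked core reactions themselves (their dead-end metabolites are
    # exactly what needs connecting)
    kept_st <- ctx$stoichiometry[!ctx$stoichiometry$reaction_id %in% blocked, ]
    seed_mets <- intersect(unique(kept_st$metabolite_id), st$metabolite_id)
    targets <- parent$stoichiometry$metabolite_id[
      parent$stoichiometry$reaction_id == rid]
    targets <- setdiff(intersect(targets, st$metabolite_id), seed_mets)
    best <- NULL
    for (tg in targets) {
      for (sd in paste0("m:", setdiff(seed_mets, tg))) {
        p <- suppressWarnings(igraph::shortest_paths(
          g, from = sd, to = paste0("m:", tg), output = "vpath"))$vpath[[1]]
        if (length(p) > 1 && (is.null(best) || length(p) < length(best))) {
          best <- p
        }
      }
    }
    if (!is.null(best)) {
      rr <- sub("^r:", "", grep("^r:", names(best), value = TRUE))
      added <- union(added, rr)
    }
  }
  if (length(added)) {
    keep_ids <- union(ctx$reactions$id, added)
    ctx <- remove_reactions(parent, setdiff(parent$reactions$id, keep_ids))
  }
  list(model = ctx, added = added)
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result>\n")
  cat("  kept: ", length(x$kept_reactions),
      "  removed: ", length(x$removed_reactions),
      "  core re-added: ", length(x$forced_core_added), "\n", sep = "")
  cat("  threshold: ", format(x$threshold),
      "  inconsistency: ", format(x$inconsistency_score), "\n", sep = "")
  invisible(x)
}

#' Tidy per-reaction extraction decisions
#' @param x An `extraction_result`.
#' @param ... Unused.
#' @return Tibble `reaction_id`, `status`
#'   (`"kept"`/`"removed"`/`"core_readded"`).
#' @method tidy extraction_result
#' @export
tidy.extraction_result <- function(x, ...) {
  tibble::tibble(
    reaction_id = c(x$kept_reactions, x$removed_reactions),
    status = c(ifelse(x$kept_reactions %in% x$forced_core_added,
                      "core_readded", "kept"),
               rep("removed", length(x$removed_reactions))))
}

#' One-row summary of an extraction
#' @param x An `extraction_result`.
#' @param ... Unused.
#' @return Tibble with counts, threshold, growth guarantee and the
#'   GIMME inconsistency score.
#' @method glance extraction_result
#' @export
glance.extraction_result <- function(x, ...) {
  tibble::tibble(n_kept = length(x$kept_reactions),
                 n_removed = length(x$removed_reactions),
                 n_core_readded = length(x$forced_core_added),
                 threshold = x$threshold,
                 growth_fraction = x$growth_fraction,
                 parent_optimum = x$parent_optimum,
                 inconsistency_score = x$inconsistency_score)
}

#' Prune flux-inconsistent reactions
#'
#' Iteratively removes reactions that cannot carry flux of magnitude
#' `tol` in any feasible steady state (FVA at objective fraction 0),
#' then drops orphaned metabolites and genes. The result is a fully
#' functional model in which every surviving reaction can be active.
#'
#' @param model A feasible `metabolic_model`.
#' @param tol Blocked-reaction flux tolerance (default 1e-6).
#' @return The pruned `metabolic_model`.
#' @export
prune_model <- function(model, tol = 1e-6) {
  if (fba(model)$status != "optimal") {
    stop("model infeasible; nothing to prune", call. = FALSE)
  }
  repeat {
    fv <- fva(model, fraction = 0)
    blocked <- fv$reaction_id[pmax(abs(fv$min_flux), abs(fv$max_flux)) < tol]
    if (!length(blocked)) break
    if (model$objective_id %in% blocked) {
      stop("pruning would remove the objective reaction; model degenerate",
           call. = FALSE)
    }
    model <- remove_reactions(model, blocked)
  }
  model
}

#' Extract and prune a lineage context model in one call
#'
#' Convenience pipeline: [map_expression_to_reactions()] on pooled
#' expression, [gimme_extract()], then [prune_model()].
#'
#' @param model A `metabolic_model`.
#' @param pooled Tibble `gene_id`, `intensity` (see
#'   [normalize_and_pool()]).
#' @param config A [gimme_config()].
#' @return An `extraction_result` whose `context_model` is pruned; the
#'   ids dropped by pruning are recorded in `pruned_reactions`.
#' @export
extract_context_model <- function(model, pooled, config = gimme_config()) {
  rxn_expr <- map_expression_to_reactions(model, pooled)
  res <- gimme_extract(model, rxn_expr, config)
  before <- res$context_model$reactions$id
  res$context_model <- prune_model(res$context_model, config$prune_tolerance)
  res$pruned_reactions <- setdiff(before, res$context_model$reactions$id)
  res$kept_reactions <- res$context_model$reactions$id
  res
}
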