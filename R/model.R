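# Tibble-backed container for constraint-based metabolic models.
#
# A `metabolic_model` is a list of four tibbles plus metadata:
#   metabolites   id, name, formula, charge, compartment
#   reactions     id, name, lower_bound, upper_bound, subsystem, gpr, is_exchange
#   stoichiometry reaction_id, metabolite_id, coefficient  (long form)
#   genes         id
# Flux bounds are in mmol/gDW/h. Sign convention for boundary reactions:
# negative flux = uptake, positive flux = secretion.

DEFAULT_BOUND <- 1000

#' Construct a metabolic model
#'
#' Assembles and validates a constraint-based metabolic model from tidy
#' tables. Gene lists may be omitted, in which case they are inferred
#' from the GPR rules; `is_exchange` may be omitted, in which case a
#' reaction is flagged as an exchange when it touches exactly one
#' metabolite and that metabolite sits in the extracellular compartment.
#'
#' @param metabolites Data frame with columns `id`, `compartment` and
#'   optionally `name`, `formula` (elemental formula string, may be
#'   empty) and `charge` (integer, may be `NA`).
#' @param reactions Data frame with columns `id` and optionally `name`,
#'   `lower_bound`, `upper_bound` (default `-1000`/`1000`), `subsystem`,
#'   `gpr` (rule string) and `is_exchange`.
#' @param stoichiometry Data frame with columns `reaction_id`,
#'   `metabolite_id`, `coefficient` (nonzero; negative = consumed).
#' @param genes Optional data frame with column `id`.
#' @param objective_id Reaction id of the objective (biomass) reaction.
#' @param name Model name.
#' @param extracellular Compartment tag of the extracellular space
#'   (default `"e"`).
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objective_id, name = "model",
                            extracellular = "e") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- ""
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_integer_
  metabolites$formula[is.na(metabolites$formula)] <- ""
  metabolites <- metabolites[, c("id", "name", "formula", "charge", "compartment")]

  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- -DEFAULT_BOUND
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- DEFAULT_BOUND
  reactions$lower_bound[is.na(reactions$lower_bound)] <- -DEFAULT_BOUND
  reactions$upper_bound[is.na(reactions$upper_bound)] <- DEFAULT_BOUND
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""

  stoichiometry <- stoichiometry[, c("reaction_id", "metabolite_id", "coefficient")]

  if (!"is_exchange" %in% names(reactions)) {
    deg <- table(stoichiometry$reaction_id)
    single <- names(deg)[deg == 1]
    ext <- metabolites$id[metabolites$compartment == extracellular]
    single_met <- stats::setNames(stoichiometry$metabolite_id,
                                  stoichiometry$reaction_id)[single]
    is_ex <- reactions$id %in% single[single_met %in% ext]
    reactions$is_exchange <- is_ex
  }
  reactions <- reactions[, c("id", "name", "lower_bound", "upper_bound",
                             "subsystem", "gpr", "is_exchange")]

  if (is.null(genes)) {
    gids <- unique(unlist(lapply(reactions$gpr, function(g) gpr_genes(parse_gpr(g)))))
    genes <- tibble::tibble(id = sort(gids %||% character()))
  } else {
    genes <- tibble::as_tibble(genes)[, "id", drop = FALSE]
  }

  model <- structure(
    list(name = name, objective_id = objective_id,
         metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = genes,
         extracellular = extracellular),
    class = "metabolic_model")
  validate_metabolic_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, resolvable stoichiometry references, bound
#' ordering, non-empty stoichiometries, the existence of the objective,
#' exchange-reaction shape (one extracellular metabolite) and that every
#' GPR leaf names a listed gene. Errors on the first violation.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_metabolic_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met <- model$metabolites; rxn <- model$reactions; st <- model$stoichiometry
  if (anyDuplicated(met$id)) {
    stop("integrity error: duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rxn$id)) {
    stop("integrity error: duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(met$compartment) | is.na(met$compartment))) {
    stop("integrity error: metabolite with empty compartment", call. = FALSE)
  }
  bad <- setdiff(st$metabolite_id, met$id)
  if (length(bad)) {
    stop("integrity error: stoichiometry references unknown metabolite(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(st$reaction_id, rxn$id)
  if (length(bad)) {
    stop("integrity error: stoichiometry references unknown reaction(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(st$coefficient == 0)) {
    stop("integrity error: zero stoichiometric coefficient", call. = FALSE)
  }
  empty <- setdiff(rxn$id, st$reaction_id)
  if (length(empty)) {
    stop("integrity error: reaction(s) with empty stoichiometry: ",
         paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    stop("integrity error: lower_bound > upper_bound for: ",
         paste(rxn$id[rxn$lower_bound > rxn$upper_bound], collapse = ", "),
         call. = FALSE)
  }
  if (!model$objective_id %in% rxn$id) {
    stop("integrity error: objective reaction '", model$objective_id,
         "' not in model", call. = FALSE)
  }
  ext <- met$id[met$compartment == model$extracellular]
  for (rid in rxn$id[rxn$is_exchange]) {
    mets <- st$metabolite_id[st$reaction_id == rid]
    if (length(mets) != 1 || !mets %in% ext) {
      stop("integrity error: exchange reaction '", rid,
           "' must touch exactly one extracellular metabolite", call. = FALSE)
    }
  }
  gpr_ids <- unique(unlist(lapply(rxn$gpr, function(g) gpr_genes(parse_gpr(g)))))
  bad <- setdiff(gpr_ids, model$genes$id)
  if (length(bad)) {
    stop("integrity error: GPR references unlisted gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$name, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", nrow(x$genes), "\n", sep = "")
  cat("  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Assemble the stoichiometric matrix
#'
#' @param model A `metabolic_model`.
#' @return A dense numeric matrix with one row per metabolite (rownames =
#'   metabolite ids) and one column per reaction (colnames = reaction
#'   ids); entry `S[i, j]` is the stored coefficient.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  idx <- cbind(match(model$stoichiometry$metabolite_id, model$metabolites$id),
               match(model$stoichiometry$reaction_id, model$reactions$id))
  S[idx] <- model$stoichiometry$coefficient
  S
}

#' Set flux bounds on reactions
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Character vector of reaction ids.
#' @param lower,upper Replacement bounds, recycled along `reaction_id`;
#'   `NULL` leaves the respective bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (anyNA(i)) {
    stop("unknown reaction id(s): ",
         paste(reaction_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  if (!is.null(lower)) model$reactions$lower_bound[i] <- rep_len(lower, length(i))
  if (!is.null(upper)) model$reactions$upper_bound[i] <- rep_len(upper, length(i))
  model
}

#' Add a reaction to a model
#'
#' @param model A `metabolic_model`.
#' @param id New reaction id (must not exist).
#' @param stoichiometry Named numeric vector: metabolite id -> coefficient.
#'   All metabolites must already be in the model.
#' @param lower_bound,upper_bound Flux bounds.
#' @param name,subsystem,gpr Optional annotation.
#' @return The modified model.
#' @export
add_reaction <- function(model, id, stoichiometry,
                         lower_bound = 0, upper_bound = DEFAULT_BOUND,
                         name = id, subsystem = "", gpr = "") {
  if (id %in% model$reactions$id) {
    stop("reaction '", id, "' already in model", call. = FALSE)
  }
  mets <- names(stoichiometry)
  ext <- model$metabolites$id[model$metabolites$compartment == model$extracellular]
  is_ex <- length(mets) == 1 && mets %in% ext
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = id, name = name, lower_bound = lower_bound,
                   upper_bound = upper_bound, subsystem = subsystem,
                   gpr = gpr, is_exchange = is_ex))
  model$stoichiometry <- dplyr::bind_rows(
    model$stoichiometry,
    tibble::tibble(reaction_id = id, metabolite_id = mets,
                   coefficient = as.numeric(stoichiometry)))
  new_genes <- setdiff(gpr_genes(parse_gpr(gpr)), model$genes$id)
  if (length(new_genes)) {
    model$genes <- dplyr::bind_rows(model$genes, tibble::tibble(id = new_genes))
  }
  validate_metabolic_model(model)
  model
}

#' Remove reactions from a model
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to drop.
#' @param drop_orphans Also drop metabolites and genes no longer
#'   referenced by any remaining reaction (default `TRUE`).
#' @return The modified model.
#' @export
remove_reactions <- function(model, ids, drop_orphans = TRUE) {
  if (model$objective_id %in% ids) {
    stop("cannot remove the objective reaction '", model$objective_id, "'",
         call. = FALSE)
  }
  model$reactions <- model$reactions[!model$reactions$id %in% ids, ]
  model$stoichiometry <-
    model$stoichiometry[!model$stoichiometry$reaction_id %in% ids, ]
  if (drop_orphans) {
    used <- unique(model$stoichiometry$metabolite_id)
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, ]
    gused <- unique(unlist(lapply(model$reactions$gpr,
                                  function(g) gpr_genes(parse_gpr(g)))))
    model$genes <- model$genes[model$genes$id %in% gused, ]
  }
  model
}

#' Exchange reactions of a model
#'
#' @param model A `metabolic_model`.
#' @return Tibble of the exchange rows of `model$reactions` with an
#'   extra `metabolite_id` column (the single extracellular metabolite).
#' @export
exchange_reactions <- function(model) {
  ex <- model$reactions[model$reactions$is_exchange, ]
  st <- model$stoichiometry
  ex$metabolite_id <- st$metabolite_id[match(ex$id, st$reaction_id)]
  ex
}

#' Look up the exchange reaction of a metabolite
#' @param model A `metabolic_model`.
#' @param metabolite_id Extracellular metabolite id.
#' @return The exchange reaction id, or `NA` if none exists.
#' @keywords internal
exchange_for_metabolite <- function(model, metabolite_id) {
  ex <- exchange_reactions(model)
  ex$id[match(metabolite_id, ex$metabolite_id)]
}
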