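# Elemental and charge balance checking.

#' Parse an elemental formula
#'
#' @param formula A Hill-style formula string such as `"C6H12O6"`; an
#'   empty string or `NA` means the composition is unknown.
#' @return Named numeric vector of element counts, or `NULL` when the
#'   formula is unknown.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- as.numeric(sub("^[A-Z][a-z]?", "", parts))
  n[is.na(n)] <- 1
  tapply(n, el, sum)
}

#' Check elemental and charge balance of every reaction
#'
#' Classifies each non-exchange reaction as `balanced`, `unbalanced` or
#' `unevaluated` (some participant has an unknown formula). Charge is
#' treated alongside the elements when every participant carries a known
#' charge. Exchange reactions are boundary pseudo-reactions and are
#' exempt.
#'
#' @param model A `metabolic_model`.
#' @param tol Absolute tolerance on a net elemental coefficient
#'   (default `1e-6`).
#' @return A tibble (class `balance_report`) with one row per
#'   non-exchange reaction: `reaction_id`, `status`, and `imbalance`, a
#'   list-column of named per-element net coefficients (plus `"charge"`)
#'   for unbalanced reactions.
#' @export
check_balance <- function(model, tol = 1e-6) {
  comp <- lapply(model$metabolites$formula, parse_formula)
  names(comp) <- model$metabolites$id
  charge <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  rxns <- model$reactions$id[!model$reactions$is_exchange]
  st <- split(model$stoichiometry, model$stoichiometry$reaction_id)

  rows <- lapply(rxns, function(rid) {
    s <- st[[rid]]
    forms <- comp[s$metabolite_id]
    if (any(vapply(forms, is.null, logical(1)))) {
      return(tibble::tibble(reaction_id = rid, status = "unevaluated",
                            imbalance = list(NULL)))
    }
    net <- numeric()
    for (k in seq_len(nrow(s))) {
      f <- forms[[k]] * s$coefficient[k]
      for (el in names(f)) net[el] <- (net[el] %||na% 0) + f[[el]]
    }
    ch <- charge[s$metabolite_id]
    if (!anyNA(ch)) net["charge"] <- sum(ch * s$coefficient)
    net <- net[abs(net) > tol]
    tibble::tibble(reaction_id = rid,
                   status = if (length(net)) "unbalanced" else "balanced",
                   imbalance = list(if (length(net)) net else NULL))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("balance_report", class(out))
  out
}

`%||na%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Ids of unbalanced reactions in a balance report
#' @param report A `balance_report` from [check_balance()].
#' @return Character vector of unbalanced reaction ids.
#' @export
unbalanced_reactions <- function(report) {
  report$reaction_id[report$status == "unbalanced"]
}
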