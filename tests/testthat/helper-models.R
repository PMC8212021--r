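# Toy model builders and independent oracles shared across tests.

suppressMessages({
  library(tibble)
  library(dplyr)
})
# helper functions are evaluated with the package namespace as parent,
# which does not see attached packages; bind the constructors locally
tibble <- tibble::tibble
bind_rows <- dplyr::bind_rows

# linear chain: EX_a (uptake <= 1) -> a_c -> b_c -> EX_b
chain_model <- function(uptake = 1) {
  mets <- tibble(id = c("a_c", "b_c", "a_e", "b_e"),
                 compartment = c("c", "c", "e", "e"),
                 formula = "", charge = NA_integer_)
  rxns <- tibble(id = c("EX_a", "At", "T", "Bt", "EX_b"),
                 lower_bound = c(-uptake, 0, 0, 0, 0),
                 upper_bound = c(0, 1000, 1000, 1000, 1000))
  st <- bind_rows(
    tibble(reaction_id = "EX_a", metabolite_id = "a_e", coefficient = -1),
    tibble(reaction_id = "At", metabolite_id = c("a_e", "a_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "T", metabolite_id = c("a_c", "b_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "Bt", metabolite_id = c("b_c", "b_e"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "EX_b", metabolite_id = "b_e", coefficient = -1))
  metabolic_model(mets, rxns, st, objective_id = "EX_b", name = "chain")
}

# two identical parallel branches sharing a fixed demand of 1
parallel_model <- function(demand = 1) {
  mets <- tibble(id = c("a_c", "b_c", "a_e"),
                 compartment = c("c", "c", "e"),
                 formula = "", charge = NA_integer_)
  rxns <- tibble(id = c("EX_a", "At", "P1", "P2", "DM_b"),
                 lower_bound = c(-1000, 0, 0, 0, demand),
                 upper_bound = c(0, 1000, 1000, 1000, demand))
  st <- bind_rows(
    tibble(reaction_id = "EX_a", metabolite_id = "a_e", coefficient = -1),
    tibble(reaction_id = "At", metabolite_id = c("a_e", "a_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "P1", metabolite_id = c("a_c", "b_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "P2", metabolite_id = c("a_c", "b_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "DM_b", metabolite_id = "b_c", coefficient = -1))
  metabolic_model(mets, rxns, st, objective_id = "DM_b", name = "parallel")
}

# fixed inflow of 1 split over k free branches: flux vector uniform on
# the (k-1)-simplex
simplex_model <- function(k = 2) {
  mets <- tibble(id = "a_c", compartment = "c", formula = "",
                 charge = NA_integer_)
  ids <- c("IN", paste0("V", seq_len(k)))
  rxns <- tibble(id = ids,
                 lower_bound = c(1, rep(0, k)),
                 upper_bound = c(1, rep(1000, k)))
  st <- tibble(reaction_id = ids, metabolite_id = "a_c",
               coefficient = c(1, rep(-1, k)))
  metabolic_model(mets, rxns, st, objective_id = "IN", name = paste0("simplex", k))
}

# GIMME toy: substrate convertible to product through a well-expressed
# one-step pathway PA or a poorly expressed two-step pathway PB1+PB2
two_pathway_model <- function() {
  mets <- tibble(id = c("s_c", "x_c", "p_c", "s_e"),
                 compartment = c("c", "c", "c", "e"),
                 formula = "", charge = NA_integer_)
  rxns <- tibble(id = c("EX_s", "St", "PA", "PB1", "PB2", "DM_p"),
                 lower_bound = c(-10, 0, 0, 0, 0, 0),
                 upper_bound = c(0, rep(1000, 5)))
  st <- bind_rows(
    tibble(reaction_id = "EX_s", metabolite_id = "s_e", coefficient = -1),
    tibble(reaction_id = "St", metabolite_id = c("s_e", "s_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "PA", metabolite_id = c("s_c", "p_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "PB1", metabolite_id = c("s_c", "x_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "PB2", metabolite_id = c("x_c", "p_c"),
           coefficient = c(-1, 1)),
    tibble(reaction_id = "DM_p", metabolite_id = "p_c", coefficient = -1))
  metabolic_model(mets, rxns, st, objective_id = "DM_p", name = "two_pathway")
}

# random branched substrate-to-biomass network, always feasible
random_toy_model <- function(seed) {
  withr::with_seed(seed, {
    n_path <- sample(2:4, 1)
    lens <- sample(1:3, n_path, replace = TRUE)
    mets <- tibble(id = c("s_e", "s_c", "bm_c"),
                   compartment = c("e", "c", "c"),
                   formula = "", charge = NA_integer_)
    rxns <- tibble(id = c("EX_s", "St"),
                   lower_bound = c(-10, 0), upper_bound = c(0, 1000))
    st <- bind_rows(
      tibble(reaction_id = "EX_s", metabolite_id = "s_e", coefficient = -1),
      tibble(reaction_id = "St", metabolite_id = c("s_e", "s_c"),
             coefficient = c(-1, 1)))
    for (p in seq_len(n_path)) {
      nodes <- c("s_c", if (lens[p] > 1)
        paste0("m", p, "_", seq_len(lens[p] - 1), "_c"), "bm_c")
      for (nd in setdiff(nodes, mets$id)) {
        mets <- bind_rows(mets, tibble(id = nd, compartment = "c",
                                       formula = "", charge = NA_integer_))
      }
      for (i in seq_len(length(nodes) - 1)) {
        rid <- paste0("P", p, "_", i)
        rxns <- bind_rows(rxns, tibble(id = rid, lower_bound = 0,
                                       upper_bound = runif(1, 5, 1000)))
        st <- bind_rows(st, tibble(reaction_id = rid,
                                   metabolite_id = c(nodes[i], nodes[i + 1]),
                                   coefficient = c(-1, 1)))
      }
    }
    rxns <- bind_rows(rxns, tibble(id = "DM_bm", lower_bound = 0,
                                   upper_bound = 1000))
    st <- bind_rows(st, tibble(reaction_id = "DM_bm", metabolite_id = "bm_c",
                               coefficient = -1))
    metabolic_model(mets, rxns, st, objective_id = "DM_bm",
                    name = paste0("random", seed))
  })
}

# independent GPR oracle: rewrite the rule as an R boolean expression
# and evaluate it with base R
eval_gpr_base_r <- function(rule, present) {
  if (is.null(rule) || !nzchar(trimws(rule))) return(TRUE)
  ex <- gsub("\\band\\b", "&", rule, ignore.case = TRUE)
  ex <- gsub("\\bor\\b", "|", ex, ignore.case = TRUE)
  env <- list2env(as.list(present))
  isTRUE(eval(parse(text = ex), envir = env))
}

# exact hypergeometric upper tail by the combinatorial sum
hyper_tail_sum <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# exact hypergeometric upper tail by full enumeration of draws
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# wrap a flux matrix as a flux_sample object
make_sample <- function(reactions, samples, name = "synthetic") {
  structure(list(reactions = reactions, samples = samples,
                 model_name = name,
                 config = sampling_config(n_samples = nrow(samples))),
            class = "flux_sample")
}

# chain with k extra parallel closed branches (planted relaxation
# conflicts): branch i is Zi: a_c -> zi_c plus DMzi: zi_c ->, both closed
planted_conflict_model <- function(k = 1) {
  m <- chain_model(uptake = 10)
  for (i in seq_len(k)) {
    zid <- paste0("z", i, "_c")
    m$metabolites <- bind_rows(
      m$metabolites, tibble(id = zid, name = zid, formula = "",
                            charge = NA_integer_, compartment = "c"))
    m$stoichiometry <- bind_rows(
      m$stoichiometry,
      tibble(reaction_id = paste0("Z", i),
             metabolite_id = c("a_c", zid), coefficient = c(-1, 1)),
      tibble(reaction_id = paste0("DMz", i), metabolite_id = zid,
             coefficient = -1))
    m$reactions <- bind_rows(
      m$reactions,
      tibble(id = paste0("Z", i), name = paste0("Z", i), lower_bound = 0,
             upper_bound = 0, subsystem = "", gpr = "", is_exchange = FALSE),
      tibble(id = paste0("DMz", i), name = paste0("DMz", i), lower_bound = 0,
             upper_bound = 1000, subsystem = "", gpr = "", is_exchange = FALSE))
  }
  validate_metabolic_model(m)
  m
}

# cache the fixture: building it is cheap but used everywhere
core_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_core_network()
    cache
  }
})
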