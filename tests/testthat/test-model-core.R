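test_that("model constructor enforces structural invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_true(all(c("EX_a", "EX_b") %in%
                    m$reactions$id[m$reactions$is_exchange]))
  expect_false(m$reactions$is_exchange[m$reactions$id == "T"])

  # stoichiometry referencing a missing metabolite is an integrity error
  bad_st <- dplyr::bind_rows(m$stoichiometry,
                             tibble::tibble(reaction_id = "T",
                                            metabolite_id = "ghost_c",
                                            coefficient = 1))
  expect_error(
    metabolic_model(m$metabolites, m$reactions, bad_st, objective_id = "EX_b"),
    "integrity error.*ghost_c")

  # duplicate reaction ids
  expect_error(
    metabolic_model(m$metabolites,
                    dplyr::bind_rows(m$reactions, m$reactions[1, ]),
                    dplyr::bind_rows(m$stoichiometry, m$stoichiometry[1, ]),
                    objective_id = "EX_b"),
    "duplicate reaction")

  # objective must exist; bounds must be ordered
  expect_error(
    metabolic_model(m$metabolites, m$reactions, m$stoichiometry,
                    objective_id = "nope"),
    "objective")
  r2 <- m$reactions
  r2$lower_bound[3] <- 5; r2$upper_bound[3] <- -5
  expect_error(metabolic_model(m$metabolites, r2, m$stoichiometry,
                               objective_id = "EX_b"),
               "lower_bound")
})

test_that("stoichiometric matrix assembly is exact and repeatable", {
  m <- core_fixture()
  S1 <- stoich_matrix(m)
  S2 <- stoich_matrix(m)
  expect_identical(S1, S2)
  expect_equal(dim(S1), c(nrow(m$metabolites), nrow(m$reactions)))
  for (k in sample(nrow(m$stoichiometry), 25)) {
    row <- m$stoichiometry[k, ]
    expect_identical(S1[row$metabolite_id, row$reaction_id], row$coefficient)
  }
})

test_that("JSON and SBML round trips preserve the model", {
  m <- core_fixture()
  eq_models <- function(a, b) {
    ra <- a$reactions[order(a$reactions$id), ]
    rb <- b$reactions[order(b$reactions$id), ]
    expect_identical(ra$id, rb$id)
    expect_equal(ra$lower_bound, rb$lower_bound)
    expect_equal(ra$upper_bound, rb$upper_bound)
    expect_identical(ra$subsystem, rb$subsystem)
    # GPR semantics: compare canonical deparse of the parsed trees
    expect_identical(
      vapply(ra$gpr, function(g) gpr_to_string(parse_gpr(g)), character(1)),
      vapply(rb$gpr, function(g) gpr_to_string(parse_gpr(g)), character(1)))
    expect_setequal(a$metabolites$id, b$metabolites$id)
    expect_identical(a$objective_id, b$objective_id)
    Sa <- stoich_matrix(a)
    Sb <- stoich_matrix(b)[rownames(Sa), colnames(Sa)]
    expect_equal(max(abs(Sa - Sb)), 0)
  }
  jf <- withr::local_tempfile(fileext = ".json")
  sf <- withr::local_tempfile(fileext = ".xml")
  write_gem(m, jf)
  write_gem(m, sf)
  eq_models(m, read_gem(jf))
  eq_models(m, read_gem(sf))

  # json -> sbml -> json preserves bounds numerically
  mj <- read_gem(jf)
  sf2 <- withr::local_tempfile(fileext = ".xml")
  write_gem(mj, sf2)
  ms <- read_gem(sf2)
  jf2 <- withr::local_tempfile(fileext = ".json")
  write_gem(ms, jf2)
  m2 <- read_gem(jf2)
  o <- order(m2$reactions$id)
  o0 <- order(m$reactions$id)
  expect_equal(m2$reactions$lower_bound[o], m$reactions$lower_bound[o0])
  expect_equal(m2$reactions$upper_bound[o], m$reactions$upper_bound[o0])

  # empty GPR survives the round trip as empty
  expect_identical(
    read_gem(sf)$reactions$gpr[read_gem(sf)$reactions$id == "EX_glc"], "")
})

test_that("reading a file with an unresolved metabolite fails loudly", {
  m <- chain_model()
  jf <- withr::local_tempfile(fileext = ".json")
  write_gem(m, jf)
  txt <- readLines(jf)
  txt <- gsub('"id": "a_c"', '"id": "renamed_c"', txt, fixed = TRUE)
  writeLines(txt, jf)
  expect_error(read_gem(jf), "integrity error")
  writeLines("{ not json", jf)
  expect_error(read_gem(jf), "parse error")
})

test_that("balance checking classifies balanced, planted and unknown cases", {
  mets <- tibble::tibble(id = c("A_c", "B_c", "U_c"),
                         compartment = "c",
                         formula = c("C3H4O3", "C3H4O3", ""),
                         charge = c(-1L, -1L, NA))
  rxns <- tibble::tibble(id = c("ISO", "DUP", "UNK"),
                         lower_bound = 0, upper_bound = 10)
  st <- dplyr::bind_rows(
    tibble::tibble(reaction_id = "ISO", metabolite_id = c("A_c", "B_c"),
                   coefficient = c(-1, 1)),
    tibble::tibble(reaction_id = "DUP", metabolite_id = c("A_c", "B_c"),
                   coefficient = c(-1, 2)),
    tibble::tibble(reaction_id = "UNK", metabolite_id = c("A_c", "U_c"),
                   coefficient = c(-1, 1)))
  m <- metabolic_model(mets, rxns, st, objective_id = "ISO")
  rep <- check_balance(m)
  expect_identical(rep$status[rep$reaction_id == "ISO"], "balanced")
  expect_identical(rep$status[rep$reaction_id == "DUP"], "unbalanced")
  expect_identical(rep$status[rep$reaction_id == "UNK"], "unevaluated")
  expect_identical(unbalanced_reactions(rep), "DUP")
})

test_that("fixture is elementally clean; injected imbalances are all recovered", {
  m <- core_fixture()
  rep <- check_balance(m)
  expect_length(unbalanced_reactions(rep), 0)
  # biomass consumes into an unknown-formula pseudo-metabolite
  expect_identical(rep$status[rep$reaction_id == "BIOMASS"], "unevaluated")

  # fuzz: corrupt k random internal balanced coefficients
  internal <- rep$reaction_id[rep$status == "balanced"]
  for (seed in 1:5) {
    withr::with_seed(seed, {
      k <- sample(1:4, 1)
      victims <- sample(internal, k)
      m2 <- m
      for (rid in victims) {
        i <- which(m2$stoichiometry$reaction_id == rid)[1]
        m2$stoichiometry$coefficient[i] <-
          m2$stoichiometry$coefficient[i] * 2
      }
      found <- unbalanced_reactions(check_balance(m2))
      expect_setequal(found, victims)
    })
  }
})

test_that("GPR parsing honors precedence, parentheses and rejects bad input", {
  t1 <- parse_gpr("g1 and g2")
  expect_identical(gpr_to_string(t1), "g1 and g2")
  expect_identical(t1$op, "and")

  # AND binds tighter than OR
  t2 <- parse_gpr("g1 and g2 or g3")
  expect_identical(t2$op, "or")
  expect_identical(gpr_to_string(t2$children[[1]]), "g1 and g2")
  expect_identical(t2$children[[2]]$gene, "g3")

  t3 <- parse_gpr("(g1 or g2) and (g3 or g4)")
  expect_identical(t3$op, "and")
  expect_identical(gpr_to_string(t3), "(g1 or g2) and (g3 or g4)")

  expect_error(parse_gpr("g1 and (g2 or g3"), "parenthes")
  expect_error(parse_gpr("g1 and or g2"), "empty operand")
  expect_error(parse_gpr("g1 &| g2"), "invalid token")
  expect_null(parse_gpr(""))

  # deparse -> reparse is the identity on semantics for fixture rules
  for (g in setdiff(unique(core_fixture()$reactions$gpr), "")) {
    expect_identical(gpr_to_string(parse_gpr(gpr_to_string(parse_gpr(g)))),
                     gpr_to_string(parse_gpr(g)))
  }
})

test_that("GPR boolean evaluation matches an independent base-R oracle", {
  m <- core_fixture()
  rules <- setdiff(unique(m$reactions$gpr), "")
  genes <- m$genes$id
  withr::with_seed(42, {
    for (rep_i in 1:20) {
      present <- stats::setNames(stats::runif(length(genes)) > 0.4, genes)
      for (g in rules) {
        expect_identical(eval_gpr(parse_gpr(g), present),
                         eval_gpr_base_r(g, present),
                         info = g)
      }
    }
  })
})

test_that("expression scoring follows min/max with unknown-dropping", {
  vals <- c(g1 = 100, g2 = 10, g3 = 50)
  expect_equal(score_gpr(parse_gpr("g1 and g2"), vals), 10)
  expect_equal(score_gpr(parse_gpr("g1 or g2"), vals), 100)
  expect_equal(score_gpr(parse_gpr("(g1 and g2) or g3"), vals), 50)
  # unmeasured genes drop from OR; AND unknown only when all unknown
  expect_equal(score_gpr(parse_gpr("g1 or gX"), vals), 100)
  expect_equal(score_gpr(parse_gpr("g1 and gX"), vals), 100)
  expect_true(is.na(score_gpr(parse_gpr("gX and gY"), vals)))
  expect_true(is.na(score_gpr(NULL, vals)))
})
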