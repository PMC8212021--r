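# Synthetic study inputs: a calibrated core central-metabolism network,
# three-lineage transcriptomes with planted subsystem differences, and
# noisy exometabolomic time courses with known true exchange rates.

#' Build the core central-metabolism fixture network
#'
#' A deterministic ~60-reaction human-style core network: glycolysis
#' with substrate-level phosphorylation, the pentose phosphate shunt,
#' pyruvate dehydrogenase, the full TCA cycle, NAD-dependent malic
#' enzyme, glutaminase plus NAD-dependent glutamate dehydrogenase, an
#' electron transport chain with proton translocation calibrated to
#' textbook P/O ratios (10 protons per NADH, 6 per FADH2) and a
#' 4-proton ATP synthase, lactate fermentation with proton symport, a
#' three-cycle octanoate beta-oxidation arm, exchanges for a basal
#' glucose/glutamine medium, an ATP hydrolysis demand and a lumped
#' biomass reaction. Pumped protons live in a dedicated `i`
#' (intermembrane) compartment that touches only the respiratory chain
#' and the synthase, so the proton-motive force cannot be short-circuited
#' through the medium.
#'
#' The calibration gives exact LP optima of 32 mol ATP per mol glucose
#' aerobically (2 + 2 substrate-level, 10 NADH x 2.5, 2 FADH2 x 1.5),
#' 2 anaerobically (lactate fermentation), and 22.5 per mol glutamine
#' aerobically (7 NADH, 2 FADH2, 2 substrate-level).
#'
#' @return A `metabolic_model` named `"core_msc"` whose objective is the
#'   lumped `BIOMASS` reaction. Growth is glutamine-limited by design
#'   (uptake cap 0.3 mmol/gDW/h against a 0.3 per-unit requirement), so
#'   the wild-type biomass optimum is exactly 1, aerobically or not.
#' @export
build_core_network <- function() {
  met <- function(base, comp, formula, charge, name = base) {
    tibble::tibble(id = paste0(base, "_", comp), name = name,
                   formula = formula, charge = as.integer(charge),
                   compartment = comp)
  }
  metabolites <- dplyr::bind_rows(
    met("glc", "c", "C6H12O6", 0, "D-glucose"),
    met("g6p", "c", "C6H11O9P", -2, "glucose 6-phosphate"),
    met("f6p", "c", "C6H11O9P", -2, "fructose 6-phosphate"),
    met("fdp", "c", "C6H10O12P2", -4, "fructose 1,6-bisphosphate"),
    met("dhap", "c", "C3H5O6P", -2, "dihydroxyacetone phosphate"),
    met("g3p", "c", "C3H5O6P", -2, "glyceraldehyde 3-phosphate"),
    met("13dpg", "c", "C3H4O10P2", -4, "1,3-bisphosphoglycerate"),
    met("3pg", "c", "C3H4O7P", -3, "3-phosphoglycerate"),
    met("pep", "c", "C3H2O6P", -3, "phosphoenolpyruvate"),
    met("pyr", "c", "C3H3O3", -1, "pyruvate"),
    met("lac", "c", "C3H5O3", -1, "L-lactate"),
    met("6pgl", "c", "C6H9O9P", -2, "6-phosphogluconolactone"),
    met("6pgc", "c", "C6H10O10P", -3, "6-phosphogluconate"),
    met("ru5p", "c", "C5H9O8P", -2, "ribulose 5-phosphate"),
    met("r5p", "c", "C5H9O8P", -2, "ribose 5-phosphate"),
    met("xu5p", "c", "C5H9O8P", -2, "xylulose 5-phosphate"),
    met("s7p", "c", "C7H13O10P", -2, "sedoheptulose 7-phosphate"),
    met("e4p", "c", "C4H7O7P", -2, "erythrose 4-phosphate"),
    met("accoa", "c", "C23H34N7O17P3S", -4, "acetyl-CoA"),
    met("coa", "c", "C21H32N7O16P3S", -4, "coenzyme A"),
    met("cit", "c", "C6H5O7", -3, "citrate"),
    met("icit", "c", "C6H5O7", -3, "isocitrate"),
    met("akg", "c", "C5H4O5", -2, "2-oxoglutarate"),
    met("succoa", "c", "C25H35N7O19P3S", -5, "succinyl-CoA"),
    met("succ", "c", "C4H4O4", -2, "succinate"),
    met("fum", "c", "C4H2O4", -2, "fumarate"),
    met("mal", "c", "C4H4O5", -2, "L-malate"),
    met("oaa", "c", "C4H2O5", -2, "oxaloacetate"),
    met("glu", "c", "C5H8NO4", -1, "L-glutamate"),
    met("gln", "c", "C5H10N2O3", 0, "L-glutamine"),
    met("nh4", "c", "H4N", 1, "ammonium"),
    met("atp", "c", "C10H12N5O13P3", -4, "ATP"),
    met("adp", "c", "C10H12N5O10P2", -3, "ADP"),
    met("pi", "c", "HPO4", -2, "phosphate"),
    met("nad", "c", "C21H26N7O14P2", -1, "NAD+"),
    met("nadh", "c", "C21H27N7O14P2", -2, "NADH"),
    met("nadp", "c", "C21H25N7O17P3", -3, "NADP+"),
    met("nadph", "c", "C21H26N7O17P3", -4, "NADPH"),
    met("fad", "c", "C27H31N9O15P2", -2, "FAD"),
    met("fadh2", "c", "C27H33N9O15P2", -2, "FADH2"),
    met("h2o", "c", "H2O", 0, "water"),
    met("o2", "c", "O2", 0, "oxygen"),
    met("co2", "c", "CO2", 0, "carbon dioxide"),
    met("h", "c", "H", 1, "proton"),
    met("fa", "c", "C8H15O2", -1, "octanoate"),
    met("facoa", "c", "C29H46N7O17P3S", -4, "octanoyl-CoA"),
    met("c6coa", "c", "C27H42N7O17P3S", -4, "hexanoyl-CoA"),
    met("c4coa", "c", "C25H38N7O17P3S", -4, "butanoyl-CoA"),
    met("biomass", "c", "", NA, "biomass pseudo-metabolite"),
    met("h", "i", "H", 1, "proton (intermembrane)"),
    met("glc", "e", "C6H12O6", 0, "D-glucose (medium)"),
    met("gln", "e", "C5H10N2O3", 0, "L-glutamine (medium)"),
    met("o2", "e", "O2", 0, "oxygen (medium)"),
    met("lac", "e", "C3H5O3", -1, "L-lactate (medium)"),
    met("co2", "e", "CO2", 0, "carbon dioxide (medium)"),
    met("h2o", "e", "H2O", 0, "water (medium)"),
    met("h", "e", "H", 1, "proton (medium)"),
    met("pi", "e", "HPO4", -2, "phosphate (medium)"),
    met("nh4", "e", "H4N", 1, "ammonium (medium)"),
    met("fa", "e", "C8H15O2", -1, "octanoate (medium)")
  )
  # medium amino acids consumed by biomass (lineage-neutral background)
  aa <- tibble::tribble(
    ~base, ~formula, ~charge, ~aaname, ~gene,
    "ala", "C3H7NO2", 0L, "L-alanine", "slc38a1",
    "arg", "C6H15N4O2", 1L, "L-arginine", "slc7a1",
    "asn", "C4H8N2O3", 0L, "L-asparagine", "slc38a5",
    "asp", "C4H6NO4", -1L, "L-aspartate", "slc1a3",
    "gly", "C2H5NO2", 0L, "glycine", "slc6a9",
    "his", "C6H9N3O2", 0L, "L-histidine", "slc15a4",
    "ile", "C6H13NO2", 0L, "L-isoleucine", "slc7a5",
    "leu", "C6H13NO2", 0L, "L-leucine", "slc7a5",
    "lys", "C6H15N2O2", 1L, "L-lysine", "slc7a2",
    "phe", "C9H11NO2", 0L, "L-phenylalanine", "slc7a8",
    "ser", "C3H7NO3", 0L, "L-serine", "slc1a4",
    "thr", "C4H9NO3", 0L, "L-threonine", "slc38a2")
  for (k in seq_len(nrow(aa))) {
    metabolites <- dplyr::bind_rows(
      metabolites,
      met(aa$base[k], "c", aa$formula[k], aa$charge[k], aa$aaname[k]),
      met(aa$base[k], "e", aa$formula[k], aa$charge[k],
          paste0(aa$aaname[k], " (medium)")))
  }

  rx <- list()
  add <- function(id, stoich, lb, ub, subsystem, gpr = "", name = id) {
    rx[[length(rx) + 1]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub,
                                  subsystem = subsystem, gpr = gpr, name = name)
  }
  B <- DEFAULT_BOUND

  # glycolysis
  add("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1, h_c = 1),
      0, B, "Glycolysis", "hk1 or hk2", "hexokinase")
  add("PGI", c(g6p_c = -1, f6p_c = 1), -B, B, "Glycolysis", "gpi",
      "glucose-6-phosphate isomerase")
  add("PFK", c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1, h_c = 1),
      0, B, "Glycolysis", "pfkl or pfkm", "phosphofructokinase")
  add("FBA", c(fdp_c = -1, dhap_c = 1, g3p_c = 1), -B, B, "Glycolysis",
      "aldoa", "fructose-bisphosphate aldolase")
  add("TPI", c(dhap_c = -1, g3p_c = 1), -B, B, "Glycolysis", "tpi1",
      "triose-phosphate isomerase")
  add("GAPD", c(g3p_c = -1, nad_c = -1, pi_c = -1, `13dpg_c` = 1, nadh_c = 1, h_c = 1),
      -B, B, "Glycolysis", "gapdh", "glyceraldehyde-3-phosphate dehydrogenase")
  add("PGK", c(`13dpg_c` = -1, adp_c = -1, `3pg_c` = 1, atp_c = 1),
      -B, B, "Glycolysis", "pgk1", "phosphoglycerate kinase")
  add("ENO", c(`3pg_c` = -1, pep_c = 1, h2o_c = 1), -B, B, "Glycolysis",
      "eno1 or eno2", "phosphoglycerate mutase + enolase (lumped)")
  add("PYK", c(pep_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1),
      0, B, "Glycolysis", "pkm", "pyruvate kinase")

  # pyruvate metabolism
  add("LDH", c(pyr_c = -1, nadh_c = -1, h_c = -1, lac_c = 1, nad_c = 1),
      -B, B, "Pyruvate metabolism", "ldha or ldhb", "lactate dehydrogenase")
  add("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1, accoa_c = 1, co2_c = 1, nadh_c = 1),
      0, B, "Pyruvate metabolism", "pdha1 and dlat and dld",
      "pyruvate dehydrogenase complex")

  # TCA cycle
  add("CS", c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1, coa_c = 1, h_c = 1),
      0, B, "TCA cycle", "cs", "citrate synthase")
  add("ACONT", c(cit_c = -1, icit_c = 1), -B, B, "TCA cycle", "aco2", "aconitase")
  add("ICDHx", c(icit_c = -1, nad_c = -1, akg_c = 1, co2_c = 1, nadh_c = 1),
      0, B, "TCA cycle", "idh3a and idh3g", "isocitrate dehydrogenase (NAD)")
  add("AKGDH", c(akg_c = -1, coa_c = -1, nad_c = -1, succoa_c = 1, co2_c = 1, nadh_c = 1),
      0, B, "TCA cycle", "ogdh and dlst and dld", "2-oxoglutarate dehydrogenase")
  add("SUCOAS", c(succoa_c = -1, adp_c = -1, pi_c = -1, succ_c = 1, coa_c = 1, atp_c = 1),
      0, B, "TCA cycle", "sucla2 and suclg1", "succinyl-CoA synthetase")
  add("SUCDH", c(succ_c = -1, fad_c = -1, fum_c = 1, fadh2_c = 1),
      0, B, "TCA cycle", "sdha and sdhb", "succinate dehydrogenase")
  add("FUM", c(fum_c = -1, h2o_c = -1, mal_c = 1), -B, B, "TCA cycle", "fh", "fumarase")
  add("MDH", c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1, h_c = 1),
      -B, B, "TCA cycle", "mdh2", "malate dehydrogenase")
  add("ME1", c(mal_c = -1, nad_c = -1, pyr_c = 1, co2_c = 1, nadh_c = 1),
      0, B, "TCA cycle", "me2", "malic enzyme (NAD)")

  # glutamine catabolism
  add("GLS", c(gln_c = -1, h2o_c = -1, glu_c = 1, nh4_c = 1),
      0, B, "Glutamine metabolism", "gls", "glutaminase")
  add("GDH", c(glu_c = -1, h2o_c = -1, nad_c = -1, akg_c = 1, nh4_c = 1,
               nadh_c = 1, h_c = 1),
      0, B, "Glutamine metabolism", "glud1", "glutamate dehydrogenase (NAD)")

  # pentose phosphate shunt
  add("G6PDH", c(g6p_c = -1, nadp_c = -1, `6pgl_c` = 1, nadph_c = 1, h_c = 1),
      0, B, "Pentose phosphate pathway", "g6pd", "glucose-6-phosphate dehydrogenase")
  add("PGL", c(`6pgl_c` = -1, h2o_c = -1, `6pgc_c` = 1, h_c = 1),
      0, B, "Pentose phosphate pathway", "pgls", "6-phosphogluconolactonase")
  add("GND", c(`6pgc_c` = -1, nadp_c = -1, ru5p_c = 1, co2_c = 1, nadph_c = 1),
      0, B, "Pentose phosphate pathway", "pgd", "6-phosphogluconate dehydrogenase")
  add("RPI", c(ru5p_c = -1, r5p_c = 1), -B, B, "Pentose phosphate pathway",
      "rpia", "ribose-5-phosphate isomerase")
  add("RPE", c(ru5p_c = -1, xu5p_c = 1), -B, B, "Pentose phosphate pathway",
      "rpe", "ribulose-5-phosphate epimerase")
  add("TKT1", c(xu5p_c = -1, r5p_c = -1, s7p_c = 1, g3p_c = 1),
      -B, B, "Pentose phosphate pathway", "tkt", "transketolase 1")
  add("TALA", c(s7p_c = -1, g3p_c = -1, e4p_c = 1, f6p_c = 1),
      -B, B, "Pentose phosphate pathway", "taldo1", "transaldolase")
  add("TKT2", c(xu5p_c = -1, e4p_c = -1, f6p_c = 1, g3p_c = 1),
      -B, B, "Pentose phosphate pathway", "tkt", "transketolase 2")

  # oxidative phosphorylation: P/O 2.5 (NADH) and 1.5 (FADH2) with a
  # 4 H+/ATP synthase -> 10 and 6 pumped protons respectively
  add("NADH2", c(nadh_c = -1, h_c = -11, o2_c = -0.5, nad_c = 1, h_i = 10, h2o_c = 1),
      0, B, "Oxidative phosphorylation", "ndufs1 and uqcrc1 and cox4i1",
      "NADH:O2 oxidoreductase (lumped chain)")
  add("FADH2OR", c(fadh2_c = -1, h_c = -6, o2_c = -0.5, fad_c = 1, h_i = 6, h2o_c = 1),
      0, B, "Oxidative phosphorylation", "etfa and etfdh",
      "FADH2:O2 oxidoreductase (lumped chain)")
  add("ATPS", c(adp_c = -1, pi_c = -1, h_i = -4, atp_c = 1, h2o_c = 1, h_c = 3),
      0, B, "Oxidative phosphorylation", "atp5f1a and atp5f1b", "ATP synthase")

  # beta-oxidation of octanoate (three cycles)
  add("FACOAL", c(fa_c = -1, coa_c = -1, atp_c = -1, facoa_c = 1, adp_c = 1, pi_c = 1),
      0, B, "Fatty acid oxidation", "acsl1", "fatty-acyl-CoA ligase")
  add("FAOX1", c(facoa_c = -1, coa_c = -1, fad_c = -1, nad_c = -1, h2o_c = -1,
                 c6coa_c = 1, accoa_c = 1, fadh2_c = 1, nadh_c = 1, h_c = 1),
      0, B, "Fatty acid oxidation", "acadm and hadha", "beta-oxidation cycle C8->C6")
  add("FAOX2", c(c6coa_c = -1, coa_c = -1, fad_c = -1, nad_c = -1, h2o_c = -1,
                 c4coa_c = 1, accoa_c = 1, fadh2_c = 1, nadh_c = 1, h_c = 1),
      0, B, "Fatty acid oxidation", "acadm and hadha", "beta-oxidation cycle C6->C4")
  add("FAOX3", c(c4coa_c = -1, coa_c = -1, fad_c = -1, nad_c = -1, h2o_c = -1,
                 accoa_c = 2, fadh2_c = 1, nadh_c = 1, h_c = 1),
      0, B, "Fatty acid oxidation", "acads and hadha", "beta-oxidation cycle C4->2xC2")
  add("FAt", c(fa_e = -1, fa_c = 1), 0, B, "Fatty acid oxidation",
      "slc27a1 or cd36", "fatty acid uptake transport")

  # transports
  add("GLCt", c(glc_e = -1, glc_c = 1), 0, B, "Transport", "slc2a1", "glucose uniport")
  add("GLNt", c(gln_e = -1, gln_c = 1), 0, B, "Transport", "slc1a5", "glutamine transport")
  add("O2t", c(o2_e = -1, o2_c = 1), -B, B, "Transport", "", "oxygen diffusion")
  add("CO2t", c(co2_c = -1, co2_e = 1), -B, B, "Transport", "", "CO2 diffusion")
  add("H2Ot", c(h2o_e = -1, h2o_c = 1), -B, B, "Transport", "aqp1", "water diffusion")
  add("LACt", c(lac_c = -1, h_c = -1, lac_e = 1, h_e = 1), -B, B, "Transport",
      "slc16a1 or slc16a3", "lactate-proton symport")
  add("NH4t", c(nh4_c = -1, nh4_e = 1), -B, B, "Transport", "", "ammonium transport")
  add("PIt", c(pi_e = -1, pi_c = 1), -B, B, "Transport", "slc20a1", "phosphate transport")
  add("Ht", c(h_e = -1, h_c = 1), -B, B, "Transport", "", "proton diffusion (plasma membrane)")

  # exchanges (negative flux = uptake); basal medium: glucose, glutamine,
  # oxygen, phosphate, water, protons, octanoate
  add("EX_glc", c(glc_e = -1), -15, B, "Exchange", "", "glucose exchange")
  add("EX_gln", c(gln_e = -1), -0.3, B, "Exchange", "", "glutamine exchange")
  add("EX_o2", c(o2_e = -1), -B, B, "Exchange", "", "oxygen exchange")
  add("EX_lac", c(lac_e = -1), 0, B, "Exchange", "", "lactate exchange")
  add("EX_co2", c(co2_e = -1), 0, B, "Exchange", "", "CO2 exchange")
  add("EX_h2o", c(h2o_e = -1), -B, B, "Exchange", "", "water exchange")
  add("EX_h", c(h_e = -1), -B, B, "Exchange", "", "proton exchange")
  add("EX_pi", c(pi_e = -1), -10, B, "Exchange", "", "phosphate exchange")
  add("EX_nh4", c(nh4_e = -1), 0, B, "Exchange", "", "ammonium exchange")
  add("EX_fa", c(fa_e = -1), -1, B, "Exchange", "", "octanoate exchange")

  # amino-acid uptake arms: exchange + transport, drained by biomass
  for (k in seq_len(nrow(aa))) {
    b <- aa$base[k]
    add(paste0(toupper(b), "t"),
        stats::setNames(c(-1, 1), paste0(b, c("_e", "_c"))),
        0, B, "Transport", aa$gene[k], paste0(aa$aaname[k], " transport"))
    add(paste0("EX_", b), stats::setNames(-1, paste0(b, "_e")),
        -1, B, "Exchange", "", paste0(aa$aaname[k], " exchange"))
  }

  # demands and biomass
  add("DM_atp", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      0, B, "Energy demand", "", "ATP hydrolysis demand")
  bm <- c(g6p_c = -0.2, r5p_c = -0.1, gln_c = -0.1,
          glu_c = -0.2, nadph_c = -0.4, atp_c = -20, h2o_c = -20,
          adp_c = 20, pi_c = 20, h_c = 20, nadp_c = 0.4,
          biomass_c = 1)
  bm <- c(bm, stats::setNames(rep(-0.05, nrow(aa)), paste0(aa$base, "_c")))
  add("BIOMASS", bm, 0, B, "Biomass", "", "lumped biomass synthesis")
  add("DM_biomass", c(biomass_c = -1), 0, B, "Biomass", "", "biomass drain")

  reactions <- dplyr::bind_rows(lapply(rx, function(r) {
    tibble::tibble(id = r$id, name = r$name, lower_bound = r$lb,
                   upper_bound = r$ub, subsystem = r$subsystem, gpr = r$gpr)
  }))
  stoich <- dplyr::bind_rows(lapply(rx, function(r) {
    tibble::tibble(reaction_id = r$id, metabolite_id = names(r$stoich),
                   coefficient = as.numeric(r$stoich))
  }))
  metabolic_model(metabolites, reactions, stoich,
                  objective_id = "BIOMASS", name = "core_msc")
}

#' Baseline expression intensity per fixture subsystem
#'
#' The mean intensity assigned to genes of each subsystem before lineage
#' multipliers. Expansion-phase MSC metabolism is modeled as glycolytic:
#' the oxidative subsystems (TCA cycle, oxidative phosphorylation) and
#' the fatty-acid arm sit below the default GIMME threshold unless a
#' lineage boosts them.
#'
#' @return Named numeric vector of intensities (arbitrary units, max
#'   dataset intensity is rescaled to ~1000 downstream).
#' @export
baseline_subsystem_intensity <- function() {
  c("Glycolysis" = 400,
    "Pentose phosphate pathway" = 250,
    "Pyruvate metabolism" = 260,
    "Glutamine metabolism" = 220,
    "TCA cycle" = 70,
    "Oxidative phosphorylation" = 70,
    "Fatty acid oxidation" = 30,
    "Transport" = 200)
}

#' Lineage specification for synthetic transcriptomes
#'
#' Per-subsystem expression multipliers encoding the planted metabolic
#' programs: `expansion` is glycolytic (all multipliers 1), `osteogenic`
#' boosts the oxidative subsystems (TCA cycle and oxidative
#' phosphorylation x4), `adipogenic` boosts the fatty-acid arm (x8) and
#' moderately the oxidative machinery needed to run it (x3).
#'
#' @param lineage One of `"expansion"`, `"osteogenic"`, `"adipogenic"`.
#' @param multipliers Optional named numeric vector overriding the
#'   lineage defaults (names are fixture subsystems; values > 0).
#' @param baseline Named numeric vector of per-subsystem baseline
#'   intensities (default [baseline_subsystem_intensity()]).
#' @param seed Integer seed for the generator.
#' @return A list of class `lineage_spec`.
#' @export
lineage_spec <- function(lineage = c("expansion", "osteogenic", "adipogenic"),
                         multipliers = NULL,
                         baseline = baseline_subsystem_intensity(),
                         seed = 1L) {
  lineage <- match.arg(lineage)
  if (is.null(multipliers)) {
    multipliers <- switch(lineage,
      expansion = c("Glycolysis" = 1),
      osteogenic = c("TCA cycle" = 4, "Oxidative phosphorylation" = 4),
      adipogenic = c("Fatty acid oxidation" = 12, "TCA cycle" = 4,
                     "Oxidative phosphorylation" = 4))
  }
  stopifnot(all(multipliers > 0))
  structure(list(lineage = lineage, multipliers = multipliers,
                 baseline = baseline, seed = as.integer(seed)),
            class = "lineage_spec")
}

#' Noise model for the synthetic generators
#'
#' @param conc_rel_sd Relative (multiplicative Gaussian) measurement sd
#'   for concentrations (default 0.05, i.e. 5%).
#' @param expr_sd_log Per-gene lognormal sd for expression intensities
#'   (default 0.15).
#' @param seed Integer seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(conc_rel_sd = 0.05, expr_sd_log = 0.15, seed = 1L) {
  stopifnot(conc_rel_sd >= 0, expr_sd_log >= 0)
  structure(list(conc_rel_sd = conc_rel_sd, expr_sd_log = expr_sd_log,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Simulate lineage-specific expression datasets
#'
#' Draws per-gene intensities: subsystem baseline x lineage multiplier x
#' lognormal gene noise x per-dataset scale jitter, then rescales each
#' dataset so its maximum sits near 1000 (emulating arrays normalized to
#' a common magnitude). A gene attached to several reactions inherits
#' the highest applicable subsystem intensity and multiplier.
#'
#' @param model A `metabolic_model` (typically [build_core_network()]).
#' @param spec A [lineage_spec()].
#' @param n_datasets Number of datasets to emit (default 2).
#' @param noise A [noise_model()].
#' @return Tibble `dataset_id`, `gene_id`, `intensity`. Deterministic
#'   given `spec$seed`.
#' @export
simulate_expression <- function(model, spec, n_datasets = 2L,
                                noise = noise_model()) {
  stopifnot(inherits(spec, "lineage_spec"))
  unknown <- setdiff(names(spec$multipliers), unique(model$reactions$subsystem))
  if (length(unknown)) {
    stop("lineage_spec references unknown subsystem(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  # gene -> strongest subsystem context among its reactions
  glist <- lapply(seq_len(nrow(model$reactions)), function(i) {
    g <- gpr_genes(parse_gpr(model$reactions$gpr[i]))
    if (!length(g)) return(NULL)
    tibble::tibble(gene_id = g, subsystem = model$reactions$subsystem[i])
  })
  gmap <- dplyr::bind_rows(glist)
  base <- spec$baseline
  mult <- spec$multipliers
  gmap$level <- unname(base[gmap$subsystem])
  gmap$level[is.na(gmap$level)] <- 200
  gmap$level <- gmap$level * unname(ifelse(is.na(mult[gmap$subsystem]), 1,
                                           mult[gmap$subsystem]))
  glevel <- gmap |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(level = max(.data$level), .groups = "drop")

  withr::with_seed(spec$seed, {
    # gene-level lognormal effects are a property of the lineage; the
    # datasets that measure it differ by an overall scale jitter
    effect <- glevel$level * exp(stats::rnorm(nrow(glevel), 0, noise$expr_sd_log))
    out <- lapply(seq_len(n_datasets), function(d) {
      jitter <- stats::runif(1, 0.8, 1.25)
      val <- effect / max(effect) * 1000 * jitter
      tibble::tibble(dataset_id = paste0(spec$lineage, "_", d),
                     gene_id = glevel$gene_id, intensity = val)
    })
    dplyr::bind_rows(out)
  })
}

#' Growth parameters of a culture
#'
#' @param initial_cell_count Cells at seeding (default 3.3e6).
#' @param doubling_time Population doubling time in hours (default 35,
#'   typical for expanding MSC; `Inf` = non-growing culture).
#' @param dry_weight_per_cell Grams dry weight per cell (default 3e-10).
#' @param culture_volume Culture medium volume in liters (default 0.05).
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(initial_cell_count = 3.3e6, doubling_time = 35,
                          dry_weight_per_cell = 3e-10, culture_volume = 0.05) {
  stopifnot(initial_cell_count > 0, doubling_time > 0,
            dry_weight_per_cell > 0, culture_volume > 0)
  structure(list(initial_cell_count = initial_cell_count,
                 doubling_time = doubling_time,
                 dry_weight_per_cell = dry_weight_per_cell,
                 culture_volume = culture_volume),
            class = "growth_params")
}

# time-averaged biomass in gDW over [0, span] under exponential growth
mean_biomass <- function(gp, span) {
  x0 <- gp$initial_cell_count * gp$dry_weight_per_cell
  d <- gp$doubling_time
  if (!is.finite(d) || span <= 0) return(x0)
  x0 * (2^(span / d) - 1) * d / (span * log(2))
}

#' Simulate exometabolomic time courses with known true rates
#'
#' Integrates `dC/dt = q X(t) / V` with exponential biomass
#' `X(t) = X0 2^(t/d)` to the closed form
#' `C(t) = C0 + (q/V) X0 (2^(t/d) - 1) d / ln 2`, then applies
#' multiplicative Gaussian measurement noise per replicate and time
#' point. Concentrations driven below zero are truncated at zero and
#' flagged `depleted`.
#'
#' @param true_rates Tibble with columns `metabolite_id`, `rate`
#'   (mmol/gDW/h, negative = uptake) and `conc0` (initial mM).
#' @param gp A [growth_params()].
#' @param noise A [noise_model()]; its `seed` drives the randomness.
#' @param times Sampling times in hours (increasing, starting at 0).
#' @param n_replicates Number of replicate cultures/donors (default 3).
#' @return Tibble `metabolite_id`, `replicate_id`, `time_h`, `conc_mM`,
#'   `depleted`. The noiseless trajectory at `conc_rel_sd = 0` is exact.
#' @export
simulate_timecourse <- function(true_rates, gp, noise = noise_model(),
                                times = c(0, 12, 24, 36, 48),
                                n_replicates = 3L) {
  stopifnot(inherits(gp, "growth_params"), all(diff(times) > 0))
  x0 <- gp$initial_cell_count * gp$dry_weight_per_cell
  d <- gp$doubling_time
  cum <- if (is.finite(d)) x0 * (2^(times / d) - 1) * d / log(2) else x0 * times
  withr::with_seed(noise$seed, {
    rows <- lapply(seq_len(nrow(true_rates)), function(k) {
      traj <- true_rates$conc0[k] + true_rates$rate[k] * cum / gp$culture_volume
      dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
        eps <- stats::rnorm(length(times), 0, noise$conc_rel_sd)
        obs <- traj * (1 + eps)
        tibble::tibble(metabolite_id = true_rates$metabolite_id[k],
                       replicate_id = paste0("rep", r),
                       time_h = times,
                       conc_mM = pmax(obs, 0),
                       depleted = obs < 0 | traj < 0)
      }))
    })
    dplyr::bind_rows(rows)
  })
}
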