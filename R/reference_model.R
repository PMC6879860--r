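# Reduced reference instance of the integrated neuroendocrine-metabolic
# model: HPA axis with GR central negative feedback, inflammation with a
# GR anti-inflammatory arm, regulatory signaling (insulin, cAMP/PKA,
# HIF1a), and a core metabolic network (glycolysis -> pyruvate/lactate,
# TCA entry via citrate, urea-cycle arm, lipid arm, amino-acid arm) with
# conserved ATP/ADP and NADH/NAD pools and blood-tissue transports.
#
# The two headline parameters are the GR sensitivity Hill exponents:
#   n  - cooperativity of GR's central negative feedback (CRH/ACTH
#        inhibition by cortisol) and of GR nuclear translocation; the
#        cortisol operating point sits ABOVE the central half-effect
#        constants, so raising n sharpens the feedback.
#   nx - cooperativity of GR's anti-inflammatory inhibition of IL-6/TNF;
#        the cortisol operating point sits BELOW the immune half-effect
#        constant, so raising nx weakens cytokine suppression at ambient
#        cortisol.  Jointly raising n and nx therefore disinhibits the
#        cytokines, which feed back on the HPA axis and drive insulin
#        resistance, a catabolic/hypoxic regulatory state, and the
#        metabolic-dysfunction signature.

ref_species <- function() {
  df <- function(id, compartment, initial, role) {
    data.frame(id = id, compartment = compartment, initial = initial,
               role = role, stringsAsFactors = FALSE)
  }
  rbind(
    df("stress", "plasma", 1, "input"),
    df("epinephrine", "plasma", 1, "input"),
    df("glycogen", "tissue", 1, "metabolite"),
    df("crh", "plasma", 1, "hormone"),
    df("acth", "plasma", 1, "hormone"),
    df("cortisol", "plasma", 1, "hormone"),
    df("gr_nuclear", "tissue", 1, "signaling"),
    df("il6", "plasma", 1, "cytokine"),
    df("tnf", "plasma", 1, "cytokine"),
    df("hif1a", "tissue", 1, "transcription_factor"),
    df("camp", "tissue", 1, "signaling"),
    df("insulin", "plasma", 1, "hormone"),
    df("glucose", "plasma", 1, "metabolite"),
    df("lactate", "plasma", 1, "metabolite"),
    df("glucose_cyt", "tissue", 1, "metabolite"),
    df("pyruvate", "tissue", 1, "metabolite"),
    df("lactate_cyt", "tissue", 1, "metabolite"),
    df("citrate", "tissue", 1, "metabolite"),
    df("akg", "tissue", 1, "metabolite"),
    df("alanine", "tissue", 1, "metabolite"),
    df("glutamine", "tissue", 1, "metabolite"),
    df("fatty_acids", "plasma", 1, "metabolite"),
    df("triglycerides", "plasma", 1, "metabolite"),
    df("carnitines", "tissue", 1, "metabolite"),
    df("arginine", "tissue", 1, "metabolite"),
    df("ornithine", "tissue", 1, "metabolite"),
    df("citrulline", "tissue", 1, "metabolite"),
    df("atp", "tissue", 2, "metabolite"),
    df("adp", "tissue", 1, "metabolite"),
    df("nadh", "tissue", 0.5, "metabolite"),
    df("nad", "tissue", 1.5, "metabolite")
  )
}

ref_parameters <- function() {
  c(
    # GR sensitivity (the headline MCA parameters)
    n = 2, nx = 2,
    # HPA axis
    k_crh = 1, kd_crh = 1, K_stress = 0.5, w_cyt = 4, K_il6_hpa = 0.7,
    K_cn = 1.06, k_acth = 1.6, kd_acth = 1, K_cn2 = 1.06,
    k_cort = 1, kd_cort = 1, k_gr = 1, kd_gr = 1, K_gr = 0.55,
    # inflammation
    k_il6 = 1.2, kd_il6 = 1, w_tnf_il6 = 0.8, K_tnf_il6 = 1,
    K_cx = 1.4, k_tnf = 1.5, kd_tnf = 1, K_cx2 = 1.4,
    # signaling
    k_hif = 0.5, kd_hif = 1, K_lact_hif = 1, w_lact_hif = 1,
    K_il6_hif = 1, w_il6_hif = 1.5,
    k_camp = 1, kd_camp = 1, K_epi = 1,
    k_ins = 1, kd_ins = 1, K_gins = 0.5, n_gins = 3, w_gins = 3,
    # glucose handling
    Vm_gng = 1.5, Km_pyr_gng = 1, Km_atp_gng = 0.5, w_gr_gng = 1,
    w_camp_gng = 1, K_gr_gng = 1, K_camp_gng = 1,
    Vm_glyc = 0.5, Km_gly = 1, w_camp_glyc = 1, K_camp_glyc = 1,
    Vm_upt = 2.5, Km_glu_upt = 1, w_ins_upt = 2, K_ins_upt = 1,
    K_ir = 1.2, n_ir = 2, kd_glu = 0.1,
    t_glu = 0.2, K_glu_b = 1, K_glu_t = 1,
    # glycolysis and mitochondrial entry
    Vm_glyco = 3, Km_glu_cyt = 1, Km_nad_glyco = 0.5, Km_adp_glyco = 0.5,
    w_hif_glyco = 1.5, K_hif_glyco = 1,
    Vm_ldh = 1.5, Km_pyr_ldh = 1, Km_nadh_ldh = 0.2, w_hif_ldh = 3,
    K_hif_ldh = 1,
    Vm_pdh = 2, Km_pyr_pdh = 1, Km_nad_pdh = 0.5, w_ins_pdh = 1,
    K_ins_pdh = 1, K_ir2 = 1.1, n_ir2 = 2, K_hif_pdh = 1.4, n_hif_pdh = 2,
    Vm_alat = 1.5, Km_ala = 1, kd_ala = 0.3,
    Vm_tca = 1.5, Km_cit = 1, Km_nad_tca = 0.5,
    Vm_akgd = 2.5, Km_akg = 1, Km_nad_akgd = 0.5, Km_adp_akgd = 0.5,
    Vm_glnl = 0.4, Km_gln = 1, w_hif_glnl = 0.3, K_hif_glnl = 1,
    # oxidative phosphorylation and demand
    Vm_oxphos = 3, Km_nadh_ox = 0.5, Km_adp_ox = 0.5,
    k_atpase = 2.5, Km_atp_dem = 0.5,
    # lipids
    k_lip = 1, w_camp_lip = 1, K_camp_lip = 1, w_gr_lip = 0.05,
    K_gr_lip = 1,
    Vm_box = 3, Km_fa_box = 0.3, Km_carn_box = 1, Km_adp_box = 0.5,
    Km_nad_box = 0.5, K_hif_box = 1.0, n_hif_box = 2, K_gr_box = 1.3,
    n_gr_box = 2,
    k_carn = 0.15, kd_carn = 0.02,
    Vm_tg = 0.32, Km_fa_tg = 0.02, Km_atp_tg = 0.02, w_ins_tg = 6, K_ins_tg = 2, n_ins_tg = 3, w_gr_tg = 1, K_gr_tg = 1,
    kd_tg = 0.5, kd_fa = 0.1,
    # amino acids
    k_prot = 0.8, w_gr_prot = 1.5, K_gr_prot = 1, w_tnf_prot = 1,
    K_tnf_prot = 1, kd_gln = 0.3,
    # urea cycle
    k_orn = 0.3, kd_orn = 0.1,
    Vm_ocs = 1.3, Km_orn = 1, Km_atp_urea = 1.4,
    Vm_ass = 2, Km_citr = 1, Km_atp_ass = 1.0,
    Vm_arginase = 0.3, Km_arg = 1, w_il6_arginase = 3, K_il6_arginase = 1,
    w_gr_arginase = 0.5, K_gr_arginase = 1,
    k_nos = 0.1, Km_arg_nos = 1,
    # lactate handling
    eps_lact = 1, kd_lact = 1
  )
}

rxn <- function(id, vmax, stoich, substrates = list(), regulators = list(),
                law = "saturating") {
  list(id = id, vmax = vmax, law = law, substrates = substrates,
       stoich = stoich, regulators = regulators)
}
sub <- function(species, km = NULL) {
  if (is.null(km)) species else list(species = species, km = km)
}
act <- function(species, k, n = 1, weight = 1) {
  list(species = species, mode = "activate", layer = "signaling",
       n = n, k = k, weight = weight)
}
deact <- function(species, k, n = 1) {
  list(species = species, mode = "deactivate", layer = "signaling",
       n = n, k = k)
}

ref_reactions <- function() {
  list(
    # --- HPA axis ---
    rxn("crh_prod", "k_crh", c(crh = 1), regulators = list(
      act("stress", "K_stress"),
      act("il6", "K_il6_hpa", weight = "w_cyt"),
      deact("cortisol", "K_cn", n = "n"))),
    rxn("crh_deg", "kd_crh", c(crh = -1), list(sub("crh")),
        law = "mass_action"),
    rxn("acth_prod", "k_acth", c(acth = 1), list(sub("crh")),
        regulators = list(deact("cortisol", "K_cn2", n = "n")),
        law = "mass_action"),
    rxn("acth_deg", "kd_acth", c(acth = -1), list(sub("acth")),
        law = "mass_action"),
    rxn("cort_prod", "k_cort", c(cortisol = 1), list(sub("acth")),
        law = "mass_action"),
    rxn("cort_deg", "kd_cort", c(cortisol = -1), list(sub("cortisol")),
        law = "mass_action"),
    rxn("grn_prod", "k_gr", c(gr_nuclear = 1), regulators = list(
      act("cortisol", "K_gr", n = "n"))),
    rxn("grn_deg", "kd_gr", c(gr_nuclear = -1), list(sub("gr_nuclear")),
        law = "mass_action"),
    # --- inflammation (GR anti-inflammatory arm carries nx) ---
    rxn("il6_prod", "k_il6", c(il6 = 1), regulators = list(
      act("tnf", "K_tnf_il6", weight = "w_tnf_il6"),
      deact("cortisol", "K_cx", n = "nx"))),
    rxn("il6_deg", "kd_il6", c(il6 = -1), list(sub("il6")),
        law = "mass_action"),
    rxn("tnf_prod", "k_tnf", c(tnf = 1), regulators = list(
      deact("cortisol", "K_cx2", n = "nx"))),
    rxn("tnf_deg", "kd_tnf", c(tnf = -1), list(sub("tnf")),
        law = "mass_action"),
    # --- signaling ---
    rxn("hif_prod", "k_hif", c(hif1a = 1), regulators = list(
      act("lactate_cyt", "K_lact_hif", weight = "w_lact_hif"),
      act("il6", "K_il6_hif", weight = "w_il6_hif"))),
    rxn("hif_deg", "kd_hif", c(hif1a = -1), list(sub("hif1a")),
        law = "mass_action"),
    rxn("camp_prod", "k_camp", c(camp = 1), regulators = list(
      act("epinephrine", "K_epi"))),
    rxn("camp_deg", "kd_camp", c(camp = -1), list(sub("camp")),
        law = "mass_action"),
    rxn("ins_prod", "k_ins", c(insulin = 1), regulators = list(
      act("glucose", "K_gins", n = "n_gins", weight = "w_gins"))),
    rxn("ins_deg", "kd_ins", c(insulin = -1), list(sub("insulin")),
        law = "mass_action"),
    # --- glucose handling ---
    rxn("gluconeogenesis", "Vm_gng",
        c(pyruvate = -1, atp = -2, adp = 2, glucose = 1),
        list(sub("pyruvate", "Km_pyr_gng"), sub("atp", "Km_atp_gng")),
        regulators = list(
          act("gr_nuclear", "K_gr_gng", weight = "w_gr_gng"),
          act("camp", "K_camp_gng", weight = "w_camp_gng"))),
    rxn("glycogenolysis", "Vm_glyc", c(glucose = 1),
        list(sub("glycogen", "Km_gly")),
        regulators = list(act("camp", "K_camp_glyc",
                              weight = "w_camp_glyc"))),
    rxn("glucose_uptake", "Vm_upt", c(glucose = -1, glucose_cyt = 1),
        list(sub("glucose", "Km_glu_upt")),
        regulators = list(
          act("insulin", "K_ins_upt", weight = "w_ins_upt"),
          deact("tnf", "K_ir", n = "n_ir"))),
    rxn("glucose_clearance", "kd_glu", c(glucose = -1),
        list(sub("glucose")), law = "mass_action"),
    # --- glycolysis, lactate, mitochondrial entry ---
    rxn("glycolysis", "Vm_glyco",
        c(glucose_cyt = -1, pyruvate = 1, nadh = 1, nad = -1,
          atp = 1, adp = -1),
        list(sub("glucose_cyt", "Km_glu_cyt"),
             sub("nad", "Km_nad_glyco"), sub("adp", "Km_adp_glyco")),
        regulators = list(act("hif1a", "K_hif_glyco",
                              weight = "w_hif_glyco"))),
    rxn("ldh", "Vm_ldh",
        c(pyruvate = -1, nadh = -1, nad = 1, lactate_cyt = 1),
        list(sub("pyruvate", "Km_pyr_ldh"), sub("nadh", "Km_nadh_ldh")),
        regulators = list(act("hif1a", "K_hif_ldh",
                              weight = "w_hif_ldh"))),
    rxn("pdh_tca_entry", "Vm_pdh",
        c(pyruvate = -1, nad = -1, nadh = 1, citrate = 1),
        list(sub("pyruvate", "Km_pyr_pdh"), sub("nad", "Km_nad_pdh")),
        regulators = list(
          act("insulin", "K_ins_pdh", weight = "w_ins_pdh"),
          deact("tnf", "K_ir2", n = "n_ir2"),
          deact("hif1a", "K_hif_pdh", n = "n_hif_pdh"))),
    rxn("ala_transamination", "Vm_alat", c(alanine = -1, pyruvate = 1),
        list(sub("alanine", "Km_ala"))),
    rxn("ala_clearance", "kd_ala", c(alanine = -1),
        list(sub("alanine")), law = "mass_action"),
    rxn("tca", "Vm_tca", c(citrate = -1, akg = 1, nadh = 1, nad = -1),
        list(sub("citrate", "Km_cit"), sub("nad", "Km_nad_tca"))),
    rxn("akg_oxidation", "Vm_akgd",
        c(akg = -1, nadh = 1, nad = -1, atp = 1, adp = -1),
        list(sub("akg", "Km_akg"), sub("nad", "Km_nad_akgd"),
             sub("adp", "Km_adp_akgd"))),
    rxn("glutaminolysis", "Vm_glnl", c(glutamine = -1, akg = 1),
        list(sub("glutamine", "Km_gln")),
        regulators = list(act("hif1a", "K_hif_glnl",
                              weight = "w_hif_glnl"))),
    # --- oxidative phosphorylation and ATP demand ---
    rxn("oxphos", "Vm_oxphos",
        c(nadh = -1, nad = 1, atp = 2, adp = -2),
        list(sub("nadh", "Km_nadh_ox"), sub("adp", "Km_adp_ox"))),
    rxn("atpase", "k_atpase", c(atp = -1, adp = 1),
        list(sub("atp", "Km_atp_dem"))),
    # --- lipid arm ---
    rxn("lipolysis", "k_lip", c(fatty_acids = 1), regulators = list(
      act("camp", "K_camp_lip", weight = "w_camp_lip"),
      act("gr_nuclear", "K_gr_lip", weight = "w_gr_lip"))),
    rxn("beta_oxidation", "Vm_box",
        c(fatty_acids = -1, carnitines = -1, atp = 2, adp = -2,
          nadh = 1, nad = -1),
        list(sub("fatty_acids", "Km_fa_box"),
             sub("carnitines", "Km_carn_box"), sub("adp", "Km_adp_box"),
             sub("nad", "Km_nad_box")),
        regulators = list(
          deact("hif1a", "K_hif_box", n = "n_hif_box"),
          deact("gr_nuclear", "K_gr_box", n = "n_gr_box"))),
    rxn("carnitine_supply", "k_carn", c(carnitines = 1)),
    rxn("carnitine_clearance", "kd_carn", c(carnitines = -1),
        list(sub("carnitines")), law = "mass_action"),
    rxn("tg_synthesis", "Vm_tg",
        c(fatty_acids = -1, atp = -1, adp = 1, triglycerides = 1),
        list(sub("fatty_acids", "Km_fa_tg"), sub("atp", "Km_atp_tg")),
        regulators = list(
          act("insulin", "K_ins_tg", n = "n_ins_tg", weight = "w_ins_tg"),
          act("gr_nuclear", "K_gr_tg", weight = "w_gr_tg"))),
    rxn("tg_clearance", "kd_tg", c(triglycerides = -1),
        list(sub("triglycerides")), law = "mass_action"),
    rxn("fa_clearance", "kd_fa", c(fatty_acids = -1),
        list(sub("fatty_acids")), law = "mass_action"),
    # --- amino-acid arm ---
    rxn("proteolysis", "k_prot", c(alanine = 1, glutamine = 1),
        regulators = list(
          act("gr_nuclear", "K_gr_prot", weight = "w_gr_prot"),
          act("tnf", "K_tnf_prot", weight = "w_tnf_prot"))),
    rxn("gln_export", "kd_gln", c(glutamine = -1),
        list(sub("glutamine")), law = "mass_action"),
    # --- urea-cycle arm ---
    rxn("ornithine_supply", "k_orn", c(ornithine = 1)),
    rxn("ornithine_clearance", "kd_orn", c(ornithine = -1),
        list(sub("ornithine")), law = "mass_action"),
    rxn("ocs", "Vm_ocs",
        c(ornithine = -1, atp = -2, adp = 2, citrulline = 1),
        list(sub("ornithine", "Km_orn"), sub("atp", "Km_atp_urea"))),
    rxn("ass", "Vm_ass",
        c(citrulline = -1, atp = -1, adp = 1, arginine = 1),
        list(sub("citrulline", "Km_citr"), sub("atp", "Km_atp_ass"))),
    rxn("arginase", "Vm_arginase", c(arginine = -1, ornithine = 1),
        list(sub("arginine", "Km_arg")),
        regulators = list(
          act("il6", "K_il6_arginase", weight = "w_il6_arginase"),
          act("gr_nuclear", "K_gr_arginase", weight = "w_gr_arginase"))),
    rxn("no_synthase", "k_nos", c(arginine = -1),
        list(sub("arginine", "Km_arg_nos"))),
    # --- lactate clearance ---
    rxn("lactate_clearance", "kd_lact", c(lactate = -1),
        list(sub("lactate")), law = "mass_action")
  )
}

ref_transports <- function() {
  list(
    list(id = "glucose_transport", kind = "facilitated",
         species_blood = "glucose", species_tissue = "glucose_cyt",
         t_max = "t_glu", k_blood = "K_glu_b", k_tissue = "K_glu_t"),
    list(id = "lactate_transport", kind = "passive",
         species_blood = "lactate", species_tissue = "lactate_cyt",
         epsilon = "eps_lact")
  )
}

#' Reduced reference model of the integrated stress-metabolism network
#'
#' Builds the shipped reduced instance (31 species, ~45 reactions, 2
#' transports) of the integrated HPA-axis / inflammation / regulatory
#' signaling / core metabolism model.  Glycogen and the two exogenous
#' inputs (stress drive, epinephrine) are clamped; the glycogen clamp
#' mimics steady substrate supply during control analysis.  The same
#' instance is shipped as a JSON document under
#' `inst/extdata/reference_model.json` for [load_model()].
#'
#' @return A [model_spec()].
#' @export
reference_model <- function() {
  model_spec(species = ref_species(),
             compartments = data.frame(id = c("plasma", "tissue"),
                                       volume = c(1, 1),
                                       stringsAsFactors = FALSE),
             reactions = ref_reactions(),
             transports = ref_transports(),
             parameters = ref_parameters(),
             clamps = c("glycogen", "stress", "epinephrine"))
}

#' Path to the shipped reference model document
#'
#' @return File path of the installed `reference_model.json`.
#' @export
reference_model_path <- function() {
  system.file("extdata", "reference_model.json", package = "gcmet",
              mustWork = TRUE)
}
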