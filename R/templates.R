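# Statement template banks for the synthetic-corpus generator.
#
# Each item carries: `detectable` sentences (guaranteed to fire the default
# library — the coverage test enforces this), `undetectable` paraphrases
# (real-world phrasings the library intentionally misses; used to inject
# calibrated miss rates), and `false_alarm` sentences (lexically match a
# library pattern but are semantically negative and survive the cleaning
# rules; used to inject calibrated false-alarm rates). Gold labels always
# follow the planted content, not its detectability.
#
# Sentences are written to express only their own item: a species sentence
# never mentions sex, staining, randomization etc., so per-item ground
# truth stays clean.

synth_templates <- function() {
  list(
    species = list(
      section = "methods",
      detectable = list(
        mouse = c(
          "Adult C57BL/6J mice were obtained from the institutional breeding colony.",
          "All experiments used transgenic mice housed under a 12 h light cycle.",
          "Mus musculus subjects were bred in-house under standard conditions."),
        rat = c(
          "Adult Wistar rats were housed in pairs with food ad libitum.",
          "Sprague-Dawley rats were acclimatized for one week before the experiments."),
        zebrafish = c(
          "Adult zebrafish (Danio rerio) were maintained at 28 degrees Celsius.")),
      undetectable = c(
        "The study used a common laboratory rodent strain maintained in-house.",
        "Subjects were sourced from an accredited commercial breeder."),
      false_alarm = c(
        "Culture media were supplemented with heat-inactivated murine serum."),
      echo = list(
        mouse = "We report longitudinal findings in mice.",
        rat = "We report longitudinal findings in rats.",
        zebrafish = "We report longitudinal findings in zebrafish.")),

    sex = list(
      section = "methods",
      detectable = list(
        male = c(
          "Only male animals were included in the study.",
          "Male animals aged ten weeks were used throughout."),
        female = c(
          "Only female animals were included in the study.",
          "Female animals aged ten weeks were used throughout."),
        both = c(
          "Animals of both sexes were included in equal numbers.",
          "Male and female animals were allocated in equal proportion.")),
      undetectable = c(
        "Animal sex was recorded but not considered in the design."),
      false_alarm = c(
        "Offspring were genotyped irrespective of the dam's litter composition, with male-line inheritance assumed."),
      echo = list(
        male = "The cohort comprised male animals.",
        female = "The cohort comprised female animals.",
        both = "The cohort comprised animals of both sexes.")),

    disease_model = list(
      section = "methods",
      detectable = list(
        motor_neuron_disease = c(
          "Transgenic SOD1-G93A animals were used to model amyotrophic lateral sclerosis.",
          "Disease was modelled by TDP-43 overexpression as previously described.",
          "A motor neuron disease phenotype was induced in the transgenic line."),
        multiple_sclerosis = c(
          "Experimental autoimmune encephalomyelitis (EAE) was induced by immunization.",
          "Demyelination was induced with cuprizone feeding for five weeks.",
          "Focal lesions were produced by lysolecithin injection.")),
      undetectable = c(
        "A chronic neurodegenerative phenotype was induced as previously described."),
      false_alarm = c(
        "Published work on amyotrophic lateral sclerosis registries motivated the sampling frame."),
      echo = list(
        motor_neuron_disease = "We studied a motor neuron disease model.",
        multiple_sclerosis = "We studied a multiple sclerosis model.")),

    outcome_histology = list(
      section = "methods",
      detectable = c(
        "Brain sections were processed for immunohistochemistry.",
        "Histological analysis was performed on paraffin-embedded tissue.",
        "Sections were stained with hematoxylin and eosin."),
      undetectable = c(
        "Tissue morphology was examined microscopically after perfusion."),
      false_alarm = c(
        "Antibody lots were validated by the supplier using immunostaining of control tissue."),
      echo = "Tissue pathology was assessed by immunohistochemistry."),

    outcome_behaviour = list(
      section = "methods",
      detectable = c(
        "Motor coordination was evaluated with the rotarod test.",
        "Behavioural testing included the open-field arena.",
        "Grip-strength measurements were collected weekly."),
      undetectable = c(
        "Locomotor activity was monitored continuously in the home cage."),
      false_alarm = c(
        "A brief behavioural test battery is described in the cited protocol paper only."),
      echo = "Motor performance was tracked with the rotarod test."),

    outcome_imaging = list(
      section = "methods",
      detectable = c(
        "In vivo magnetic resonance imaging was performed on a 7 T scanner.",
        "T2-weighted images were acquired at baseline and follow-up.",
        "Animals underwent positron emission tomography under anaesthesia."),
      undetectable = c(
        "Whole-brain scans were acquired longitudinally on a dedicated scanner."),
      false_alarm = c(
        "Clinical MRI findings in patients motivated the present work."),
      echo = "Magnetic resonance imaging tracked lesion evolution."),

    randomization = list(
      section = "methods",
      detectable = c(
        "Animals were randomly allocated to treatment groups.",
        "Group assignment was performed using a randomization schedule.",
        "Animals were assigned to experimental groups at random."),
      undetectable = c(
        "Allocation to groups was decided by coin toss without a formal scheme."),
      false_alarm = c(
        "Differences in connectivity were assessed with a randomization test of 1000 permutations.")),

    blinding = list(
      section = "methods",
      detectable = c(
        "Outcome assessment was performed by a blinded investigator.",
        "Scoring was carried out in a blinded fashion.",
        "Investigators were masked to group allocation."),
      undetectable = c(
        "The assessor was unaware of treatment assignments during scoring."),
      false_alarm = c(
        "Congenitally blinded animals served as controls for visual deprivation.")),

    animal_welfare = list(
      section = "methods",
      detectable = c(
        "All procedures were approved by the institutional animal care and use committee.",
        "Experiments complied with the Animal Welfare Act and institutional policy.",
        "The protocol was approved by the cantonal veterinary office."),
      undetectable = c(
        "Housing conditions met institutional husbandry standards."),
      false_alarm = c(
        "The history of animal welfare legislation is reviewed elsewhere.")),

    conflict_of_interest = list(
      section = "discussion",
      detectable = c(
        "The authors declare no conflict of interest.",
        "There are no competing financial interests to report.",
        "All authors declared no potential conflicts."),
      undetectable = c(
        "The authors report no relationships that could have influenced this work."),
      false_alarm = c(
        "Conflicts of interest in science policy are beyond the scope of this study.")),

    sample_size_calculation = list(
      section = "methods",
      detectable = c(
        "Sample sizes were calculated using a power analysis.",
        "An a priori power analysis determined the group sizes.",
        "Group sizes were determined with G*Power."),
      undetectable = c(
        "Group sizes matched those used in previous studies."),
      false_alarm = c(
        "The statistical power of the post hoc comparison was limited.")),

    arrive_guidelines = list(
      section = "discussion",
      detectable = c(
        "Reporting follows the ARRIVE guidelines.",
        "The study is reported in accordance with the ARRIVE 2.0 guidelines.",
        "This work adheres to the Animal Research: Reporting of In Vivo Experiments criteria."),
      undetectable = c(
        "Reporting followed a community checklist for animal experiments."),
      false_alarm = c(
        "As new data arrive guidelines for this assay are updated accordingly.")),

    data_availability = list(
      section = "discussion",
      detectable = c(
        "The data are available upon reasonable request.",
        "All raw data will be made publicly available.",
        "Data availability: all datasets were deposited in a public repository."),
      undetectable = c(
        "Underlying datasets can be obtained from the authors."),
      false_alarm = c(
        "Antibodies are available from the corresponding author."))
  )
}

# phrases the cleaning rules exist for; planted as distractors
distractor_phrases <- function() {
  c("cDNA was synthesized using random primers.",
    "Libraries were prepared with random hexamer priming.",
    "Animals were randomly assigned to cages for husbandry before the study began.")
}

# decoy citations for the references block; lexically loaded with item
# vocabulary that must never produce hits once references are stripped
reference_decoys <- function() {
  c("1. Smith J, et al. A randomized controlled trial of exercise in ALS. J Neurol 2019.",
    "2. Jones A, Brown K. Blinded assessment of histological outcomes in EAE mice. Glia 2020.",
    "3. Lee S. Power analysis and sample size calculation for animal studies. Lab Anim 2018.",
    "4. Patel R. The ARRIVE guidelines and data availability statements. PLoS Biol 2021.")
}

filler_sentences <- function() {
  c("The study addresses progressive neural dysfunction in a controlled setting.",
    "Previous work has characterized disease progression in similar preparations.",
    "Lesion burden increased steadily over the observation period.",
    "Group differences reached statistical significance at the final time point.",
    "These findings extend earlier observations from independent laboratories.",
    "Several mechanisms could account for the observed effect.",
    "The time course of recovery varied across individuals.",
    "Quantification was performed with standard image-analysis software.",
    "Supplementary analyses are provided in the appendix.",
    "Future work should address the underlying cellular mechanisms.")
}

#' Heading dialects emulated by the generator
#'
#' Five journal heading styles (plain, full "Materials and Methods",
#' numbered, all-caps, and an alternative synonym set with "Summary" /
#' "Experimental Procedures" / "Bibliography"; the numbered dialect has an
#' unlabelled abstract). Used to exercise the section segmenter.
#'
#' @return Named list: dialect -> named list of heading strings per
#'   section (`NA` means the section has no heading).
#' @export
heading_dialects <- function() {
  list(
    plain = list(abstract = "Abstract", introduction = "Introduction",
                 methods = "Methods", results = "Results",
                 discussion = "Discussion", references = "References"),
    full = list(abstract = "Abstract", introduction = "Introduction",
                methods = "Materials and Methods", results = "Results",
                discussion = "Discussion", references = "References"),
    numbered = list(abstract = NA, introduction = "1. Introduction",
                    methods = "2. Materials and Methods", results = "3. Results",
                    discussion = "4. Discussion", references = "References"),
    upper = list(abstract = "ABSTRACT", introduction = "INTRODUCTION",
                 methods = "MATERIALS AND METHODS", results = "RESULTS",
                 discussion = "DISCUSSION", references = "REFERENCES"),
    alt = list(abstract = "Summary", introduction = "Background",
               methods = "Experimental Procedures",
               results = "Results and Discussion",
               discussion = "General Discussion",
               references = "Bibliography")
  )
}
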