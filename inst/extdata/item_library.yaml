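# Default item library: a curated phrase bank per item, reconstructed for
# preclinical neuroscience corpora (motor neuron disease, multiple
# sclerosis). It is a functional default, intended to be replaced or
# extended per field; the library FORMAT (this file's schema) is the
# contract. All patterns are matched case-insensitively; word-boundary
# anchors keep short tokens ("rat", "ALS") from firing inside longer words.
- item_id: species
  patterns:
    - pattern_id: species_mouse
      pattern: '\b(mice|mouse|mus musculus|murine)\b'
      category: mouse
    - pattern_id: species_mouse_strain
      pattern: '\b(C57BL/?6?J?|BALB/c|CD-?1 mice)\b'
      category: mouse
    - pattern_id: species_rat
      pattern: '\b(rats?|rattus norvegicus|sprague[- ]dawley|wistar|long[- ]evans)\b'
      category: rat
    - pattern_id: species_zebrafish
      pattern: '\b(zebrafish|danio rerio)\b'
      category: zebrafish
    - pattern_id: species_pig
      pattern: '\b(pigs?|minipigs?|swine|porcine)\b'
      category: pig
    - pattern_id: species_dog
      pattern: '\b(dogs?|beagles?|canine)\b'
      category: dog
    - pattern_id: species_nhp
      pattern: '\b(macaques?|marmosets?|rhesus|cynomolgus|non[- ]human primates?)\b'
      category: nonhuman_primate
- item_id: sex
  patterns:
    - pattern_id: sex_both
      pattern: '\b(both sexes|males? and females?|females? and males?|either sex|mixed[- ]sex)\b'
      category: both
    - pattern_id: sex_male
      pattern: '\bmales?\b'
      category: male
    - pattern_id: sex_female
      pattern: '\bfemales?\b'
      category: female
- item_id: disease_model
  patterns:
    - pattern_id: model_mnd
      pattern: '\b(SOD1(-?G93A)?|TDP-?43|C9orf72|FUS)\b|amyotrophic lateral sclerosis|\bALS\b|motor neurone? disease|\bwobbler\b'
      category: motor_neuron_disease
    - pattern_id: model_ms
      pattern: '\bEAE\b|experimental autoimmune encephalomyelitis|\bcuprizone\b|\blysolecithin\b|\btheiler''?s?\b|MOG[- ]induced|multiple sclerosis'
      category: multiple_sclerosis
- item_id: outcome_histology
  patterns:
    - pattern_id: hist_general
      pattern: 'histolog(y|ical|ically)|histopatholog\w*'
    - pattern_id: hist_ihc
      pattern: 'immunohistochem\w*|immunofluorescen\w*|immunostain\w*'
    - pattern_id: hist_stains
      pattern: '(h(a?)ematoxylin( and eosin)?|\bH&E\b|nissl|cresyl violet|luxol fast blue)'
    - pattern_id: hist_staining
      pattern: '\bstain(ed|ing)\b'
- item_id: outcome_behaviour
  patterns:
    - pattern_id: behav_general
      pattern: 'behaviou?r(al)?\s+(test(s|ing)?|assessment|analys[ei]s|task|phenotyp\w*|performance)'
    - pattern_id: behav_tests
      pattern: '\b(rotarod|open[- ]field|grip[- ]strength|morris water maze|elevated plus maze|gait analysis|wire[- ]hang(ing)? test|catwalk)\b'
    - pattern_id: behav_motor
      pattern: 'motor (function|performance) (test(s|ing)?|was assessed|assessment)'
- item_id: outcome_imaging
  patterns:
    - pattern_id: img_mri
      pattern: 'magnetic resonance imaging|\bMRI\b|\b(T1|T2)[- ]weighted\b|diffusion tensor imaging|\bDTI\b|magnetic resonance spectroscopy'
    - pattern_id: img_pet_ct
      pattern: 'positron emission tomography|\bPET\b|computed tomography|micro-?CT\b'
    - pattern_id: img_other
      pattern: '\bin vivo imaging\b|ultrasound imaging|bioluminescence imaging'
- item_id: randomization
  patterns:
    - pattern_id: rand_word
      pattern: '\brandom(ly|i[sz]ed|i[sz]ation|i[sz]e[ds]?)\b'
    - pattern_id: rand_phrase
      pattern: '\b(at random|random (allocation|assignment|sequence|number (table|generator)))\b'
  negative_patterns:
    - 'random[- ]effects?'
    - 'random\s+(primers?|hexamers?)'
- item_id: blinding
  patterns:
    - pattern_id: blind_word
      pattern: '\bblind(ed|ing)\b'
    - pattern_id: blind_phrase
      pattern: '\bblind (assessment|fashion|manner|to)\b'
    - pattern_id: blind_masked
      pattern: '\bmasked (to|fashion|manner)\b|investigators? (were|remained) masked'
- item_id: animal_welfare
  patterns:
    - pattern_id: welfare_committee
      pattern: 'institutional animal care and use committee|\bIACUC\b|animal (care|welfare|ethics) (committee|authority|office)|ethic(s|al) (review )?committee|veterinary office'
    - pattern_id: welfare_regulations
      pattern: 'animal welfare (act|regulations|legislation|guidelines)|directive 2010/63|guide for the care and use of laboratory animals'
    - pattern_id: welfare_approval
      pattern: '(experiments?|procedures?|protocols?) (were|was) (approved|conducted in accordance)|approved by the (local|national|institutional|cantonal) (animal|ethics|veterinary)'
- item_id: conflict_of_interest
  patterns:
    - pattern_id: coi_phrase
      pattern: 'conflicts? of interest|competing (financial )?interests?'
    - pattern_id: coi_none
      pattern: '(declared? no|have no|nothing to) (potential )?(conflicts?|competing interests?|disclos\w*)'
- item_id: sample_size_calculation
  patterns:
    - pattern_id: power_analysis
      pattern: 'power (analysis|calculation)|a priori power|statistical power of|powered to detect'
    - pattern_id: samplesize_phrase
      pattern: 'sample[- ]sizes? (calculation|estimation|(was|were) (calculated|determined|estimated|chosen based))'
    - pattern_id: gpower
      pattern: 'G\*?Power'
- item_id: arrive_guidelines
  patterns:
    - pattern_id: arrive_name
      pattern: '\bARRIVE\b\s*(guidelines?|criteria|checklist|2\.0)'
    - pattern_id: arrive_full
      pattern: 'animal research:? reporting of in vivo experiments'
    - pattern_id: arrive_accordance
      pattern: '(in accordance|complian(ce|t)) with (the )?ARRIVE\b'
- item_id: data_availability
  patterns:
    - pattern_id: da_statement
      pattern: 'data availability( statement)?'
    - pattern_id: da_available
      pattern: 'data (are|is|will be) (made )?((publicly|freely) )?available|available (up)?on (reasonable )?request|available from the corresponding author'
    - pattern_id: da_deposited
      pattern: 'deposited (in|at|on) [^.\n]{0,60}(repositor\w*|database|archive)|open science framework'
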