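# ICEBERG screening instrument: nine geriatric domains, 14 scoreable sub-items,
# attainable total score 1-30 (Q2 always contributes at least 1 point for a
# patient aged 70+). Higher totals indicate more geriatric syndromes and a
# greater need for geriatric consultation.
name: ICEBERG
threshold_default: 10
items:
  - id: Q1
    domain: social_situation
    prompt: "Where does the patient live?"
    options:
      - label: independent_at_home
        weight: 0
      - label: home_with_support
        weight: 2
      - label: nursing_home
        weight: 3
  - id: Q2
    domain: age
    prompt: "What is the patient's age?"
    required: true
    options:
      - label: 70-79
        weight: 1
      - label: 80_plus
        weight: 2
  - id: Q3a
    domain: mobility_falls
    prompt: "Falls (2+) in the last 12 months?"
    options:
      - label: "yes"
        weight: 3
      - label: "no"
        weight: 0
  - id: Q3b
    domain: mobility_falls
    prompt: "Is a fall the reason for the current ER visit?"
    options:
      - label: "yes"
        weight: 1
      - label: "no"
        weight: 0
  - id: Q4a
    domain: cognition_depression
    prompt: "Is there any sign for a cognitive disorder impacting everyday life activities?"
    options:
      - label: "yes"
        weight: 3
      - label: "no"
        weight: 0
  - id: Q4b
    domain: cognition_depression
    prompt: "Has the patient felt down, depressed, or fatigued lately?"
    options:
      - label: "yes"
        weight: 2
      - label: "no"
        weight: 0
  - id: Q5
    domain: delirium
    prompt: "Can the patient count the months of the year backwards without any error up to and including September?"
    options:
      - label: "yes"
        weight: 0
      - label: "no"
        weight: 3
  - id: Q6a
    domain: prior_care_contact
    prompt: "ER or emergency visit at GP in past month?"
    options:
      - label: "yes"
        weight: 2
      - label: "no"
        weight: 0
  - id: Q6b
    domain: prior_care_contact
    prompt: "Hospitalization in past 6 months?"
    options:
      - label: "yes"
        weight: 2
      - label: "no"
        weight: 0
  - id: Q7
    domain: polypharmacy
    prompt: "How many drugs does the patient take regularly?"
    options:
      - label: 0-3_drugs
        weight: 0
      - label: 4-7_drugs
        weight: 1
      - label: 8_plus_drugs
        weight: 2
  - id: Q8a
    domain: functional_limitation
    prompt: "Does the patient usually need any help with taking showers or bathing?"
    options:
      - label: "yes"
        weight: 2
      - label: "no"
        weight: 0
  - id: Q8b
    domain: functional_limitation
    prompt: "Right now, can the patient transfer from a lying or sitting position to a standing position independently?"
    options:
      - label: "yes"
        weight: 0
      - label: "no"
        weight: 2
  - id: Q9a
    domain: malnutrition
    prompt: "Has the patient lost more than 3 kg weight without trying and/or do the clothes not fit anymore?"
    options:
      - label: "yes"
        weight: 2
      - label: "no"
        weight: 0
  - id: Q9b
    domain: malnutrition
    prompt: "Has the patient been eating poorly because of decreased appetite?"
    options:
      - label: "yes"
        weight: 1
      - label: "no"
        weight: 0
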