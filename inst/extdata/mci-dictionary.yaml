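version: concept-reconstruction-1.0
entries:
- cui: S_EXCL
  description: References to stroke (used to exclude patients from analysis)
  role: patient_exclusion
  max_gap: 2
  patterns:
  - stroke
  - cva
  - cerebrovascular accident
  - transient ischemic attack
  - tia
- cui: WITHX
  description: Patient accompanied by family member
  role: feature
  max_gap: 2
  patterns:
  - accompanied by daughter
  - accompanied by son
  - accompanied by wife
  - accompanied by husband
  - accompanied by family
  - here with daughter
  - here with son
- cui: RESPONS
  description: Responsibility being assumed by family member
  role: feature
  max_gap: 2
  patterns:
  - daughter manages medication
  - son manages medication
  - family manages finances
  - wife handles medication
  - husband handles finances
- cui: NEGATE
  description: Atenolol, hypercalcemia, statins, and "remember to take" boilerplate
    language
  role: feature
  max_gap: 2
  patterns:
  - remember to take
  - atenolol
  - hypercalcemia
  - statin
  - simvastatin
  - atorvastatin
- cui: HALLUC
  description: Hallucination issues
  role: feature
  max_gap: 2
  patterns:
  - hallucination
  - hallucinate
  - hearing voices
  - seeing things
- cui: HEADACHE
  description: Headache/concern for stroke or brain injury
  role: feature
  max_gap: 2
  patterns:
  - headache
  - migraine
  - worst headache
- cui: W_EXCL
  description: Traumatic brain injury, dehydration, etc. (used to exclude patients
    from analysis)
  role: patient_exclusion
  max_gap: 2
  patterns:
  - traumatic brain injury
  - tbi
  - dehydration
  - concussion
- cui: DECLINE
  description: Declining memory/cognitive abilities
  role: feature
  max_gap: 2
  patterns:
  - loss cognitive ability
  - memory loss
  - cognitive decline
  - declining memory
  - memory impairment
  - memory worse
- cui: WANDER
  description: Wandering, getting lost, or unable to recognize
  role: feature
  max_gap: 2
  patterns:
  - wander
  - getting lost
  - got lost
  - unable to recognize
- cui: CALLED
  description: Reference to communication going through family member
  role: feature
  max_gap: 2
  patterns:
  - daughter called
  - son called
  - wife called
  - husband called
  - family called about
- cui: FORGET
  description: Forget/can't remember
  role: feature
  max_gap: 2
  patterns:
  - forget
  - forgot
  - can't remember
  - cannot remember
- cui: DONEPEZIL
  description: Donepezil, Aricept discussed (e.g., regarding what the medications
    can do)
  role: feature
  max_gap: 2
  patterns:
  - donepezil
  - aricept
- cui: CONCERN
  description: Family showing concern for patient
  role: feature
  max_gap: 2
  patterns:
  - family concerned
  - daughter concerned
  - son concerned
  - family worried
  - wife concerned
  - husband concerned
- cui: FORGETFL
  description: Forgetful
  role: feature
  max_gap: 2
  patterns:
  - forgetful
  - forgetfulness
- cui: EXAM
  description: Cognitive evaluation
  role: feature
  max_gap: 2
  patterns:
  - mmse
  - moca
  - mini mental
  - cognitive testing
  - cognitive evaluation
  - clock draw
- cui: OTHER_SA
  description: Communication goes through family members
  role: feature
  max_gap: 2
  patterns:
  - spoke with daughter
  - spoke with son
  - per daughter
  - per son
  - information from family
- cui: S_HALLUC
  description: Strong hallucination concern
  role: feature
  max_gap: 2
  patterns:
  - frightening hallucinations
  - vivid hallucinations
  - severe hallucinations
- cui: ICD_EXCL
  description: Dementia ICD diagnosis code appearing in text
  role: feature
  max_gap: 2
  patterns:
  - 290 0
  - 294 10
  - 294 11
  - dementia code
- cui: DEMENTIA
  description: Severe dementia noted
  role: feature
  max_gap: 2
  patterns:
  - severe dementia
  - advanced dementia
  - end stage dementia
- cui: REFERAL
  description: Referral for cognitive assessment
  role: feature
  max_gap: 2
  patterns:
  - refer memory clinic
  - referral cognitive testing
  - refer neuropsychology
  - neuropsychological testing
- cui: COMPREHE
  description: Poor understanding/comprehension
  role: feature
  max_gap: 2
  patterns:
  - poor comprehension
  - difficulty understanding
  - does not understand instructions
- cui: W_DECLIN
  description: Decline in word finding, vocabulary, explaining, etc
  role: feature
  max_gap: 2
  patterns:
  - word finding difficulty
  - trouble finding words
  - difficulty naming
- cui: CONCENTR
  description: Difficulty concentrating
  role: feature
  max_gap: 2
  patterns:
  - difficulty concentrating
  - poor concentration
  - trouble focusing
- cui: EARLY
  description: Early dementia
  role: feature
  max_gap: 2
  patterns:
  - early dementia
  - early cognitive impairment
- cui: DECLINE_
  description: Communication/call concerning memory decline
  role: feature
  max_gap: 2
  patterns:
  - called about memory
  - call regarding memory
  - message about memory
- cui: FORGETX
  description: Forget [something] e.g., keys
  role: feature
  max_gap: 2
  patterns:
  - forget keys
  - forget appointment
  - forget name
- cui: S_CONCER
  description: Worsening or strong concern for dementia
  role: feature
  max_gap: 2
  patterns:
  - very worried about memory
  - serious concern dementia
  - worsening memory concern
- cui: PLAN
  description: Related care plan to family member
  role: feature
  max_gap: 2
  patterns:
  - care plan daughter
  - care plan son
  - plan discussed family
- cui: HAL_EXCL
  description: Hallucination issues resolved
  role: feature
  max_gap: 2
  patterns:
  - hallucinations resolved
  - no further hallucinations
- cui: BOI_INCL
  description: Boilerplate text describing memory problems not necessarily specific
    to the patient
  role: feature
  max_gap: 2
  patterns:
  - memory loss can occur
  - memory problems are common
- cui: OTH_EXCL
  description: Headache/memory complaint relating to non-patient
  role: feature
  max_gap: 2
  patterns:
  - mother memory problems
  - husband has dementia
  - family history dementia
- cui: RISK
  description: Risk of dementia
  role: feature
  max_gap: 2
  patterns:
  - risk of dementia
  - risk for dementia
  - dementia risk
- cui: W_CONCER
  description: Concern for word finding, vocabulary, explaining, etc
  role: feature
  max_gap: 2
  patterns:
  - concerned word finding
  - worried about vocabulary
- cui: ICD_INCL
  description: MCI ICD diagnosis code appearing in text but not in structured data
  role: feature
  max_gap: 2
  patterns:
  - 331 83
  - mild cognitive impairment code
- cui: DENIAL
  description: Patient denies problem with memory or functioning
  role: feature
  max_gap: 2
  patterns:
  - denies memory problems
  - denies memory loss
  - no memory complaints
- cui: EXM_EXCL
  description: Normal cognitive exam
  role: feature
  max_gap: 2
  patterns:
  - normal cognitive exam
  - cognition intact
  - mmse normal
- cui: STIMULANT
  description: Stimulant medications (modafinil, Provigil, etc.)
  role: feature
  max_gap: 2
  patterns:
  - modafinil
  - provigil
  - methylphenidate
  - ritalin
- cui: SENILE
  description: Not thinking well/not lucid
  role: feature
  max_gap: 2
  patterns:
  - senile
  - not lucid
  - not thinking well
- cui: BURDEN
  description: Burden on family member
  role: feature
  max_gap: 2
  patterns:
  - burden on family
  - caregiver burden
  - caregiver stress
- cui: BOOK
  description: Names of relevant books, including 36-h Day, Dignified Life, and Ageless
    Outings
  role: feature
  max_gap: 2
  patterns:
  - 36 hour day
  - dignified life
  - ageless outings
- cui: EXCLUDE
  description: Words referencing forgetfulness excluded because of ambiguity concerns
  role: feature
  max_gap: 2
  patterns:
  - forget it
  - forgettable
- cui: WELLNESS
  description: Wellness check
  role: feature
  max_gap: 2
  patterns: []
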