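# Default tracer-indicator registry: 24 indicators, 17 tracer areas,
# 5 tracer domains.  Values are district-level percentages on the 0-100
# scale.  Indicators flagged `adverse_incidence` are stored as incidences
# (low = good) and complemented (100 - x) before any aggregation.
domains:
  - key: rmnch
    name: Reproductive, maternal, newborn and child health
    areas:
      - key: pregnancy_delivery
        name: Pregnancy and delivery care
        indicators:
          - id: anc4
            name: Mothers with at least four antenatal care visits (%)
          - id: pnc
            name: Mothers receiving postnatal care from skilled personnel within 2 days (%)
          - id: sba
            name: Live births attended by skilled health personnel (%)
          - id: inst_delivery
            name: Births occurring in health facilities (%)
      - key: family_planning
        name: Family planning
        indicators:
          - id: mod_contraception
            name: Married women 15-49 using modern contraception (%)
      - key: immunization
        name: Full immunization
        indicators:
          - id: full_immunization
            name: Children 12-23 months fully immunized (BCG, measles, 3x polio, 3x DPT) (%)
  - key: infectious
    name: Infectious diseases
    areas:
      - key: wash
        name: Water, sanitation and hygiene
        indicators:
          - id: sanitation
            name: Population using an improved sanitation facility (%)
          - id: water
            name: Population using an improved drinking-water source (%)
      - key: tb
        name: Effective treatment of tuberculosis
        indicators:
          - id: tb_treatment
            name: Treatment success rate for new pulmonary smear-positive TB (%)
  - key: ncd
    name: Noncommunicable diseases
    areas:
      - key: cvd
        name: Prevention of cardiovascular diseases
        indicators:
          - id: bp_normal
            name: Adults 18+ with SBP < 140 mmHg and DBP < 90 mmHg (%)
      - key: diabetes
        name: Prevention of diabetes
        indicators:
          - id: glucose_normal
            name: Adults 18+ with blood glucose <= 140 mg/dL (%)
      - key: tobacco
        name: Tobacco control and tobacco use
        indicators:
          - id: non_smoking
            name: Adults 15+ not smoking tobacco (%)
      - key: cancer
        name: Cancer detection and treatment
        indicators:
          - id: cervical_screening
            name: Women ever screened for cervical cancer (%)
          - id: breast_screening
            name: Women ever screened for breast cancer (%)
  - key: capacity
    name: Service capacity and access
    areas:
      - key: facility_access
        name: Health facility access
        indicators:
          - id: facility_24x7
            name: Functioning facilities providing round-the-clock care per IPHS norms (%)
      - key: infrastructure
        name: Health infrastructure
        indicators:
          - id: beds
            name: Beds available as a percentage of the IPHS norm (%)
      - key: medicines
        name: Essential medicines
        indicators:
          - id: essential_medicines
            name: Essential medicines (IPHS list) available in PHCs and CHCs (%)
      - key: workforce
        name: Health workforce
        indicators:
          - id: doctors
            name: Doctors available as a percentage of the IPHS norm (%)
          - id: paramedics
            name: Paramedical staff available as a percentage of the IPHS norm (%)
      - key: mch_training
        name: Health personnel with maternal and child health training
        indicators:
          - id: sba_training
            name: Health personnel trained in skilled birth attendance in past 5 years (%)
          - id: emoc_training
            name: Health personnel trained in basic emergency obstetric care in past 5 years (%)
  - key: frp
    name: Financial risk protection
    areas:
      - key: insurance
        name: Health insurance coverage
        indicators:
          - id: insurance
            name: Population covered by a health insurance scheme (%)
      - key: catastrophic
        name: Protection from catastrophic health expenditure
        indicators:
          - id: cat_expenditure
            name: Population experiencing catastrophic health expenditure (%)
            orientation: adverse_incidence
      - key: impoverishment
        name: Protection from impoverishment
        indicators:
          - id: impoverishment
            name: Population impoverished by health expenses (%)
            orientation: adverse_incidence

# The 14-indicator subset used for subgroup (equity) analysis: the
# household-survey-derived indicators (all RMNCH, WASH, all NCD, health
# insurance).  User-overridable; every id must exist above.
equity_subset:
  - anc4
  - pnc
  - sba
  - inst_delivery
  - mod_contraception
  - full_immunization
  - sanitation
  - water
  - bp_normal
  - glucose_normal
  - non_smoking
  - cervical_screening
  - breast_screening
  - insurance
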