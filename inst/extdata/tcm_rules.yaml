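# Default MedDRA -> TCM functional-system mapping rules.
# 16-system vocabulary: five Zang organs plus the Pericardium, six Fu
# organs, and four cross-cutting systems (Body Surface, Chong-Ren
# Meridians, Meridians and Collaterals, Qi-Blood-Fluid).
# Exact-PT rules take precedence over SOC defaults; this file is data and
# may be edited/extended.
systems:
  - Liver
  - Heart
  - Spleen
  - Lung
  - Kidney
  - Pericardium
  - Gallbladder
  - Stomach
  - Small Intestine
  - Large Intestine
  - Bladder
  - San Jiao
  - Body Surface
  - Chong-Ren Meridians
  - Meridians and Collaterals
  - Qi-Blood-Fluid

pt_rules:
  Vomiting: [Stomach]
  Jaundice: [Liver]
  Drug-induced liver injury: [Liver, Qi-Blood-Fluid]
  Hepatitis: [Liver, Qi-Blood-Fluid]
  Acute pulmonary oedema: [Lung, Qi-Blood-Fluid]
  Pulmonary embolism: [Lung, Qi-Blood-Fluid]
  Gastric haemorrhage: [Stomach, Qi-Blood-Fluid]
  Small intestinal haemorrhage: [Small Intestine, Qi-Blood-Fluid]
  Tremor: [Body Surface]
  Haematemesis: [Stomach, Qi-Blood-Fluid]
  Constipation: [Large Intestine]
  Diarrhoea: [Spleen, Large Intestine]
  Urinary retention: [Bladder]
  Menstrual disorder: [Chong-Ren Meridians]
  Paraesthesia: [Meridians and Collaterals]
  Chest pain: [Pericardium, Heart]
  Oedema: [San Jiao, Qi-Blood-Fluid]

soc_rules:
  Gastrointestinal disorders: [Spleen, Stomach]
  Hepatobiliary disorders: [Liver]
  Cardiac disorders: [Heart]
  Respiratory, thoracic and mediastinal disorders: [Lung]
  Skin and subcutaneous tissue disorders: [Body Surface]
  Ear and labyrinth disorders: [Kidney]
  Nervous system disorders: [Liver]
  Renal and urinary disorders: [Kidney, Bladder]
  Vascular disorders: [Qi-Blood-Fluid]
  Blood and lymphatic system disorders: [Qi-Blood-Fluid]
  Psychiatric disorders: [Heart]
  Eye disorders: [Liver]
  Musculoskeletal and connective tissue disorders: [Liver, Kidney]
  Metabolism and nutrition disorders: [Spleen]
  Reproductive system and breast disorders: [Kidney, Chong-Ren Meridians]
  Immune system disorders: [Qi-Blood-Fluid]
  General disorders and administration site conditions: [Qi-Blood-Fluid]
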