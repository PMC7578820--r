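{
  "schema_version": "1.0.0",
  "description": "Patient-centered digestive system tumor knowledge graph schema: 7 top-level classes with data properties, subconcept tree, and 16 semantic relationship types (13 clinical + 3 structural) with head/tail class constraints.",
  "classes": [
    {"name": "patient", "parent": null, "data_properties": ["ID", "sex", "age", "occupation", "native place"], "source": ""},
    {"name": "disease", "parent": null, "data_properties": ["English name", "nonpreferred term", "state"], "source": "SNOMED CT; ICD-10"},
    {"name": "disease type", "parent": null, "data_properties": ["English name", "nonpreferred term", "histological grade", "pathological stage", "naked eye type", "tumor size"], "source": "WHO classification of digestive system tumors"},
    {"name": "clinical finding", "parent": null, "data_properties": ["English name", "nonpreferred term", "state"], "source": "SNOMED CT"},
    {"name": "test", "parent": null, "data_properties": ["English name", "nonpreferred term"], "source": "SNOMED CT; ICD-10"},
    {"name": "treatment", "parent": null, "data_properties": ["English name", "nonpreferred term"], "source": "NCI Metathesaurus"},
    {"name": "body structure", "parent": null, "data_properties": ["English name", "nonpreferred term"], "source": "SNOMED CT"},
    {"name": "noncancerous disease", "parent": "disease", "data_properties": [], "source": "SNOMED CT; ICD-10"},
    {"name": "cancer", "parent": "disease", "data_properties": [], "source": "SNOMED CT; ICD-10"},
    {"name": "symptom", "parent": "clinical finding", "data_properties": [], "source": "SNOMED CT"},
    {"name": "sign", "parent": "clinical finding", "data_properties": [], "source": "SNOMED CT"},
    {"name": "surgery", "parent": "treatment", "data_properties": [], "source": "NCI Metathesaurus"},
    {"name": "medicine", "parent": "treatment", "data_properties": [], "source": "NCI Metathesaurus"},
    {"name": "radiotherapy", "parent": "treatment", "data_properties": [], "source": "NCI Metathesaurus"},
    {"name": "laboratory test", "parent": "test", "data_properties": [], "source": "configurable placeholder"},
    {"name": "imaging test", "parent": "test", "data_properties": [], "source": "configurable placeholder"},
    {"name": "endoscopy", "parent": "test", "data_properties": [], "source": "configurable placeholder"},
    {"name": "pathology test", "parent": "test", "data_properties": [], "source": "configurable placeholder"}
  ],
  "relations": [
    {"label": "TeCD", "definition": "Test is conducted to investigate the disease.", "coarse_category": "Test-disease relation", "structural": false,
     "pairs": [{"head": "test", "tail": "disease"}]},
    {"label": "TeRD", "definition": "Test reveals the disease.", "coarse_category": "Test-disease relation", "structural": false,
     "pairs": [{"head": "test", "tail": "disease"}]},
    {"label": "TeRS", "definition": "Test reveals the symptoms and signs.", "coarse_category": "Test-clinical finding relation", "structural": false,
     "pairs": [{"head": "test", "tail": "clinical finding"}]},
    {"label": "TeAS", "definition": "Test is administered for the symptoms and signs.", "coarse_category": "Test-clinical finding relation", "structural": false,
     "pairs": [{"head": "test", "tail": "clinical finding"}]},
    {"label": "TrAD", "definition": "Treatment is administered for the disease.", "coarse_category": "Treatment-disease relation", "structural": false,
     "pairs": [{"head": "treatment", "tail": "disease"}]},
    {"label": "TrCD", "definition": "Treatment causes the disease.", "coarse_category": "Treatment-disease relation", "structural": false,
     "pairs": [{"head": "treatment", "tail": "disease"}]},
    {"label": "TrAS", "definition": "Treatment is administered for the symptoms and signs.", "coarse_category": "Treatment-clinical finding relation", "structural": false,
     "pairs": [{"head": "treatment", "tail": "clinical finding"}]},
    {"label": "TrCS", "definition": "Treatment causes the symptoms and signs.", "coarse_category": "Treatment-clinical finding relation", "structural": false,
     "pairs": [{"head": "treatment", "tail": "clinical finding"}]},
    {"label": "DCS", "definition": "Disease causes symptoms and signs.", "coarse_category": "Disease-clinical finding relation", "structural": false,
     "pairs": [{"head": "disease", "tail": "clinical finding"}]},
    {"label": "SID", "definition": "Symptoms and signs indicate the disease.", "coarse_category": "Disease-clinical finding relation", "structural": false,
     "pairs": [{"head": "clinical finding", "tail": "disease"}]},
    {"label": "CLAS", "definition": "Cancer disease type", "coarse_category": "Disease-disease type relation", "structural": false,
     "pairs": [{"head": "disease", "tail": "disease type"}]},
    {"label": "LOCI", "definition": "Symptoms and signs are located in the body structure.", "coarse_category": "Clinical finding-body structure relation", "structural": false,
     "pairs": [{"head": "clinical finding", "tail": "body structure"}, {"head": "disease", "tail": "body structure"}]},
    {"label": "has_a", "definition": "The patient has a certain disease, clinical finding, test, or treatment.", "coarse_category": "Patient-disease, clinical finding, test, and treatment relation", "structural": false,
     "pairs": [{"head": "patient", "tail": "disease"}, {"head": "patient", "tail": "clinical finding"}, {"head": "patient", "tail": "test"}, {"head": "patient", "tail": "treatment"}]},
    {"label": "attribute_of", "definition": "Connects a concept with its data property values.", "coarse_category": "Structural", "structural": true,
     "pairs": [{"head": "any-concept", "tail": "any-concept"}]},
    {"label": "instance_of", "definition": "Connects a concept with its entities.", "coarse_category": "Structural", "structural": true,
     "pairs": [{"head": "any-concept", "tail": "any-concept"}]},
    {"label": "is_a", "definition": "Connects a concept with its hyponym.", "coarse_category": "Structural", "structural": true,
     "pairs": [{"head": "any-concept", "tail": "any-concept"}]}
  ]
}
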