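pt	low_level	broad	manual
Case-Control Studies	Observational Epidemiologic Study Designs	Observational Clinical Research	FALSE
Cross-Sectional Studies	Observational Epidemiologic Study Designs	Observational Clinical Research	FALSE
Longitudinal Studies	Observational Epidemiologic Study Designs	Observational Clinical Research	FALSE
Cohort Studies	Observational Epidemiologic Study Designs	Observational Clinical Research	FALSE
Retrospective Studies	Observational Epidemiologic Study Designs	Observational Clinical Research	FALSE
Multicentre Study	General Clinical & Observational Studies	Observational Clinical Research	FALSE
Clinical Study	General Clinical & Observational Studies	Observational Clinical Research	FALSE
Prospective Studies	General Clinical & Observational Studies	Observational Clinical Research	FALSE
Follow-Up Studies	General Clinical & Observational Studies	Observational Clinical Research	FALSE
Observational Study	General Clinical & Observational Studies	Observational Clinical Research	FALSE
Cross-Cultural Comparison	Qualitative & Sociocultural Research Methods	Qualitative & Genetic Methods	FALSE
Focus Groups	Qualitative & Sociocultural Research Methods	Qualitative & Genetic Methods	FALSE
Interviews as Topic	Qualitative & Sociocultural Research Methods	Qualitative & Genetic Methods	FALSE
Genome-Wide Association Study	Genetic & Matched Population Analyses	Qualitative & Genetic Methods	FALSE
Matched-Pair Analysis	Genetic & Matched Population Analyses	Qualitative & Genetic Methods	FALSE
Twin Study	Genetic & Matched Population Analyses	Qualitative & Genetic Methods	FALSE
Case Reports	Clinical Case-Based Evidence	Clinical Evaluation & Validation	FALSE
Case Series	Clinical Case-Based Evidence	Clinical Evaluation & Validation	FALSE
Diagnostic Test Accuracy	Diagnostic & Methodological Validation Studies	Clinical Evaluation & Validation	FALSE
Predictive Value of Tests	Diagnostic & Methodological Validation Studies	Clinical Evaluation & Validation	FALSE
Reproducibility of Results	Diagnostic & Methodological Validation Studies	Clinical Evaluation & Validation	FALSE
Validation Study	Diagnostic & Methodological Validation Studies	Clinical Evaluation & Validation	FALSE
Evaluation Studies as Topic	Program & Process Evaluation Studies	Clinical Evaluation & Validation	FALSE
Evaluation Study	Program & Process Evaluation Studies	Clinical Evaluation & Validation	FALSE
Feasibility Studies	Program & Process Evaluation Studies	Clinical Evaluation & Validation	FALSE
Clinical Trial, Phase I	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Clinical Trial, Phase II	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Clinical Trial, Phase III	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Clinical Trial, Phase IV	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Clinical Trial Protocol	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Pragmatic Clinical Trial	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Adaptive Clinical Trial	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Equivalence Trial	Interventional Clinical Trial Phases & Designs	Interventional Trial Research	FALSE
Clinical Trial, Veterinary	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Randomized Controlled Trial, Veterinary	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Cross-Over Studies	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Double-Blind Method	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Clinical Trial	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Controlled Clinical Trial	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Random Allocation	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Randomized Controlled Trial	Controlled & Randomized Trial Methodology	Interventional Trial Research	FALSE
Practice Guidelines as Topic	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Review	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Systematic Review	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Meta-Analysis	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Meta-Analysis as Topic	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Systematic Reviews as Topic	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Practice Guideline	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Congress	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
Consensus Development Conference	Evidence Synthesis & Clinical Guidance	Scholarly Discourse and Evidence Synthesis	FALSE
News	Scientific Commentary & Professional Discourse	Scholarly Discourse and Evidence Synthesis	FALSE
Letter	Scientific Commentary & Professional Discourse	Scholarly Discourse and Evidence Synthesis	FALSE
Comment	Scientific Commentary & Professional Discourse	Scholarly Discourse and Evidence Synthesis	FALSE
Editorial	Scientific Commentary & Professional Discourse	Scholarly Discourse and Evidence Synthesis	FALSE
Clinical Conference	Scientific Commentary & Professional Discourse	Scholarly Discourse and Evidence Synthesis	FALSE
Lecture	Scientific Commentary & Professional Discourse	Scholarly Discourse and Evidence Synthesis	FALSE
Legal Case	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Portrait	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Biography	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Historical Article	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Interview	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Autobiography	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Personal Narrative	Biographical, Historical & Narrative Works	Scholarly Discourse and Evidence Synthesis	FALSE
Scientific Integrity Review	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	TRUE
Clinical Studies as Topic	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Clinical Trials As Topic	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Human Experimentation	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Newspaper Article	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Bibliography	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Expression of Concern	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Published Erratum	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
Retraction of Publication	Scholarly Publishing & Research Integrity	Scholarly Discourse and Evidence Synthesis	FALSE
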