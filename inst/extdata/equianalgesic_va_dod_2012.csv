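drug,factor,citation
hydromorphone,4,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
oxymorphone,3,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
methadone,1.5,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
oxycodone,2,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
hydrocodone,1,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
morphine,1,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
tramadol,0.3,"VA/DoD Clinical Practice Guideline for Management of Opioid Therapy for Chronic Pain, 2012"
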