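{"patient_id":"P001","note_id":"P001-N01","timestamp":"2023-03-01T08:10:00","text":"Pt remains confused and agitated overnight. Became agitated and required frequent reorientation. Vital signs stable overnight."}
{"patient_id":"P001","note_id":"P001-N02","timestamp":"2023-03-02T07:55:00","text":"Altered mental status with inattention noted. Restraints applied for agitation per protocol. Tolerating diet well."}
{"patient_id":"P001","note_id":"P001-N03","timestamp":"2023-03-03T08:30:00","text":"Mental status improving. No evidence of delirium today. Plan to continue current antibiotics."}
{"patient_id":"P002","note_id":"P002-N01","timestamp":"2023-03-01T09:00:00","text":"No evidence of delirium at this time. Patient alert and oriented x3, no confusion. Ambulating in hallway with physical therapy."}
{"patient_id":"P002","note_id":"P002-N02","timestamp":"2023-03-02T09:05:00","text":"Wife confused about medication schedule. Family meeting held to discuss goals of care."}
{"patient_id":"P003","note_id":"P003-N01","timestamp":"2023-03-04T10:15:00","text":"Dr. Lee reviewed labs. Denies hallucination and is not agitated. Social work following for placement."}
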