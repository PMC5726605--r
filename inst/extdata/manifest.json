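{
 "description": "Group-level connection-probability matrices (percent of 24 participants with a suprathreshold pathway, individual threshold 2.5% of streamlines) and reference network metrics, transcribed from the published tables.",
 "n_nodes": 43,
 "n_subjects": 24,
 "n_cells": 903,
 "tables": {
  "1": "intra-temporal (20 ROIs, upper triangle)",
  "2": "temporal x fronto-parietal (20 x 23, full rectangle)",
  "3": "fronto-parietal (23 ROIs, upper triangle)"
 },
 "bold_rule": "bold flags mark cells reported suprathreshold in at least 12/24 participants (percent >= 50.0)",
 "flagged_cells": [
  {
   "row": "MED",
   "col": "mFG",
   "percent": 50.0,
   "bold": false,
   "note": "percent >= 50 but printed without bold; bold/percent rules disagree here"
  },
  {
   "row": "aITG",
   "col": "pFG",
   "percent": 54.2,
   "bold": false,
   "note": "percent >= 50 but printed without bold; bold/percent rules disagree here"
  }
 ],
 "table4_degree_note": "the reference degree column sums to 380 (190 edges) while the bold cells define 194 edges; six nodes (mSTG, mMTG, medOFC, latOFC, PF, PFcm) have reference degree below the bold-cell count, an inconsistency internal to the source tables that is reported, not corrected"
}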