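[
 {
  "param_id": "p_any_to_bsc",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.0542,
  "x3dcrt": 0.0542,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_rp_g1",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.095,
  "x3dcrt": 0.046,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_rp_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.005,
  "x3dcrt": 0.053,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_rp_g3",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.0025,
  "x3dcrt": 0.026,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_rp_g1_pe_g1",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.157,
  "x3dcrt": 0.179,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_rp_g1_pce_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.076,
  "x3dcrt": 0.081,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_pe_g1",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.008,
  "x3dcrt": 0.041,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_pe_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.017,
  "x3dcrt": 0.015,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_pe_g3",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0,
  "x3dcrt": 0.06,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_pce_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.0024,
  "x3dcrt": 0.02,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_pce_g3",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.001,
  "x3dcrt": 0.075,
  "perturbable": true
 },
 {
  "param_id": "p_noae_to_pce_g3_pe_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.003,
  "x3dcrt": 0.028,
  "perturbable": true
 },
 {
  "param_id": "p_rp_g3_to_rp_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.25,
  "x3dcrt": 0.25,
  "perturbable": true
 },
 {
  "param_id": "p_rp_g2_to_rp_g1",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.25,
  "x3dcrt": 0.25,
  "perturbable": true
 },
 {
  "param_id": "p_pce_g3_to_drainage",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.1,
  "x3dcrt": 0.1,
  "perturbable": true
 },
 {
  "param_id": "p_drainage_to_pce_g2",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 0.617,
  "x3dcrt": 0.617,
  "perturbable": true
 },
 {
  "param_id": "p_bsc_to_death",
  "kind": "probability",
  "family": null,
  "grade": null,
  "pbt": 1,
  "x3dcrt": 1,
  "perturbable": true
 },
 {
  "param_id": "u_no_late_ae",
  "kind": "utility",
  "family": null,
  "grade": null,
  "pbt": 0.91,
  "x3dcrt": 0.91,
  "perturbable": true
 },
 {
  "param_id": "u_rp_g1",
  "kind": "utility",
  "family": "rp",
  "grade": 1,
  "pbt": 0.87,
  "x3dcrt": 0.87,
  "perturbable": true
 },
 {
  "param_id": "u_rp_g2",
  "kind": "utility",
  "family": "rp",
  "grade": 2,
  "pbt": 0.83,
  "x3dcrt": 0.83,
  "perturbable": true
 },
 {
  "param_id": "u_rp_g3",
  "kind": "utility",
  "family": "rp",
  "grade": 3,
  "pbt": 0.54,
  "x3dcrt": 0.54,
  "perturbable": true
 },
 {
  "param_id": "u_pe_g1",
  "kind": "utility",
  "family": "pe",
  "grade": 1,
  "pbt": 0.87,
  "x3dcrt": 0.87,
  "perturbable": true
 },
 {
  "param_id": "u_pe_g2",
  "kind": "utility",
  "family": "pe",
  "grade": 2,
  "pbt": 0.76,
  "x3dcrt": 0.76,
  "perturbable": true
 },
 {
  "param_id": "u_pe_g3",
  "kind": "utility",
  "family": "pe",
  "grade": 3,
  "pbt": 0.58,
  "x3dcrt": 0.58,
  "perturbable": true
 },
 {
  "param_id": "u_pce_g2",
  "kind": "utility",
  "family": "pce",
  "grade": 1,
  "pbt": 0.87,
  "x3dcrt": 0.87,
  "perturbable": true
 },
 {
  "param_id": "u_pce_g3",
  "kind": "utility",
  "family": "pce",
  "grade": 2,
  "pbt": 0.63,
  "x3dcrt": 0.63,
  "perturbable": true
 },
 {
  "param_id": "u_pce_g3_pe_g2",
  "kind": "utility",
  "family": "pce",
  "grade": 3,
  "pbt": 0.57,
  "x3dcrt": 0.57,
  "perturbable": true
 },
 {
  "param_id": "u_rp_g1_pe_g1",
  "kind": "utility",
  "family": null,
  "grade": null,
  "pbt": 0.87,
  "x3dcrt": 0.87,
  "perturbable": true
 },
 {
  "param_id": "u_rp_g1_pce_g2",
  "kind": "utility",
  "family": null,
  "grade": null,
  "pbt": 0.87,
  "x3dcrt": 0.87,
  "perturbable": true
 },
 {
  "param_id": "u_resolved_pce",
  "kind": "utility",
  "family": null,
  "grade": null,
  "pbt": 0.87,
  "x3dcrt": 0.87,
  "perturbable": true
 },
 {
  "param_id": "u_bsc",
  "kind": "utility",
  "family": null,
  "grade": null,
  "pbt": 0.32,
  "x3dcrt": 0.32,
  "perturbable": true
 },
 {
  "param_id": "c_3dcrt_fee",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 727600,
  "x3dcrt": 727600,
  "perturbable": false
 },
 {
  "param_id": "c_admission_crt",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 1325370,
  "x3dcrt": 1325370,
  "perturbable": true
 },
 {
  "param_id": "c_followup_year1",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 45615,
  "x3dcrt": 45615,
  "perturbable": true
 },
 {
  "param_id": "c_followup_later",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 28480,
  "x3dcrt": 28480,
  "perturbable": true
 },
 {
  "param_id": "c_rp_g2",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 62160,
  "x3dcrt": 62160,
  "perturbable": true
 },
 {
  "param_id": "c_rp_g3",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 571120,
  "x3dcrt": 571120,
  "perturbable": true
 },
 {
  "param_id": "c_pe_g2_year1",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 47165,
  "x3dcrt": 47165,
  "perturbable": true
 },
 {
  "param_id": "c_pe_g2_later",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 30030,
  "x3dcrt": 30030,
  "perturbable": true
 },
 {
  "param_id": "c_pe_g3",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 302700,
  "x3dcrt": 302700,
  "perturbable": true
 },
 {
  "param_id": "c_drainage",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 448220,
  "x3dcrt": 448220,
  "perturbable": true
 },
 {
  "param_id": "c_pericardiotomy",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 595641,
  "x3dcrt": 595641,
  "perturbable": true
 },
 {
  "param_id": "c_bsc",
  "kind": "cost",
  "family": null,
  "grade": null,
  "pbt": 632100,
  "x3dcrt": 632100,
  "perturbable": true
 }
]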