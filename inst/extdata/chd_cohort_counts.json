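{
  "description": "Summary counts of a reference CHD screening cohort (synthetic reconstruction from published per-branch totals; no patient-level data). 22 affected patients; 7 with no extractable four-chamber view; the 15 extractable patients contributed 2 images each.",
  "n_patients": 22,
  "n_nonextractable": 7,
  "images_per_video": 2,
  "branches": {
    "unet3p": { "abnormal_images": 19, "abnormal_patients": 10 },
    "segformer": { "abnormal_images": 20, "abnormal_patients": 11 }
  }
}
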