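# Bundled reference tables

Small plain-text fixtures transcribed from the published summary tables of
the eight-blend cold-pressed oil study that this package models. They hold
replicate *summaries* (means, SDs, n) only — no raw instrument data was ever
deposited, so raw-shaped inputs are produced by the seeded generators in
`R/synthetic_data.R` instead.

- `blend_fatty_acid_profiles.csv` — mean fatty-acid composition (% of total
  fatty acids) and per-acid SD for the 8 blends; `nd` = not detected.
- `blend_reference_indices.csv` — published nutritional indices, calculated
  iodine value and omega-6/omega-3 ratio, used as cross-check references.
- `blend_heating_tpc.csv` — total polar compounds (%) per blend x heating
  condition, mean ± SD, n = 4.
- `blend_relaxometry_dsc.csv` — water content, T1/T2 relaxation times, mean
  correlation time and oxidation induction time per blend.
- `blend_recipes.csv` — component oils and mass fractions of each blend.
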