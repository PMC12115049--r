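Synthetic example survey (not field data).

Generated with metalsource::simulate_survey(make_scenario(seed = 101)):
36 paired soil/plant samples, 4 species, 7 metals, on the
"kalamaili-like" preset (two factories, a railway, two highways, known
per-metal source shares). Values rounded to 6 significant digits.

soil.csv    sample_id, x, y (planar km), 7 metal columns (mg/kg)
plants.csv  sample_id, species, x, y, 7 metal columns (mg/kg)
sources.csv name, vertex, x, y (points have one vertex, polylines several)
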