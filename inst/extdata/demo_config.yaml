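# Demo run configuration: three small synthetic fields (one per marker),
# quantification, inclusion-stratified statistics and the expression stage.
seed: 1
output_dir: "maptquant_out"
alpha: 0.01
percentile_q: 95
um_per_px: 0.5
simulate:
  n_fields: 3
  marker_types: ["neuron", "oligodendrocyte", "astrocyte"]
  cells_per_type:
    neuron: 12
    oligodendrocyte: 12
    astrocyte: 12
  field_size: [448, 448]
  expr:
    n_cells_per_group: 300
quantify:
  transcript_method: "otsu"
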