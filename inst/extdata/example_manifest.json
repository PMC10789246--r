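{
  "n_frames": 20,
  "n_atoms": 24,
  "n_residues": 6,
  "format": "gro",
  "events": [
    {
      "kind": "step_displacement",
      "region": "2-4",
      "onset_frame": 11,
      "displacement": [3, 4, 0],
      "ramp_frames": 0
    }
  ]
}
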