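# Minimal greenhouse layout: one passage of 4 sections, 4 beacons on the
# two flanking ridges. Lengths in metres.
n_passages: 1
n_sections_x: 4
field_length_x: 12.0
field_width_y: 2.0
end_sections: [0, 3]
beacons:
- beacon_id: B1
  x: 1.5
  y: 0.0
  ridge: 0
- beacon_id: B2
  x: 7.5
  y: 0.0
  ridge: 0
- beacon_id: B3
  x: 4.5
  y: 2.0
  ridge: 1
- beacon_id: B4
  x: 10.5
  y: 2.0
  ridge: 1
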