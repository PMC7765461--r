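# Default four-band UAV camera definition (center/full-width, nm).
bands:
  - {name: green, center_nm: 550, width_nm: 40, shape: boxcar}
  - {name: red, center_nm: 660, width_nm: 40, shape: boxcar}
  - {name: red_edge, center_nm: 735, width_nm: 10, shape: boxcar}
  - {name: nir, center_nm: 790, width_nm: 40, shape: boxcar}
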