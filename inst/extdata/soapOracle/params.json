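{
  "description": "Frozen reference SOAP power spectra (matched-convention oracle) for the structures in structures.xyz, one row per structure, center = atom 0 (Zn), columns in the package's flattened layout.",
  "species": [
    "H",
    "C",
    "Zn"
  ],
  "rCut": 4.0,
  "nMax": 3,
  "lMax": 3,
  "sigmaAtom": 0.5,
  "rbf": "gto",
  "cutoffWidth": 0.0,
  "centerIndex": 0,
  "nStructures": 20,
  "descriptorLength": 180,
  "referenceLibrary": "dscribe 2.x (SOAP, periodic=False)"
}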