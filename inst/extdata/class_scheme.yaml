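# Subcellular localization class scheme: 31 fine annotation labels and the
# 19 grouped competition classes. Grouped ids are 0-based; Negative is last.
# Fine labels with group DISCARDED have no grouped destination and are
# dropped during grouping.
version: 1
grouped_classes:
  - Nucleoplasm
  - Nuclear membrane
  - Nucleoli
  - Nucleolar fibrillar center
  - Nuclear speckles
  - Nuclear bodies
  - Endoplasmic reticulum
  - Golgi apparatus
  - Intermediate filaments
  - Actin filaments
  - Microtubules
  - Mitotic spindle
  - Centrosome
  - Plasma membrane
  - Mitochondria
  - Aggresome
  - Cytosol
  - Vesicles and punctate cytosolic pattern
  - Negative
fine_labels:
  - {name: Nucleoplasm, group: Nucleoplasm}
  - {name: Nuclear membrane, group: Nuclear membrane}
  - {name: Nucleoli, group: Nucleoli}
  - {name: Nucleolar fibrillar center, group: Nucleolar fibrillar center}
  - {name: Nuclear speckles, group: Nuclear speckles}
  - {name: Nuclear bodies, group: Nuclear bodies}
  - {name: Endoplasmic reticulum, group: Endoplasmic reticulum}
  - {name: Golgi apparatus, group: Golgi apparatus}
  - {name: Peroxisomes, group: Vesicles and punctate cytosolic pattern}
  - {name: Endosomes, group: Vesicles and punctate cytosolic pattern}
  - {name: Lysosomes, group: Vesicles and punctate cytosolic pattern}
  - {name: Intermediate filaments, group: Intermediate filaments}
  - {name: Actin filaments, group: Actin filaments}
  - {name: Focal adhesion sites, group: Actin filaments}
  - {name: Microtubules, group: Microtubules}
  - {name: Microtubule ends, group: DISCARDED}
  - {name: Mitotic spindle, group: Mitotic spindle}
  - {name: Centrosome, group: Centrosome}
  - {name: Lipid droplets, group: Vesicles and punctate cytosolic pattern}
  - {name: Plasma membrane, group: Plasma membrane}
  - {name: Cell Junctions, group: Plasma membrane}
  - {name: Mitochondria, group: Mitochondria}
  - {name: Aggresome, group: Aggresome}
  - {name: Cytosol, group: Cytosol}
  - {name: Cytoplasmic bodies, group: Vesicles and punctate cytosolic pattern}
  - {name: Rods and Rings, group: DISCARDED}
  - {name: Cleavage furrow, group: DISCARDED}
  - {name: Centriolar satellite, group: Centrosome}
  - {name: Vesicles, group: Vesicles and punctate cytosolic pattern}
  - {name: Mitotic chromosome, group: DISCARDED}
  - {name: Negative/Unspecific, group: Negative}
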