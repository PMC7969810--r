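# Pharmacophore feature perception rules (editable; see ?feature_rules).
# Catalyst-style conventions: acceptors are N/O with an available lone pair
# and no positive charge (amide and trisubstituted aromatic N excluded),
# donors are N-H / O-H, hydrophobes are connected nonpolar-carbon components
# collapsed to centroids, aromatic rings are 5/6-membered C/N rings.
# Element symbols are quoted: bare N/Y are YAML booleans.
version: "1.0"
hba_elements: ["N", "O"]
hbd_elements: ["N", "O"]
hba_exclude_amide_n: true
hy_min_size: 3
hy_polar_neighbours: ["N", "O", "F", "S", "P"]
aromatic_ring_sizes: [5, 6]
projected_points: false
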