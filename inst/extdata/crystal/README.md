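# Crystal-structure worked example (user-supplied inputs)

Place here, to enable the optional real-data check (the four-tryptophan
dihedral of two diabody crystal structures that share the same value, about
77 degrees, despite different overall conformations):

* `5fcs.pdb`, `5iwl.pdb` — the PDB entries (https://files.rcsb.org/download/);
  they are not redistributed with this package.
* `5fcs.yaml`, `5iwl.yaml` — anchor configs in the schema of
  `?read_domain_definition`, declaring per site the V_H/V_L selections and
  the anchor tryptophans (Kabat W36 in V_H, W35 in V_L, as explicit
  chain/resno references in each entry's own numbering).

With the files present, the crystal-structure block of the test suite and
the `crystal_dihedral_*` entries of `scripts/acceptance.R` run automatically.
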