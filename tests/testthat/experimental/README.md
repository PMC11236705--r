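# Experimental reference data (not redistributed)

Three acceptance checks in `test-acceptance.R` compare package metrics
against values measured on experimentally solved structures. The coordinate
and sequence files are third-party PDB data and are not shipped with the
package; to run those checks, place the following files in this directory:

| file                  | contents                                                              |
|-----------------------|-----------------------------------------------------------------------|
| `clf4_xray.pdb`       | X-ray structure of the solubilized claudin-fold design (PDB 8OYV)     |
| `claudin_target.pdb`  | claudin design target fold (derived from PDB 4P79, loops rebuilt)     |
| `rpf9_xray.pdb`       | X-ray structure of the solubilized rhomboid-fold design (PDB 8OYW)    |
| `rhomboid_target.pdb` | rhomboid protease design target fold (PDB 3ZEB)                       |
| `glf18_xray.pdb`      | X-ray structure of the solubilized GPCR-fold design (PDB 8OYX)        |
| `gpcr_target.pdb`     | GPCR design target fold (derived from PDB 6FFI)                       |
| `gpcr_native.pdb`     | native GPCR reference, crystallization fusion removed (6FFI, residues 679-838 deleted) |
| `clf_designs.fasta`   | sequences of the characterized claudin-fold designs                   |
| `claudin_native.fasta`| native claudin sequence                                               |

Structures must be trimmed to matching residue ranges for the index-wise
correspondence the checks use. Without these files the three checks fail
with a "reference file not available offline" error; all other tests are
self-contained.
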