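Reference data drop-in directory.

The DnaK-specific checks and report fields use the ATP-bound DnaK crystal
structure, PDB entry 4B9Q, which is not redistributed with the package.
Download 4B9Q.pdb from the Protein Data Bank and place it in this directory
of the *installed* package (the path printed by
allomap::dnak_structure_file()), or point
options(allomap.dnak_structure = "/path/to/4B9Q.pdb") at a copy.
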