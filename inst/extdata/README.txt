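Place the crystal structure of the autoinhibited kinase dimer here as
"3alo.pdb" (RCSB entry 3ALO, https://files.rcsb.org/download/3ALO.pdb)
to activate the three crystal-reference acceptance tests (per-subunit
apex angles and interval-shift validation). The file is not bundled:
it is not redistributable with the package and the build environment
has no network access. All other fixtures are generated in code.
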