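REMARK synthetic test fragment: two models of a six-residue portal-loop
REMARK stretch (resid 55-60, chain A) with one water and one ligand atom.
REMARK hand-built for parser tests; not derived from any deposited entry.
MODEL        1
ATOM      1  N   LEU A  55      10.000   5.000   3.000  1.00  0.00           N
ATOM      2  CA  LEU A  55      11.200   5.600   3.400  1.00  0.00           C
ATOM      3  C   LEU A  55      12.400   4.800   3.000  1.00  0.00           C
ATOM      4  O   LEU A  55      12.500   3.700   3.500  1.00  0.00           O
ATOM      5  CB  LEU A  55      11.300   7.000   2.800  1.00  0.00           C
ATOM      6  N   GLY A  56      13.300   5.300   2.200  1.00  0.00           N
ATOM      7  CA  GLY A  56      14.500   4.600   1.800  1.00  0.00           C
ATOM      8  C   GLY A  56      15.700   5.400   2.300  1.00  0.00           C
ATOM      9  O   GLY A  56      15.800   6.600   2.000  1.00  0.00           O
ATOM     10  N   PHE A  57      16.600   4.700   3.000  1.00  0.00           N
ATOM     11  CA  PHE A  57      17.800   5.300   3.600  1.00  0.00           C
ATOM     12  CB  PHE A  57      17.500   6.300   4.700  1.00  0.00           C
ATOM     13  CG  PHE A  57      18.700   7.000   5.300  1.00  0.00           C
ATOM     14  CD1 PHE A  57      19.300   8.100   4.700  1.00  0.00           C
ATOM     15  CD2 PHE A  57      19.200   6.500   6.500  1.00  0.00           C
ATOM     16  C   PHE A  57      18.800   4.300   4.200  1.00  0.00           C
ATOM     17  O   PHE A  57      18.500   3.100   4.300  1.00  0.00           O
ATOM     18  N   LYS A  58      20.000   4.800   4.600  1.00  0.00           N
ATOM     19  CA  LYS A  58      21.100   4.000   5.200  1.00  0.00           C
ATOM     20  CB  LYS A  58      21.700   3.000   4.200  1.00  0.00           C
ATOM     21  N   THR A  59      22.200   4.900   5.700  1.00  0.00           N
ATOM     22  CA  THR A  59      23.400   4.300   6.300  1.00  0.00           C
ATOM     23  N   VAL A  60      24.500   5.200   6.700  1.00  0.00           N
ATOM     24  CA  VAL A  60      25.700   4.700   7.400  1.00  0.00           C
TER      25      VAL A  60
HETATM   26  C1  PLM A 201      15.000   6.000   6.000  1.00  0.00           C
HETATM   27  O   HOH A 301      13.000   9.000   6.000  1.00  0.00           O
ENDMDL
MODEL        2
ATOM      1  N   LEU A  55      10.100   5.100   3.100  1.00  0.00           N
ATOM      2  CA  LEU A  55      11.300   5.700   3.500  1.00  0.00           C
ATOM      3  C   LEU A  55      12.500   4.900   3.100  1.00  0.00           C
ATOM      4  O   LEU A  55      12.600   3.800   3.600  1.00  0.00           O
ATOM      5  CB  LEU A  55      11.400   7.100   2.900  1.00  0.00           C
ATOM      6  N   GLY A  56      13.400   5.400   2.300  1.00  0.00           N
ATOM      7  CA  GLY A  56      14.600   4.700   1.900  1.00  0.00           C
ATOM      8  C   GLY A  56      15.800   5.500   2.400  1.00  0.00           C
ATOM      9  O   GLY A  56      15.900   6.700   2.100  1.00  0.00           O
ATOM     10  N   PHE A  57      16.700   4.800   3.100  1.00  0.00           N
ATOM     11  CA  PHE A  57      17.900   5.400   3.700  1.00  0.00           C
ATOM     12  CB  PHE A  57      17.600   6.400   4.800  1.00  0.00           C
ATOM     13  CG  PHE A  57      18.800   7.100   5.400  1.00  0.00           C
ATOM     14  CD1 PHE A  57      19.400   8.200   4.800  1.00  0.00           C
ATOM     15  CD2 PHE A  57      19.300   6.600   6.600  1.00  0.00           C
ATOM     16  C   PHE A  57      18.900   4.400   4.300  1.00  0.00           C
ATOM     17  O   PHE A  57      18.600   3.200   4.400  1.00  0.00           O
ATOM     18  N   LYS A  58      20.100   4.900   4.700  1.00  0.00           N
ATOM     19  CA  LYS A  58      21.200   4.100   5.300  1.00  0.00           C
ATOM     20  CB  LYS A  58      21.800   3.100   4.300  1.00  0.00           C
ATOM     21  N   THR A  59      22.300   5.000   5.800  1.00  0.00           N
ATOM     22  CA  THR A  59      23.500   4.400   6.400  1.00  0.00           C
ATOM     23  N   VAL A  60      24.600   5.300   6.800  1.00  0.00           N
ATOM     24  CA  VAL A  60      25.800   4.800   7.500  1.00  0.00           C
TER      25      VAL A  60
HETATM   26  C1  PLM A 201      15.100   6.100   6.100  1.00  0.00           C
HETATM   27  O   HOH A 301      13.100   9.100   6.100  1.00  0.00           O
ENDMDL
END
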