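#!/usr/bin/env python
"""Deterministic single-conformer 3D embedding.

Reads a tab-separated file of (compound_id, smiles, seed) rows, embeds one
conformer per molecule with ETKDG distance geometry at the given random
seed, minimizes it with MMFF94 (UFF fallback), and writes an SDF whose
molecule titles are the compound ids. Molecules that fail to parse or
embed are skipped; the caller detects them by their absent title.

Usage: embed_conformers.py <input.tsv> <output.sdf>
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed_one(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(mol, params) != 0:
        return None
    try:
        if AllChem.MMFFHasAllMoleculeParams(mol):
            AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
        else:
            AllChem.UFFOptimizeMolecule(mol, maxIters=500)
    except Exception:
        pass  # an unminimized conformer is still usable
    return mol


def main(inp, out):
    writer = Chem.SDWriter(out)
    writer.SetKekulize(True)
    with open(inp) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smiles, seed = line.split("\t")
            mol = embed_one(smiles, seed)
            if mol is None:
                continue
            mol.SetProp("_Name", cid)
            writer.write(mol)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
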