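#!/usr/bin/env python
"""Per-atom property backend for fragment-pooled descriptors.

Reads JSON on stdin:  {"smiles": ["...", ...], "radii": [2, 4, 6]}
Writes JSON on stdout: a list with one record per molecule:
  {
    "valid": bool, "error": str|None, "canonical": str, "n_atoms": int,
    "anchor": int,            # carboxyl carbon, 0-based
    "n_anchors": int,         # number of carboxyl groups found
    "levels": [[...], ...],   # 0-based atom indices within each bond radius
    "bonds": [[i, j], ...],   # 0-based bond list (for independent BFS checks)
    "props": {"PEOE_charge": [...], "LogP": [...], "MR": [...],
              "LabuteASA": [...], "TPSA": [...]}   # per-atom contributions
  }
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdMolDescriptors, rdPartialCharges, rdmolops

RDLogger.DisableLog("rdApp.*")

ANCHOR = Chem.MolFromSmarts("[CX3](=[OX1])[OX2H1,OX1-]")


def process(smiles, radii):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"valid": False, "error": "unparsable SMILES"}
    matches = mol.GetSubstructMatches(ANCHOR, uniquify=True)
    if not matches:
        return {"valid": True, "error": "no carboxyl anchor",
                "canonical": Chem.MolToSmiles(mol),
                "n_atoms": mol.GetNumAtoms(), "n_anchors": 0}
    # first anchor by atom index of the carboxyl carbon
    anchor = sorted(m[0] for m in matches)[0]
    dm = rdmolops.GetDistanceMatrix(mol)
    levels = [sorted(i for i in range(mol.GetNumAtoms())
                     if dm[anchor][i] <= r) for r in radii]

    rdPartialCharges.ComputeGasteigerCharges(mol)
    peoe = [a.GetDoubleProp("_GasteigerCharge") for a in mol.GetAtoms()]
    crippen = rdMolDescriptors._CalcCrippenContribs(mol)
    logp = [c[0] for c in crippen]
    mr = [c[1] for c in crippen]
    labute = list(rdMolDescriptors._CalcLabuteASAContribs(mol)[0])
    tpsa = list(rdMolDescriptors._CalcTPSAContribs(mol))
    bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx()] for b in mol.GetBonds()]
    return {
        "valid": True, "error": None,
        "canonical": Chem.MolToSmiles(mol),
        "n_atoms": mol.GetNumAtoms(),
        "anchor": anchor, "n_anchors": len(matches),
        "levels": levels, "bonds": bonds,
        "props": {"PEOE_charge": peoe, "LogP": logp, "MR": mr,
                  "LabuteASA": labute, "TPSA": tpsa},
    }


def main():
    req = json.load(sys.stdin)
    radii = req.get("radii", [2, 4, 6])
    out = [process(s, radii) for s in req["smiles"]]
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
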