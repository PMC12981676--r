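"""Batched SMILES property extraction for the R package.

Reads one JSON object from stdin:
    {"smiles": ["CCO", ...], "fingerprint": false, "kekulize": false}
and writes one JSON array to stdout with, per molecule, either an error
or canonical SMILES, atom property rows, bond list (0-based indices with
bond order as a double) and optionally Morgan fingerprint on-bits
(radius 2, 2048 bits).
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def atom_row(atom):
    cip = ""
    if atom.HasProp("_CIPCode"):
        cip = atom.GetProp("_CIPCode")
    return {
        "sym": atom.GetSymbol(),
        "degree": atom.GetDegree(),
        "charge": atom.GetFormalCharge(),
        "hyb": str(atom.GetHybridization()),
        "numh": atom.GetTotalNumHs(),
        "aromatic": bool(atom.GetIsAromatic()),
        "ring": bool(atom.IsInRing()),
        "cip": cip,
    }


def featurize(smi, want_fp, kekulize):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "error": "unparseable SMILES"}
    if mol.GetNumHeavyAtoms() < 1:
        return {"ok": False, "error": "no heavy atoms"}
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    out = {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "n_atoms": mol.GetNumHeavyAtoms(),
        "atoms": [atom_row(a) for a in mol.GetAtoms()],
    }
    bmol = mol
    if kekulize:
        bmol = Chem.Mol(mol)
        Chem.Kekulize(bmol, clearAromaticFlags=True)
    out["bonds"] = [
        [b.GetBeginAtomIdx(), b.GetEndAtomIdx(), b.GetBondTypeAsDouble()]
        for b in bmol.GetBonds()
    ]
    if want_fp:
        from rdkit.Chem import rdFingerprintGenerator

        gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=2048)
        fp = gen.GetFingerprint(mol)
        out["fp_bits"] = list(fp.GetOnBits())
    return out


def main():
    req = json.load(sys.stdin)
    want_fp = bool(req.get("fingerprint", False))
    kekulize = bool(req.get("kekulize", False))
    res = [featurize(s, want_fp, kekulize) for s in req["smiles"]]
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
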