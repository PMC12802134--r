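"""Structure parsing and fingerprint primitives backed by RDKit.

Reads a JSON request {"what": ..., "structures": [...]} from the file named
by argv[1] and writes a JSON response to argv[2]. Each structure may be a
SMILES or an InChI (detected by the "InChI=" prefix). Unparsable structures
yield null entries rather than aborting the batch.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def to_mol(s):
    if not s:
        return None
    if s.startswith("InChI="):
        return Chem.MolFromInchi(s)
    return Chem.MolFromSmiles(s)


def morgan_bits(mol, n_bits=2048, radius=2):
    fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=n_bits)
    return [int(b) for b in fp.ToBitString()]


def mqn_counts(mol):
    return list(rdMolDescriptors.MQNs_(mol))


def atom_pair_shingles(mol, max_radius=2):
    """Atom-pair shingles: per atom pair, the canonical circular-environment
    SMILES of both atoms at each radius joined with their topological
    distance. The MinHashing itself happens on the caller's side."""
    n = mol.GetNumAtoms()
    if n == 0:
        return []
    dm = Chem.GetDistanceMatrix(mol)
    env_smiles = [[None] * n for _ in range(max_radius)]
    for r in range(1, max_radius + 1):
        for a in range(n):
            env = Chem.FindAtomEnvironmentOfRadiusN(mol, r, a)
            amap = {}
            sub = Chem.PathToSubmol(mol, env, atomMap=amap)
            if a in amap:
                smi = Chem.MolToSmiles(sub, rootedAtAtom=amap[a],
                                       canonical=True)
            else:
                smi = mol.GetAtomWithIdx(a).GetSymbol()
            env_smiles[r - 1][a] = smi
    shingles = set()
    for i in range(n):
        for j in range(i, n):
            d = int(dm[i][j])
            for r in range(max_radius):
                a, b = sorted((env_smiles[r][i], env_smiles[r][j]))
                shingles.add(f"{a}|{d}|{b}")
    return sorted(shingles)


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    what = req["what"]
    out = []
    for s in req["structures"]:
        mol = to_mol(s)
        if mol is None:
            out.append(None)
        elif what == "canonical":
            out.append(Chem.MolToSmiles(mol))
        elif what == "morgan":
            out.append(morgan_bits(mol))
        elif what == "mqn":
            out.append(mqn_counts(mol))
        elif what == "shingles":
            out.append(atom_pair_shingles(mol))
        else:
            raise SystemExit(f"unknown request: {what}")
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
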