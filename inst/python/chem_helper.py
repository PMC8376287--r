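"""Batch chemistry helper.

Called as: python chem_helper.py <request.json> <response.json>

The request is {"op": <string>, "smiles": [<string>, ...], ...options}.
Every op maps the input list positionally; entries that fail to parse map
to null (the caller decides how to treat failures).  This file is the only
place the package touches RDKit.
"""

import json
import sys
import os

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, Lipinski, BRICS, rdMolDescriptors
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit.Chem import RDConfig

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
try:
    import sascorer
    HAVE_SA = True
except ImportError:  # pragma: no cover - Contrib ships with conda rdkit
    HAVE_SA = False


def mol_from_smiles(smi):
    if not isinstance(smi, str) or smi.strip() == "":
        return None
    m = Chem.MolFromSmiles(smi)
    if m is None or m.GetNumAtoms() == 0:
        return None
    return m


def ring_counts(mol):
    """SSSR ring counts: aromatic iff every ring bond is aromatic."""
    ri = mol.GetRingInfo()
    n_arom = 0
    n_alip = 0
    for bond_ring in ri.BondRings():
        if all(mol.GetBondWithIdx(b).GetIsAromatic() for b in bond_ring):
            n_arom += 1
        else:
            n_alip += 1
    return n_alip, n_arom


def sa_score(mol):
    if not HAVE_SA:
        return None
    s = sascorer.calculateScore(mol)
    return min(10.0, max(1.0, s))


def op_parse(smiles, opts):
    out = []
    for smi in smiles:
        m = mol_from_smiles(smi)
        if m is None:
            out.append({"valid": False})
            continue
        n_alip, n_arom = ring_counts(m)
        out.append({
            "valid": True,
            "canonical": Chem.MolToSmiles(m),
            "n_aliphatic_rings": n_alip,
            "n_aromatic_rings": n_arom,
            "n_hba": Lipinski.NumHAcceptors(m),
            "n_hbd": Lipinski.NumHDonors(m),
            "has_charged_atom": any(a.GetFormalCharge() != 0
                                    for a in m.GetAtoms()),
            "mw": Descriptors.MolWt(m),
            "logp": Descriptors.MolLogP(m),
            "sa": sa_score(m),
        })
    return out


def op_fingerprints(smiles, opts):
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(opts.get("radius", 2)),
        fpSize=int(opts.get("nbits", 2048)))
    counts = bool(opts.get("counts", False))
    out = []
    for smi in smiles:
        m = mol_from_smiles(smi)
        if m is None:
            out.append(None)
        elif counts:
            nz = gen.GetCountFingerprint(m).GetNonzeroElements()
            out.append([[int(k), int(v)] for k, v in sorted(nz.items())])
        else:
            out.append(list(gen.GetFingerprint(m).GetOnBits()))
    return out


def op_fragments(smiles, opts):
    out = []
    for smi in smiles:
        m = mol_from_smiles(smi)
        if m is None:
            out.append(None)
        else:
            out.append(sorted(BRICS.BRICSDecompose(m)))
    return out


def op_scaffolds(smiles, opts):
    out = []
    for smi in smiles:
        m = mol_from_smiles(smi)
        if m is None:
            out.append(None)
        else:
            scaf = MurckoScaffold.GetScaffoldForMol(m)
            out.append(Chem.MolToSmiles(scaf) if scaf.GetNumAtoms() else "")
    return out


# Descriptor panel for the Frechet-distance activation surrogate; order is
# part of the contract with the R side.
DESCRIPTOR_NAMES = ["mw", "logp", "tpsa", "hba", "hbd", "rot",
                    "rings", "arom_rings", "fcsp3", "heavy"]


def op_descriptors(smiles, opts):
    out = []
    for smi in smiles:
        m = mol_from_smiles(smi)
        if m is None:
            out.append(None)
            continue
        _, n_arom = ring_counts(m)
        out.append([
            Descriptors.MolWt(m),
            Descriptors.MolLogP(m),
            rdMolDescriptors.CalcTPSA(m),
            float(Lipinski.NumHAcceptors(m)),
            float(Lipinski.NumHDonors(m)),
            float(Lipinski.NumRotatableBonds(m)),
            float(rdMolDescriptors.CalcNumRings(m)),
            float(n_arom),
            float(rdMolDescriptors.CalcFractionCSP3(m)),
            float(m.GetNumHeavyAtoms()),
        ])
    return out


OPS = {
    "parse": op_parse,
    "fingerprints": op_fingerprints,
    "fragments": op_fragments,
    "scaffolds": op_scaffolds,
    "descriptors": op_descriptors,
}


def main():
    req_path, resp_path = sys.argv[1], sys.argv[2]
    with open(req_path) as fh:
        req = json.load(fh)
    op = req["op"]
    if op == "ping":
        result = {"ok": True, "have_sa": HAVE_SA}
    else:
        result = OPS[op](req.get("smiles", []), req)
    with open(resp_path, "w") as fh:
        json.dump({"op": op, "result": result,
                   "descriptor_names": DESCRIPTOR_NAMES}, fh)


if __name__ == "__main__":
    main()
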