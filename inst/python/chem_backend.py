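"""Batch chemistry backend for the skinsens R package.

Invoked as:  python chem_backend.py <op> <in.json> <out.json>

Each op reads one JSON payload and writes one JSON result. All operations are
deterministic; anything stochastic (UMAP) takes an explicit seed.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, MACCSkeys
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

HEAVY_ATOM_CAP_DEFAULT = 100

# Carbon-containing fragments that are recognized counterIONS and may be
# stripped when they accompany a parent organic. Neutral organic solvents are
# deliberately absent: a neutral multi-organic entry is a mixture, not a salt.
_COUNTERION_SMILES = [
    "CC(=O)[O-]",            # acetate
    "[O-]C(=O)C(F)(F)F",     # trifluoroacetate
    "[O-]C=O",               # formate
    "[O-]S(=O)(=O)c1ccc(C)cc1",  # tosylate
    "[O-]S(=O)(=O)C",        # mesylate
    "[O-]C(=O)C(=O)[O-]",    # oxalate
    "[O-]C(=O)/C=C/C(=O)[O-]",   # fumarate
    "[O-]C(=O)/C=C\\C(=O)[O-]",  # maleate
    "OC(=O)CC(O)(CC(=O)[O-])C(=O)O",  # citrate (mono-anion)
    "[O-]C(=O)C(O)C(O)C(=O)[O-]",     # tartrate
]


def _canon(mol):
    return Chem.MolToSmiles(mol)


def _counterion_set():
    out = set()
    for s in _COUNTERION_SMILES:
        m = Chem.MolFromSmiles(s)
        if m is not None:
            out.add(_canon(m))
    return out


_COUNTERIONS = _counterion_set()
_UNCHARGER = rdMolStandardize.Uncharger()


def _has_carbon(mol):
    return any(a.GetAtomicNum() == 6 for a in mol.GetAtoms())


def standardize_one(smi, heavy_cap):
    if smi is None or not str(smi).strip():
        return {"status": "rejected", "reason": "unparsable"}
    mol = Chem.MolFromSmiles(str(smi))
    if mol is None:
        return {"status": "rejected", "reason": "unparsable"}
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) > 1:
        organics, strippable = [], []
        for f in frags:
            try:
                Chem.SanitizeMol(f)
            except Exception:
                return {"status": "rejected", "reason": "unparsable"}
            if not _has_carbon(f):
                strippable.append(f)
            elif _canon(f) in _COUNTERIONS:
                strippable.append(f)
            else:
                organics.append(f)
        if not organics:
            # salt of recognized ions only, or fully inorganic entry
            carbon_frags = [f for f in frags if _has_carbon(f)]
            if not carbon_frags:
                return {"status": "rejected", "reason": "inorganic"}
            organics = carbon_frags  # e.g. sodium acetate: keep the organic ion
        uniq = {}
        for f in organics:
            uniq[_canon(f)] = f
        if len(uniq) > 1:
            return {"status": "rejected", "reason": "mixture"}
        mol = next(iter(uniq.values()))
    if not _has_carbon(mol):
        return {"status": "rejected", "reason": "inorganic"}
    try:
        mol = rdMolStandardize.Normalize(mol)
        mol = _UNCHARGER.uncharge(mol)
        Chem.SanitizeMol(mol)
    except Exception:
        return {"status": "rejected", "reason": "unparsable"}
    if mol.GetNumHeavyAtoms() > heavy_cap:
        return {"status": "rejected", "reason": "large_organic"}
    return {"status": "ok", "std_smiles": _canon(mol)}


def op_standardize(payload):
    cap = int(payload.get("heavy_cap", HEAVY_ATOM_CAP_DEFAULT))
    return [standardize_one(s, cap) for s in payload["smiles"]]


def _mol_or_none(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(str(smi))


def op_fingerprints(payload):
    """On-bit indices (0-based) per molecule for ecfp4/morgan2 or maccs."""
    kind = payload["kind"]
    out = []
    for smi in payload["smiles"]:
        mol = _mol_or_none(smi)
        if mol is None:
            out.append(None)
            continue
        if kind in ("ecfp4", "morgan2"):
            nbits = int(payload.get("nbits", 2048))
            fp = AllChem.GetMorganFingerprintAsBitVect(
                mol, int(payload.get("radius", 2)), nBits=nbits)
            out.append(sorted(fp.GetOnBits()))
        elif kind == "maccs":
            fp = MACCSkeys.GenMACCSKeys(mol)
            out.append(sorted(fp.GetOnBits()))
        else:
            raise ValueError("unknown fingerprint kind: %s" % kind)
    return out


def op_descriptors(payload):
    """Full RDKit 2-D descriptor block; non-finite values emitted as null."""
    names = [n for n, _ in Descriptors.descList]
    rows = []
    for smi in payload["smiles"]:
        mol = _mol_or_none(smi)
        if mol is None:
            rows.append(None)
            continue
        vals = Descriptors.CalcMolDescriptors(mol)
        row = []
        for n in names:
            v = vals.get(n)
            try:
                v = float(v)
            except (TypeError, ValueError):
                v = None
            if v is not None and (v != v or v in (float("inf"), float("-inf"))):
                v = None
            row.append(v)
        rows.append(row)
    return {"names": names, "rows": rows}


def op_bit_atoms(payload):
    """For each molecule: n_atoms, on-bits, and per-atom list of owning bits.

    A bit belongs to an atom when the atom lies inside any circular
    environment that hashed to that bit (collision-shared bits belong to every
    owning atom's set).
    """
    radius = int(payload.get("radius", 2))
    nbits = int(payload.get("nbits", 2048))
    out = []
    for smi in payload["smiles"]:
        mol = _mol_or_none(smi)
        if mol is None:
            out.append(None)
            continue
        info = {}
        fp = AllChem.GetMorganFingerprintAsBitVect(
            mol, radius, nBits=nbits, bitInfo=info)
        atom_bits = [set() for _ in range(mol.GetNumAtoms())]
        for bit, envs in info.items():
            for center, rad in envs:
                if rad == 0:
                    atoms = {center}
                else:
                    env = Chem.FindAtomEnvironmentOfRadiusN(mol, rad, center)
                    atoms = {center}
                    for bidx in env:
                        b = mol.GetBondWithIdx(bidx)
                        atoms.add(b.GetBeginAtomIdx())
                        atoms.add(b.GetEndAtomIdx())
                for a in atoms:
                    atom_bits[a].add(bit)
        out.append({
            "n_atoms": mol.GetNumAtoms(),
            "symbols": [a.GetSymbol() for a in mol.GetAtoms()],
            "on_bits": sorted(fp.GetOnBits()),
            "atom_bits": [sorted(s) for s in atom_bits],
        })
    return out


def op_smarts(payload):
    """Match atom indices (0-based, union over matches) per smiles x pattern."""
    patts = []
    for p in payload["patterns"]:
        pm = Chem.MolFromSmarts(p)
        if pm is None:
            raise ValueError("bad SMARTS: %s" % p)
        patts.append(pm)
    out = []
    for smi in payload["smiles"]:
        mol = _mol_or_none(smi)
        if mol is None:
            out.append(None)
            continue
        res = []
        for pm in patts:
            matches = mol.GetSubstructMatches(pm)
            atoms = sorted({a for m in matches for a in m})
            res.append({"n_matches": len(matches), "atoms": atoms})
        out.append(res)
    return out


def op_embed(payload):
    """Seeded 2-D UMAP embedding of a binary matrix given as on-bit indices."""
    import numpy as np
    import umap

    n = int(payload["n"])
    ncol = int(payload["ncol"])
    X = np.zeros((n, ncol), dtype=np.float32)
    for i, bits in enumerate(payload["onbits"]):
        if bits:
            X[i, np.asarray(bits, dtype=int)] = 1.0
    nn = int(payload.get("n_neighbors", 15))
    nn = max(2, min(nn, n - 1))
    reducer = umap.UMAP(
        n_components=2,
        n_neighbors=nn,
        min_dist=float(payload.get("min_dist", 0.1)),
        metric=payload.get("metric", "jaccard"),
        random_state=int(payload["seed"]),
        n_jobs=1,
    )
    emb = reducer.fit_transform(X)
    return {"coords": [[float(a), float(b)] for a, b in emb]}


def op_depict(payload):
    """SVG depiction with per-atom diverging highlights.

    weight > 0 -> green (raises predicted sensitization probability),
    weight < 0 -> purple; intensity scales with |weight| (weights in [-1,1]).
    """
    from rdkit.Chem.Draw import rdMolDraw2D

    mol = _mol_or_none(payload["smiles"])
    if mol is None:
        raise ValueError("bad smiles for depiction")
    weights = payload["weights"]
    if len(weights) != mol.GetNumAtoms():
        raise ValueError("weight/atom count mismatch")
    AllChem.Compute2DCoords(mol)
    highlight, colors = [], {}
    for i, w in enumerate(weights):
        w = float(w)
        if w == 0:
            continue
        highlight.append(i)
        a = min(1.0, abs(w))
        if w > 0:   # green
            colors[i] = (1.0 - 0.8 * a, 1.0, 1.0 - 0.8 * a)
        else:       # purple
            colors[i] = (1.0 - 0.35 * a, 1.0 - 0.75 * a, 1.0 - 0.15 * a)
    d = rdMolDraw2D.MolDraw2DSVG(
        int(payload.get("width", 400)), int(payload.get("height", 350)))
    rdMolDraw2D.PrepareAndDrawMolecule(
        d, mol, highlightAtoms=highlight, highlightAtomColors=colors)
    d.FinishDrawing()
    with open(payload["out_file"], "w") as fh:
        fh.write(d.GetDrawingText())
    return {"written": payload["out_file"], "n_highlighted": len(highlight)}


OPS = {
    "standardize": op_standardize,
    "fingerprints": op_fingerprints,
    "descriptors": op_descriptors,
    "bit_atoms": op_bit_atoms,
    "smarts": op_smarts,
    "embed": op_embed,
    "depict": op_depict,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: chem_backend.py <op> <in.json> <out.json>\n")
        return 2
    op, inf, outf = argv[1], argv[2], argv[3]
    if op not in OPS:
        sys.stderr.write("unknown op: %s\n" % op)
        return 2
    with open(inf) as fh:
        payload = json.load(fh)
    result = OPS[op](payload)
    with open(outf, "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
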